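# Element and drug view augmentation; two-hop knowledge edges.

test_that("shared attributes become EE edges; 3-hop pairs get none", {
  ekg <- fx_ekg()
  ee <- two_hop_edges(ekg, c("C", "O"))
  ee_p2 <- ee[ee$type == "EE" & ee$intermediate == "Period2", ]
  expect_equal(nrow(ee_p2), 1L)  # C and O are both in Period 2
  expect_equal(ee_p2$feature[[1]], as.numeric(ekg$attributes["Period2", ]))
  # H reaches Sulfonamide only through >= 3 hops: no edge at all
  hs <- two_hop_edges(ekg, c("H", "Sulfonamide"))
  expect_equal(nrow(hs), 0L)
  # single active entity: no pairs, no self-loops
  expect_equal(nrow(two_hop_edges(ekg, "C")), 0L)
})

test_that("two-hop edge features recompute exactly from their intermediate", {
  ekg <- fx_ekg()
  df <- two_hop_edges(ekg, c("C", "N", "O", "Ester", "Amide"))
  expect_gt(nrow(df), 0)
  for (r in seq_len(nrow(df))) {
    if (!is.na(df$intermediate[r])) {
      want <- as.numeric(ekg$attributes[df$intermediate[r], ])
      expect_equal(df$feature[[r]][seq_along(want)], want)
    } else {
      expect_false(is.na(df$relation[r]))  # 1-hop edges carry a relation
      expect_equal(df$type[r], "EFu")
    }
  }
})

test_that("benzene element view adds one element node, AE pairs, no groups", {
  gem <- attach_element_view(fx_mol_graph("c1ccccc1"), fx_ekg())
  tc <- hmg_type_counts(gem)
  expect_equal(as.integer(tc$node_types["element"]), 1L)
  expect_false("functional_group" %in% names(tc$node_types))
  expect_equal(as.integer(tc$edge_types["AE"]), 12L)  # 6 pairs
  expect_equal(gem$view, "EM")
})

test_that("the ester-bearing fragments get FrFu pairs", {
  gem <- attach_element_view(fx_mol_graph("CC(=O)OC"), fx_ekg())
  expect_true("fg_Ester" %in% gem$nodes$id)
  frfu <- gem$edges[gem$edges$type == "FrFu" & gem$edges$dst == "fg_Ester", ]
  expect_gte(nrow(frfu), 1L)
})

test_that("element view adds at most 2 node and 5 edge types, M content unchanged", {
  for (smi in c("CC(=O)OC", "CS(=O)(=O)Nc1ccccc1", "CCOCC")) {
    gm <- fx_mol_graph(smi)
    gem <- attach_element_view(gm, fx_ekg())
    new_nt <- setdiff(unique(gem$nodes$type), unique(gm$nodes$type))
    new_et <- setdiff(unique(gem$edges$type), unique(gm$edges$type))
    expect_true(all(new_nt %in% c("element", "functional_group")))
    expect_lte(length(new_nt), 2L)
    expect_true(all(new_et %in% c("AE", "FrFu", "EE", "FuFu", "EFu")))
    expect_lte(length(new_et), 5L)
    # monotone containment by id
    expect_true(all(gm$nodes$id %in% gem$nodes$id))
    expect_true(all(gm$edges$id %in% gem$edges$id))
    expect_identical(gm$nodes, gem$nodes[seq_len(nrow(gm$nodes)), ])
  }
})

test_that("knowledge edges never span more than 2 KG hops", {
  ekg <- fx_ekg()
  # adjacency over triples, undirected
  adj <- function(id) {
    tr <- ekg$triples
    unique(c(tr$tail[tr$head == id], tr$head[tr$tail == id]))
  }
  for (smi in c("CC(=O)OC", "CC(=O)Nc1ccccc1")) {
    gem <- attach_element_view(fx_mol_graph(smi), ekg)
    ke <- gem$edges[gem$edges$type %in% c("EE", "FuFu", "EFu"), ]
    for (r in seq_len(nrow(ke))) {
      a <- gem$nodes$ref[match(ke$src[r], gem$nodes$id)]
      b <- gem$nodes$ref[match(ke$dst[r], gem$nodes$id)]
      if (is.na(ke$intermediate[r])) {
        expect_true(b %in% adj(a))            # 1 hop
      } else {
        expect_true(ke$intermediate[r] %in% adj(a))
        expect_true(ke$intermediate[r] %in% adj(b))  # exactly 2 hops
      }
    }
  }
})

test_that("elements missing from the KG are skipped with a warning", {
  tiny <- gen_element_kg(n_elements = 2, n_fgroups = 1, seed = 1)  # H, C
  gm <- fx_mol_graph("CCO")
  expect_warning(gem <- attach_element_view(gm, tiny),
                 class = "hmg_missing_element")
  els <- gem$nodes$ref[gem$nodes$type == "element"]
  expect_setequal(els, "C")
})

test_that("drug view adds one dnode and 2(A+F) directed hub edges", {
  dkg <- fx_dkg()
  did <- drug_entities(dkg)[1]
  gm <- fx_mol_graph("c1ccccc1")
  gdm <- attach_drug_view(gm, did, dkg)
  tc <- hmg_type_counts(gdm)
  expect_equal(as.integer(tc$node_types["dnode"]), 1L)
  expect_equal(as.integer(tc$edge_types["AD"]), 12L)
  expect_equal(as.integer(tc$edge_types["FrD"]), 2L)
  expect_equal(nrow(gdm$edges) - nrow(gm$edges), 14L)
  dn <- which(gdm$nodes$type == "dnode")
  expect_equal(gdm$node_features[[dn]], drug_embedding(dkg, did))
  expect_equal(gdm$view, "DM")
  expect_error(attach_drug_view(gm, "NOPE", dkg), class = "hmg_lookup_error")
})

test_that("view augmentation is order-stable (byte-identical rebuilds)", {
  a <- attach_element_view(fx_mol_graph("CC(=O)OC"), fx_ekg())
  b <- attach_element_view(fx_mol_graph("CC(=O)OC"), fx_ekg())
  expect_identical(a, b)
})
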