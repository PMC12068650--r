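# View augmentation: the element view (EM) attaches element and
# functional-group nodes from the elemental KG; the drug view (DM) attaches
# a single DNode carrying a drug-KG embedding. Knowledge-derived EE / FuFu /
# EFu edges materialize 2-hop KG paths (feature = the intermediate entity's
# attribute vector) and direct element-functional-group relations (feature =
# relation one-hot); nothing beyond 2 KG hops enters the graph.

#' Two-hop and direct knowledge edges among chemical-level entities
#'
#' For every unordered pair of active entities, one edge is emitted per
#' length-2 path between them in the element KG (parallel edges for
#' multiple shared intermediates), typed EE (element-element), FuFu
#' (functional group pair) or EFu (mixed). Direct element-functional-group
#' triples are also emitted as 1-hop EFu edges with relation-derived
#' features. No self-loops; no edge spans more than two KG hops.
#'
#' @param ekg an `element_kg`.
#' @param active_entities character vector of chemical-level entity ids.
#' @return data frame with columns `a`, `b`, `type`, `intermediate`,
#'   `relation` and a `feature` list-column.
#' @export
two_hop_edges <- function(ekg, active_entities) {
  active_entities <- unique(active_entities)
  chem <- chemical_entities(ekg)
  assert_that(all(active_entities %in% chem), "hmg_argument_error",
              "active entities must be chemical-level element-KG entities")
  kind <- stats::setNames(ekg$entities$kind, ekg$entities$id)
  pair_type <- function(x, y) {
    kx <- kind[[x]]; ky <- kind[[y]]
    if (kx == "element" && ky == "element") "EE"
    else if (kx == "functional_group" && ky == "functional_group") "FuFu"
    else "EFu"
  }
  efu_dim <- EKG_ATTR_DIM + length(ELEMENT_KG_RELATIONS)

  out <- list()
  acts <- sort(active_entities)
  nbrs <- lapply(acts, function(x) kg_neighbors(ekg, x))
  names(nbrs) <- acts
  if (length(acts) >= 2) {
    for (xi in seq_len(length(acts) - 1)) {
      for (yi in (xi + 1):length(acts)) {
        x <- acts[xi]; y <- acts[yi]
        ty <- pair_type(x, y)
        common <- sort(intersect(setdiff(nbrs[[x]]$nbr, c(x, y)),
                                 setdiff(nbrs[[y]]$nbr, c(x, y))))
        for (m in common) {
          feat <- as.numeric(ekg$attributes[m, ])
          if (ty == "EFu") feat <- c(feat, numeric(length(ELEMENT_KG_RELATIONS)))
          out[[length(out) + 1]] <- list(a = x, b = y, type = ty,
                                         intermediate = m,
                                         relation = NA_character_,
                                         feature = feat)
        }
        # direct 1-hop relations between mixed element / functional-group pairs
        if (ty == "EFu") {
          tr <- ekg$triples
          direct <- tr[(tr$head == x & tr$tail == y) |
                         (tr$head == y & tr$tail == x), , drop = FALSE]
          for (r in seq_len(nrow(direct))) {
            feat <- c(numeric(EKG_ATTR_DIM),
                      one_hot(direct$relation[r], ELEMENT_KG_RELATIONS))
            out[[length(out) + 1]] <- list(a = x, b = y, type = ty,
                                           intermediate = NA_character_,
                                           relation = direct$relation[r],
                                           feature = feat)
          }
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(a = character(0), b = character(0), type = character(0),
                      intermediate = character(0), relation = character(0),
                      feature = I(list())))
  }
  df <- data.frame(
    a = vapply(out, `[[`, "", "a"),
    b = vapply(out, `[[`, "", "b"),
    type = vapply(out, `[[`, "", "type"),
    intermediate = vapply(out, `[[`, "", "intermediate"),
    relation = vapply(out, `[[`, "", "relation"),
    stringsAsFactors = FALSE
  )
  df$feature <- I(lapply(out, `[[`, "feature"))
  df
}

# append new nodes/edges to a featurized graph, keeping existing ids stable
# and inserting the additions in canonical (type, id) order
append_to_graph <- function(g, new_nodes, new_node_features, new_edges,
                            new_edge_features, view) {
  if (nrow(new_nodes) > 0) {
    no <- order(.node_rank[new_nodes$type], new_nodes$id)
    new_nodes <- new_nodes[no, , drop = FALSE]
    new_node_features <- new_node_features[no]
    g$nodes <- rbind(g$nodes, new_nodes)
    rownames(g$nodes) <- NULL
    g$node_features <- c(g$node_features, new_node_features)
    g$pos <- rbind(g$pos, matrix(0, nrow(new_nodes), ncol(g$pos)))
  }
  if (nrow(new_edges) > 0) {
    eo <- order(.edge_rank[new_edges$type], new_edges$src, new_edges$dst,
                new_edges$intermediate)
    new_edges <- new_edges[eo, , drop = FALSE]
    new_edge_features <- new_edge_features[eo]
    start <- nrow(g$edges)
    new_edges <- cbind(id = pad_id("e", start + seq_len(nrow(new_edges))),
                       new_edges, stringsAsFactors = FALSE)
    g$edges <- rbind(g$edges, new_edges)
    rownames(g$edges) <- NULL
    g$edge_features <- c(g$edge_features, new_edge_features)
  }
  g$view <- view
  validate_hmgraph(g)
  g
}

both_directions <- function(base, features) {
  rev <- base; rev$src <- base$dst; rev$dst <- base$src
  list(edges = rbind(base, rev), features = c(features, features))
}

#' Augment a molecule view into the element view
#'
#' Adds one element node per distinct chemical symbol of the molecule that
#' exists in the KG (AE edge pairs to all matching atoms), one functional-
#' group node per KG group whose SMARTS matches inside a BRICS fragment
#' (FrFu edge pairs to that fragment), and EE/FuFu/EFu knowledge edges
#' among the added entities. Symbols absent from the KG are skipped with a
#' warning. The molecule-view content is unchanged (ids stable).
#'
#' @param gm a featurized molecule-view `hmgraph`.
#' @param ekg an `element_kg`.
#' @return an `hmgraph` with view tag `"EM"`.
#' @export
attach_element_view <- function(gm, ekg) {
  assert_that(gm$view == "M", "hmg_argument_error",
              "attach_element_view expects a molecule view")
  assert_that(has_features(gm), "hmg_argument_error",
              "attach_element_view expects a featurized graph")
  mol <- parse_smiles(gm$smiles)
  fmap <- brics_fragments(mol)
  ent <- ekg$entities
  kg_symbols <- ent$symbol[ent$kind == "element"]

  syms <- unique(mol$atoms$symbol)
  missing <- setdiff(syms, kg_symbols)
  if (length(missing) > 0) {
    hmg_warn("hmg_missing_element",
             sprintf("element(s) %s not in the element KG; skipped",
                     paste(missing, collapse = ",")))
    syms <- setdiff(syms, missing)
  }
  syms <- sort(syms)

  atom_rows <- which(gm$nodes$type == "atom")
  atom_ids <- gm$nodes$id[atom_rows]
  atom_sym <- mol$atoms$symbol[as.integer(gm$nodes$ref[atom_rows])]
  frag_rows <- which(gm$nodes$type == "fragment")
  frag_ids <- stats::setNames(gm$nodes$id[frag_rows],
                              gm$nodes$ref[frag_rows])

  new_nodes <- list(); new_feats <- list()
  base_edges <- list(); base_feats <- list()

  for (s in syms) {
    nid <- paste0("el_", s)
    new_nodes[[length(new_nodes) + 1]] <- data.frame(
      id = nid, type = "element", ref = s, stringsAsFactors = FALSE)
    new_feats[[length(new_feats) + 1]] <-
      c(one_hot(s, PERIODIC_TABLE$symbol), as.numeric(ekg$attributes[s, ]))
    for (aid in atom_ids[atom_sym == s]) {
      base_edges[[length(base_edges) + 1]] <- data.frame(
        src = aid, dst = nid, type = "AE", intermediate = NA_character_,
        relation = NA_character_, ref = NA_character_)
      base_feats[[length(base_feats) + 1]] <- hub_relation_feature("AE")
    }
  }

  # A fragment bears a functional group iff removing the fragment's atoms
  # strictly reduces the whole-molecule SMARTS match count. This locates
  # matches per fragment using only match counts and correctly credits
  # groups that span a BRICS cut (e.g. an ester) to the fragments involved.
  fgs <- ent[ent$kind == "functional_group", , drop = FALSE]
  active_fgs <- character(0)
  all_atoms <- seq_len(nrow(mol$atoms))
  for (k in seq_len(nrow(fgs))) {
    c0 <- tryCatch(
      suppressWarnings(smarts_match_count(mol, fgs$smarts[k])),
      error = function(e) 0L)
    if (is.na(c0) || c0 == 0) next
    hit_frags <- integer(0)
    for (f in seq_len(fmap$n_fragments)) {
      rest <- setdiff(all_atoms, which(fmap$fragment_id == f))
      cf <- if (length(rest) == 0) 0L else tryCatch(
        suppressWarnings(smarts_match_count(mol, fgs$smarts[k], rest)),
        error = function(e) c0)
      if (!is.na(cf) && cf < c0) hit_frags <- c(hit_frags, f)
    }
    if (length(hit_frags) == 0) next
    nid <- paste0("fg_", fgs$id[k])
    active_fgs <- c(active_fgs, fgs$id[k])
    new_nodes[[length(new_nodes) + 1]] <- data.frame(
      id = nid, type = "functional_group", ref = fgs$id[k],
      stringsAsFactors = FALSE)
    new_feats[[length(new_feats) + 1]] <- as.numeric(ekg$attributes[fgs$id[k], ])
    for (f in hit_frags) {
      base_edges[[length(base_edges) + 1]] <- data.frame(
        src = frag_ids[[as.character(f)]], dst = nid, type = "FrFu",
        intermediate = NA_character_, relation = NA_character_,
        ref = NA_character_)
      base_feats[[length(base_feats) + 1]] <- hub_relation_feature("FrFu")
    }
  }

  active <- c(syms, active_fgs)
  node_id_of <- function(entity) {
    if (entity %in% syms) paste0("el_", entity) else paste0("fg_", entity)
  }
  if (length(active) > 0) {
    kge <- two_hop_edges(ekg, active)
    for (r in seq_len(nrow(kge))) {
      base_edges[[length(base_edges) + 1]] <- data.frame(
        src = node_id_of(kge$a[r]), dst = node_id_of(kge$b[r]),
        type = kge$type[r], intermediate = kge$intermediate[r],
        relation = kge$relation[r], ref = NA_character_)
      base_feats[[length(base_feats) + 1]] <- kge$feature[[r]]
    }
  }

  new_nodes <- if (length(new_nodes)) do.call(rbind, new_nodes) else
    data.frame(id = character(0), type = character(0), ref = character(0))
  if (length(base_edges)) {
    bd <- both_directions(do.call(rbind, base_edges), base_feats)
  } else {
    bd <- list(edges = data.frame(src = character(0), dst = character(0),
                                  type = character(0),
                                  intermediate = character(0),
                                  relation = character(0), ref = character(0)),
               features = list())
  }
  append_to_graph(gm, new_nodes, new_feats, bd$edges, bd$features, "EM")
}

#' Augment a molecule view into the drug view
#'
#' Adds exactly one DNode whose raw feature is the drug-KG embedding of
#' `drug_id`, with an AD edge pair to every atom node and an FrD edge pair
#' to every fragment node.
#'
#' @param gm a featurized molecule-view `hmgraph`.
#' @param drug_id a drug entity id with an embedding in `dkg`.
#' @param dkg a `drug_kg`.
#' @return an `hmgraph` with view tag `"DM"`.
#' @export
attach_drug_view <- function(gm, drug_id, dkg) {
  assert_that(gm$view == "M", "hmg_argument_error",
              "attach_drug_view expects a molecule view")
  assert_that(has_features(gm), "hmg_argument_error",
              "attach_drug_view expects a featurized graph")
  emb <- drug_embedding(dkg, drug_id)

  new_nodes <- data.frame(id = "dnode", type = "dnode", ref = drug_id,
                          stringsAsFactors = FALSE)
  base_edges <- list(); base_feats <- list()
  for (i in seq_len(nrow(gm$nodes))) {
    ty <- gm$nodes$type[i]
    if (ty == "atom") {
      et <- "AD"
    } else if (ty == "fragment") {
      et <- "FrD"
    } else next
    base_edges[[length(base_edges) + 1]] <- data.frame(
      src = gm$nodes$id[i], dst = "dnode", type = et,
      intermediate = NA_character_, relation = NA_character_,
      ref = NA_character_)
    base_feats[[length(base_feats) + 1]] <- hub_relation_feature(et)
  }
  bd <- both_directions(do.call(rbind, base_edges), base_feats)
  append_to_graph(gm, new_nodes, list(emb), bd$edges, bd$features, "DM")
}
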