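# View-batch assembly, pre-training step, prediction heads, attention
# export, fine-tuning.

fx_vb <- function() {
  if (is.null(fx$vb)) {
    dkg <- fx_dkg()
    pool <- fx_pool()
    sp <- split_pool(pool)
    plan <- make_batches(sp$s_m, sp$s_d, N = 10, n = 1, seed = 5)
    fx$vb <- build_view_batch(plan$batches[[1]], fx_ekg(), dkg)
  }
  fx$vb
}

test_that("view batches are aligned (N, N, M) with monotone element views", {
  vb <- fx_vb()
  expect_equal(vb$N, 10L)
  expect_equal(vb$M, 3L)
  expect_length(vb$graphs_m, 10L)
  expect_length(vb$graphs_em, 10L)
  expect_length(vb$graphs_dm, 3L)
  for (i in seq_len(vb$N)) {
    expect_gte(nrow(vb$graphs_em[[i]]$nodes), nrow(vb$graphs_m[[i]]$nodes))
  }
  # drug views correspond to the trailing drug records
  drugs <- vb$records$drug_id[vb$records$is_drug]
  dn <- vapply(vb$graphs_dm, function(g)
    g$nodes$ref[g$nodes$type == "dnode"], character(1))
  expect_equal(dn, drugs)
})

test_that("an all-non-drug batch warns and yields (N, N, 0)", {
  recs <- data.frame(smiles = c("CCO", "c1ccccc1"), drug_id = NA_character_,
                     is_drug = FALSE)
  expect_warning(vb <- build_view_batch(recs, fx_ekg(), fx_dkg()),
                 class = "hmg_degenerate_batch")
  expect_equal(c(vb$N, vb$M), c(2L, 0L))
})

test_that("a bad record aborts the batch naming it", {
  recs <- data.frame(smiles = c("CCO", "C(((("), drug_id = NA_character_,
                     is_drug = FALSE)
  err <- tryCatch(suppressWarnings(build_view_batch(recs, fx_ekg(), fx_dkg())),
                  error = identity)
  expect_s3_class(err, "hmg_batch_error")
  expect_match(conditionMessage(err), "record 2")
})

test_that("pretrain_step is deterministic and composes with total_loss", {
  vb <- fx_vb()
  ep <- encoder_params(d = 8, K = 2, L = 1, seed = 2)
  pp <- projector_params(8, seed = 3)
  t0 <- Sys.time()
  s1 <- pretrain_step(vb, ep, pp)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 10)
  s2 <- pretrain_step(vb, ep, pp)
  expect_equal(s1$loss, s2$loss, tolerance = 1e-7)
  tl <- total_loss(s1$z)
  expect_equal(s1$loss, tl$total, tolerance = 1e-10)
  expect_equal(unname(s1$terms), unname(tl$terms), tolerance = 1e-10)
  expect_true(all(is.finite(unlist(s1$grads$encoder))))
})

test_that("property prediction: constant head, invariance, compositionality", {
  g <- fx_mol_graph("CC(=O)OC")
  ep <- encoder_params(d = 8, K = 2, L = 1, seed = 4)
  head <- predictor_head(8, width = 4, d_out = 1, seed = 1)
  zero <- head
  zero$W1 <- zero$W1 * 0; zero$W2 <- zero$W2 * 0
  zero$b2 <- matrix(3.5, 1, 1)
  expect_equal(predict_property(g, ep, zero), 3.5)
  manual <- as.numeric(hmglearn:::head_predict(encode(g, ep)$h_g, head))
  expect_equal(predict_property(g, ep, head), manual)
  gp <- permute_graph(g, 3)
  expect_equal(predict_property(gp, ep, head),
               predict_property(g, ep, head), tolerance = 1e-8)
  expect_error(predict_property(g, ep, predictor_head(9)),
               class = "hmg_schema_error")
})

test_that("DDI prediction is order-sensitive but respects constructed symmetry", {
  g1 <- fx_mol_graph("CC(=O)OC")
  g2 <- fx_mol_graph("c1ccccc1")
  ep <- encoder_params(d = 8, K = 2, L = 1, seed = 4)
  head <- predictor_head(16, width = 4, d_out = 1, seed = 6)
  p12 <- predict_ddi(g1, g2, ep, head)
  p21 <- predict_ddi(g2, g1, ep, head)
  expect_false(isTRUE(all.equal(p12, p21)))
  # a head reading only the difference of the two halves returns 0 on a == b
  diff_head <- predictor_head(16, width = 8, d_out = 1, seed = 1)
  diff_head$W1 <- rbind(diag(8), -diag(8))
  diff_head$b1 <- matrix(0, 1, 8)
  diff_head$b2 <- matrix(0, 1, 1)
  expect_equal(predict_ddi(g1, g1, ep, diff_head), 0)
  manual <- as.numeric(hmglearn:::head_predict(
    c(encode(g1, ep)$h_g, encode(g2, ep)$h_g), head))
  expect_equal(p12, manual)
  expect_error(predict_ddi(g1, g2, ep, predictor_head(8)),
               class = "hmg_schema_error")
})

test_that("attention export normalizes weights within each node type", {
  g <- attach_element_view(fx_mol_graph("CC(=O)OC"), fx_ekg())
  ep <- encoder_params(d = 8, K = 2, L = 1, seed = 9)
  w1 <- export_attention(g, ep)
  w2 <- export_attention(g, ep)
  expect_identical(w1, w2)
  for (ty in names(w1)) {
    expect_true(all(w1[[ty]] >= 0))
    s <- sum(w1[[ty]])
    expect_true(abs(s - 1) < 1e-6 || s == 0)
    ids <- g$nodes$id[g$nodes$type == ty]
    expect_setequal(names(w1[[ty]]), ids)
  }
  retained <- vapply(w1, function(x) sum(x) > 0, logical(1))
  expect_gte(sum(retained), 1L)
  single <- w1[vapply(w1, length, integer(1)) == 1 & retained]
  for (x in single) expect_equal(unname(x), 1)
})

test_that("a nitrogen-count regression is learnable within 200 epochs", {
  smis <- c("c1ccccc1", "CCN", "CCCN", "NCCN", "c1ccncc1", "CCN(CC)CC",
            "CC(=O)NC", "N#Cc1ccccc1", "CC#N", "NC(=O)c1ccccc1",
            "c1ccccc1N", "CCCC", "CCO", "C1CCNCC1", "CNC(=O)c1ccccc1",
            "CCOCC", "Nc1ccncc1", "CCNC", "NCCCN", "CN")
  labels <- vapply(smis, function(s) sum(parse_smiles(s)$atoms$symbol == "N"),
                   numeric(1))
  ds <- data.frame(smiles = smis, label = as.numeric(labels))
  ep <- encoder_params(d = 16, K = 4, L = 2, seed = 8)
  ft <- finetune(ds, ep, kind = "regression", epochs = 200, lr = 1e-2,
                 freeze_encoder = FALSE, seed = 5)
  expect_lt(tail(ft$metrics$metric, 1), 0.5)
  fx$nitrogen_rmse <- tail(ft$metrics$metric, 1)
})

test_that("frozen fine-tuning leaves encoder weights untouched, unfrozen moves them", {
  ds <- data.frame(smiles = c("CCO", "CCN", "c1ccccc1", "CCCC"),
                   label = c(0, 1, 0, 0))
  ep <- encoder_params(d = 8, K = 2, L = 1, seed = 3)
  hash <- function(p) digest_params(p)
  digest_params <- function(p) {
    f <- hmglearn:::flatten_params(p)
    f$readout.ws <- NULL; f$readout.bs <- NULL  # readout is task-rebuilt
    sum(vapply(f, function(m) sum(m * seq_along(m)), numeric(1)))
  }
  ft <- finetune(ds, ep, kind = "binary", epochs = 3, lr = 1e-2, seed = 1)
  expect_equal(digest_params(ft$enc_params), digest_params(ep))
  ft2 <- finetune(ds, ep, kind = "binary", epochs = 3, lr = 1e-2,
                  freeze_encoder = FALSE, seed = 1)
  expect_false(isTRUE(all.equal(digest_params(ft2$enc_params),
                                digest_params(ep))))
})

test_that("fine-tuning is reproducible under a fixed seed", {
  ds <- data.frame(smiles = c("CCO", "CCN", "c1ccccc1", "CCCC"),
                   label = c(0, 1, 0, 0))
  ep <- encoder_params(d = 8, K = 2, L = 1, seed = 3)
  a <- finetune(ds, ep, kind = "binary", epochs = 5, seed = 2)
  b <- finetune(ds, ep, kind = "binary", epochs = 5, seed = 2)
  expect_equal(tail(a$metrics$loss, 1), tail(b$metrics$loss, 1),
               tolerance = 1e-6)
  expect_error(finetune(ds, ep, kind = "nope"), class = "hmg_schema_error")
  bad <- ds; bad$label <- c(0.5, 1, 0, 0)
  expect_error(finetune(bad, ep, kind = "binary"), class = "hmg_schema_error")
})

test_that("cross-view alignment emerges from pre-training", {
  # after pre-training, a molecule's projected molecule-view embedding
  # should be closer to its own element view than to any other distinct
  # molecule's element view in the same batch (the pairs the loss
  # optimizes); template pools may repeat a molecule, and a duplicate's
  # element view is legitimately tied, so duplicates are excluded
  dkg <- fx_dkg()
  pool <- gen_molecule_pool(30, 0.3, dkg, seed = 61)
  res <- pretrain(pool, fx_ekg(), dkg, steps = 200, N = 10, n = 1,
                  lr = 1e-3, seed = 62,
                  enc_params = encoder_params(d = 16, K = 2, L = 1, seed = 62),
                  proj_params = projector_params(16, seed = 63))
  sp <- split_pool(pool)
  plan <- make_batches(sp$s_m, sp$s_d, N = 10, n = 1, seed = 62)
  hits <- logical(0)
  for (b in plan$batches) {
    vb <- build_view_batch(b, fx_ekg(), dkg)
    st <- pretrain_step(vb, res$enc_params, res$proj_params)
    S <- st$z$z_m %*% t(st$z$z_em)
    for (i in seq_len(nrow(S))) {
      distinct <- which(b$smiles != b$smiles[i])
      hits <- c(hits, all(S[i, distinct] < S[i, i]))
    }
  }
  expect_gte(mean(hits), 0.8)
})
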