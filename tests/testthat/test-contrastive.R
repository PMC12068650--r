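# Projector and cross-view contrastive loss: closed forms, enumeration
# oracle, pair accounting, symmetry, monotonicity, gradient sanity.

test_that("projected rows are unit norm; zero depth is identity plus norm", {
  set.seed(1)
  h <- matrix(rnorm(20), 4, 5)
  pp <- projector_params(5, depth = 2, seed = 2)
  z <- project(h, pp)
  expect_lt(max(abs(sqrt(rowSums(z^2)) - 1)), 1e-6)
  h2 <- rbind(h[1, ], h[1, ])
  z2 <- project(h2, pp)
  expect_equal(z2[1, ], z2[2, ])
  p0 <- projector_params(5, depth = 0)
  expect_equal(project(h, p0), unit_rows(h))
})

test_that("all-identical M = N = 2 rows at tau 1 give loss log 2", {
  z <- matrix(rep(c(1, 0, 0), 2), 2, 3, byrow = TRUE)
  cfg <- contrastive_config(tau = 1)
  expect_equal(pair_loss(z, z, 1, cfg), log(2), tolerance = 1e-12)
  expect_equal(pair_loss(z, z, 2, cfg), log(2), tolerance = 1e-12)
  expect_equal(view_pair_loss(z, z, cfg), 2 * log(2), tolerance = 1e-12)
})

test_that("pair_loss matches the term-by-term enumeration oracle", {
  set.seed(7)
  cfg <- contrastive_config(tau = 0.37)
  z1 <- unit_rows(matrix(rnorm(9), 3, 3))
  z2 <- unit_rows(matrix(rnorm(15), 5, 3))
  for (i in 1:3) {
    orc <- pair_loss_oracle(z1, z2, i, cfg$tau)
    expect_equal(pair_loss(z1, z2, i, cfg), orc$loss, tolerance = 1e-8)
    expect_equal(orc$n_terms, 3 + 5 - 2)
    orc2 <- pair_loss_oracle(z2, z1, i, cfg$tau)
    expect_equal(pair_loss(z2, z1, i, cfg), orc2$loss, tolerance = 1e-8)
  }
  # directedness: the two directions generally differ
  expect_false(isTRUE(all.equal(pair_loss(z1, z2, 1, cfg),
                                pair_loss(z2, z1, 1, cfg))))
})

test_that("denominator term count equals the pair accounting over a grid", {
  set.seed(3)
  for (M in 1:6) {
    for (N in M:8) {
      pc <- pair_counts(M, N)
      expect_equal(unname(pc), c(M, M - 1, N - 1))
      if (M + N - 2 == 0) next
      z1 <- unit_rows(matrix(rnorm(M * 4), M, 4))
      z2 <- unit_rows(matrix(rnorm(N * 4), N, 4))
      orc <- pair_loss_oracle(z1, z2, 1, 0.5)
      expect_equal(orc$n_terms,
                   unname(pc["inter_negatives"] + pc["intra_negatives"]))
    }
  }
  expect_error(pair_counts(5, 3), class = "hmg_argument_error")
})

test_that("view_pair_loss is symmetric while the directed loss is not", {
  set.seed(11)
  z1 <- unit_rows(matrix(rnorm(12), 4, 3))
  z2 <- unit_rows(matrix(rnorm(6), 2, 3))
  cfg <- contrastive_config(tau = 0.2)
  expect_equal(view_pair_loss(z1, z2, cfg), view_pair_loss(z2, z1, cfg),
               tolerance = 1e-12)
  e <- matrix(numeric(0), 0, 3)
  expect_warning(v <- view_pair_loss(z1, e, cfg),
                 class = "hmg_degenerate_batch")
  expect_equal(v, 0)
})

test_that("sharpening the positive drives the loss toward 0; monotonicity holds", {
  # anchor with a strictly best-matching positive
  z1 <- unit_rows(rbind(c(1, 0), c(0, 1)))
  z2 <- unit_rows(rbind(c(1, 0.05), c(-0.7, 0.9)))
  l_tau <- vapply(c(0.5, 0.1, 0.02),
                  function(tau) pair_loss(z1, z2, 1,
                                          contrastive_config(tau = tau)),
                  numeric(1))
  expect_true(all(diff(l_tau) < 0))
  expect_lt(l_tau[3], 1e-4)
  # raising the positive similarity strictly decreases the loss
  mk <- function(a) unit_rows(rbind(c(cos(a), sin(a)), c(0, -1)))
  ls <- vapply(c(1.2, 0.8, 0.4, 0.1),
               function(a) pair_loss(z1, mk(a), 1, contrastive_config()),
               numeric(1))
  expect_true(all(diff(ls) < 0))
})

test_that("total_loss composes the three pairwise terms and is positive", {
  set.seed(5)
  N <- 6; M <- 2
  zm <- unit_rows(matrix(rnorm(N * 4), N, 4))
  zem <- unit_rows(matrix(rnorm(N * 4), N, 4))
  zdm <- unit_rows(matrix(rnorm(M * 4), M, 4))
  cfg <- contrastive_config()
  tl <- total_loss(list(z_m = zm, z_em = zem, z_dm = zdm), cfg)
  expect_equal(tl$total,
               view_pair_loss(zm, zem, cfg) + view_pair_loss(zm, zdm, cfg) +
                 view_pair_loss(zem, zdm, cfg), tolerance = 1e-12)
  # brute force: every term enumerated independently
  brute_vp <- function(a, b) {
    Mm <- min(nrow(a), nrow(b))
    mean(vapply(1:Mm, function(i) pair_loss_oracle(a, b, i, cfg$tau)$loss,
                numeric(1))) +
      mean(vapply(1:Mm, function(i) pair_loss_oracle(b, a, i, cfg$tau)$loss,
                  numeric(1)))
  }
  expect_equal(tl$total, brute_vp(zm, zem) + brute_vp(zm, zdm) +
                 brute_vp(zem, zdm), tolerance = 1e-8)
  expect_true(all(vapply(1:M, function(i)
    pair_loss(zm, zdm, i, cfg) > 0, logical(1))))
  # M = 0: only the molecule/element term remains
  e <- matrix(numeric(0), 0, 4)
  # both drug-view terms are degenerate, so two warnings are raised
  expect_warning(expect_warning(
    t0 <- total_loss(list(z_m = zm, z_em = zem, z_dm = e), cfg),
    class = "hmg_degenerate_batch"), class = "hmg_degenerate_batch")
  expect_equal(t0$total, view_pair_loss(zm, zem, cfg))
})

test_that("degenerate and out-of-range anchors are rejected", {
  z <- matrix(c(1, 0), 1, 2)
  expect_error(pair_loss(z, z, 1), class = "hmg_degenerate_error")
  z2 <- unit_rows(matrix(rnorm(6), 3, 2))
  expect_error(pair_loss(z2, z2, 7), class = "hmg_index_error")
})

test_that("tape loss gradients pass a finite-difference spot check", {
  ekg <- fx_ekg(); dkg <- fx_dkg()
  recs <- data.frame(
    smiles = c("c1ccccc1", "CCO", "CC(=O)OC"),
    drug_id = c(NA, NA, drug_entities(dkg)[1]),
    is_drug = c(FALSE, FALSE, TRUE), stringsAsFactors = FALSE)
  vb <- build_view_batch(recs, ekg, dkg)
  ep <- encoder_params(d = 4, K = 1, L = 1, seed = 2)
  pp <- projector_params(4, seed = 3)
  cfg <- contrastive_config()
  st <- pretrain_step(vb, ep, pp, cfg)
  loss_at <- function(ep2, pp2) pretrain_step(vb, ep2, pp2, cfg)$loss
  eps <- 1e-5
  flat_e <- hmglearn:::flatten_params(ep)
  flat_p <- hmglearn:::flatten_params(pp)
  # five coordinates across encoder and projector parameter matrices
  probes <- list(
    list(where = "enc", name = "A.atom", idx = c(2, 2)),
    list(where = "enc", name = "layers.l1.WQ.1", idx = c(2, 2)),
    list(where = "enc", name = "readout.ws", idx = c(1, 1)),
    list(where = "enc", name = "Wdelta_e.bond", idx = c(1, 2)),
    list(where = "proj", name = "W2", idx = c(2, 3))
  )
  checked_nonzero <- 0L
  for (pr in probes) {
    bump <- function(sign) {
      fe <- flat_e; fp <- flat_p
      if (pr$where == "enc") {
        fe[[pr$name]][pr$idx[1], pr$idx[2]] <-
          fe[[pr$name]][pr$idx[1], pr$idx[2]] + sign * eps
      } else {
        fp[[pr$name]][pr$idx[1], pr$idx[2]] <-
          fp[[pr$name]][pr$idx[1], pr$idx[2]] + sign * eps
      }
      loss_at(hmglearn:::unflatten_params(ep, fe),
              hmglearn:::unflatten_params(pp, fp))
    }
    fd <- (bump(1) - bump(-1)) / (2 * eps)
    gmat <- if (pr$where == "enc") st$grads$encoder[[pr$name]] else
      st$grads$projector[[pr$name]]
    expect_true(is.finite(fd))
    expect_lt(abs(gmat[pr$idx[1], pr$idx[2]] - fd), 1e-4)
    if (abs(fd) > 1e-8) checked_nonzero <- checked_nonzero + 1L
  }
  expect_gte(checked_nonzero, 3L)
})
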