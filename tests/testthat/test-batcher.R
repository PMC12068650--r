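# Drug-aware batch generation: fingerprints, constrained clustering,
# Algorithm-style batch assembly with disjoint nearest-neighbor complements.

test_that("molecule features are deterministic and structure-sensitive", {
  recs <- data.frame(smiles = c("c1ccccc1", "c1ccccc1", "CCCCCC"),
                     drug_id = NA_character_)
  fm <- molecule_features(recs)
  expect_equal(fm[1, ], fm[2, ])
  expect_gt(sum(fm[1, ] != fm[3, ]), 0)
  expect_equal(nrow(molecule_features(recs[0, , drop = FALSE])), 0L)
})

test_that("constrained k-means recovers two well-separated blobs exactly", {
  set.seed(4)
  blob1 <- matrix(rnorm(7 * 3, mean = 0, sd = 0.05), 7, 3)
  blob2 <- matrix(rnorm(7 * 3, mean = 5, sd = 0.05), 7, 3)
  X <- rbind(blob1, blob2)
  km <- constrained_kmeans(X, 7, seed = 1)
  a <- km$assignment
  expect_true(all(a[1:7] == a[1]))
  expect_true(all(a[8:14] == a[8]))
  expect_true(a[1] != a[8])
  expect_equal(as.integer(table(a)), c(7L, 7L))
  # exhaustive check on this instance: no other balanced split has lower cost
  cost <- function(assign) {
    sum(vapply(unique(assign), function(c) {
      mem <- X[assign == c, , drop = FALSE]
      sum(sweep(mem, 2, colMeans(mem))^2)
    }, numeric(1)))
  }
  best <- cost(a)
  combs <- combn(14, 7)
  for (j in seq_len(ncol(combs))) {
    alt <- rep(2L, 14); alt[combs[, j]] <- 1L
    expect_gte(cost(alt) + 1e-9, best)
  }
})

test_that("k-means boundaries: one big cluster, leftovers dropped, determinism", {
  set.seed(5)
  X <- matrix(rnorm(30), 10, 3)
  km <- constrained_kmeans(X, 10, seed = 2)
  expect_true(all(km$assignment == 1))
  expect_warning(km2 <- constrained_kmeans(X, 4, seed = 2),
                 class = "hmg_dropped_rows")
  expect_equal(sum(!is.na(km2$assignment)), 8L)
  expect_length(km2$dropped, 2L)
  km3a <- suppressWarnings(constrained_kmeans(X, 4, seed = 9))
  km3b <- suppressWarnings(constrained_kmeans(X, 4, seed = 9))
  expect_identical(km3a, km3b)
  expect_error(constrained_kmeans(X, 11), class = "hmg_argument_error")
})

test_that("batches are 70/30 with trailing drugs and disjoint NN complements", {
  dkg <- gen_drug_kg(n_drugs = 30, n_other_entities = 10, seed = 21)
  pool <- gen_molecule_pool(100, 0.3, dkg, seed = 22)
  sp <- split_pool(pool)
  expect_equal(nrow(sp$s_m), 70L)
  expect_equal(nrow(sp$s_d), 30L)
  plan <- make_batches(sp$s_m, sp$s_d, N = 10, n = 1, seed = 23)
  expect_length(plan$batches, 10L)
  all_nn <- integer(0)
  for (b in plan$batches) {
    expect_equal(nrow(b), 10L)
    expect_equal(sum(!b$is_drug), 7L)
    expect_equal(sum(b$is_drug), 3L)
    expect_true(all(diff(b$is_drug) >= 0))  # drugs occupy trailing slots
    expect_false(any(duplicated(
      paste(b$smiles, b$drug_id)[b$is_drug])))  # no repeats within a batch
  }
  # NN complements: 2 per batch, globally disjoint
  expect_length(plan$used_drugs, 20L)
  expect_false(any(duplicated(plan$used_drugs)))
})

test_that("n at the drug-slot boundary skips the NN step entirely", {
  dkg <- fx_dkg()
  pool <- gen_molecule_pool(30, 0.3, dkg, seed = 31)
  sp <- split_pool(pool)
  plan <- make_batches(sp$s_m, sp$s_d, N = 10, n = 3, seed = 32)
  expect_length(plan$used_drugs, 0L)
  for (b in plan$batches) expect_equal(sum(b$is_drug), 3L)
})

test_that("resource errors: empty or insufficient drug sets", {
  dkg <- fx_dkg()
  pool <- gen_molecule_pool(30, 0, dkg, seed = 41)
  sp <- split_pool(pool)
  expect_error(make_batches(sp$s_m, sp$s_d, N = 10, n = 1, seed = 1),
               class = "hmg_resource_error")
  pool2 <- gen_molecule_pool(40, 0.1, dkg, seed = 42)  # 4 drugs only
  sp2 <- split_pool(pool2)
  expect_error(make_batches(sp2$s_m, sp2$s_d, N = 10, n = 0, seed = 1),
               class = "hmg_resource_error")
})

test_that("batch composition holds across seeded runs", {
  dkg <- fx_dkg()
  for (s in 1:8) {
    pool <- gen_molecule_pool(30, 0.4, dkg, seed = 100 + s)
    sp <- split_pool(pool)
    plan <- make_batches(sp$s_m, sp$s_d, N = 10, n = 1, seed = 200 + s)
    for (b in plan$batches) {
      expect_equal(c(sum(!b$is_drug), sum(b$is_drug)), c(7L, 3L))
    }
  }
})

test_that("clustering groups structurally similar molecules", {
  # planted structure: alkanes versus aromatics
  alkanes <- c("CCCC", "CCCCC", "CCCCCC", "CC(C)C", "CC(C)CC", "CCC(C)C",
               "CCCCCCC")
  aromatics <- c("c1ccccc1", "c1ccccc1C", "c1ccccc1CC", "Cc1ccc(C)cc1",
                 "c1ccncc1", "c1ccccc1Cl", "c1ccccc1F")
  s_m <- data.frame(smiles = c(alkanes, aromatics), drug_id = NA_character_)
  dkg <- fx_dkg()
  s_d <- data.frame(smiles = rep(c("CCCCO", "c1ccccc1O"), 4),
                    drug_id = drug_entities(dkg)[1:8])
  ok <- 0L
  for (s in 1:3) {
    plan <- make_batches(s_m, s_d, N = 10, n = 1, seed = 300 + s)
    fm_all <- molecule_features(rbind(s_m, s_d))
    key <- c(s_m$smiles, s_d$smiles)
    batch_of <- lapply(plan$batches, function(b) match(b$smiles, key))
    within <- cross <- numeric(0)
    for (i in seq_along(batch_of)) {
      for (j in seq_along(batch_of)) {
        d <- as.matrix(stats::dist(fm_all[c(batch_of[[i]], batch_of[[j]]), ]))
        ni <- length(batch_of[[i]])
        vals <- d[seq_len(ni), -seq_len(ni)]
        if (i == j) {
          within <- c(within, as.numeric(stats::dist(fm_all[batch_of[[i]], ])))
        } else {
          cross <- c(cross, as.numeric(vals))
        }
      }
    }
    if (mean(within) < mean(cross)) ok <- ok + 1L
  }
  expect_gte(ok, 2L)
})
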