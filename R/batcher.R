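# Drug-aware mini-batch generation: molecules without drug ids are grouped
# by structural similarity with size-constrained k-means; each cluster is
# completed with the nearest drug-annotated molecules (consumed globally,
# never reused) plus a random drug complement (reusable across batches).
# Drug members occupy the trailing batch positions, which is what the
# cross-view contrastive loss assumes.

#' Fingerprint feature matrix for molecule records
#'
#' Radius-2 circular substructure fingerprints (1024 bits), one row per
#' record; deterministic in the input.
#' @param records a `molecule_pool` data frame (or any data frame with a
#'   `smiles` column).
#' @return binary matrix with `nrow(records)` rows.
#' @export
molecule_features <- function(records) {
  mol_fingerprints(records$smiles)
}

#' Size-constrained k-means
#'
#' Partitions rows into `floor(n / cluster_size)` clusters of exactly
#' `cluster_size` members. Assignment is a greedy balanced variant of
#' Lloyd's algorithm: at each iteration points are assigned in order of
#' decreasing regret (distance gap between their best and second-best
#' centers) to the nearest center with free capacity. Leftover rows that do
#' not fill a cluster are dropped with a warning.
#'
#' @param features numeric matrix (rows = molecules).
#' @param cluster_size exact cluster size (>= 1).
#' @param seed integer seed (center initialization).
#' @param max_iter maximum Lloyd iterations.
#' @return list with `assignment` (integer per row, `NA` = dropped),
#'   `centers` (k x d matrix), `dropped` (row indices).
#' @export
constrained_kmeans <- function(features, cluster_size, seed = 1L,
                               max_iter = 25L) {
  cluster_size <- assert_count(cluster_size, "cluster_size", 1L)
  n <- nrow(features)
  if (is.null(n) || n < cluster_size) {
    hmg_error("hmg_argument_error",
              sprintf("need at least %d rows, got %s", cluster_size,
                      toString(n)))
  }
  k <- n %/% cluster_size
  with_seed(seed, {
    # k-means++ style seeding
    centers <- features[sample.int(n, 1L), , drop = FALSE]
    while (nrow(centers) < k) {
      d2 <- apply(features, 1, function(x)
        min(colSums((t(centers) - x)^2)))
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers <- rbind(centers, features[sample.int(n, 1L, prob = probs), ,
                                         drop = FALSE])
    }
    assignment <- rep(NA_integer_, n)
    for (iter in seq_len(max_iter)) {
      D <- as.matrix(stats::dist(rbind(centers, features)))[
        seq_len(k), k + seq_len(n), drop = FALSE]
      new_assign <- rep(NA_integer_, n)
      capacity <- rep(cluster_size, k)
      regret <- if (k > 1) {
        apply(D, 2, function(col) diff(sort(col)[1:2]))
      } else rep(0, n)
      for (p in order(-regret, seq_len(n))) {
        ord <- order(D[, p], seq_len(k))
        for (c in ord) {
          if (capacity[c] > 0) {
            new_assign[p] <- c
            capacity[c] <- capacity[c] - 1L
            break
          }
        }
      }
      for (c in seq_len(k)) {
        members <- which(new_assign == c)
        if (length(members) > 0) {
          centers[c, ] <- colMeans(features[members, , drop = FALSE])
        }
      }
      if (identical(new_assign, assignment)) break
      assignment <- new_assign
    }
    dropped <- which(is.na(assignment))
    if (length(dropped) > 0) {
      hmg_warn("hmg_dropped_rows",
               sprintf("%d leftover row(s) dropped (do not fill a cluster)",
                       length(dropped)))
    }
    list(assignment = assignment, centers = centers, dropped = dropped)
  })
}

#' Generate drug-aware mini-batches
#'
#' Clusters the non-drug records into groups of `ceiling(0.7 * N)` by
#' fingerprint similarity; then, per cluster in index order, appends the
#' `ceiling(0.3 * N) - n` drug records nearest to the cluster center that
#' have not yet been used (recording them in the used set), and finally
#' appends `n` records sampled uniformly from the remaining drug records
#' (random fills are reusable across batches but never repeat within one).
#' Every batch has exactly `N` members with the drug records last.
#'
#' @param s_m records without drug ids (`molecule_pool` rows).
#' @param s_d records with drug ids.
#' @param N batch size.
#' @param n random complement size, `0 <= n <= ceiling(0.3 * N)`.
#' @param seed integer seed.
#' @return a `batch_plan`: list with `batches` (list of data frames with
#'   `smiles`, `drug_id`, `is_drug`), `centers`, `used_drugs` (indices into
#'   `s_d` consumed as nearest-neighbor complements), `n_nondrug`,
#'   `n_drug`.
#' @export
make_batches <- function(s_m, s_d, N, n = 1L, seed = 1L) {
  N <- assert_count(N, "N", 2L)
  n <- assert_count(n, "n", 0L)
  n_nondrug <- as.integer(ceiling(0.7 * N))
  n_drug <- N - n_nondrug
  assert_that(n <= n_drug, "hmg_argument_error",
              sprintf("n must be <= %d (the drug slot count)", n_drug))
  if (nrow(s_d) == 0 && n_drug > 0) {
    hmg_error("hmg_resource_error", "no drug records available")
  }
  if (nrow(s_m) < n_nondrug) {
    hmg_error("hmg_argument_error",
              sprintf("need at least %d non-drug records, got %d",
                      n_nondrug, nrow(s_m)))
  }
  fm <- molecule_features(s_m)
  km <- withCallingHandlers(
    constrained_kmeans(fm, n_nondrug, seed = seed),
    hmg_warning = function(w) invokeRestart("muffleWarning"))
  k <- nrow(km$centers)
  need <- k * (n_drug - n) + n
  if (nrow(s_d) < need) {
    hmg_error("hmg_resource_error",
              sprintf("need %d drug records (%d clusters x %d nearest + %d random), have %d",
                      need, k, n_drug - n, n, nrow(s_d)))
  }
  fd <- molecule_features(s_d)
  used <- integer(0)
  batches <- vector("list", k)
  # nearest-neighbor complements, cluster by cluster, globally disjoint
  for (i in seq_len(k)) {
    members <- which(km$assignment == i)
    avail <- setdiff(seq_len(nrow(s_d)), used)
    d2 <- colSums((t(fd[avail, , drop = FALSE]) - km$centers[i, ])^2)
    nn <- avail[order(d2, avail)][seq_len(n_drug - n)]
    used <- c(used, nn)
    batches[[i]] <- list(members = members, nn = nn)
  }
  # random fills from the never-used remainder (not recorded as used)
  with_seed(seed + 1L, {
    for (i in seq_len(k)) {
      pool <- setdiff(seq_len(nrow(s_d)), used)
      fill <- if (n > 0) sort(sample(pool, n)) else integer(0)
      b <- batches[[i]]
      df <- rbind(
        data.frame(smiles = s_m$smiles[b$members],
                   drug_id = NA_character_, is_drug = FALSE),
        data.frame(smiles = s_d$smiles[c(b$nn, fill)],
                   drug_id = s_d$drug_id[c(b$nn, fill)], is_drug = TRUE)
      )
      rownames(df) <- NULL
      batches[[i]] <- df
    }
  })
  structure(list(batches = batches, centers = km$centers,
                 used_drugs = used, n_nondrug = n_nondrug, n_drug = n_drug),
            class = "batch_plan")
}

#' Split a molecule pool into non-drug and drug record sets
#' @param pool a `molecule_pool`.
#' @return list with `s_m` (no drug id) and `s_d` (with drug id).
#' @export
split_pool <- function(pool) {
  list(s_m = pool[is.na(pool$drug_id), , drop = FALSE],
       s_d = pool[!is.na(pool$drug_id), , drop = FALSE])
}
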