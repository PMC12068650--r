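# Projector head and the cross-view contrastive objective with imbalanced
# view sizes. Similarity is cosine (rows are unit-normalized after
# projection). For an anchor in one view, the positive is the same
# molecule's row in the partner view; the denominator sums the anchor's
# intra-view negatives (all other rows of its own view) and inter-view
# negatives (all non-positive rows of the partner view) -- N + M - 2
# exponential terms when the views hold N and M rows. The positive term is
# not part of the denominator. Because the drug view covers only the last
# M batch positions, anchors and positives are aligned from the tail.

#' Contrastive configuration
#' @param tau temperature (> 0) scaling the logits; default 0.1.
#' @param sim similarity function identifier; only `"cosine"` is provided.
#' @return a `contrastive_config` list.
#' @export
contrastive_config <- function(tau = 0.1, sim = "cosine") {
  assert_that(is.numeric(tau) && tau > 0, "hmg_argument_error",
              "tau must be > 0")
  assert_that(identical(sim, "cosine"), "hmg_argument_error",
              "only cosine similarity is implemented")
  structure(list(tau = tau, sim = sim), class = "contrastive_config")
}

#' Construct projector parameters
#'
#' A 2-layer MLP d -> d -> d with tanh between, used only during
#' pre-training and discarded at fine-tuning. `depth = 0` yields the
#' identity (normalization only).
#' @param d embedding width.
#' @param depth 0 or 2.
#' @param seed integer seed.
#' @return a `projector_params` object.
#' @export
projector_params <- function(d, depth = 2L, seed = 1L) {
  assert_that(depth %in% c(0L, 2L), "hmg_argument_error",
              "projector depth must be 0 or 2")
  with_seed(seed, {
    u <- function(nr, nc) {
      lim <- 1 / sqrt(nr)
      matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
    }
    p <- if (depth == 0L) list(d = d, depth = 0L) else
      list(d = d, depth = 2L, W1 = u(d, d), b1 = matrix(0, 1, d),
           W2 = u(d, d), b2 = matrix(0, 1, d))
    structure(p, class = "projector_params")
  })
}

# tape-level projector forward: rows in, unit rows out
proj_forward <- function(tape, H, PP) {
  if (PP$depth == 0L) return(ad_l2norm_rows(H))
  z <- ad_add(ad_matmul(ad_tanh(ad_add(ad_matmul(H, PP$W1), PP$b1)),
                        PP$W2), PP$b2)
  ad_l2norm_rows(z)
}

#' Project encoder embeddings for the contrastive objective
#'
#' Row-wise projector MLP followed by L2 normalization, so similarity is
#' the dot product (cosine).
#' @param h matrix of encoder outputs (rows = graphs).
#' @param params a `projector_params`.
#' @return matrix of unit-norm rows, same shape.
#' @export
project <- function(h, params) {
  if (!is.matrix(h)) h <- matrix(h, nrow = 1)
  z <- if (params$depth == 0L) h else
    sweep(tanh(sweep(h %*% params$W1, 2, as.numeric(params$b1), "+")) %*%
            params$W2, 2, as.numeric(params$b2), "+")
  z / sqrt(rowSums(z^2) + 1e-12)
}

#' Negative-pair accounting between two views
#'
#' For views of sizes `M <= N`, there are `M` positive pairs; each anchor
#' sees `M - 1` inter-view negatives and `N - 1` intra-view negatives,
#' `N + M - 2` in total.
#' @param M smaller view size.
#' @param N larger view size.
#' @return named vector `positives`, `inter_negatives`, `intra_negatives`.
#' @export
pair_counts <- function(M, N) {
  M <- assert_count(M, "M", 0L); N <- assert_count(N, "N", 0L)
  assert_that(M <= N, "hmg_argument_error", "pair_counts requires M <= N")
  c(positives = M, inter_negatives = max(M - 1L, 0L),
    intra_negatives = max(N - 1L, 0L))
}

# anchor/positive row indices for tail-aligned views
.align_rows <- function(n1, n2, i) {
  M <- min(n1, n2)
  list(M = M, a1 = n1 - M + i, p2 = n2 - M + i)
}

#' Directed contrastive loss of one anchor
#'
#' `-log( exp(sim(anchor, positive)/tau) / (sum intra-negatives + sum
#' inter-negatives) )`. Rows are tail-aligned: when view sizes differ, row
#' `i` of the smaller view corresponds to the last rows of the larger one.
#' The loss is directed: swapping the views changes the negative sets.
#'
#' @param z1 anchor-view matrix (unit rows).
#' @param z2 partner-view matrix (unit rows), tail-aligned with `z1`.
#' @param i anchor index in `1..min(nrow(z1), nrow(z2))`.
#' @param cfg a `contrastive_config`.
#' @return scalar loss.
#' @export
pair_loss <- function(z1, z2, i, cfg = contrastive_config()) {
  n1 <- nrow(z1); n2 <- nrow(z2)
  al <- .align_rows(n1, n2, i)
  if (!(is.numeric(i) && length(i) == 1L && i >= 1 && i <= al$M)) {
    hmg_error("hmg_index_error",
              sprintf("anchor index %s out of range 1..%d", toString(i), al$M))
  }
  anchor <- z1[al$a1, ]
  s_intra <- (z1 %*% anchor)[-al$a1] / cfg$tau
  s_inter <- (z2 %*% anchor)[-al$p2] / cfg$tau
  s_pos <- sum(z2[al$p2, ] * anchor) / cfg$tau
  negs <- c(s_intra, s_inter)
  if (length(negs) == 0) {
    hmg_error("hmg_degenerate_error",
              "contrastive loss undefined: no negative terms (M = N = 1)")
  }
  mx <- max(negs)
  log(sum(exp(negs - mx))) + mx - s_pos
}

#' Symmetric contrastive loss between two views
#'
#' Sum of the two directed anchor averages over the `M = min` aligned
#' molecules (both directions divided by `M`). Invariant under swapping the
#' views. An empty view pair returns 0 with a warning.
#'
#' @param z1,z2 view matrices (unit rows), tail-aligned.
#' @param cfg a `contrastive_config`.
#' @return scalar loss.
#' @export
view_pair_loss <- function(z1, z2, cfg = contrastive_config()) {
  M <- min(nrow(z1), nrow(z2))
  if (M == 0) {
    hmg_warn("hmg_degenerate_batch",
             "empty view in contrastive pair; returning 0")
    return(0)
  }
  f <- vapply(seq_len(M), function(i) pair_loss(z1, z2, i, cfg), numeric(1))
  b <- vapply(seq_len(M), function(i) pair_loss(z2, z1, i, cfg), numeric(1))
  mean(f) + mean(b)
}

#' Total cross-view contrastive loss of a projected batch
#'
#' `L_total = L(M,EM) + L(M,DM) + L(EM,DM)`; terms involving the drug view
#' use its `M` molecules (the trailing batch positions) as anchors.
#'
#' @param batch a list with unit-row matrices `z_m`, `z_em` (N rows each)
#'   and `z_dm` (M <= N rows, aligned to the last M positions).
#' @param cfg a `contrastive_config`.
#' @return list with `total` and the three `terms`.
#' @export
total_loss <- function(batch, cfg = contrastive_config()) {
  assert_that(all(c("z_m", "z_em", "z_dm") %in% names(batch)),
              "hmg_argument_error", "batch needs z_m, z_em, z_dm")
  assert_that(nrow(batch$z_m) == nrow(batch$z_em), "hmg_argument_error",
              "molecule and element views must have equal size")
  assert_that(nrow(batch$z_dm) <= nrow(batch$z_m), "hmg_argument_error",
              "drug view cannot exceed the batch size")
  t1 <- view_pair_loss(batch$z_m, batch$z_em, cfg)
  t2 <- view_pair_loss(batch$z_m, batch$z_dm, cfg)
  t3 <- view_pair_loss(batch$z_em, batch$z_dm, cfg)
  list(total = t1 + t2 + t3,
       terms = c(m_em = t1, m_dm = t2, em_dm = t3))
}

# --- tape version used during pre-training -----------------------------

# directed mean loss over the M tail-aligned anchors, as tape nodes
contrastive_dir_tape <- function(z1, z2, tau) {
  n1 <- nrow(ad_value(z1)); n2 <- nrow(ad_value(z2))
  M <- min(n1, n2)
  a1 <- (n1 - M) + seq_len(M)
  p2 <- (n2 - M) + seq_len(M)
  S11 <- ad_scale(ad_matmul(ad_rows(z1, a1), ad_t(z1)), 1 / tau)  # M x n1
  S12 <- ad_scale(ad_matmul(ad_rows(z1, a1), ad_t(z2)), 1 / tau)  # M x n2
  logits <- ad_cbind(list(S11, S12))
  mask <- matrix(1, M, n1 + n2)
  mask[cbind(seq_len(M), a1)] <- 0              # drop the anchor itself
  mask[cbind(seq_len(M), n1 + p2)] <- 0         # drop the positive
  logden <- ad_masked_logsumexp_rows(logits, mask)
  posind <- matrix(0, M, n2)
  posind[cbind(seq_len(M), p2)] <- 1
  pos <- ad_rowsums(ad_mul(S12, ad_const(z1$tape, posind)))
  ad_mean(ad_sub(logden, pos))
}

contrastive_total_tape <- function(zm, zem, zdm, tau) {
  vp <- function(a, b) {
    if (min(nrow(ad_value(a)), nrow(ad_value(b))) == 0) return(NULL)
    ad_add(contrastive_dir_tape(a, b, tau), contrastive_dir_tape(b, a, tau))
  }
  terms <- list(m_em = vp(zm, zem), m_dm = vp(zm, zdm), em_dm = vp(zem, zdm))
  keep <- Filter(Negate(is.null), terms)
  total <- keep[[1]]
  if (length(keep) > 1) for (k in 2:length(keep)) total <- ad_add(total, keep[[k]])
  list(total = total, terms = terms)
}
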