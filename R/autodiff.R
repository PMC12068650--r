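# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Values are matrices throughout (scalars are 1x1). A tape records nodes in
# creation order, which is already a topological order, so the backward
# pass is a single reverse sweep. Only the operations needed by the
# graph-transformer encoder, projector and losses are implemented.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t$n <- 0L
  t
}

ad_node <- function(tape, val, parents = list(), backward = NULL,
                    requires_grad = TRUE) {
  n <- new.env(parent = emptyenv())
  n$val <- val
  n$grad <- NULL
  n$parents <- parents
  n$backward <- backward
  n$requires_grad <- requires_grad ||
    any(vapply(parents, function(p) p$requires_grad, logical(1)))
  n$tape <- tape
  tape$n <- tape$n + 1L
  tape$nodes[[tape$n]] <- n
  n
}

ad_const <- function(tape, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  ad_node(tape, x, requires_grad = FALSE)
}

ad_param <- function(tape, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  ad_node(tape, x, requires_grad = TRUE)
}

.acc <- function(node, g) {
  if (!node$requires_grad) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Run the backward sweep from a scalar (1x1) root.
ad_backward <- function(root) {
  tape <- root$tape
  stopifnot(length(root$val) == 1L)
  root$grad <- matrix(1, 1, 1)
  for (i in seq(tape$n, 1L)) {
    n <- tape$nodes[[i]]
    if (!is.null(n$grad) && !is.null(n$backward) && n$requires_grad) {
      n$backward(n$grad)
    }
  }
  invisible(NULL)
}

ad_grad <- function(node) {
  node$grad %||% matrix(0, nrow(node$val), ncol(node$val))
}

ad_matmul <- function(a, b) {
  ad_node(a$tape, a$val %*% b$val, list(a, b), function(g) {
    .acc(a, g %*% t(b$val))
    .acc(b, t(a$val) %*% g)
  }, requires_grad = FALSE)
}

ad_add <- function(a, b) {
  # b may be a 1-row bias broadcast over a's rows
  bv <- b$val
  if (nrow(bv) == 1L && nrow(a$val) > 1L) {
    val <- sweep(a$val, 2, as.numeric(bv), "+")
    ad_node(a$tape, val, list(a, b), function(g) {
      .acc(a, g)
      .acc(b, matrix(colSums(g), 1))
    }, requires_grad = FALSE)
  } else {
    ad_node(a$tape, a$val + bv, list(a, b), function(g) {
      .acc(a, g)
      .acc(b, g)
    }, requires_grad = FALSE)
  }
}

ad_sub <- function(a, b) {
  ad_node(a$tape, a$val - b$val, list(a, b), function(g) {
    .acc(a, g)
    .acc(b, -g)
  }, requires_grad = FALSE)
}

ad_mul <- function(a, b) {
  ad_node(a$tape, a$val * b$val, list(a, b), function(g) {
    .acc(a, g * b$val)
    .acc(b, g * a$val)
  }, requires_grad = FALSE)
}

ad_scale <- function(a, s) {
  ad_node(a$tape, a$val * s, list(a), function(g) .acc(a, g * s),
          requires_grad = FALSE)
}

# select rows (gather); idx may repeat
ad_rows <- function(a, idx) {
  idx <- as.integer(idx)
  ad_node(a$tape, a$val[idx, , drop = FALSE], list(a), function(g) {
    ga <- matrix(0, nrow(a$val), ncol(a$val))
    rs <- rowsum(g, group = idx)
    ga[as.integer(rownames(rs)), ] <- rs
    .acc(a, ga)
  }, requires_grad = FALSE)
}

ad_rbind <- function(blocks) {
  sizes <- vapply(blocks, function(b) nrow(b$val), integer(1))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  ad_node(blocks[[1]]$tape, do.call(rbind, lapply(blocks, `[[`, "val")),
          blocks, function(g) {
            for (k in seq_along(blocks)) {
              .acc(blocks[[k]], g[starts[k]:ends[k], , drop = FALSE])
            }
          }, requires_grad = FALSE)
}

ad_cbind <- function(blocks) {
  widths <- vapply(blocks, function(b) ncol(b$val), integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(blocks[[1]]$tape, do.call(cbind, lapply(blocks, `[[`, "val")),
          blocks, function(g) {
            for (k in seq_along(blocks)) {
              .acc(blocks[[k]], g[, starts[k]:ends[k], drop = FALSE])
            }
          }, requires_grad = FALSE)
}

ad_rowsums <- function(a) {
  ad_node(a$tape, matrix(rowSums(a$val), ncol = 1), list(a), function(g) {
    .acc(a, matrix(g, nrow(a$val), ncol(a$val)))
  }, requires_grad = FALSE)
}

ad_sum <- function(a) {
  ad_node(a$tape, matrix(sum(a$val), 1, 1), list(a), function(g) {
    .acc(a, matrix(as.numeric(g), nrow(a$val), ncol(a$val)))
  }, requires_grad = FALSE)
}

# sum rows of a by group id into ngroups rows (empty groups give zeros)
ad_segment_sum <- function(a, groups, ngroups) {
  groups <- as.integer(groups)
  val <- matrix(0, ngroups, ncol(a$val))
  if (nrow(a$val) > 0) {
    rs <- rowsum(a$val, group = groups)
    val[as.integer(rownames(rs)), ] <- rs
  }
  ad_node(a$tape, val, list(a), function(g) {
    .acc(a, g[groups, , drop = FALSE])
  }, requires_grad = FALSE)
}

# numerically stable softmax of a column vector within segments; the
# per-segment max shift is treated as constant (softmax is shift-invariant)
ad_segment_softmax <- function(s, groups) {
  groups <- as.integer(groups)
  sv <- as.numeric(s$val)
  if (length(sv) == 0) {
    return(ad_node(s$tape, s$val, list(s), function(g) .acc(s, g),
                   requires_grad = FALSE))
  }
  mx <- tapply(sv, groups, max)
  e <- exp(sv - mx[as.character(groups)])
  tot <- tapply(e, groups, sum)
  w <- e / tot[as.character(groups)]
  wv <- matrix(w, ncol = 1)
  ad_node(s$tape, wv, list(s), function(g) {
    gv <- as.numeric(g)
    dot <- tapply(w * gv, groups, sum)
    .acc(s, matrix(w * (gv - dot[as.character(groups)]), ncol = 1))
  }, requires_grad = FALSE)
}

ad_leaky_relu <- function(a, slope = 0.01) {
  mask <- ifelse(a$val > 0, 1, slope)
  ad_node(a$tape, a$val * mask, list(a), function(g) .acc(a, g * mask),
          requires_grad = FALSE)
}

ad_tanh <- function(a) {
  v <- tanh(a$val)
  ad_node(a$tape, v, list(a), function(g) .acc(a, g * (1 - v^2)),
          requires_grad = FALSE)
}

# L2-normalize each row (safe at ~zero rows via eps)
ad_l2norm_rows <- function(a, eps = 1e-12) {
  nr <- sqrt(rowSums(a$val^2) + eps)
  v <- a$val / nr
  ad_node(a$tape, v, list(a), function(g) {
    dot <- rowSums(a$val * g)
    .acc(a, g / nr - a$val * (dot / nr^3))
  }, requires_grad = FALSE)
}

# log(sum(exp(row))) over masked entries of each row; mask is a constant
# 0/1 matrix with at least one 1 per row
ad_masked_logsumexp_rows <- function(a, mask) {
  av <- a$val
  neg <- ifelse(mask > 0, 0, -Inf)
  shifted <- av + neg
  mx <- apply(shifted, 1, max)
  e <- exp(shifted - mx) * mask
  tot <- rowSums(e)
  val <- matrix(log(tot) + mx, ncol = 1)
  w <- e / tot
  ad_node(a$tape, val, list(a), function(g) {
    .acc(a, w * matrix(as.numeric(g), nrow(av), ncol(av)))
  }, requires_grad = FALSE)
}

ad_mean <- function(a) ad_scale(ad_sum(a), 1 / length(a$val))

# scale each row of a (n x d) by the matching entry of column vector s (n x 1)
ad_mul_rows <- function(a, s) {
  sv <- as.numeric(s$val)
  ad_node(a$tape, a$val * sv, list(a, s), function(g) {
    .acc(a, g * sv)
    .acc(s, matrix(rowSums(g * a$val), ncol = 1))
  }, requires_grad = FALSE)
}

# value extraction
ad_value <- function(node) node$val

ad_t <- function(a) {
  ad_node(a$tape, t(a$val), list(a), function(g) .acc(a, t(g)),
          requires_grad = FALSE)
}

# elementwise log(1 + exp(a)), numerically stable; gradient is sigmoid(a)
ad_softplus <- function(a) {
  v <- pmax(a$val, 0) + log1p(exp(-abs(a$val)))
  sig <- 1 / (1 + exp(-a$val))
  ad_node(a$tape, v, list(a), function(g) .acc(a, g * sig),
          requires_grad = FALSE)
}
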