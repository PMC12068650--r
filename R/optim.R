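# Adam optimizer over flattened parameter trees.

# flatten a nested parameter tree to a named list of matrices
flatten_params <- function(p, prefix = "") {
  if (is.matrix(p)) {
    out <- list(p); names(out) <- prefix
    return(out)
  }
  if (is.list(p)) {
    nms <- names(p) %||% as.character(seq_along(p))
    out <- list()
    for (k in seq_along(p)) {
      path <- if (nzchar(prefix)) paste0(prefix, ".", nms[k]) else nms[k]
      out <- c(out, flatten_params(p[[k]], path))
    }
    return(out)
  }
  list()
}

# write a flat named list of matrices back into the tree template
unflatten_params <- function(template, flat, prefix = "") {
  if (is.matrix(template)) return(flat[[prefix]])
  if (is.list(template)) {
    nms <- names(template) %||% as.character(seq_along(template))
    for (k in seq_along(template)) {
      path <- if (nzchar(prefix)) paste0(prefix, ".", nms[k]) else nms[k]
      template[[k]] <- unflatten_params(template[[k]], flat, path)
    }
  }
  template
}

adam_init <- function(flat) {
  list(t = 0L,
       m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0))
}

# one Adam step; returns list(flat = updated params, state = updated state)
adam_step <- function(flat, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    flat[[nm]] <- flat[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(flat = flat, state = state)
}
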