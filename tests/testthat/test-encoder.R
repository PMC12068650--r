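# Encoder: initialization algebra, oracle equivalence, attention
# normalization, permutation invariance, directedness, finiteness.

test_that("edge initialization carries the source node embedding", {
  g <- fx_mol_graph("CC(=O)OC")
  p <- encoder_params(d = 8, K = 2, L = 1, seed = 3)
  st <- init_state(g, p)
  # h_eij - h_eji = h_vi - h_vj for every reverse pair of the same type
  e <- g$edges
  ni <- match(e$src, g$nodes$id); nj <- match(e$dst, g$nodes$id)
  for (r in seq_len(nrow(e))) {
    rev <- which(e$src == e$dst[r] & e$dst == e$src[r] & e$type == e$type[r] &
                   (is.na(e$intermediate) | e$intermediate == e$intermediate[r]))
    rev <- rev[1]
    expect_lt(max(abs((st$h_e[r, ] - st$h_e[rev, ]) -
                        (st$h_v[ni[r], ] - st$h_v[nj[r], ]))), 1e-10)
  }
  # some directed pair differs (heteroatom-terminated bonds exist)
  diffs <- vapply(seq_len(nrow(e)), function(r) {
    rev <- which(e$src == e$dst[r] & e$dst == e$src[r] & e$type == e$type[r])[1]
    max(abs(st$h_e[r, ] - st$h_e[rev, ]))
  }, numeric(1))
  expect_gt(max(diffs), 0)
})

test_that("zero features and zero biases give zero node states", {
  g <- rand_graph(5)
  g$node_features <- lapply(g$node_features, function(f) f * 0)
  g$pos <- g$pos * 0
  p <- encoder_params(d = 8, K = 2, L = 0, seed = 1)
  p$a0 <- p$a0 * 0; p$c0 <- p$c0 * 0
  st <- init_state(g, p)
  expect_lt(max(abs(st$h_v)), 1e-12)
  # edge state then reduces to beta * B + b0
  B <- p$B; b0 <- as.numeric(p$b0)
  for (r in seq_len(nrow(g$edges))) {
    want <- as.numeric(matrix(g$edge_features[[r]], 1) %*%
                         B[[g$edges$type[r]]]) + b0
    expect_lt(max(abs(st$h_e[r, ] - want)), 1e-10)
  }
})

test_that("full pipeline matches the dense oracle on random graphs", {
  worst <- 0
  for (s in 1:20) {
    g <- rand_graph(100 + s)
    p <- encoder_params(d = 8, K = 2, L = 2, seed = s)
    got <- encode(g, p)$h_g
    orc <- dense_encode_oracle(g, p)
    worst <- max(worst, max(abs(got - orc$hg)))
    expect_lt(max(abs(got - orc$hg)), 1e-5)
    # attention weights over every receiver and head sum to 1
    expect_lt(max(abs(orc$attn_sums - 1)), 1e-6)
  }
  expect_lt(worst, 1e-5)
})

test_that("stepwise operations match the oracle layer by layer", {
  g <- rand_graph(42)
  p <- encoder_params(d = 8, K = 2, L = 2, seed = 9)
  orc <- dense_encode_oracle(g, p)
  st <- init_state(g, p)
  expect_lt(max(abs(st$h_v - orc$states[[1]]$hv)), 1e-8)
  expect_lt(max(abs(st$h_e - orc$states[[1]]$he)), 1e-8)
  for (l in 1:2) {
    msg <- attention_messages(st, g, p, l)
    expect_lt(max(abs(msg$m_v - orc$states[[l + 1]]$mv)), 1e-8)
    expect_lt(max(abs(msg$m_e - orc$states[[l + 1]]$me)), 1e-8)
    st <- update_state(st, msg, g, p, l)
    expect_lt(max(abs(st$h_v - orc$states[[l + 1]]$hv)), 1e-8)
    expect_lt(max(abs(st$h_e - orc$states[[l + 1]]$he)), 1e-8)
  }
})

test_that("with identity type transforms the attention reduces to standard QKV", {
  g <- rand_graph(17)
  g$nodes$type <- rep("atom", nrow(g$nodes))
  dims <- hmg_feature_dims()
  g$node_features <- lapply(g$node_features, function(f)
    stats::runif(dims$node[["atom"]]))
  g$edges$type <- rep("bond", nrow(g$edges))
  g$edge_features <- lapply(g$edge_features, function(f)
    stats::runif(dims$edge[["bond"]]))
  p <- encoder_params(d = 8, K = 2, L = 1, seed = 4)
  for (t in names(p$Wdelta_v)) p$Wdelta_v[[t]] <- diag(p$dk)
  for (t in names(p$Wdelta_e)) p$Wdelta_e[[t]] <- diag(p$dk)
  st <- init_state(g, p)
  msg <- attention_messages(st, g, p, 1)
  # independent standard attention: q = h WQ, k = h WK, v = h WV directly
  lp <- p$layers[[1]]
  dst <- match(g$edges$dst, g$nodes$id)
  mv <- matrix(0, nrow(g$nodes), p$d)
  for (i in seq_len(nrow(g$nodes))) {
    inc <- which(dst == i)
    if (length(inc) == 0) next
    heads <- numeric(0)
    for (k in 1:p$K) {
      q <- as.numeric(matrix(st$h_v[i, ], 1) %*% lp$WQ[[k]])
      ke <- st$h_e[inc, , drop = FALSE] %*% lp$WK[[k]]
      ve <- st$h_e[inc, , drop = FALSE] %*% lp$WV[[k]]
      sc <- as.numeric(ke %*% q) / sqrt(p$dk)
      w <- exp(sc - max(sc)); w <- w / sum(w)
      heads <- c(heads, as.numeric(t(w) %*% ve))
    }
    mv[i, ] <- as.numeric(matrix(heads, 1) %*% lp$WVmix)
  }
  expect_lt(max(abs(msg$m_v - mv)), 1e-8)
})

test_that("graph embedding is invariant and node states equivariant under relabeling", {
  for (s in c(3, 8)) {
    g <- rand_graph(200 + s)
    p <- encoder_params(d = 8, K = 2, L = 2, seed = s)
    gp <- permute_graph(g, s)
    e1 <- encode(g, p)$h_g
    e2 <- encode(gp, p)$h_g
    expect_lt(max(abs(e1 - e2)), 1e-6)
    st1 <- init_state(g, p); st2 <- init_state(gp, p)
    perm <- match(gp$nodes$id, g$nodes$id)
    expect_lt(max(abs(st1$h_v[perm, ] - st2$h_v)), 1e-8)
  }
})

test_that("isolated receivers get zero messages and L = 0 is the readout of init", {
  g <- rand_graph(31)
  # add an isolated node
  g$nodes <- rbind(g$nodes, data.frame(id = "n99", type = "atom", ref = "n99"))
  g$node_features <- c(g$node_features,
                       list(stats::runif(hmg_feature_dims()$node[["atom"]])))
  g$pos <- rbind(g$pos, stats::runif(ncol(g$pos)))
  p <- encoder_params(d = 8, K = 2, L = 1, seed = 2)
  st <- init_state(g, p)
  msg <- attention_messages(st, g, p, 1)
  iso <- which(g$nodes$id == "n99")
  expect_lt(max(abs(msg$m_v[iso, ])), 1e-12)

  p0 <- encoder_params(d = 8, K = 2, L = 0, seed = 2)
  emb <- encode(g, p0)
  orc <- dense_encode_oracle(g, p0)
  expect_lt(max(abs(emb$h_g - orc$hg)), 1e-8)
  expect_lt(abs(sum(emb$pooling$weight) - 1), 1e-6)
})

test_that("encoder outputs stay finite on fixture molecules across parameter draws", {
  graphs <- list(fx_mol_graph("CC(=O)OC"),
                 attach_element_view(fx_mol_graph("c1ccccc1"), fx_ekg()))
  for (s in 1:25) {
    p <- encoder_params(d = 8, K = 2, L = 2, seed = 1000 + s)
    for (g in graphs) {
      h <- encode(g, p)$h_g
      expect_true(all(is.finite(h)))
    }
  }
})

test_that("encoding an empty graph errors", {
  g <- fx_mol_graph("c1ccccc1")
  g$nodes <- g$nodes[0, , drop = FALSE]
  g$node_features <- list(); g$edges <- g$edges[0, , drop = FALSE]
  g$edge_features <- list(); g$pos <- g$pos[0, , drop = FALSE]
  expect_error(encode(g, encoder_params(d = 8, K = 2, L = 1)),
               class = "hmg_argument_error")
})
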