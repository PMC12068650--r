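# The dual node-edge message-passing graph-transformer encoder.
#
# Initialization projects each raw node/edge feature through a type-specific
# linear map (plus a positional term for nodes; each directed edge absorbs
# its source node's initial embedding, so the two directions of a bond can
# differ). Every layer runs synchronous multi-head attention twice: nodes
# aggregate their incoming directed edges; each directed edge e_ij
# aggregates its source node v_i together with the edges incoming at v_i
# (which include the reverse edge e_ji). Queries come from the receiver,
# keys/values from the senders; type-specific transforms W_delta project
# heterogeneous types into one comparison space. Updates concatenate the
# previous state with the message and apply a type-specific linear map with
# LeakyReLU. The readout scores all final node and edge embeddings with a
# shared linear+tanh scorer, keeps the top ceil(r * #units), and returns
# the softmax-weighted, score-scaled sum (self-attention graph pooling).

#' Construct the learnable parameter set of the HMG encoder
#'
#' One parameter set serves all three views; types absent from a graph
#' simply leave their parameters unused. The type-specific comparison
#' transforms `W_delta` are shared across layers and heads (one per type);
#' the per-layer, per-head projections `W_Q`, `W_K`, `W_V` are shared
#' between the node and edge streams. Initialization is uniform scaled by
#' fan-in, under `seed`.
#'
#' @param d hidden width (must be divisible by `K`).
#' @param K number of attention heads.
#' @param L number of message-passing layers.
#' @param r self-attention pooling keep ratio in (0, 1].
#' @param d_kg drug-KG embedding dimension (raw feature width of the DNode).
#' @param leak LeakyReLU negative slope.
#' @param seed integer seed for initialization.
#' @return an `encoder_params` object.
#' @export
encoder_params <- function(d = 16L, K = 4L, L = 2L, r = 0.5, d_kg = 8L,
                           leak = 0.01, seed = 1L) {
  d <- assert_count(d, "d", 1L); K <- assert_count(K, "K", 1L)
  L <- assert_count(L, "L", 0L)
  assert_that(d %% K == 0, "hmg_argument_error", "d must be divisible by K")
  assert_that(r > 0 && r <= 1, "hmg_argument_error", "r must be in (0, 1]")
  dims <- hmg_feature_dims(d_kg)
  dk <- d %/% K
  with_seed(seed, {
    u <- function(nr, nc) {
      lim <- 1 / sqrt(nr)
      matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
    }
    p <- list(
      d = d, K = K, L = L, r = r, dk = dk, leak = leak, d_kg = d_kg,
      k_pos = dims$k_pos,
      A = lapply(dims$node, function(dv) u(dv, d)),
      a0 = u(1, d),
      C0 = u(dims$k_pos, d),
      c0 = u(1, d),
      B = lapply(dims$edge, function(de) u(de, d)),
      b0 = u(1, d),
      Wdelta_v = lapply(dims$node, function(.) u(dk, dk)),
      Wdelta_e = lapply(dims$edge, function(.) u(dk, dk)),
      layers = lapply(seq_len(L), function(l) list(
        WQ = lapply(seq_len(K), function(k) u(d, dk)),
        WK = lapply(seq_len(K), function(k) u(d, dk)),
        WV = lapply(seq_len(K), function(k) u(d, dk)),
        WVmix = u(d, d),
        WEmix = u(d, d),
        Wupd_v = lapply(dims$node, function(.) u(2 * d, d)),
        Wupd_e = lapply(dims$edge, function(.) u(2 * d, d))
      )),
      readout = list(ws = u(d, 1), bs = matrix(0, 1, 1))
    )
    names(p$layers) <- if (L > 0) paste0("l", seq_len(L)) else character(0)
    structure(p, class = "encoder_params")
  })
}

# --- parameter trees ---------------------------------------------------

# recursively wrap every matrix of a parameter (sub)tree in tape nodes
wrap_params <- function(tape, p, trainable = TRUE) {
  if (is.matrix(p)) {
    return(if (trainable) ad_param(tape, p) else ad_const(tape, p))
  }
  if (is.list(p)) return(lapply(p, wrap_params, tape = tape,
                                trainable = trainable))
  p  # scalars / metadata pass through
}

# recursively extract gradients from a wrapped tree (zeros when untouched)
grad_tree <- function(w) {
  if (is.environment(w)) return(ad_grad(w))
  if (is.list(w)) return(lapply(w, grad_tree))
  NULL
}

# elementwise map over two parallel parameter trees
tree_map2 <- function(f, a, b) {
  if (is.matrix(a)) return(f(a, b))
  if (is.list(a)) {
    out <- a
    for (k in seq_along(a)) out[[k]] <- tree_map2(f, a[[k]], b[[k]])
    return(out)
  }
  a
}

tree_map <- function(f, a) {
  if (is.matrix(a)) return(f(a))
  if (is.list(a)) return(lapply(a, tree_map, f = f))
  a
}

# --- graph compilation -------------------------------------------------

# Precompute the integer index structures the forward pass needs. Multiple
# graphs may be compiled as one disjoint union (block-diagonal batching);
# `graph_of_*` tracks membership for per-graph readout.
compile_graph <- function(graphs) {
  if (inherits(graphs, "hmgraph")) graphs <- list(graphs)
  assert_that(length(graphs) > 0, "hmg_argument_error", "no graphs to encode")
  for (g in graphs) {
    assert_that(has_features(g), "hmg_argument_error",
                "graphs must be featurized before encoding")
    assert_that(nrow(g$nodes) > 0, "hmg_argument_error",
                "cannot encode an empty graph")
  }
  node_type <- character(0); edge_type <- character(0)
  node_key <- character(0); edge_key <- character(0)
  feats_v <- list(); feats_e <- list()
  lambda <- NULL
  esrc <- integer(0); edst <- integer(0)
  graph_of_node <- integer(0); graph_of_edge <- integer(0)
  n_off <- 0L
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]
    n <- nrow(g$nodes); m <- nrow(g$edges)
    node_type <- c(node_type, g$nodes$type)
    node_key <- c(node_key, g$nodes$id)
    feats_v <- c(feats_v, g$node_features)
    lambda <- rbind(lambda, g$pos)
    graph_of_node <- c(graph_of_node, rep(gi, n))
    if (m > 0) {
      idx <- match(g$edges$src, g$nodes$id)
      jdx <- match(g$edges$dst, g$nodes$id)
      esrc <- c(esrc, idx + n_off); edst <- c(edst, jdx + n_off)
      edge_type <- c(edge_type, g$edges$type)
      edge_key <- c(edge_key, g$edges$id)
      feats_e <- c(feats_e, g$edge_features)
      graph_of_edge <- c(graph_of_edge, rep(gi, m))
    }
    n_off <- n_off + n
  }
  n <- length(node_type); m <- length(edge_type)

  group_of <- function(types) split(seq_along(types), types)
  node_groups <- group_of(node_type)
  edge_groups <- group_of(edge_type)
  stack_feats <- function(groups, feats) {
    lapply(groups, function(idx) do.call(rbind, feats[idx]))
  }
  # permutation recovering original order from type-stacked rows
  inv_perm <- function(groups, ntot) {
    conc <- unlist(groups, use.names = FALSE)
    match(seq_len(ntot), conc)
  }

  incoming <- split(seq_len(m), factor(edst, levels = seq_len(n)))
  pr <- integer(0); pk <- logical(0); pi <- integer(0)
  if (m > 0) {
    n_in <- lengths(incoming)[esrc]
    pr <- rep(seq_len(m), times = 1L + n_in)
    pk <- unlist(lapply(seq_len(m), function(e)
      c(TRUE, rep(FALSE, n_in[e]))), use.names = FALSE)
    pi <- unlist(lapply(seq_len(m), function(e)
      c(esrc[e], incoming[[esrc[e]]])), use.names = FALSE)
  }
  # stacking order for pair sources: node-kind pairs first, then edge-kind
  pair_node <- which(pk); pair_edge <- which(!pk)
  pair_inv <- match(seq_along(pk), c(pair_node, pair_edge))

  list(
    n = n, m = m, n_graphs = length(graphs),
    node_type = node_type, edge_type = edge_type,
    node_key = node_key, edge_key = edge_key,
    node_groups = node_groups, edge_groups = edge_groups,
    Xv = stack_feats(node_groups, feats_v),
    Xe = stack_feats(edge_groups, feats_e),
    node_inv = inv_perm(node_groups, n),
    edge_inv = inv_perm(edge_groups, m),
    lambda = lambda,
    esrc = esrc, edst = edst,
    pair_recv = pr, pair_is_node = pk, pair_src = pi,
    pair_node = pair_node, pair_edge = pair_edge, pair_inv = pair_inv,
    graph_of_node = graph_of_node, graph_of_edge = graph_of_edge
  )
}

# --- forward pass (tape) ----------------------------------------------

# apply per-type linear maps W[[t]] to the rows of the typed blocks and
# restore original row order
typed_linear <- function(tape, blocks, W, inv) {
  outs <- lapply(names(blocks), function(t) ad_matmul(blocks[[t]], W[[t]]))
  stacked <- if (length(outs) == 1) outs[[1]] else ad_rbind(outs)
  ad_rows(stacked, inv)
}

# same, but applied to an already-assembled embedding matrix H
typed_linear_rows <- function(H, groups, W, inv) {
  outs <- lapply(names(groups), function(t)
    ad_matmul(ad_rows(H, groups[[t]]), W[[t]]))
  stacked <- if (length(outs) == 1) outs[[1]] else ad_rbind(outs)
  ad_rows(stacked, inv)
}

enc_init <- function(tape, cg, P) {
  Xv <- lapply(cg$Xv, ad_const, tape = tape)
  Xe <- lapply(cg$Xe, ad_const, tape = tape)
  lam <- ad_const(tape, cg$lambda)
  hv <- ad_add(
    ad_add(typed_linear(tape, Xv, P$A[names(Xv)], cg$node_inv), P$a0),
    ad_add(ad_matmul(lam, P$C0), P$c0))
  he <- NULL
  if (cg$m > 0) {
    he <- ad_add(
      ad_add(typed_linear(tape, Xe, P$B[names(Xe)], cg$edge_inv), P$b0),
      ad_rows(hv, cg$esrc))
  }
  list(hv = hv, he = he)
}

enc_layer <- function(tape, cg, P, lp, hv, he) {
  dk <- P$dk
  scale <- 1 / sqrt(dk)
  if (cg$m == 0) {
    # no edges anywhere: every message-source set is empty
    return(list(mv = ad_const(tape, matrix(0, cg$n, P$d)), me = NULL))
  }
  heads_v <- list(); heads_e <- list()
  for (k in seq_len(P$K)) {
    qn <- typed_linear_rows(ad_matmul(hv, lp$WQ[[k]]), cg$node_groups,
                            P$Wdelta_v[names(cg$node_groups)], cg$node_inv)
    kn <- typed_linear_rows(ad_matmul(hv, lp$WK[[k]]), cg$node_groups,
                            P$Wdelta_v[names(cg$node_groups)], cg$node_inv)
    vn <- typed_linear_rows(ad_matmul(hv, lp$WV[[k]]), cg$node_groups,
                            P$Wdelta_v[names(cg$node_groups)], cg$node_inv)
    qe <- typed_linear_rows(ad_matmul(he, lp$WQ[[k]]), cg$edge_groups,
                            P$Wdelta_e[names(cg$edge_groups)], cg$edge_inv)
    ke <- typed_linear_rows(ad_matmul(he, lp$WK[[k]]), cg$edge_groups,
                            P$Wdelta_e[names(cg$edge_groups)], cg$edge_inv)
    ve <- typed_linear_rows(ad_matmul(he, lp$WV[[k]]), cg$edge_groups,
                            P$Wdelta_e[names(cg$edge_groups)], cg$edge_inv)

    # node aggregation: receiver = edge destination, senders = incoming edges
    sc_v <- ad_scale(ad_rowsums(ad_mul(ad_rows(qn, cg$edst), ke)), scale)
    al_v <- ad_segment_softmax(sc_v, cg$edst)
    heads_v[[k]] <- ad_segment_sum(ad_mul_rows(ve, al_v), cg$edst, cg$n)

    # edge aggregation: receiver = each directed edge; senders = source node
    # plus the edges incoming at the source (incl. the reverse edge)
    k_src <- ad_rows(ad_rbind(list(ad_rows(kn, cg$pair_src[cg$pair_node]),
                                   ad_rows(ke, cg$pair_src[cg$pair_edge]))),
                     cg$pair_inv)
    v_src <- ad_rows(ad_rbind(list(ad_rows(vn, cg$pair_src[cg$pair_node]),
                                   ad_rows(ve, cg$pair_src[cg$pair_edge]))),
                     cg$pair_inv)
    sc_e <- ad_scale(ad_rowsums(ad_mul(ad_rows(qe, cg$pair_recv), k_src)),
                     scale)
    al_e <- ad_segment_softmax(sc_e, cg$pair_recv)
    heads_e[[k]] <- ad_segment_sum(ad_mul_rows(v_src, al_e), cg$pair_recv,
                                   cg$m)
  }
  mv <- ad_matmul(if (P$K == 1) heads_v[[1]] else ad_cbind(heads_v), lp$WVmix)
  me <- ad_matmul(if (P$K == 1) heads_e[[1]] else ad_cbind(heads_e), lp$WEmix)
  list(mv = mv, me = me)
}

enc_update <- function(cg, P, lp, hv, he, mv, me) {
  uv <- ad_leaky_relu(typed_linear_rows(ad_cbind(list(hv, mv)),
                                        cg$node_groups,
                                        lp$Wupd_v[names(cg$node_groups)],
                                        cg$node_inv), P$leak)
  ue <- NULL
  if (!is.null(he)) {
    ue <- ad_leaky_relu(typed_linear_rows(ad_cbind(list(he, me)),
                                          cg$edge_groups,
                                          lp$Wupd_e[names(cg$edge_groups)],
                                          cg$edge_inv), P$leak)
  }
  list(hv = uv, he = ue)
}

# self-attention pooling over the union of node and edge units, per graph
enc_readout <- function(tape, cg, P, hv, he) {
  U <- if (is.null(he)) hv else ad_rbind(list(hv, he))
  graph_of_unit <- c(cg$graph_of_node, cg$graph_of_edge)
  unit_key <- c(paste0("v:", cg$node_key), paste0("e:", cg$edge_key))
  s <- ad_tanh(ad_add(ad_matmul(U, P$readout$ws), P$readout$bs))
  sval <- as.numeric(ad_value(s))
  kept <- integer(0)
  for (gi in seq_len(cg$n_graphs)) {
    units <- which(graph_of_unit == gi)
    kg <- ceiling(P$r * length(units))
    ord <- units[order(-sval[units], unit_key[units])]
    kept <- c(kept, ord[seq_len(kg)])
  }
  kept <- sort(kept)
  s_kept <- ad_rows(s, kept)
  a <- ad_segment_softmax(s_kept, graph_of_unit[kept])
  w <- ad_mul(a, s_kept)
  hg <- ad_segment_sum(ad_mul_rows(ad_rows(U, kept), w),
                       graph_of_unit[kept], cg$n_graphs)
  list(hg = hg, kept = kept, attn = as.numeric(ad_value(a)),
       graph_of_unit = graph_of_unit, unit_key = unit_key,
       unit_is_node = c(rep(TRUE, cg$n), rep(FALSE, cg$m)),
       unit_type = c(cg$node_type, cg$edge_type))
}

# full forward over a compiled (possibly batched) graph
enc_forward <- function(tape, cg, P) {
  st <- enc_init(tape, cg, P)
  hv <- st$hv; he <- st$he
  for (l in seq_len(P$L)) {
    lp <- P$layers[[l]]
    msg <- enc_layer(tape, cg, P, lp, hv, he)
    upd <- enc_update(cg, P, lp, hv, he, msg$mv, msg$me)
    hv <- upd$hv; he <- upd$he
  }
  ro <- enc_readout(tape, cg, P, hv, he)
  c(list(hv = hv, he = he), ro)
}

check_types_covered <- function(cg, params) {
  miss_v <- setdiff(names(cg$node_groups), names(params$A))
  miss_e <- setdiff(names(cg$edge_groups), names(params$B))
  if (length(miss_v) + length(miss_e) > 0) {
    hmg_error("hmg_schema_error",
              sprintf("encoder parameters missing type(s): %s",
                      paste(c(miss_v, miss_e), collapse = ",")))
  }
  for (t in names(cg$node_groups)) {
    if (ncol(cg$Xv[[t]]) != nrow(params$A[[t]])) {
      hmg_error("hmg_schema_error",
                sprintf("node type '%s': feature width %d != projection %d",
                        t, ncol(cg$Xv[[t]]), nrow(params$A[[t]])))
    }
  }
  invisible(TRUE)
}

# --- public operations -------------------------------------------------

#' Initialize encoder state for a graph
#'
#' Applies the type-specific input projections: node states get the feature
#' and positional terms; each directed edge state adds its source node's
#' initial embedding (so reverse edges differ whenever their sources do).
#'
#' @param graph a featurized `hmgraph`.
#' @param params an `encoder_params`.
#' @return an `encoder_state`: list with matrices `h_v` (nodes x d) and
#'   `h_e` (directed edges x d), and `layer = 0`.
#' @export
init_state <- function(graph, params) {
  cg <- compile_graph(graph)
  check_types_covered(cg, params)
  tape <- ad_tape()
  P <- wrap_params(tape, params, trainable = FALSE)
  st <- enc_init(tape, cg, P)
  structure(list(h_v = ad_value(st$hv),
                 h_e = if (is.null(st$he)) matrix(0, 0, params$d) else
                   ad_value(st$he),
                 layer = 0L),
            class = "encoder_state")
}

#' Compute one layer of attention messages
#'
#' Node messages aggregate the node's incoming directed edges; edge
#' messages aggregate the edge's source node and the edges incoming at the
#' source. Per receiver and head, attention weights over the sender set sum
#' to one; head outputs are concatenated and mixed. All messages are
#' computed from the supplied state (synchronous semantics).
#'
#' @param state an `encoder_state` at layer `layer - 1`.
#' @param graph the featurized `hmgraph` the state was built from.
#' @param params an `encoder_params`.
#' @param layer layer index in `1..L`.
#' @return list with `m_v` (nodes x d) and `m_e` (edges x d).
#' @export
attention_messages <- function(state, graph, params, layer) {
  assert_that(layer >= 1 && layer <= params$L, "hmg_argument_error",
              "layer out of range")
  cg <- compile_graph(graph)
  tape <- ad_tape()
  P <- wrap_params(tape, params, trainable = FALSE)
  hv <- ad_const(tape, state$h_v)
  he <- if (cg$m > 0) ad_const(tape, state$h_e) else NULL
  msg <- enc_layer(tape, cg, P, P$layers[[layer]], hv, he)
  list(m_v = ad_value(msg$mv),
       m_e = if (is.null(msg$me)) matrix(0, 0, params$d) else
         ad_value(msg$me))
}

#' Apply the update function to a state and its messages
#'
#' `h^l = LeakyReLU([h^{l-1} || m^l] W_type)` for all nodes and directed
#' edges, with the receiver's type-specific update matrix.
#'
#' @param state an `encoder_state`.
#' @param messages output of [attention_messages()].
#' @param graph the corresponding `hmgraph`.
#' @param params an `encoder_params`.
#' @param layer layer index (recorded in the result).
#' @return the updated `encoder_state`.
#' @export
update_state <- function(state, messages, graph, params, layer) {
  cg <- compile_graph(graph)
  tape <- ad_tape()
  P <- wrap_params(tape, params, trainable = FALSE)
  hv <- ad_const(tape, state$h_v)
  he <- if (cg$m > 0) ad_const(tape, state$h_e) else NULL
  mv <- ad_const(tape, messages$m_v)
  me <- if (cg$m > 0) ad_const(tape, messages$m_e) else NULL
  upd <- enc_update(cg, P, P$layers[[layer]], hv, he, mv, me)
  structure(list(h_v = ad_value(upd$hv),
                 h_e = if (is.null(upd$he)) matrix(0, 0, params$d) else
                   ad_value(upd$he),
                 layer = as.integer(layer)),
            class = "encoder_state")
}

#' Encode a graph into a d-dimensional embedding
#'
#' Runs initialization, `L` synchronous message-passing rounds and the
#' self-attention pooling readout.
#'
#' @param graph a featurized `hmgraph` (or list of graphs, encoded as a
#'   disjoint union with one embedding per graph).
#' @param params an `encoder_params`.
#' @return for a single graph, a `graph_embedding`: list with `h_g`
#'   (numeric, length d), and `pooling` (data frame of retained units with
#'   their normalized attention scores, which sum to 1). For a list input,
#'   a matrix with one row per graph.
#' @export
encode <- function(graph, params) {
  single <- inherits(graph, "hmgraph")
  cg <- compile_graph(graph)
  check_types_covered(cg, params)
  tape <- ad_tape()
  P <- wrap_params(tape, params, trainable = FALSE)
  fw <- enc_forward(tape, cg, P)
  if (!single) return(ad_value(fw$hg))
  pooling <- data.frame(
    unit = fw$unit_key[fw$kept],
    type = fw$unit_type[fw$kept],
    is_node = fw$unit_is_node[fw$kept],
    weight = fw$attn,
    stringsAsFactors = FALSE
  )
  structure(list(h_g = as.numeric(ad_value(fw$hg)), pooling = pooling),
            class = "graph_embedding")
}
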