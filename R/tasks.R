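# Orchestration: assembling aligned three-view batches, the contrastive
# pre-training step/loop, predictor heads for molecular property and DDI
# prediction, fine-tuning, and attention export for interpretation.

#' Build the aligned three-view batch for one mini-batch of records
#'
#' Produces N molecule views, N element views and M drug views (one per
#' drug-annotated record; those occupy the trailing batch positions).
#' Graph construction failures abort the batch naming the offending record.
#'
#' @param batch data frame with `smiles`, `drug_id`, `is_drug` (drug rows
#'   last), as produced by [make_batches()].
#' @param ekg an `element_kg`.
#' @param dkg a `drug_kg`.
#' @return a `view_batch`: lists `graphs_m`, `graphs_em`, `graphs_dm`,
#'   the drug count `M`, and precompiled encodings of each view set.
#' @export
build_view_batch <- function(batch, ekg, dkg) {
  N <- nrow(batch)
  assert_that(N > 0, "hmg_argument_error", "empty batch")
  if (any(batch$is_drug)) {
    assert_that(all(diff(batch$is_drug) >= 0), "hmg_argument_error",
                "drug records must occupy the trailing batch positions")
  } else {
    hmg_warn("hmg_degenerate_batch", "batch has no drug records")
  }
  graphs_m <- vector("list", N)
  graphs_em <- vector("list", N)
  graphs_dm <- list()
  for (i in seq_len(N)) {
    res <- tryCatch({
      gm <- featurize(build_molecule_view(batch$smiles[i]))
      gem <- attach_element_view(gm, ekg)
      gdm <- if (batch$is_drug[i])
        attach_drug_view(gm, batch$drug_id[i], dkg) else NULL
      list(gm = gm, gem = gem, gdm = gdm)
    }, hmg_error = function(e) {
      hmg_error("hmg_batch_error",
                sprintf("record %d ('%s'): %s", i, batch$smiles[i],
                        conditionMessage(e)))
    })
    graphs_m[[i]] <- res$gm
    graphs_em[[i]] <- res$gem
    if (!is.null(res$gdm)) graphs_dm[[length(graphs_dm) + 1]] <- res$gdm
  }
  structure(list(
    graphs_m = graphs_m, graphs_em = graphs_em, graphs_dm = graphs_dm,
    N = N, M = length(graphs_dm), records = batch,
    cg_m = compile_graph(graphs_m),
    cg_em = compile_graph(graphs_em),
    cg_dm = if (length(graphs_dm) > 0) compile_graph(graphs_dm) else NULL
  ), class = "view_batch")
}

#' One pre-training step: encode all views, project, contrastive loss
#'
#' All three view sets are encoded with the same shared encoder parameters
#' and projected with the same projector; the cross-view contrastive loss
#' and its gradients with respect to every encoder and projector parameter
#' are returned along with a per-term log record.
#'
#' @param vb a `view_batch`.
#' @param enc_params an `encoder_params`.
#' @param proj_params a `projector_params`.
#' @param cfg a `contrastive_config`.
#' @return list with `loss`, `terms` (named numeric), `grads` (list with
#'   flattened `encoder` and `projector` gradients), `z` (projected
#'   matrices) and `log` (record for JSON logging).
#' @export
pretrain_step <- function(vb, enc_params, proj_params,
                          cfg = contrastive_config()) {
  tape <- ad_tape()
  P <- wrap_params(tape, enc_params, trainable = TRUE)
  PP <- wrap_params(tape, proj_params, trainable = TRUE)
  check_types_covered(vb$cg_m, enc_params)
  check_types_covered(vb$cg_em, enc_params)
  hm <- enc_forward(tape, vb$cg_m, P)$hg
  hem <- enc_forward(tape, vb$cg_em, P)$hg
  zm <- proj_forward(tape, hm, PP)
  zem <- proj_forward(tape, hem, PP)
  if (!is.null(vb$cg_dm)) {
    check_types_covered(vb$cg_dm, enc_params)
    hdm <- enc_forward(tape, vb$cg_dm, P)$hg
    zdm <- proj_forward(tape, hdm, PP)
  } else {
    hmg_warn("hmg_degenerate_batch",
             "no drug views in batch; drug-view loss terms are 0")
    zdm <- ad_const(tape, matrix(numeric(0), 0, enc_params$d))
  }
  lt <- contrastive_total_tape(zm, zem, zdm, cfg$tau)
  ad_backward(lt$total)
  term_val <- vapply(lt$terms, function(x)
    if (is.null(x)) 0 else as.numeric(ad_value(x)), numeric(1))
  list(
    loss = as.numeric(ad_value(lt$total)),
    terms = term_val,
    grads = list(encoder = flatten_params(grad_tree(P)),
                 projector = flatten_params(grad_tree(PP))),
    z = list(z_m = ad_value(zm), z_em = ad_value(zem), z_dm = ad_value(zdm)),
    log = list(loss = as.numeric(ad_value(lt$total)),
               l_m_em = unname(term_val["m_em"]),
               l_m_dm = unname(term_val["m_dm"]),
               l_em_dm = unname(term_val["em_dm"]),
               tau = cfg$tau, N = vb$N, M = vb$M)
  )
}

#' Contrastive pre-training loop
#'
#' Generates drug-aware batches from the pool, builds the three-view sets
#' once, and runs Adam over the shared encoder and projector parameters,
#' cycling through the batches.
#'
#' @param pool a `molecule_pool`.
#' @param ekg an `element_kg`.
#' @param dkg a `drug_kg`.
#' @param steps number of optimization steps.
#' @param enc_params,proj_params initial parameters (fresh ones are created
#'   from `seed` when omitted).
#' @param cfg a `contrastive_config`.
#' @param N,n batch size and random complement size.
#' @param lr Adam learning rate.
#' @param seed integer seed.
#' @param log_path optional path for a JSON-lines training log.
#' @return list with trained `enc_params`, `proj_params`, and `history`
#'   (data frame of per-step losses).
#' @export
pretrain <- function(pool, ekg, dkg, steps = 50L, enc_params = NULL,
                     proj_params = NULL, cfg = contrastive_config(),
                     N = 10L, n = 1L, lr = 1e-3, seed = 1L,
                     log_path = NULL) {
  sp <- split_pool(pool)
  plan <- make_batches(sp$s_m, sp$s_d, N = N, n = n, seed = seed)
  vbs <- lapply(plan$batches, build_view_batch, ekg = ekg, dkg = dkg)
  if (is.null(enc_params)) enc_params <- encoder_params(seed = seed)
  if (is.null(proj_params)) proj_params <- projector_params(enc_params$d,
                                                            seed = seed + 1L)
  flat <- c(stats::setNames(flatten_params(enc_params),
                            paste0("enc.", names(flatten_params(enc_params)))),
            stats::setNames(flatten_params(proj_params),
                            paste0("proj.", names(flatten_params(proj_params)))))
  opt <- adam_init(flat)
  history <- data.frame(step = integer(0), loss = numeric(0))
  logcon <- if (!is.null(log_path)) file(log_path, open = "w") else NULL
  on.exit(if (!is.null(logcon)) close(logcon), add = TRUE)
  for (s in seq_len(steps)) {
    vb <- vbs[[((s - 1L) %% length(vbs)) + 1L]]
    st <- pretrain_step(vb, enc_params, proj_params, cfg)
    g <- c(stats::setNames(st$grads$encoder,
                           paste0("enc.", names(st$grads$encoder))),
           stats::setNames(st$grads$projector,
                           paste0("proj.", names(st$grads$projector))))
    res <- adam_step(flat, g, opt, lr = lr)
    flat <- res$flat; opt <- res$state
    enc_names <- grepl("^enc\\.", names(flat))
    enc_params <- unflatten_params(
      enc_params, stats::setNames(flat[enc_names],
                                  sub("^enc\\.", "", names(flat)[enc_names])))
    proj_params <- unflatten_params(
      proj_params, stats::setNames(flat[!enc_names],
                                   sub("^proj\\.", "", names(flat)[!enc_names])))
    history <- rbind(history, data.frame(step = s, loss = st$loss))
    if (!is.null(logcon)) {
      writeLines(jsonlite::toJSON(c(list(step = s), st$log),
                                  auto_unbox = TRUE, digits = NA), logcon)
    }
  }
  list(enc_params = enc_params, proj_params = proj_params, history = history)
}

#' Construct a predictor head
#'
#' A 2-layer MLP (tanh hidden layer) mapping an embedding of width `d_in`
#' (`d` for property prediction, `2d` for DDI) to `d_out` task outputs.
#' @param d_in input width.
#' @param width hidden width.
#' @param d_out output width.
#' @param seed integer seed.
#' @return a `predictor_head` object.
#' @export
predictor_head <- function(d_in, width = 32L, d_out = 1L, seed = 1L) {
  with_seed(seed, {
    u <- function(nr, nc) {
      lim <- 1 / sqrt(nr)
      matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
    }
    structure(list(d_in = d_in, width = width, d_out = d_out,
                   W1 = u(d_in, width), b1 = matrix(0, 1, width),
                   W2 = u(width, d_out), b2 = matrix(0, 1, d_out)),
              class = "predictor_head")
  })
}

head_forward <- function(tape, H, HP) {
  ad_add(ad_matmul(ad_tanh(ad_add(ad_matmul(H, HP$W1), HP$b1)), HP$W2),
         HP$b2)
}

head_predict <- function(H, head) {
  if (!is.matrix(H)) H <- matrix(H, nrow = 1)
  sweep(tanh(sweep(H %*% head$W1, 2, as.numeric(head$b1), "+")) %*% head$W2,
        2, as.numeric(head$b2), "+")
}

#' Predict a molecular property from a molecule view
#'
#' Encodes the graph and applies the property head; classification heads
#' emit logits.
#' @param g a featurized molecule-view `hmgraph`.
#' @param enc_params an `encoder_params`.
#' @param head a `predictor_head` with `d_in = d`.
#' @return numeric vector of length `d_out`.
#' @export
predict_property <- function(g, enc_params, head) {
  assert_that(head$d_in == enc_params$d, "hmg_schema_error",
              sprintf("head input width %d != encoder d %d", head$d_in,
                      enc_params$d))
  as.numeric(head_predict(encode(g, enc_params)$h_g, head))
}

#' Predict a drug-drug interaction from two molecule views
#'
#' Both graphs are encoded with the same encoder; the embeddings are
#' concatenated in argument order (the prediction is order-sensitive).
#' @param g1,g2 featurized molecule-view `hmgraph`s.
#' @param enc_params an `encoder_params`.
#' @param head a `predictor_head` with `d_in = 2d`.
#' @return numeric vector of length `d_out` (logits for classification).
#' @export
predict_ddi <- function(g1, g2, enc_params, head) {
  assert_that(head$d_in == 2L * enc_params$d, "hmg_schema_error",
              sprintf("head input width %d != 2 * encoder d %d", head$d_in,
                      2L * enc_params$d))
  h <- c(encode(g1, enc_params)$h_g, encode(g2, enc_params)$h_g)
  as.numeric(head_predict(h, head))
}

#' Export per-node pooling attention weights grouped by node type
#'
#' Weights come from the final self-attention pooling layer; units dropped
#' by pooling receive weight 0, and weights are renormalized within each
#' node type to sum to 1 (types with no retained node return zeros).
#'
#' @param g a featurized `hmgraph`.
#' @param enc_params an `encoder_params`.
#' @return named list (per node type) of named weight vectors over node ids.
#' @export
export_attention <- function(g, enc_params) {
  emb <- encode(g, enc_params)
  pooling <- emb$pooling[emb$pooling$is_node, , drop = FALSE]
  pooling$unit <- sub("^v:", "", pooling$unit)
  out <- list()
  for (ty in unique(g$nodes$type)) {
    ids <- g$nodes$id[g$nodes$type == ty]
    w <- stats::setNames(rep(0, length(ids)), ids)
    kept <- pooling[pooling$type == ty, , drop = FALSE]
    w[kept$unit] <- kept$weight
    if (sum(w) > 0) w <- w / sum(w)
    out[[ty]] <- w
  }
  out
}

#' Fine-tune a predictor head (and optionally the encoder) on a dataset
#'
#' Molecule-view-only encoding; the pre-training projector is not used.
#' By default the readout (pooling) parameters are re-initialized for the
#' task and the message-passing weights are kept frozen; with
#' `freeze_encoder = FALSE` the full encoder is trained. Loss is MSE for
#' regression and sigmoid cross-entropy for binary / multilabel tasks.
#'
#' @param dataset data frame with `smiles` (plus `smiles2` for DDI) and
#'   `label` columns.
#' @param enc_params pre-trained `encoder_params`.
#' @param kind one of `"regression"`, `"binary"`, `"multilabel"`.
#' @param epochs gradient-descent epochs (full batch).
#' @param lr Adam learning rate.
#' @param width hidden width of the head.
#' @param freeze_encoder keep encoder parameters fixed (default `TRUE`).
#' @param reset_readout re-initialize the pooling scorer for the task.
#' @param seed integer seed.
#' @return list with `head`, `enc_params`, `metrics` (per-epoch data
#'   frame) and `predictions` at the final epoch.
#' @export
finetune <- function(dataset, enc_params, kind = "regression", epochs = 200L,
                     lr = 1e-2, width = 32L, freeze_encoder = TRUE,
                     reset_readout = TRUE, seed = 1L) {
  assert_that(kind %in% c("regression", "binary", "multilabel"),
              "hmg_schema_error", sprintf("unknown task kind '%s'", kind))
  assert_that("smiles" %in% names(dataset) && "label" %in% names(dataset),
              "hmg_format_error", "dataset needs smiles and label columns")
  y <- as.matrix(dataset$label)
  if (kind != "regression" && !all(y %in% c(0, 1))) {
    hmg_error("hmg_schema_error",
              sprintf("labels for a %s task must be 0/1", kind))
  }
  is_ddi <- "smiles2" %in% names(dataset)
  if (reset_readout) {
    fresh <- encoder_params(d = enc_params$d, K = enc_params$K,
                            L = enc_params$L, r = enc_params$r,
                            d_kg = enc_params$d_kg, leak = enc_params$leak,
                            seed = seed + 17L)
    enc_params$readout <- fresh$readout
  }
  graphs1 <- lapply(dataset$smiles,
                    function(s) featurize(build_molecule_view(s)))
  graphs2 <- if (is_ddi) lapply(dataset$smiles2, function(s)
    featurize(build_molecule_view(s))) else NULL
  d_in <- if (is_ddi) 2L * enc_params$d else enc_params$d
  head <- predictor_head(d_in, width = width, d_out = ncol(y), seed = seed)
  cg1 <- compile_graph(graphs1)
  cg2 <- if (is_ddi) compile_graph(graphs2) else NULL

  task_loss <- function(tape, pred, Y) {
    if (kind == "regression") {
      ad_mean(ad_mul(ad_sub(pred, Y), ad_sub(pred, Y)))
    } else {
      # mean sigmoid cross-entropy, elementwise (covers multilabel):
      # log(1 + exp(p)) - y * p
      ad_mean(ad_sub(ad_softplus(pred), ad_mul(Y, pred)))
    }
  }

  flat <- flatten_params(head)
  if (!freeze_encoder) {
    ef <- flatten_params(enc_params)
    flat <- c(stats::setNames(flatten_params(head),
                              paste0("head.", names(flatten_params(head)))),
              stats::setNames(ef, paste0("enc.", names(ef))))
  }
  opt <- adam_init(flat)
  H_fixed <- NULL
  if (freeze_encoder) {
    H_fixed <- encode(graphs1, enc_params)
    if (is_ddi) H_fixed <- cbind(H_fixed, encode(graphs2, enc_params))
  }
  metrics <- data.frame(epoch = integer(0), loss = numeric(0),
                        metric = numeric(0))
  preds <- NULL
  for (ep in seq_len(epochs)) {
    tape <- ad_tape()
    HP <- wrap_params(tape, head, trainable = TRUE)
    if (freeze_encoder) {
      H <- ad_const(tape, H_fixed)
    } else {
      P <- wrap_params(tape, enc_params, trainable = TRUE)
      H <- enc_forward(tape, cg1, P)$hg
      if (is_ddi) H <- ad_cbind(list(H, enc_forward(tape, cg2, P)$hg))
    }
    pred <- head_forward(tape, H, HP)
    loss <- task_loss(tape, pred, ad_const(tape, y))
    ad_backward(loss)
    g <- flatten_params(grad_tree(HP))
    if (!freeze_encoder) {
      g <- c(stats::setNames(flatten_params(grad_tree(HP)),
                             paste0("head.", names(flatten_params(grad_tree(HP))))),
             stats::setNames(flatten_params(grad_tree(P)),
                             paste0("enc.", names(flatten_params(grad_tree(P))))))
    }
    res <- adam_step(flat, g, opt, lr = lr)
    flat <- res$flat; opt <- res$state
    if (freeze_encoder) {
      head <- unflatten_params(head, flat)
    } else {
      hn <- grepl("^head\\.", names(flat))
      head <- unflatten_params(
        head, stats::setNames(flat[hn], sub("^head\\.", "", names(flat)[hn])))
      enc_params <- unflatten_params(
        enc_params, stats::setNames(flat[!hn],
                                    sub("^enc\\.", "", names(flat)[!hn])))
    }
    pv <- ad_value(pred)
    met <- if (kind == "regression") sqrt(mean((pv - y)^2)) else
      mean((pv > 0) == (y > 0.5))
    metrics <- rbind(metrics,
                     data.frame(epoch = ep, loss = as.numeric(ad_value(loss)),
                                metric = met))
    preds <- pv
  }
  list(head = head, enc_params = enc_params, metrics = metrics,
       predictions = preds)
}
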