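# Independent dense oracles, written with explicit loops and plain matrix
# math (no tape, no index precomputation), used to cross-check the encoder
# and the contrastive loss.

# full encoder forward: returns per-layer states, attention weight lists,
# and the pooled graph embedding
dense_encode_oracle <- function(g, p) {
  n <- nrow(g$nodes); m <- nrow(g$edges)
  d <- p$d; K <- p$K; dk <- p$dk
  ntype <- g$nodes$type; etype <- g$edges$type
  src <- match(g$edges$src, g$nodes$id)
  dst <- match(g$edges$dst, g$nodes$id)

  hv <- matrix(0, n, d)
  for (i in seq_len(n)) {
    hv[i, ] <- as.numeric(matrix(g$node_features[[i]], 1) %*%
                            p$A[[ntype[i]]]) +
      as.numeric(p$a0) +
      as.numeric(matrix(g$pos[i, ], 1) %*% p$C0) + as.numeric(p$c0)
  }
  he <- matrix(0, max(m, 0), d)
  for (e in seq_len(m)) {
    he[e, ] <- as.numeric(matrix(g$edge_features[[e]], 1) %*%
                            p$B[[etype[e]]]) +
      as.numeric(p$b0) + hv[src[e], ]
  }
  states <- list(list(hv = hv, he = he))
  attn_sums <- numeric(0)

  for (l in seq_len(p$L)) {
    lp <- p$layers[[l]]
    qv <- kv <- vv <- array(0, c(n, dk, K))
    qe <- ke <- ve <- array(0, c(max(m, 1), dk, K))
    for (k in seq_len(K)) {
      for (i in seq_len(n)) {
        base_q <- matrix(hv[i, ], 1) %*% lp$WQ[[k]]
        base_k <- matrix(hv[i, ], 1) %*% lp$WK[[k]]
        base_v <- matrix(hv[i, ], 1) %*% lp$WV[[k]]
        qv[i, , k] <- base_q %*% p$Wdelta_v[[ntype[i]]]
        kv[i, , k] <- base_k %*% p$Wdelta_v[[ntype[i]]]
        vv[i, , k] <- base_v %*% p$Wdelta_v[[ntype[i]]]
      }
      for (e in seq_len(m)) {
        qe[e, , k] <- matrix(he[e, ], 1) %*% lp$WQ[[k]] %*%
          p$Wdelta_e[[etype[e]]]
        ke[e, , k] <- matrix(he[e, ], 1) %*% lp$WK[[k]] %*%
          p$Wdelta_e[[etype[e]]]
        ve[e, , k] <- matrix(he[e, ], 1) %*% lp$WV[[k]] %*%
          p$Wdelta_e[[etype[e]]]
      }
    }
    mv <- matrix(0, n, d)
    for (i in seq_len(n)) {
      inc <- which(dst == i)
      heads <- numeric(0)
      for (k in seq_len(K)) {
        if (length(inc) == 0) {
          heads <- c(heads, rep(0, dk))
          next
        }
        sc <- vapply(inc, function(e)
          sum(qv[i, , k] * ke[e, , k]) / sqrt(dk), numeric(1))
        w <- exp(sc - max(sc)); w <- w / sum(w)
        attn_sums <- c(attn_sums, sum(w))
        acc <- rep(0, dk)
        for (t in seq_along(inc)) acc <- acc + w[t] * ve[inc[t], , k]
        heads <- c(heads, acc)
      }
      mv[i, ] <- as.numeric(matrix(heads, 1) %*% lp$WVmix)
    }
    me <- matrix(0, max(m, 0), d)
    for (e in seq_len(m)) {
      i <- src[e]
      inc <- which(dst == i)   # includes the reverse edge
      heads <- numeric(0)
      for (k in seq_len(K)) {
        sc <- c(sum(qe[e, , k] * kv[i, , k]) / sqrt(dk),
                vapply(inc, function(e2)
                  sum(qe[e, , k] * ke[e2, , k]) / sqrt(dk), numeric(1)))
        w <- exp(sc - max(sc)); w <- w / sum(w)
        attn_sums <- c(attn_sums, sum(w))
        acc <- w[1] * vv[i, , k]
        for (t in seq_along(inc)) acc <- acc + w[1 + t] * ve[inc[t], , k]
        heads <- c(heads, acc)
      }
      me[e, ] <- as.numeric(matrix(heads, 1) %*% lp$WEmix)
    }
    hv2 <- matrix(0, n, d)
    for (i in seq_len(n)) {
      z <- matrix(c(hv[i, ], mv[i, ]), 1) %*% lp$Wupd_v[[ntype[i]]]
      hv2[i, ] <- ifelse(z > 0, z, p$leak * z)
    }
    he2 <- matrix(0, max(m, 0), d)
    for (e in seq_len(m)) {
      z <- matrix(c(he[e, ], me[e, ]), 1) %*% lp$Wupd_e[[etype[e]]]
      he2[e, ] <- ifelse(z > 0, z, p$leak * z)
    }
    hv <- hv2; he <- he2
    states[[l + 1]] <- list(hv = hv, he = he, mv = mv, me = me)
  }

  U <- rbind(hv, he)
  keys <- c(paste0("v:", g$nodes$id), paste0("e:", g$edges$id))
  s <- as.numeric(tanh(U %*% p$readout$ws + as.numeric(p$readout$bs)))
  kg <- ceiling(p$r * length(s))
  kept <- order(-s, keys)[seq_len(kg)]
  w <- exp(s[kept] - max(s[kept])); w <- w / sum(w)
  hg <- rep(0, d)
  for (t in seq_along(kept)) hg <- hg + w[t] * s[kept[t]] * U[kept[t], ]
  list(hg = hg, states = states, attn_sums = attn_sums,
       kept = sort(kept), pool_weights = w)
}

# literal term-by-term contrastive pair loss: enumerate every negative
# exponential explicitly
pair_loss_oracle <- function(z1, z2, i, tau) {
  n1 <- nrow(z1); n2 <- nrow(z2); M <- min(n1, n2)
  a1 <- n1 - M + i; p2 <- n2 - M + i
  num <- exp(sum(z1[a1, ] * z2[p2, ]) / tau)
  den <- 0; terms <- 0L
  for (j in seq_len(n1)) {
    if (j == a1) next
    den <- den + exp(sum(z1[a1, ] * z1[j, ]) / tau)
    terms <- terms + 1L
  }
  for (j in seq_len(n2)) {
    if (j == p2) next
    den <- den + exp(sum(z1[a1, ] * z2[j, ]) / tau)
    terms <- terms + 1L
  }
  list(loss = -log(num / den), n_terms = terms)
}

unit_rows <- function(m) m / sqrt(rowSums(m^2))
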