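# Independent oracles, written straight from the definitions and kept
# free of the package's internal code paths.

# Brute-force DFS over the type graph: all type paths from `from` of
# exactly `len` edges, every consecutive pair a schema relation.
oracle_type_paths <- function(schema, from, len) {
  has_rel <- function(a, b) {
    r <- schema$relations
    any((r$type_a == a & r$type_b == b) | (r$type_a == b & r$type_b == a))
  }
  out <- list()
  recurse <- function(path) {
    if (length(path) == len + 1) {
      out[[length(out) + 1]] <<- path
      return(invisible(NULL))
    }
    for (t in schema$node_types)
      if (has_rel(path[length(path)], t)) recurse(c(path, t))
  }
  recurse(from)
  out
}

# The enumeration rules, recomputed from the type-path oracle.
oracle_node_specific <- function(schema, anchors) {
  res <- character(0)
  for (a in intersect(anchors, schema$node_types)) {
    for (p in oracle_type_paths(schema, a, 2))
      if (p[3] == a) res <- c(res, paste(p, collapse = "-"))
  }
  sort(unique(res))
}

oracle_common <- function(schema, src, dst) {
  res <- character(0)
  for (len in 2:3) {
    for (p in oracle_type_paths(schema, src, len)) {
      if (p[length(p)] != dst) next
      mids <- p[-c(1, length(p))]
      if (any(mids %in% c(src, dst))) next
      res <- c(res, paste(p, collapse = "-"))
    }
  }
  r <- schema$relations
  if (any((r$type_a == src & r$type_b == dst) |
          (r$type_a == dst & r$type_b == src)))
    res <- c(res, paste(c(src, dst, src, dst), collapse = "-"))
  sort(unique(res))
}

# Brute-force node-level instance enumeration for a metapath type on a
# graph: recursive expansion over the raw edge lists, node-simple.
# Returns a matrix of global node indices (possibly 0 rows).
oracle_instances <- function(graph, types, start_global) {
  off <- local({
    sizes <- lengths(graph$nodes)
    stats::setNames(cumsum(c(0, sizes[-length(sizes)])), names(sizes))
  })
  neighbors <- function(g, from_type, to_type) {
    res <- integer(0)
    r <- graph$schema$relations
    for (i in seq_len(nrow(r))) {
      e <- graph$edges[[r$label[i]]]
      if (nrow(e) == 0) next
      if (r$type_a[i] == from_type && r$type_b[i] == to_type) {
        loc <- g - off[[from_type]]
        res <- c(res, off[[to_type]] + e[e[, 1] == loc, 2])
      }
      if (r$type_b[i] == from_type && r$type_a[i] == to_type) {
        loc <- g - off[[from_type]]
        res <- c(res, off[[to_type]] + e[e[, 2] == loc, 1])
      }
    }
    res
  }
  out <- list()
  recurse <- function(path) {
    k <- length(path)
    if (k == length(types)) {
      out[[length(out) + 1]] <<- path
      return(invisible(NULL))
    }
    for (nb in neighbors(path[k], types[k], types[k + 1]))
      if (!(nb %in% path)) recurse(c(path, nb))
  }
  recurse(start_global)
  if (length(out) == 0) matrix(integer(0), 0, length(types))
  else do.call(rbind, out)
}

# ---- straight-line single-pair pipeline oracle ---------------------------
# Composes projection, one RGCN layer, instance encoding, mean intra
# aggregation, inter-class self-attention and the decoder for ONE pair,
# all in plain loops.

oracle_softmax <- function(x) { z <- exp(x - max(x)); z / sum(z) }
oracle_lrelu <- function(x, s = 0.01) ifelse(x >= 0, x, s * x)

oracle_mlp <- function(prm, x, slope = 0.01) {
  z <- as.numeric(prm$W_in %*% x + prm$b_in)
  mu <- mean(z); sd <- sqrt(mean((z - mu)^2) + 1e-5)
  xhat <- (z - mu) / sd
  a <- oracle_lrelu(prm$g * xhat + prm$b_ln, slope)
  as.numeric(prm$W_out %*% a + prm$b_out)
}

oracle_score <- function(graph, state, config, u_id, v_id) {
  sch <- graph$schema
  off <- local({
    sizes <- lengths(graph$nodes)
    stats::setNames(cumsum(c(0, sizes[-length(sizes)])), names(sizes))
  })
  N <- sum(lengths(graph$nodes))
  d <- config$d
  # projection
  H0 <- matrix(0, N, d)
  for (t in sch$node_types) {
    for (i in seq_along(graph$nodes[[t]])) {
      x <- if (is.null(graph$features[[t]])) state$feat[[t]][i, ]
           else graph$features[[t]][i, ]
      H0[off[[t]] + i, ] <- as.numeric(state$proj$W[[t]] %*% x)
    }
  }
  # single RGCN layer, c_r = per-node per-directed-relation degree
  H1 <- matrix(0, N, d)
  for (t in sch$node_types) {
    for (i in seq_along(graph$nodes[[t]])) {
      g <- off[[t]] + i
      acc <- as.numeric(state$rgcn[[1]]$W0 %*% H0[g, ])
      for (ri in seq_len(nrow(sch$relations))) {
        lab <- sch$relations$label[ri]
        ta <- sch$relations$type_a[ri]; tb <- sch$relations$type_b[ri]
        e <- graph$edges[[lab]]
        if (nrow(e) == 0) next
        if (tb == t) {   # messages a -> b use W "<lab>|ab"
          nb <- off[[ta]] + e[e[, 2] == i, 1]
          if (length(nb))
            acc <- acc + as.numeric(state$rgcn[[1]]$Wr[[paste0(lab, "|ab")]] %*%
                                      colMeans(H0[nb, , drop = FALSE]))
        }
        if (ta == t) {   # messages b -> a use W "<lab>|ba"
          nb <- off[[tb]] + e[e[, 1] == i, 2]
          if (length(nb))
            acc <- acc + as.numeric(state$rgcn[[1]]$Wr[[paste0(lab, "|ba")]] %*%
                                      colMeans(H0[nb, , drop = FALSE]))
        }
      }
      H1[g, ] <- oracle_lrelu(acc, config$slope)
    }
  }
  H <- if (config$use_hmpnn) H1 else H0
  tys <- c("miRNA", "disease")
  u_loc <- match(u_id, graph$nodes$miRNA)
  v_loc <- match(v_id, graph$nodes$disease)
  gu <- off[["miRNA"]] + u_loc; gv <- off[["disease"]] + v_loc

  class_vec <- function(insts, W_P) {
    enc <- t(apply(insts, 1, function(p)
      as.numeric(W_P %*% colMeans(H[p, , drop = FALSE]))))
    if (nrow(insts) == 1)
      enc <- matrix(as.numeric(W_P %*% colMeans(H[insts[1, ], , drop = FALSE])),
                    nrow = 1)
    oracle_lrelu(colMeans(enc), config$slope)
  }
  inter <- function(Hcls, prm) {
    M <- nrow(Hcls)
    X <- t(apply(Hcls, 1, function(h) tanh(as.numeric(t(prm$W1) %*% h) + prm$b1)))
    Q <- X %*% prm$WQ; K <- X %*% prm$WK; V <- X %*% prm$WV
    dk <- ncol(Q)
    S <- Q %*% t(K) / sqrt(dk)
    A <- t(apply(S, 1, oracle_softmax))
    braw <- as.numeric((A %*% V) %*% prm$W2)
    beta <- oracle_softmax(braw)
    list(h = as.numeric(t(Hcls) %*% beta), beta = beta)
  }
  node_embed <- function(anchor_type, g_anchor, prm_inter) {
    cls <- enumerate_node_specific_types(sch, c("miRNA", "disease"))
    cls <- cls[vapply(cls, function(m) m$types[1] == anchor_type, TRUE)]
    Hcls <- t(vapply(names(cls), function(nm) {
      mp <- cls[[nm]]
      insts <- oracle_instances(graph, mp$types, g_anchor)
      if (nrow(insts) == 0) insts <- matrix(g_anchor, 1, 1)
      class_vec(insts, state$wp_node[[nm]])
    }, numeric(d)))
    inter(Hcls, prm_inter)
  }
  hu <- node_embed("miRNA", gu, state$inter_m)$h
  hv <- node_embed("disease", gv, state$inter_d)$h
  cls_p <- enumerate_common_types(sch)
  Hcls_p <- t(vapply(names(cls_p), function(nm) {
    mp <- cls_p[[nm]]
    insts <- oracle_instances(graph, mp$types, gu)
    if (nrow(insts)) insts <- insts[insts[, ncol(insts)] == gv, , drop = FALSE]
    if (nrow(insts)) {   # target-edge exclusion
      bad <- apply(insts, 1, function(p) {
        any((p[-length(p)] == gu & p[-1] == gv) |
            (p[-length(p)] == gv & p[-1] == gu))
      })
      insts <- insts[!bad, , drop = FALSE]
    }
    if (nrow(insts) == 0) insts <- matrix(c(gu, gv), 1, 2)
    class_vec(insts, state$wp_pair[[nm]])
  }, numeric(d)))
  huv <- inter(Hcls_p, state$inter_p)$h
  z <- oracle_mlp(state$dec$f1, hu * hv, config$slope) +
    state$dec$beta_dec * oracle_mlp(state$dec$f2, huv, config$slope)
  oracle_mlp(state$dec$f, z, config$slope)
}

# ---- metric oracles ------------------------------------------------------

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

oracle_ap <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  P <- numeric(length(th)); R <- numeric(length(th))
  M <- sum(labels == 1)
  for (k in seq_along(th)) {
    pred <- scores >= th[k]
    P[k] <- sum(pred & labels == 1) / sum(pred)
    R[k] <- sum(pred & labels == 1) / M
  }
  P <- c(1, P); R <- c(0, R)
  s <- 0
  for (k in seq_len(length(th)))
    s <- s + (R[k + 1] - R[k]) * (P[k] + P[k + 1]) / 2
  s
}
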