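# Batched assembly of the full forward pass:
# projection -> (RGCN) -> per-class metapath encoding -> intra aggregation
# -> inter-class attention -> structure-guided decoder.

# Precompute the sparse gather operators for a fixed pair set.  For every
# metapath class c a sparse matrix B_c maps node embeddings to the
# *instance-mean-of-node-means* per anchor (node classes) or per pair
# (common classes); with mean intra-class aggregation the class vector is
# then sigma((B_c H) t(W_c)).  For attention intra mode the per-instance
# averaging matrices and group maps are kept instead.
build_design <- function(graph, store, pairs, config) {
  tys <- store$anchor_types
  off <- type_offsets(graph)
  N <- n_nodes(graph)
  pairs <- as.matrix(pairs[, 1:2, drop = FALSE])
  am <- sort(unique(pairs[, 1]))
  ad <- sort(unique(pairs[, 2]))
  iu <- match(pairs[, 1], am)
  iv <- match(pairs[, 2], ad)

  node_class_names <- names(store$node_classes)
  m_classes <- node_class_names[vapply(store$node_classes,
                                       function(x) x$types[1] == tys[1],
                                       logical(1))]
  d_classes <- node_class_names[vapply(store$node_classes,
                                       function(x) x$types[1] == tys[2],
                                       logical(1))]
  p_classes <- names(store$pair_classes)

  gather_node <- function(cls, anchors, type) {
    lapply(cls, function(nm) {
      mp <- store$node_classes[[nm]]
      mats <- lapply(anchors, function(a) node_instances(store, a, mp))
      build_gather(mats, N, config$intra_mode)
    })
  }
  gather_pair <- function(cls) {
    lapply(cls, function(nm) {
      mp <- store$pair_classes[[nm]]
      mats <- lapply(seq_len(nrow(pairs)), function(i)
        pair_instances(store, pairs[i, 1], pairs[i, 2], mp))
      build_gather(mats, N, config$intra_mode)
    })
  }

  Bm <- setNames(gather_node(m_classes, am, tys[1]), m_classes)
  Bd <- setNames(gather_node(d_classes, ad, tys[2]), d_classes)
  Bp <- setNames(gather_pair(p_classes), p_classes)

  list(graph = graph, pairs = pairs, am = am, ad = ad, iu = iu, iv = iv,
       tys = tys, off = off, N = N,
       m_classes = m_classes, d_classes = d_classes, p_classes = p_classes,
       Bm = Bm, Bd = Bd, Bp = Bp,
       ops = if (config$use_hmpnn) rgcn_operators(graph) else NULL,
       pair_ids = cbind(graph$nodes[[tys[1]]][pairs[, 1]],
                        graph$nodes[[tys[2]]][pairs[, 2]]))
}

# mats: list (one per key) of instance matrices (global node indices).
build_gather <- function(mats, N, intra_mode) {
  K <- length(mats)
  if (intra_mode == "mean") {
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    for (k in seq_len(K)) {
      m <- mats[[k]]
      w <- 1 / (nrow(m) * ncol(m))
      ii <- c(ii, rep.int(k, length(m)))
      jj <- c(jj, as.integer(m))
      xx <- c(xx, rep.int(w, length(m)))
    }
    list(B = Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(K, N)),
         K = K)
  } else {
    # per-instance node-mean rows plus group index per key
    n_inst <- vapply(mats, nrow, integer(1))
    tot <- sum(n_inst)
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    row0 <- 0L
    for (k in seq_len(K)) {
      m <- mats[[k]]
      ii <- c(ii, rep(row0 + seq_len(nrow(m)), times = ncol(m)))
      jj <- c(jj, as.integer(m))
      xx <- c(xx, rep.int(1 / ncol(m), length(m)))
      row0 <- row0 + nrow(m)
    }
    grp <- rep(seq_len(K), n_inst)
    idx_by_key <- split(seq_len(tot), grp)
    list(Minst = Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                      dims = c(tot, N)),
         grp = grp, idx_by_key = idx_by_key, K = K)
  }
}

# Class-vector computation for one class (forward), mean or attention
# intra mode.  Returns the K x d class matrix plus cache.
class_forward <- function(gath, H, Wp, theta, config) {
  if (config$intra_mode == "mean") {
    U <- as.matrix(gath$B %*% H)
    S <- U %*% t(Wp)
    Z <- leaky_relu(S, config$slope)
    list(Z = Z, cache = list(U = U, S = S))
  } else {
    Mh <- as.matrix(gath$Minst %*% H)
    E <- Mh %*% t(Wp)
    sraw <- as.numeric(E %*% theta)
    s <- leaky_relu(sraw, config$slope)
    alpha <- numeric(length(s))
    out <- matrix(0, gath$K, ncol(E))
    for (k in seq_len(gath$K)) {
      idx <- gath$idx_by_key[[k]]
      a <- softmax_vec(s[idx])
      alpha[idx] <- a
      out[k, ] <- as.numeric(crossprod(E[idx, , drop = FALSE], a))
    }
    Z <- leaky_relu(out, config$slope)
    list(Z = Z, cache = list(Mh = Mh, E = E, sraw = sraw, s = s,
                             alpha = alpha, out = out))
  }
}

class_backward <- function(gath, H, Wp, theta, config, cache, dZ) {
  if (config$intra_mode == "mean") {
    dS <- dZ * leaky_relu_grad(cache$S, config$slope)
    dWp <- crossprod(dS, cache$U)
    dU <- dS %*% Wp
    dH <- as.matrix(Matrix::crossprod(gath$B, dU))
    list(dH = dH, dWp = dWp, dtheta = numeric(length(theta)))
  } else {
    dout <- dZ * leaky_relu_grad(cache$out, config$slope)
    E <- cache$E
    dE <- matrix(0, nrow(E), ncol(E))
    ds <- numeric(nrow(E))
    for (k in seq_len(gath$K)) {
      idx <- gath$idx_by_key[[k]]
      a <- cache$alpha[idx]
      dk_vec <- dout[k, ]
      dalpha <- as.numeric(E[idx, , drop = FALSE] %*% dk_vec)
      dE[idx, ] <- dE[idx, ] + tcrossprod(a, dk_vec)
      ds[idx] <- a * (dalpha - sum(a * dalpha))
    }
    dsraw <- ds * leaky_relu_grad(cache$sraw, config$slope)
    dtheta <- as.numeric(crossprod(E, dsraw))
    dE <- dE + tcrossprod(dsraw, theta)
    dWp <- crossprod(dE, cache$Mh)
    dMh <- dE %*% Wp
    dH <- as.matrix(Matrix::crossprod(gath$Minst, dMh))
    list(dH = dH, dWp = dWp, dtheta = dtheta)
  }
}

#' Full forward pass over a batch of candidate pairs
#'
#' Runs projection, the RGCN pre-encoding (once per call), the
#' node-specific pipelines for the two endpoints, the common-metapath
#' pipeline for each pair, and the structure-guided decoder.  Each pair is
#' scored independently of the rest of the batch.
#'
#' @param pairs two-column matrix of (miRNA, disease) local node indices,
#'   or a matrix with additional columns (extras ignored).
#' @param graph the training [hetero_graph()].
#' @param store an [build_instance_store()] covering the pairs.
#' @param state a [model_init()] parameter tree.
#' @param config an [mda_config()].
#' @return A data.frame with columns `miRNA_id`, `disease_id`,
#'   `probability`, `logit`; the per-pair inter-class weights are attached
#'   as attribute `"beta"` (pairs x common classes).
#' @export
forward_batch <- function(pairs, graph, store, state, config = mda_config()) {
  design <- build_design(graph, store, pairs, config)
  fw <- model_forward(state, design, config)
  out <- data.frame(miRNA_id = design$pair_ids[, 1],
                    disease_id = design$pair_ids[, 2],
                    probability = stats::plogis(fw$logits),
                    logit = fw$logits,
                    stringsAsFactors = FALSE)
  beta <- fw$beta_pair
  colnames(beta) <- design$p_classes
  attr(out, "beta") <- beta
  out
}

model_forward <- function(state, design, config, keep_cache = TRUE) {
  graph <- design$graph
  off <- design$off
  d <- config$d
  # projection (Eq-6-style type-specific maps)
  H0 <- matrix(0, design$N, d)
  Xs <- list()
  for (t in graph$schema$node_types) {
    n_t <- n_nodes(graph, t)
    if (n_t == 0) next
    X <- graph$features[[t]] %||% state$feat[[t]]
    Xs[[t]] <- X
    H0[off[[t]] + seq_len(n_t), ] <- X %*% t(state$proj$W[[t]])
  }
  # RGCN pre-encoding
  rg_cache <- list()
  H <- H0
  if (config$use_hmpnn) {
    for (l in seq_len(config$n_layers)) {
      prm <- state$rgcn[[l]]
      Z <- H %*% t(prm$W0)
      AH <- list()
      for (key in names(design$ops)) {
        AH[[key]] <- as.matrix(design$ops[[key]] %*% H)
        Z <- Z + AH[[key]] %*% t(prm$Wr[[key]])
      }
      rg_cache[[l]] <- list(Hin = H, Z = Z, AH = AH)
      H <- leaky_relu(Z, config$slope)
    }
  }
  # class vectors per pipeline
  run_classes <- function(cls, gaths, wps, thetas) {
    Zs <- list(); caches <- list()
    for (nm in cls) {
      cf <- class_forward(gaths[[nm]], H, wps[[nm]], thetas[[nm]], config)
      Zs[[nm]] <- cf$Z; caches[[nm]] <- cf$cache
    }
    list(Zs = Zs, caches = caches)
  }
  cm <- run_classes(design$m_classes, design$Bm, state$wp_node,
                    state$theta_node)
  cd <- run_classes(design$d_classes, design$Bd, state$wp_node,
                    state$theta_node)
  cp <- run_classes(design$p_classes, design$Bp, state$wp_pair,
                    state$theta_pair)
  stack <- function(Zs, cls) {
    M <- length(cls); K <- nrow(Zs[[cls[1]]])
    Hs <- matrix(0, K * M, d)
    for (c in seq_along(cls)) Hs[seq(c, K * M, by = M), ] <- Zs[[cls[c]]]
    Hs
  }
  Hs_m <- stack(cm$Zs, design$m_classes)
  Hs_d <- stack(cd$Zs, design$d_classes)
  Hs_p <- stack(cp$Zs, design$p_classes)
  inter_fn <- if (config$inter_mode == "self") {
    function(Hs, M, prm) inter_forward(Hs, M, prm, config$beta_normalize)
  } else {
    function(Hs, M, prm) additive_forward(Hs, M, prm)
  }
  im <- inter_fn(Hs_m, length(design$m_classes), state$inter_m)
  id_ <- inter_fn(Hs_d, length(design$d_classes), state$inter_d)
  ip <- inter_fn(Hs_p, length(design$p_classes), state$inter_p)
  Hu <- im$Hout[design$iu, , drop = FALSE]
  Hv <- id_$Hout[design$iv, , drop = FALSE]
  P <- Hu * Hv
  f1 <- mlp_forward(state$dec$f1, P, config$slope)
  f2 <- mlp_forward(state$dec$f2, ip$Hout, config$slope)
  Zdec <- if (config$use_link) f1$y + state$dec$beta_dec * f2$y else f1$y
  f <- mlp_forward(state$dec$f, Zdec, config$slope)
  logits <- as.numeric(f$y)
  res <- list(logits = logits, beta_pair = ip$beta,
              beta_m = im$beta, beta_d = id_$beta)
  if (keep_cache) {
    res$cache <- list(H0 = H0, H = H, Xs = Xs, rg = rg_cache,
                      cm = cm, cd = cd, cp = cp,
                      im = im, id_ = id_, ip = ip,
                      Hu = Hu, Hv = Hv, P = P,
                      f1 = f1, f2 = f2, f = f, Zdec = Zdec)
  }
  res
}

model_backward <- function(state, design, config, fw, dlogits) {
  cache <- fw$cache
  d <- config$d
  grads <- zero_like(state)
  dY <- matrix(dlogits, ncol = 1)
  # decoder
  bf <- mlp_backward(state$dec$f, cache$f$cache, dY)
  grads$dec$f <- bf$grads
  dZdec <- bf$dx
  if (config$use_link) {
    grads$dec$beta_dec <- sum(dZdec * cache$f2$y)
    dO2 <- state$dec$beta_dec * dZdec
  } else {
    grads$dec$beta_dec <- 0
    dO2 <- dZdec * 0
  }
  b1m <- mlp_backward(state$dec$f1, cache$f1$cache, dZdec)
  grads$dec$f1 <- b1m$grads
  dP <- b1m$dx
  b2m <- mlp_backward(state$dec$f2, cache$f2$cache, dO2)
  grads$dec$f2 <- b2m$grads
  dHp_out <- b2m$dx
  dHu <- dP * cache$Hv
  dHv <- dP * cache$Hu
  dHm_out <- rowsum(dHu, group = design$iu, reorder = TRUE)
  dHd_out <- rowsum(dHv, group = design$iv, reorder = TRUE)
  # inter-class attention
  back_fn <- if (config$inter_mode == "self") inter_backward
             else additive_backward
  bm <- back_fn(state$inter_m, cache$im$cache, dHm_out)
  bd <- back_fn(state$inter_d, cache$id_$cache, dHd_out)
  bp <- back_fn(state$inter_p, cache$ip$cache, dHp_out)
  grads$inter_m <- bm$grads
  grads$inter_d <- bd$grads
  grads$inter_p <- bp$grads
  # unstack per-class gradients and run class backward
  dH <- matrix(0, design$N, d)
  unstack_apply <- function(dHs, cls, gaths, caches, wps, thetas,
                            wp_slot, theta_slot) {
    M <- length(cls)
    for (c in seq_along(cls)) {
      nm <- cls[c]
      dZ <- dHs[seq(c, nrow(dHs), by = M), , drop = FALSE]
      cb <- class_backward(gaths[[nm]], cache$H, wps[[nm]], thetas[[nm]],
                           config, caches[[nm]], dZ)
      dH <<- dH + cb$dH
      grads[[wp_slot]][[nm]] <<- grads[[wp_slot]][[nm]] + cb$dWp
      grads[[theta_slot]][[nm]] <<- grads[[theta_slot]][[nm]] + cb$dtheta
    }
  }
  unstack_apply(bm$dH, design$m_classes, design$Bm, cache$cm$caches,
                state$wp_node, state$theta_node, "wp_node", "theta_node")
  unstack_apply(bd$dH, design$d_classes, design$Bd, cache$cd$caches,
                state$wp_node, state$theta_node, "wp_node", "theta_node")
  unstack_apply(bp$dH, design$p_classes, design$Bp, cache$cp$caches,
                state$wp_pair, state$theta_pair, "wp_pair", "theta_pair")
  # RGCN backward
  if (config$use_hmpnn) {
    for (l in rev(seq_len(config$n_layers))) {
      rc <- cache$rg[[l]]
      prm <- state$rgcn[[l]]
      dZ <- dH * leaky_relu_grad(rc$Z, config$slope)
      grads$rgcn[[l]]$W0 <- crossprod(dZ, rc$Hin)
      dHin <- dZ %*% prm$W0
      for (key in names(design$ops)) {
        grads$rgcn[[l]]$Wr[[key]] <- crossprod(dZ, rc$AH[[key]])
        dAH <- dZ %*% prm$Wr[[key]]
        dHin <- dHin + as.matrix(Matrix::crossprod(design$ops[[key]], dAH))
      }
      dH <- dHin
    }
  }
  # projection backward (dH is now dH0)
  for (t in names(state$proj$W)) {
    n_t <- n_nodes(design$graph, t)
    rows <- design$off[[t]] + seq_len(n_t)
    dH0t <- dH[rows, , drop = FALSE]
    grads$proj$W[[t]] <- crossprod(dH0t, cache$Xs[[t]])
    if (!is.null(state$feat[[t]]))
      grads$feat[[t]] <- dH0t %*% state$proj$W[[t]]
  }
  grads
}

#' Score one candidate pair with the structure-guided decoder
#'
#' Computes `logit = f( f1(h_u * h_v) + beta_dec * f2(h_uv) )` where `*`
#' is the Hadamard product, `h_u`/`h_v` are the two node-specific
#' embeddings and `h_uv` the common-metapath embedding.  With
#' `beta_dec = 0` the score is independent of `h_uv`.
#'
#' @param u,v node identifiers (carried through to the output).
#' @param h_u,h_v,h_uv numeric vectors of equal length `d`.
#' @param params decoder parameter list (`f1`, `f2`, `f` MLPs and scalar
#'   `beta_dec`), e.g. `state$dec`; an optional `slope` / `use_ln` entry
#'   overrides the MLP nonlinearity settings.
#' @return A one-row data.frame (`miRNA_id`, `disease_id`, `probability`,
#'   `logit`).
#' @export
score_pair <- function(u, v, h_u, h_v, h_uv, params) {
  if (length(h_u) != length(h_v) || length(h_u) != length(h_uv))
    stop("embedding dimension mismatch")
  slope <- params$slope %||% 0.01
  use_ln <- params$use_ln %||% TRUE
  p <- matrix(h_u * h_v, nrow = 1)
  o1 <- mlp_forward(params$f1, p, slope, use_ln)$y
  o2 <- mlp_forward(params$f2, matrix(h_uv, nrow = 1), slope, use_ln)$y
  z <- o1 + params$beta_dec * o2
  logit <- as.numeric(mlp_forward(params$f, z, slope, use_ln)$y)
  data.frame(miRNA_id = as.character(u), disease_id = as.character(v),
             probability = stats::plogis(logit), logit = logit,
             stringsAsFactors = FALSE)
}
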