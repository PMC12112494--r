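#' Model and training configuration
#'
#' Collects every tunable of the pipeline: latent dimensions, the ablation
#' switches, instance caps, and the optimizer protocol.  Defaults follow
#' the reference pipeline: one RGCN pre-encoding layer, mean intra-class
#' aggregation, sample-wise multiplicative self-attention across classes,
#' softmax-normalized class weights, and the structure-guided decoder term
#' active.
#'
#' @param d shared latent dimension (default 64).
#' @param d_in width of the learnable per-node free embeddings used when a
#'   type has no feature matrix (default `d`).
#' @param d_prime width of the attention transform (default `d`).
#' @param d_k query/key/value dimension (default `d/2`).
#' @param slope LeakyReLU negative slope.
#' @param n_layers number of RGCN layers (default 1).
#' @param use_hmpnn `FALSE` removes the pre-encoding (ablation `-HMPNN`);
#'   projected features feed the metapath encoders directly.
#' @param use_link `FALSE` removes the common-metapath decoder term
#'   (ablation `-link`), equivalent to pinning `beta_dec = 0`.
#' @param inter_mode `"self"` for sample-wise self-attention, `"additive"`
#'   for batch-based additive attention (ablation `-attn`).
#' @param intra_mode `"mean"` or `"attention"` (ablation `+iattn`).
#' @param beta_normalize apply softmax to inter-class scores (default);
#'   `FALSE` keeps the literal unnormalized weights.
#' @param self_supervised accepted and ignored (documented no-op: auxiliary
#'   self-supervision does not improve this architecture).
#' @param cap per-key metapath instance cap.
#' @param lr,weight_decay Adam learning rate and weight decay.
#' @param epochs,patience maximum epochs and early-stopping patience on
#'   validation AUC.
#' @param threshold classification threshold on the predicted probability.
#' @param seeds integer seeds of the multi-seed protocol.
#' @param ratios train/valid/test split fractions.
#' @param test_seed seed fixing the test split across protocol runs.
#' @param target label of the relation being predicted.
#' @return A named list of class `mda_config`.
#' @export
mda_config <- function(d = 64L, d_in = d, d_prime = d,
                       d_k = max(1L, d %/% 2L), slope = 0.01,
                       n_layers = 1L, use_hmpnn = TRUE, use_link = TRUE,
                       inter_mode = c("self", "additive"),
                       intra_mode = c("mean", "attention"),
                       beta_normalize = TRUE, self_supervised = FALSE,
                       cap = 32L, lr = 5e-3, weight_decay = 1e-4,
                       epochs = 200L, patience = 20L, threshold = 0.5,
                       seeds = 1:5, ratios = c(0.75, 0.10, 0.15),
                       test_seed = 100L, target = "miRNA-disease") {
  structure(list(
    d = as.integer(d), d_in = as.integer(d_in),
    d_prime = as.integer(d_prime), d_k = as.integer(d_k), slope = slope,
    n_layers = as.integer(n_layers), use_hmpnn = use_hmpnn,
    use_link = use_link, inter_mode = match.arg(inter_mode),
    intra_mode = match.arg(intra_mode), beta_normalize = beta_normalize,
    self_supervised = self_supervised,
    cap = as.integer(cap), lr = lr, weight_decay = weight_decay,
    epochs = as.integer(epochs), patience = as.integer(patience),
    threshold = threshold, seeds = as.integer(seeds), ratios = ratios,
    test_seed = as.integer(test_seed), target = target
  ), class = "mda_config")
}

glorot <- function(nout, nin) {
  matrix(rnorm(nout * nin, 0, sqrt(2 / (nin + nout))), nout, nin)
}

mlp_init <- function(d_in, d_hidden, d_out) {
  list(W_in = glorot(d_hidden, d_in), b_in = numeric(d_hidden),
       g = rep(1, d_hidden), b_ln = numeric(d_hidden),
       W_out = glorot(d_out, d_hidden), b_out = numeric(d_out))
}

inter_init <- function(d, dp, dk) {
  list(W1 = glorot(d, dp), b1 = numeric(dp),
       WQ = glorot(dp, dk), WK = glorot(dp, dk), WV = glorot(dp, dk),
       W2 = glorot(dk, 1), a_add = rnorm(dp, 0, 1 / sqrt(dp)))
}

#' Initialize all learnable parameter groups
#'
#' Builds the full model state for a graph: per-type projections (and
#' learnable free node embeddings for types without features), the RGCN
#' layer weights (two directed matrices per undirected relation plus the
#' self weight), one instance-encoder matrix and intra-attention vector
#' per metapath class, three inter-class attention heads (miRNA anchors,
#' disease anchors, pair classes), and the decoder MLPs with the learnable
#' structural-term scale `beta_dec` initialized to 1.
#'
#' @param graph a [hetero_graph()] (the training graph).
#' @param config an [mda_config()].
#' @param seed initialization seed.
#' @return Nested named list of parameters (the `ModelState`).
#' @export
model_init <- function(graph, config = mda_config(), seed = 1L) {
  d <- config$d
  with_seed(seed, {
    state <- list()
    state$feat <- list()
    state$proj <- list(W = list())
    for (t in graph$schema$node_types) {
      n_t <- n_nodes(graph, t)
      if (n_t == 0) next
      if (is.null(graph$features[[t]])) {
        state$feat[[t]] <- matrix(rnorm(n_t * config$d_in), n_t, config$d_in)
        d_t <- config$d_in
      } else {
        d_t <- ncol(graph$features[[t]])
      }
      state$proj$W[[t]] <- glorot(d, d_t)
    }
    state$rgcn <- lapply(seq_len(config$n_layers), function(l) {
      Wr <- list()
      for (lab in graph$schema$relations$label) {
        Wr[[paste0(lab, "|ab")]] <- glorot(d, d)
        Wr[[paste0(lab, "|ba")]] <- glorot(d, d)
      }
      list(W0 = glorot(d, d), Wr = Wr)
    })
    tys <- relation_types(graph$schema, config$target)
    node_classes <- enumerate_node_specific_types(graph$schema, tys)
    pair_classes <- enumerate_common_types(graph$schema,
                                           source = tys[1], target = tys[2])
    state$wp_node <- lapply(node_classes, function(x) glorot(d, d))
    state$wp_pair <- lapply(pair_classes, function(x) glorot(d, d))
    state$theta_node <- lapply(node_classes,
                               function(x) rnorm(d, 0, 1 / sqrt(d)))
    state$theta_pair <- lapply(pair_classes,
                               function(x) rnorm(d, 0, 1 / sqrt(d)))
    state$inter_m <- inter_init(d, config$d_prime, config$d_k)
    state$inter_d <- inter_init(d, config$d_prime, config$d_k)
    state$inter_p <- inter_init(d, config$d_prime, config$d_k)
    state$dec <- list(f1 = mlp_init(d, d, d), f2 = mlp_init(d, d, d),
                      f = mlp_init(d, d, 1), beta_dec = 1.0)
    state
  })
}

# ---- parameter-tree helpers ---------------------------------------------

tree_map <- function(x, f) {
  if (is.list(x)) lapply(x, tree_map, f = f) else f(x)
}

tree_map2 <- function(x, y, f) {
  if (is.list(x))
    mapply(tree_map2, x, y, MoreArgs = list(f = f), SIMPLIFY = FALSE)
  else f(x, y)
}

tree_map3 <- function(x, y, z, f) {
  if (is.list(x))
    mapply(tree_map3, x, y, z, MoreArgs = list(f = f), SIMPLIFY = FALSE)
  else f(x, y, z)
}

zero_like <- function(x) tree_map(x, function(v) v * 0)

tree_sum_sq <- function(x) {
  if (is.list(x)) sum(vapply(x, tree_sum_sq, numeric(1))) else sum(x^2)
}

# ---- primitive layers with backward passes ------------------------------

layernorm_forward <- function(z, g, b, eps = 1e-5) {
  mu <- rowMeans(z)
  zc <- z - mu
  sd <- sqrt(rowMeans(zc^2) + eps)
  xhat <- zc / sd
  out <- sweep(xhat * rep(g, each = nrow(z)), 2, b, "+")
  list(out = out, xhat = xhat, sd = sd)
}

layernorm_backward <- function(dout, cache, g) {
  xhat <- cache$xhat
  dxhat <- dout * rep(g, each = nrow(dout))
  dg <- colSums(dout * xhat)
  db <- colSums(dout)
  dz <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / cache$sd
  list(dz = dz, dg = dg, db = db)
}

mlp_forward <- function(prm, x, slope = 0.01, use_ln = TRUE) {
  z1 <- sweep(x %*% t(prm$W_in), 2, prm$b_in, "+")
  if (use_ln) {
    ln <- layernorm_forward(z1, prm$g, prm$b_ln)
    a_in <- ln$out
  } else {
    ln <- NULL
    a_in <- z1
  }
  a <- leaky_relu(a_in, slope)
  y <- sweep(a %*% t(prm$W_out), 2, prm$b_out, "+")
  list(y = y, cache = list(x = x, z1 = z1, ln = ln, a_in = a_in, a = a,
                           slope = slope, use_ln = use_ln))
}

mlp_backward <- function(prm, cache, dy) {
  g <- list(W_out = crossprod(dy, cache$a), b_out = colSums(dy),
            g = numeric(length(prm$g)), b_ln = numeric(length(prm$b_ln)))
  da <- dy %*% prm$W_out
  da_in <- da * leaky_relu_grad(cache$a_in, cache$slope)
  if (cache$use_ln) {
    lnb <- layernorm_backward(da_in, cache$ln, prm$g)
    g$g <- lnb$dg; g$b_ln <- lnb$db
    dz1 <- lnb$dz
  } else {
    dz1 <- da_in
  }
  g$W_in <- crossprod(dz1, cache$x)
  g$b_in <- colSums(dz1)
  dx <- dz1 %*% prm$W_in
  list(dx = dx, grads = g[c("W_in", "b_in", "g", "b_ln", "W_out", "b_out")])
}

# Sample-wise multiplicative self-attention over M classes, batched over S
# samples.  `Hstack` is (S*M) x d in sample-major order (sample s occupies
# rows (s-1)*M + 1:M).
inter_forward <- function(Hstack, M, prm, normalize = TRUE) {
  S <- nrow(Hstack) / M
  dk <- ncol(prm$WQ)
  Xp <- sweep(Hstack %*% prm$W1, 2, prm$b1, "+")
  X <- tanh(Xp)
  Q <- X %*% prm$WQ; K <- X %*% prm$WK; V <- X %*% prm$WV
  A_list <- vector("list", S)
  G <- matrix(0, S * M, dk)
  beta_raw <- matrix(0, S, M)
  for (s in seq_len(S)) {
    idx <- (s - 1) * M + seq_len(M)
    Ss <- tcrossprod(Q[idx, , drop = FALSE], K[idx, , drop = FALSE]) / sqrt(dk)
    As <- exp(Ss - apply(Ss, 1, max))
    As <- As / rowSums(As)
    A_list[[s]] <- As
    Gs <- As %*% V[idx, , drop = FALSE]
    G[idx, ] <- Gs
    beta_raw[s, ] <- as.numeric(Gs %*% prm$W2)
  }
  beta <- if (normalize) {
    t(apply(beta_raw, 1, softmax_vec))
  } else beta_raw
  if (M == 1) beta <- matrix(beta, S, 1)
  Hout <- matrix(0, S, ncol(Hstack))
  for (s in seq_len(S)) {
    idx <- (s - 1) * M + seq_len(M)
    Hout[s, ] <- as.numeric(crossprod(Hstack[idx, , drop = FALSE], beta[s, ]))
  }
  list(Hout = Hout, beta = beta,
       cache = list(Hstack = Hstack, X = X, Q = Q, K = K, V = V,
                    A_list = A_list, G = G, beta_raw = beta_raw,
                    beta = beta, M = M, normalize = normalize))
}

inter_backward <- function(prm, cache, dHout) {
  M <- cache$M
  S <- nrow(dHout)
  dk <- ncol(prm$WQ)
  H <- cache$Hstack; X <- cache$X
  dH <- matrix(0, nrow(H), ncol(H))
  dG <- matrix(0, nrow(H), dk)
  dW2 <- matrix(0, dk, 1)
  dQ <- matrix(0, nrow(H), dk); dK <- dQ; dV <- dQ
  for (s in seq_len(S)) {
    idx <- (s - 1) * M + seq_len(M)
    Hs <- H[idx, , drop = FALSE]
    beta_s <- cache$beta[s, ]
    dh <- dHout[s, ]
    dbeta <- as.numeric(Hs %*% dh)
    dH[idx, ] <- dH[idx, ] + tcrossprod(beta_s, dh)
    if (cache$normalize) {
      draw <- beta_s * (dbeta - sum(beta_s * dbeta))
    } else draw <- dbeta
    Gs <- cache$G[idx, , drop = FALSE]
    dW2 <- dW2 + crossprod(Gs, matrix(draw, ncol = 1))
    dGs <- matrix(draw, ncol = 1) %*% t(prm$W2)
    As <- cache$A_list[[s]]
    Vs <- cache$V[idx, , drop = FALSE]
    dAs <- tcrossprod(dGs, Vs)
    dV[idx, ] <- crossprod(As, dGs)
    rs <- rowSums(As * dAs)
    dSs <- As * (dAs - rs)
    dQ[idx, ] <- dSs %*% cache$K[idx, , drop = FALSE] / sqrt(dk)
    dK[idx, ] <- crossprod(dSs, cache$Q[idx, , drop = FALSE]) / sqrt(dk)
  }
  dX <- dQ %*% t(prm$WQ) + dK %*% t(prm$WK) + dV %*% t(prm$WV)
  dXp <- dX * (1 - X^2)
  grads <- list(W1 = crossprod(H, dXp), b1 = colSums(dXp),
                WQ = crossprod(X, dQ), WK = crossprod(X, dK),
                WV = crossprod(X, dV), W2 = dW2,
                a_add = numeric(length(prm$a_add)))
  dH <- dH + dXp %*% t(prm$W1)
  list(dH = dH, grads = grads)
}

# Batch-based additive attention (the `-attn` ablation): one weight per
# class, shared across the whole batch, scored from the batch mean.
additive_forward <- function(Hstack, M, prm) {
  S <- nrow(Hstack) / M
  Xp <- sweep(Hstack %*% prm$W1, 2, prm$b1, "+")
  X <- tanh(Xp)
  e <- as.numeric(X %*% prm$a_add)
  E <- matrix(e, S, M, byrow = TRUE)
  scores <- colMeans(E)
  beta_shared <- softmax_vec(scores)
  beta <- matrix(beta_shared, S, M, byrow = TRUE)
  Hout <- matrix(0, S, ncol(Hstack))
  for (s in seq_len(S)) {
    idx <- (s - 1) * M + seq_len(M)
    Hout[s, ] <- as.numeric(crossprod(Hstack[idx, , drop = FALSE], beta_shared))
  }
  list(Hout = Hout, beta = beta,
       cache = list(Hstack = Hstack, X = X, beta_shared = beta_shared,
                    M = M, S = S))
}

additive_backward <- function(prm, cache, dHout) {
  M <- cache$M; S <- cache$S
  H <- cache$Hstack; X <- cache$X
  beta_s <- cache$beta_shared
  dH <- matrix(0, nrow(H), ncol(H))
  dbeta <- numeric(M)
  for (s in seq_len(S)) {
    idx <- (s - 1) * M + seq_len(M)
    Hs <- H[idx, , drop = FALSE]
    dH[idx, ] <- dH[idx, ] + tcrossprod(beta_s, dHout[s, ])
    dbeta <- dbeta + as.numeric(Hs %*% dHout[s, ])
  }
  dscores <- beta_s * (dbeta - sum(beta_s * dbeta))
  de_rows <- matrix(dscores / S, S, M, byrow = TRUE)
  de <- as.numeric(t(de_rows))
  dX <- de %*% t(prm$a_add)
  da_add <- as.numeric(crossprod(X, de))
  dXp <- dX * (1 - X^2)
  grads <- list(W1 = crossprod(H, dXp), b1 = colSums(dXp),
                WQ = matrix(0, nrow(prm$WQ), ncol(prm$WQ)),
                WK = matrix(0, nrow(prm$WK), ncol(prm$WK)),
                WV = matrix(0, nrow(prm$WV), ncol(prm$WV)),
                W2 = matrix(0, nrow(prm$W2), 1),
                a_add = da_add)
  dH <- dH + dXp %*% t(prm$W1)
  list(dH = dH, grads = grads)
}
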