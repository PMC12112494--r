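#' Encode one metapath instance
#'
#' The instance encoding is the class weight matrix applied to the mean of
#' the embeddings of *all* nodes on the path, endpoints included.
#' Degenerate fallback instances (a single node, or the bare pair) encode
#' the mean of their one or two node embeddings.
#'
#' @param instance integer vector (or 1-row matrix) of global node indices.
#' @param h `N x d` embedding matrix.
#' @param params list with `W_P` (`d x d`).
#' @return Numeric vector of length `d`.
#' @export
encode_instance <- function(instance, h, params) {
  instance <- as.integer(instance)
  if (length(instance) == 0) stop("empty metapath instance")
  m <- colMeans(h[instance, , drop = FALSE])
  as.numeric(params$W_P %*% m)
}

#' Intra-class metapath aggregation
#'
#' Collapses the encoded instances of one metapath class into one vector.
#' In `"mean"` mode (the default pipeline) this is the activation of the
#' arithmetic mean; in `"attention"` mode instances are weighted by a
#' softmax over `LeakyReLU(Theta . h_i)` scores before the activation, and
#' the weights form a probability vector.
#'
#' @param encoded list of equal-length numeric vectors, or a matrix with
#'   one encoded instance per row.
#' @param params list with `mode` (`"mean"` or `"attention"`), `theta`
#'   (length-`d` score vector, attention mode), optional `sigma`
#'   (activation, default LeakyReLU) and `slope` for the score
#'   nonlinearity.
#' @return Numeric vector of length `d`, with attribute `"alpha"` (the
#'   instance weights) in attention mode.
#' @export
aggregate_intra <- function(encoded, params = list(mode = "mean")) {
  if (is.list(encoded)) encoded <- do.call(rbind, encoded)
  if (is.null(dim(encoded))) encoded <- matrix(encoded, nrow = 1)
  if (nrow(encoded) == 0) stop("empty instance list")
  sigma <- params$sigma %||% function(x) leaky_relu(x)
  mode <- params$mode %||% "mean"
  if (mode == "mean") {
    return(sigma(colMeans(encoded)))
  }
  slope <- params$slope %||% 0.01
  scores <- leaky_relu(as.numeric(encoded %*% params$theta), slope)
  alpha <- softmax_vec(scores)
  out <- sigma(as.numeric(crossprod(encoded, alpha)))
  attr(out, "alpha") <- alpha
  out
}

#' Inter-class sample-wise self-attention aggregation
#'
#' Fuses the `M` per-class metapath vectors of one sample into a single
#' vector through multiplicative self-attention computed entirely within
#' the sample: `X = tanh(H W1 + b1)` row-wise, `Q/K/V` linear projections
#' of `X`, attention `A = softmax(Q K' / sqrt(d_k))`, raw class scores
#' `(A V) W2`, and class weights `beta` by softmax over those scores
#' (`normalize = FALSE` keeps the raw scores, the literal unnormalized
#' variant).  The output is the beta-weighted sum of the original class
#' vectors.  Because nothing crosses sample boundaries, the operator is
#' batch independent.
#'
#' @param class_vectors `M x d` matrix (one row per metapath class, in
#'   catalogue order).
#' @param params list with `W1` (`d x d'`), `b1` (length `d'`), `WQ`, `WK`,
#'   `WV` (`d' x d_k`), `W2` (`d_k x 1`).
#' @param normalize apply the softmax to the class scores (default TRUE).
#' @return List with `h` (length-`d` vector) and `beta` (length-`M`
#'   weights).
#' @export
aggregate_inter <- function(class_vectors, params, normalize = TRUE) {
  H <- as.matrix(class_vectors)
  M <- nrow(H)
  if (M < 1) stop("need at least one class vector")
  X <- tanh(sweep(H %*% params$W1, 2, params$b1, "+"))
  Q <- X %*% params$WQ
  K <- X %*% params$WK
  V <- X %*% params$WV
  dk <- ncol(Q)
  S <- tcrossprod(Q, K) / sqrt(dk)
  A <- t(apply(S, 1, softmax_vec))
  if (M == 1) A <- matrix(A, 1, 1)
  beta_raw <- as.numeric((A %*% V) %*% params$W2)
  beta <- if (normalize) softmax_vec(beta_raw) else beta_raw
  list(h = as.numeric(crossprod(H, beta)), beta = beta)
}
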