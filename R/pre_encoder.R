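#' Type-specific feature projection
#'
#' Projects every node's raw feature vector into a shared latent space via
#' a per-type linear map: `h_v = W_T x_v`.  Raw features come from
#' `graph$features`, or from `params$X` (the learnable per-node free
#' embeddings used when no biological features are supplied).
#'
#' @param graph a [hetero_graph()].
#' @param params list with `W`, a named list of `d x d_T` matrices (one per
#'   node type), and optionally `X`, a named list of `n_T x d_T` raw
#'   feature matrices overriding `graph$features`.
#' @return A `N x d` matrix of projected embeddings in global node order.
#' @export
project_features <- function(graph, params) {
  d <- nrow(params$W[[1]])
  out <- matrix(0, n_nodes(graph), d)
  off <- type_offsets(graph)
  for (t in graph$schema$node_types) {
    n_t <- n_nodes(graph, t)
    if (n_t == 0) next
    X <- params$X[[t]] %||% graph$features[[t]]
    if (is.null(X)) stop("no features for type ", t)
    W <- params$W[[t]]
    if (ncol(W) != ncol(X))
      stop("feature width ", ncol(X), " does not match W_T (",
           ncol(W), ") for type ", t)
    out[off[[t]] + seq_len(n_t), ] <- X %*% t(W)
  }
  out
}

# Row-normalized directed message operators, one per (relation, direction):
# key "<label>|ab" sends messages from type_a endpoints to type_b nodes,
# "<label>|ba" the reverse.  Entry (v, u) = 1/|N_r(v)| (per-node in-degree
# normalizer).
rgcn_operators <- function(graph) {
  N <- n_nodes(graph)
  off <- type_offsets(graph)
  ops <- list()
  for (i in seq_len(nrow(graph$schema$relations))) {
    lab <- graph$schema$relations$label[i]
    ta <- graph$schema$relations$type_a[i]
    tb <- graph$schema$relations$type_b[i]
    e <- graph$edges[[lab]]
    ga <- off[[ta]] + e[, 1]
    gb <- off[[tb]] + e[, 2]
    mk <- function(src, dst) {
      A <- Matrix::sparseMatrix(i = dst, j = src, x = 1, dims = c(N, N))
      deg <- Matrix::rowSums(A)
      deg[deg == 0] <- 1
      Matrix::Diagonal(x = 1 / deg) %*% A
    }
    ops[[paste0(lab, "|ab")]] <- mk(ga, gb)
    ops[[paste0(lab, "|ba")]] <- mk(gb, ga)
  }
  ops
}

#' One relational graph convolution layer
#'
#' Updates every node as
#' `h_v' = sigma( W_0 h_v + sum_r sum_{u in N_r(v)} (1/|N_r(v)|) W_r h_u )`,
#' with one weight matrix per *directed* relation (each undirected relation
#' contributes two).  An isolated node receives `sigma(W_0 h_v)`.
#'
#' @param graph a [hetero_graph()].
#' @param h `N x d` embedding matrix in global node order.
#' @param params list with `W0` (`d x d`), `Wr` (named list of `d x d`
#'   matrices keyed `"<label>|ab"` / `"<label>|ba"`; missing keys are
#'   treated as zero), and optional `sigma` (activation function; default
#'   LeakyReLU with slope 0.01).
#' @return The updated `N x d` embedding matrix.
#' @export
rgcn_layer <- function(graph, h, params) {
  sigma <- params$sigma %||% function(x) leaky_relu(x)
  ops <- rgcn_operators(graph)
  z <- h %*% t(params$W0)
  for (key in names(ops)) {
    W <- params$Wr[[key]]
    if (is.null(W)) next
    z <- z + as.matrix(ops[[key]] %*% (h %*% t(W)))
  }
  sigma(z)
}
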