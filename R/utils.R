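#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils head read.table write.table
NULL

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit hash of a character key, used to derive per-key
# subsampling seeds from one base seed.
hash31 <- function(key) {
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

derive_seed <- function(base_seed, key) {
  as.integer((as.numeric(base_seed) * 1000003 + hash31(key)) %% 2147483647)
}

leaky_relu <- function(x, slope = 0.01) {
  ifelse(x >= 0, x, slope * x)
}

leaky_relu_grad <- function(x, slope = 0.01) {
  ifelse(x >= 0, 1, slope)
}

softmax_vec <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
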