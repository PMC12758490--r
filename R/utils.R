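#' @useDynLib ibflow, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats kmeans rnorm runif predict approx integrate optimize
#'   ks.test sd
#' @importFrom utils head tail
NULL

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Counter-based fan-out of one user seed into independent component seeds,
# so adding a consumer never shifts another consumer's stream.
fan_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 1000003 * as.double(index)) %%
               2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dim <- function(what, expected, actual) {
  stop(sprintf("%s: expected dimension %d, got %d", what, expected, actual),
       call. = FALSE)
}

as_matrix_rows <- function(z, dim, what = "z") {
  if (is.null(base::dim(z))) {
    if (length(z) != dim) stop_dim(what, dim, length(z))
    z <- matrix(z, nrow = 1L)
  } else {
    z <- as.matrix(z)
    if (ncol(z) != dim) stop_dim(what, dim, ncol(z))
  }
  z
}

row_norms <- function(m) sqrt(rowSums(m * m))

logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

softmax_rows <- function(logits) {
  e <- exp(logits - apply(logits, 1L, max))
  e / rowSums(e)
}
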