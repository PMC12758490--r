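# Histogram densities, symmetric KL divergence, free-energy surfaces, and
# Markov-state-model diagnostics (GMRQ, implied timescales) for evaluating
# generated latent ensembles and decoded state assignments.

#' 2D histogram density with probability floor
#'
#' Bins `points` on a 100 x 100 grid spanning the min/max of
#' `reference` along each axis (the evaluation convention: edges always come
#' from the reference/validation set). Out-of-range points are clipped into
#' the edge bins so counts are conserved. Probabilities are normalized,
#' floored at `epsilon`, and renormalized.
#'
#' @param points Two-column matrix of points to bin.
#' @param reference Two-column matrix defining the bin edges (defaults to
#'   `points`).
#' @param bins Bins per axis (default 100).
#' @param epsilon Probability floor (default 1e-5).
#' @return An object of class `"histogram2d"`: `edges` (per-axis boundary
#'   vectors), `p` (bins x bins probability matrix), `epsilon`.
#' @export
histogram_density <- function(points, reference = points, bins = 100L,
                              epsilon = 1e-5) {
  points <- as.matrix(points); reference <- as.matrix(reference)
  stopifnot(ncol(points) == 2L, ncol(reference) == 2L, nrow(points) >= 1L)
  edges <- lapply(1:2, function(j) {
    lo <- min(reference[, j]); hi <- max(reference[, j])
    if (hi <= lo) stop(sprintf("degenerate axis %d: min == max (%g)", j, lo))
    seq(lo, hi, length.out = bins + 1L)
  })
  ix <- pmin(pmax(findInterval(points[, 1], edges[[1]],
                               rightmost.closed = TRUE), 1L), bins)
  iy <- pmin(pmax(findInterval(points[, 2], edges[[2]],
                               rightmost.closed = TRUE), 1L), bins)
  counts <- matrix(tabulate(as.integer((iy - 1L) * bins + ix), bins * bins),
                   bins, bins)
  p <- counts / sum(counts)
  p <- pmax(p, epsilon)
  p <- p / sum(p)
  structure(list(edges = edges, p = p, epsilon = epsilon),
            class = "histogram2d")
}

#' @export
print.histogram2d <- function(x, ...) {
  b <- nrow(x$p)
  cat(sprintf("histogram2d: %d x %d bins, floor %g\n", b, b, x$epsilon))
  invisible(x)
}

#' Symmetric Kullback-Leibler divergence between two histograms
#'
#' `KL(P||Q) + KL(Q||P)` over the floored bin probabilities (the full sum,
#' not halved). Requires identical binning.
#'
#' @param P,Q [histogram_density()] objects on the same edges.
#' @return A nonnegative scalar; zero iff the histograms are identical.
#' @export
symmetric_kl <- function(P, Q) {
  stopifnot(inherits(P, "histogram2d"), inherits(Q, "histogram2d"))
  if (!isTRUE(all.equal(P$edges, Q$edges, tolerance = 1e-12)))
    stop("histogram binning mismatch")
  sum(P$p * log(P$p / Q$p)) + sum(Q$p * log(Q$p / P$p))
}

#' Free-energy surface from a histogram
#'
#' `F = -kT log p` per bin, shifted so the minimum is zero. The probability
#' floor guarantees finiteness.
#'
#' @param hist A [histogram_density()] object.
#' @param kT Thermal energy (default 1).
#' @return A matrix of free energies on the histogram's grid, with bin-center
#'   coordinates in attributes `"x"` and `"y"`.
#' @export
fes <- function(hist, kT = 1) {
  stopifnot(inherits(hist, "histogram2d"))
  f <- -kT * log(hist$p)
  f <- f - min(f)
  mid <- function(e) (e[-1] + e[-length(e)]) / 2
  attr(f, "x") <- mid(hist$edges[[1]])
  attr(f, "y") <- mid(hist$edges[[2]])
  f
}

#' Build a Markov state model from a label sequence
#'
#' Transition counts at the given lag (never crossing segment boundaries)
#' are symmetrized, `(C + C^T) / 2`, as a detailed-balance surrogate, then
#' row-normalized. Eigenvalues are real and sorted in decreasing order; the
#' stationary distribution is proportional to the symmetrized row sums.
#'
#' @param labels Integer state labels (1-based), or a [state_assignment()].
#' @param lag Lag in frames.
#' @param segments Optional contiguous-segment lengths (default: one
#'   segment).
#' @param n_states Optional state count (default `max(labels)`).
#' @return An object of class `"msm_model"` with `transition` (row-stochastic
#'   matrix), `eigenvalues`, `stationary`, `lag`, `n_states`.
#' @export
build_msm <- function(labels, lag, segments = NULL, n_states = NULL) {
  if (inherits(labels, "state_assignment")) labels <- labels$labels
  labels <- as.integer(labels)
  n_states <- as.integer(n_states %||% max(labels))
  if (n_states < 2L) stop("need at least 2 states")
  pairs <- make_lagged_pairs(segments %||% length(labels), lag)
  C <- matrix(0, n_states, n_states)
  tab <- table(factor(labels[pairs[, 1L]], levels = seq_len(n_states)),
               factor(labels[pairs[, 2L]], levels = seq_len(n_states)))
  C <- C + as.matrix(tab)
  Cs <- (C + t(C)) / 2
  rs <- rowSums(Cs)
  if (any(rs == 0))
    stop("state(s) ", paste(which(rs == 0), collapse = ", "),
         " have no transitions at this lag")
  P <- Cs / rs
  # reversible: eigenvalues via the symmetric similar matrix
  D <- sqrt(rs)
  S <- Cs / outer(D, D)
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  structure(list(transition = P, eigenvalues = ev,
                 stationary = unname(rs / sum(rs)), lag = lag,
                 n_states = n_states),
            class = "msm_model")
}

#' @export
print.msm_model <- function(x, ...) {
  cat(sprintf("MSM: %d states at lag %g; eigenvalues: %s\n", x$n_states,
              x$lag, paste(sprintf("%.4f", x$eigenvalues), collapse = " ")))
  invisible(x)
}

#' Implied relaxation timescales of an MSM
#'
#' `t_k = -lag * frame_interval / log(lambda_k)` for eigenvalues in (0, 1);
#' the unit eigenvalue maps to `Inf`, negative eigenvalues are skipped.
#'
#' @param msm A [build_msm()] object.
#' @param frame_interval Physical time per frame (default 1).
#' @return A decreasing vector of timescales.
#' @export
implied_timescales <- function(msm, frame_interval = 1) {
  stopifnot(inherits(msm, "msm_model"))
  lam <- msm$eigenvalues[-1L]
  out <- rep(NA_real_, length(lam))
  out[lam >= 1] <- Inf
  pos <- lam > 0 & lam < 1
  out[pos] <- -msm$lag * frame_interval / log(lam[pos])
  out[!is.na(out)]
}

#' Generalized matrix Rayleigh quotient of a state decomposition
#'
#' The sum of the leading `k` eigenvalues of the MSM built from the label
#' sequence (here: a held-out split labeled with a train-derived state
#' definition). Bounded above by `k`, attained only for perfectly metastable
#' dynamics; higher is better.
#'
#' @param labels Integer labels on the evaluation split.
#' @param lag Lag in frames.
#' @param k Number of leading eigenvalues (default: number of states).
#' @param segments Optional segment lengths.
#' @return The GMRQ score.
#' @export
gmrq <- function(labels, lag, k = NULL, segments = NULL) {
  if (inherits(labels, "state_assignment")) labels <- labels$labels
  m <- build_msm(labels, lag, segments)
  k <- as.integer(k %||% m$n_states)
  sum(m$eigenvalues[seq_len(min(k, length(m$eigenvalues)))])
}

#' State populations of a label sequence
#'
#' @param labels Integer labels or a [state_assignment()].
#' @param n_states Optional state count.
#' @return Normalized fractions per state.
#' @export
state_populations <- function(labels, n_states = NULL) {
  if (inherits(labels, "state_assignment")) return(labels$populations)
  labels <- as.integer(labels)
  if (length(labels) == 0L) stop("empty label vector")
  n_states <- as.integer(n_states %||% max(labels))
  tabulate(labels, n_states) / length(labels)
}
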