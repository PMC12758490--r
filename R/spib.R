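# Time-lagged encoder/decoder operations: state initialization by k-means,
# deterministic encoding, posterior sampling, decoding to state
# probabilities, iterative label refinement (short-lived states are absorbed
# into their most probable future states and empty states dropped), and the
# variational mixture-of-posteriors (VampPrior) density used by the vanilla
# baseline model.

#' Construct a state assignment
#'
#' @param labels Integer per-frame state indices in `1..n_states`.
#' @param n_states Optional state count (default `max(labels)`).
#' @return An object of class `"state_assignment"` with fields `labels`,
#'   `n_states` and `populations` (fractions summing to 1).
#' @export
state_assignment <- function(labels, n_states = NULL) {
  labels <- as.integer(labels)
  n_states <- as.integer(n_states %||% max(labels))
  stopifnot(all(labels >= 1L), all(labels <= n_states))
  pops <- tabulate(labels, n_states) / length(labels)
  structure(list(labels = labels, n_states = n_states, populations = pops),
            class = "state_assignment")
}

#' @export
print.state_assignment <- function(x, ...) {
  cat(sprintf("state assignment: %d frames, %d states\n",
              length(x$labels), x$n_states))
  cat("populations:", paste(sprintf("%.3f", x$populations), collapse = " "),
      "\n")
  invisible(x)
}

# Drop states with zero frames and compact indices to 1..K.
compact_labels <- function(labels) {
  keep <- sort(unique(labels))
  state_assignment(match(labels, keep), length(keep))
}

#' Initial state labels by k-means clustering
#'
#' Three-hole trajectories are clustered on the raw coordinates; LJ7
#' trajectories on the second and third central moments of their
#' coordination numbers (the standard LJ7 order-parameter plane).
#'
#' @param x A [feature_trajectory()], a list of them, or a plain matrix.
#' @param k Number of initial clusters (`k >= 2`).
#' @param seed Optional integer seed.
#' @param space `"features"` to cluster the descriptor matrix directly, or
#'   `"moments"` to cluster `(mu2, mu3)` of coordination-number descriptors.
#' @return A [state_assignment()].
#' @export
init_labels <- function(x, k, seed = NULL, space = c("features", "moments")) {
  space <- match.arg(space)
  m <- gather_frames(x)
  if (k < 2L) stop("k must be >= 2")
  if (k > nrow(m)) stop("k exceeds the number of frames")
  if (space == "moments") m <- coordination_moments(m)
  m <- scale(m)
  km <- with_seed(seed, kmeans(m, centers = k, nstart = 10L,
                               iter.max = 50L))
  state_assignment(km$cluster, k)
}

gather_frames <- function(x) {
  if (inherits(x, "feature_trajectory")) return(x$frames)
  if (is.list(x) && all(vapply(x, inherits, TRUE, "feature_trajectory")))
    return(do.call(rbind, lapply(x, `[[`, "frames")))
  as.matrix(x)
}

# --- model component operations ------------------------------------------

standardize_features <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$center))
    stop_dim("features", length(model$center), ncol(X))
  sweep(sweep(X, 2L, model$center, "-"), 2L, model$scale, "/")
}

#' Encode descriptors to latent means
#'
#' Deterministic map from descriptor rows to the mean of the Gaussian
#' posterior in the IB space.
#'
#' @param model A fitted or initialized model (see [ibflow()]).
#' @param X Descriptor matrix (rows = frames).
#' @return An `n x d_z` matrix of latent means.
#' @export
encode <- function(model, X) {
  Xs <- standardize_features(model, X)
  mlp_forward(model$encoder, Xs)$out
}

#' Sample the Gaussian posterior around latent means
#'
#' `u = mu + sigma * eps` with `eps` standard normal; `sigma` is the global,
#' input-independent posterior scale.
#'
#' @param mu Matrix of latent means.
#' @param sigma Positive posterior scale.
#' @param seed Optional integer seed.
#' @return Matrix of the same shape as `mu`.
#' @export
sample_posterior <- function(mu, sigma, seed = NULL) {
  stopifnot(sigma >= 0)
  mu <- as.matrix(mu)
  with_seed(seed, mu + sigma * matrix(rnorm(length(mu)), nrow(mu)))
}

#' Decode latent points to state probabilities
#'
#' @param model A model with a trained decoder.
#' @param z Matrix of IB-space points.
#' @return An `n x n_states` simplex matrix (rows sum to 1).
#' @export
decode <- function(model, z) {
  z <- as_matrix_rows(z, model$dim, "z")
  softmax_rows(mlp_forward(model$decoder, z)$out)
}

# Hard labels for every frame from its own configuration (argmax decoder
# probability at the encoded mean), computed in chunks.
decode_labels <- function(model, X, chunk = 20000L) {
  n <- nrow(X)
  out <- integer(n)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    out[idx] <- max.col(decode(model, encode(model, X[idx, , drop = FALSE])),
                        ties.method = "first")
  }
  out
}

#' Refine state labels with the current model
#'
#' One refinement pass: every frame is relabeled with the most probable
#' state decoded from its own configuration, states that receive no frames
#' are dropped and indices compacted. During training this pass alternates
#' with optimization until the fraction of changed labels falls below a
#' tolerance; short-lived states whose members are predicted to transit
#' elsewhere within the lag time are thereby absorbed, so refinement never
#' increases the state count.
#'
#' @param model A fitted or in-training model.
#' @param x A [feature_trajectory()], list of them, or descriptor matrix.
#' @param current Optional current labels (integer vector or
#'   [state_assignment()]) used to report the changed fraction.
#' @return A [state_assignment()] with attribute `"changed"` (fraction of
#'   frames whose label differs from `current`). Warns (does not error) if
#'   all frames collapse to a single state.
#' @export
refine_labels <- function(model, x, current = NULL) {
  X <- gather_frames(x)
  labels <- decode_labels(model, X)
  asg <- compact_labels(labels)
  if (asg$n_states == 1L)
    warning("all frames collapsed to a single state; model is degenerate")
  changed <- NA_real_
  if (!is.null(current)) {
    cur <- if (inherits(current, "state_assignment")) current$labels
           else as.integer(current)
    changed <- mean(labels != cur)  # compare pre-compaction identities
  }
  attr(asg, "changed") <- changed
  asg
}

# Drop decoder output units for states that vanished (keeps surviving
# weights); `keep` is the sorted vector of surviving old state indices.
decoder_drop_states <- function(decoder, keep) {
  L <- length(decoder$W)
  decoder$W[[L]] <- decoder$W[[L]][, keep, drop = FALSE]
  decoder$b[[L]] <- decoder$b[[L]][keep]
  decoder
}

#' VampPrior log-density
#'
#' The vanilla baseline regularizes the posterior towards a uniform mixture
#' of encoder-conditioned Gaussians at `M` learnable pseudo-inputs:
#' `r(z) = (1/M) sum_m N(z; enc(x_m), sigma^2 I)`.
#'
#' @param z Matrix of latent points.
#' @param model A model carrying `pseudo` (pseudo-input rows, descriptor
#'   space), its encoder and `log_sigma`.
#' @return Per-point log-density.
#' @export
vamp_log_density <- function(z, model) {
  if (is.null(model$pseudo) || nrow(model$pseudo) == 0L)
    stop("model has no pseudo-inputs (empty mixture)")
  z <- as_matrix_rows(z, model$dim, "z")
  e <- mlp_forward(model$encoder, model$pseudo)$out
  sigma2 <- exp(2 * model$log_sigma)
  d <- model$dim
  # n x M matrix of component log-densities
  comp <- vapply(seq_len(nrow(e)), function(m) {
    dz <- sweep(z, 2L, e[m, ], "-")
    -rowSums(dz * dz) / (2 * sigma2) - (d / 2) * log(2 * pi * sigma2)
  }, numeric(nrow(z)))
  if (is.null(dim(comp))) comp <- matrix(comp, nrow = nrow(z))
  logsumexp_rows(comp) - log(nrow(e))
}
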