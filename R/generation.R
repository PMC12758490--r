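# Temperature-conditional generation, exact likelihood scoring, state
# representatives, transition-path interpolation in the structured prior
# space, and nearest-neighbor backmapping.

#' Generate latent samples at a steerable temperature
#'
#' Samples the tilted prior at temperature `temperature`, pulls the samples
#' back through the inverse flow into the IB space, and (optionally) decodes
#' metastable-state labels.
#'
#' @param model A fitted [ibflow()] model (full model, not the baseline).
#' @param n Number of samples.
#' @param temperature Steerable temperature parameter (> 0); 1 corresponds to
#'   the lowest training temperature.
#' @param seed Optional integer seed.
#' @param method Prior sampling method, see [rtilted()].
#' @param decode Also decode state labels?
#' @return A list with `z` (IB-space samples), `w` (prior-space samples) and,
#'   if requested, `labels`.
#' @export
generate_latent <- function(model, n, temperature = 1, seed = NULL,
                            method = c("radial_icdf", "metropolis"),
                            decode = TRUE) {
  stopifnot(inherits(model, "ibflow"))
  if (model$type != "ibflow")
    stop("generation requires the flow model; this is a '", model$type,
         "' fit")
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be > 0")
  method <- match.arg(method)
  spec <- prior_spec(model$prior$tau, model$dim, temperature)
  w <- rtilted(n, spec, method = method, seed = seed)
  z <- flow_inverse(model$flow, w)$u
  out <- list(z = z, w = w)
  if (decode) out$labels <- max.col(decode(model, z), ties.method = "first")
  out
}

#' Exact log-likelihood of descriptor frames
#'
#' Encodes each frame to its latent mean and evaluates the exact model
#' likelihood there via the flow change of variables,
#' `log r(f(mu)) + log |det J_f(mu)|`.
#'
#' @param model A fitted full model.
#' @param X Descriptor matrix (rows = frames).
#' @param temperature Steerable temperature of the prior (default 1).
#' @return Per-frame log-likelihood.
#' @export
score_frames <- function(model, X, temperature = 1) {
  stopifnot(inherits(model, "ibflow"))
  if (model$type != "ibflow")
    stop("likelihood scoring requires the flow model")
  spec <- prior_spec(model$prior$tau, model$dim, temperature)
  flow_log_likelihood(model$flow, encode(model, X), spec)
}

#' Most likely frame of each metastable state
#'
#' For every state, the index of the member frame with the highest exact
#' model likelihood; ties break to the lowest frame index.
#'
#' @param model A fitted full model.
#' @param X Descriptor matrix.
#' @param assignment Per-frame labels (integer or [state_assignment()]);
#'   defaults to the model's stored training labels.
#' @return A named integer vector, one frame index per state.
#' @export
state_representatives <- function(model, X, assignment = NULL) {
  assignment <- assignment %||% model$labels
  labels <- if (inherits(assignment, "state_assignment")) assignment$labels
            else as.integer(assignment)
  stopifnot(length(labels) == nrow(X))
  ll <- score_frames(model, X)
  states <- sort(unique(labels))
  reps <- vapply(states, function(s) {
    idx <- which(labels == s)
    if (length(idx) == 0L) stop("state ", s, " has no frames")
    idx[which.max(ll[idx])]  # which.max returns the first (lowest) maximum
  }, integer(1))
  names(reps) <- paste0("state", states)
  reps
}

path_object <- function(waypoints, kind, model = NULL) {
  out <- structure(list(waypoints = waypoints, kind = kind,
                        n_waypoints = nrow(waypoints)),
                   class = "path_interpolation")
  if (!is.null(model)) out$ib <- flow_inverse(model$flow, waypoints)$u
  out
}

#' @export
print.path_interpolation <- function(x, ...) {
  cat(sprintf("%s path: %d waypoints%s\n", x$kind, x$n_waypoints,
              if (is.null(x$ib)) "" else " (with IB-space images)"))
  invisible(x)
}

#' Spherical linear interpolation between prior-space points
#'
#' Standard great-arc interpolation: waypoints sweep the angle between the
#' endpoints at linearly interpolated norms, so equal-norm endpoints give a
#' constant-norm arc.
#'
#' @param w_a,w_b Nonzero endpoint vectors (same length).
#' @param n_waypoints Number of waypoints including both endpoints.
#' @param model Optional fitted model; if given, waypoints are also
#'   inverse-flowed to IB space (`$ib`).
#' @return A `"path_interpolation"` object with `waypoints` (matrix, first
#'   and last rows are the endpoints).
#' @export
slerp_path <- function(w_a, w_b, n_waypoints = 50L, model = NULL) {
  w_a <- as.numeric(w_a); w_b <- as.numeric(w_b)
  stopifnot(length(w_a) == length(w_b), n_waypoints >= 2L)
  na <- sqrt(sum(w_a^2)); nb <- sqrt(sum(w_b^2))
  if (na == 0 || nb == 0) stop("slerp endpoints must be nonzero")
  ua <- w_a / na; ub <- w_b / nb
  cosw <- max(-1, min(1, sum(ua * ub)))
  omega <- acos(cosw)
  if (abs(pi - omega) < 1e-10)
    stop("antiparallel endpoints: great arc is undefined")
  t <- seq(0, 1, length.out = n_waypoints)
  dirs <- if (omega < 1e-12) {
    matrix(rep(ua, each = n_waypoints), n_waypoints)
  } else {
    outer(sin((1 - t) * omega) / sin(omega), ua) +
      outer(sin(t * omega) / sin(omega), ub)
  }
  wp <- dirs * ((1 - t) * na + t * nb)
  wp[1, ] <- w_a; wp[n_waypoints, ] <- w_b
  path_object(wp, "slerp", model)
}

#' Polar-linear interpolation between 2D prior-space points
#'
#' Linear interpolation of the radius and of the central angle along the
#' chosen arc (shorter by default), exploiting the shell geometry of the
#' tilted prior; used for transition-path interpolation between state
#' representatives.
#'
#' @inheritParams slerp_path
#' @param direction `"short"` (default) or `"long"`: which arc to traverse
#'   between the endpoint angles.
#' @return A `"path_interpolation"` object.
#' @export
polar_linear_path <- function(w_a, w_b, n_waypoints = 50L, model = NULL,
                              direction = c("short", "long")) {
  direction <- match.arg(direction)
  w_a <- as.numeric(w_a); w_b <- as.numeric(w_b)
  stopifnot(length(w_a) == 2L, length(w_b) == 2L, n_waypoints >= 2L)
  ra <- sqrt(sum(w_a^2)); rb <- sqrt(sum(w_b^2))
  if (ra == 0 || rb == 0) stop("polar interpolation requires nonzero radii")
  pa <- atan2(w_a[2], w_a[1]); pb <- atan2(w_b[2], w_b[1])
  dphi <- (pb - pa) %% (2 * pi)          # in [0, 2*pi)
  if (dphi > pi) dphi <- dphi - 2 * pi   # signed shorter arc
  if (direction == "long")
    dphi <- dphi - sign(dphi + (dphi == 0)) * 2 * pi
  t <- seq(0, 1, length.out = n_waypoints)
  r <- (1 - t) * ra + t * rb
  phi <- pa + t * dphi
  wp <- cbind(r * cos(phi), r * sin(phi))
  wp[1, ] <- w_a; wp[n_waypoints, ] <- w_b
  path_object(wp, "polar_linear", model)
}

#' Backmap latent points to nearest reference frames
#'
#' Euclidean nearest neighbor of each query point among the encoded
#' reference frames; ties break to the lowest frame index. Used to assign
#' generated latent samples the full configuration of their nearest
#' simulated frame.
#'
#' @param query Matrix of latent points (e.g. generated samples).
#' @param reference Matrix of encoded reference frames (same number of
#'   columns).
#' @param chunk Query rows processed per distance block (memory knob).
#' @return Integer vector of reference row indices, one per query row.
#' @export
backmap_nearest <- function(query, reference, chunk = 1024L) {
  query <- as.matrix(query); reference <- as.matrix(reference)
  stopifnot(ncol(query) == ncol(reference), nrow(reference) >= 1L)
  rn2 <- rowSums(reference^2)
  out <- integer(nrow(query))
  for (s in seq(1L, nrow(query), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(query))
    qb <- query[idx, , drop = FALSE]
    # squared distances: ||q||^2 - 2 q.r + ||r||^2 (first min = lowest index)
    d2 <- outer(rep(1, length(idx)), rn2) - 2 * tcrossprod(qb, reference)
    out[idx] <- max.col(-d2, ties.method = "first")
  }
  out
}
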