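# Built-in Langevin data generators for the two benchmark systems: a single
# particle on the 2D three-hole model potential, and the 2D Lennard-Jones
# heptamer (LJ7) described by sorted smooth coordination numbers.

#' Three-hole model potential
#'
#' The standard 2D benchmark surface: two deep wells near (+-1, 0) connected
#' by an upper channel (containing a shallow local minimum near (0, 1.5))
#' and a lower channel, with quartic confinement:
#' `V = 3 e^{-x^2-(y-1/3)^2} - 3 e^{-x^2-(y-5/3)^2} - 5 e^{-(x-1)^2-y^2}
#'  - 5 e^{-(x+1)^2-y^2} + 0.2 x^4 + 0.2 (y-1/3)^4`.
#'
#' @param x,y Coordinates (vectorized).
#' @return Potential energy values.
#' @export
three_hole_potential <- function(x, y) {
  3 * exp(-x^2 - (y - 1 / 3)^2) - 3 * exp(-x^2 - (y - 5 / 3)^2) -
    5 * exp(-(x - 1)^2 - y^2) - 5 * exp(-(x + 1)^2 - y^2) +
    0.2 * x^4 + 0.2 * (y - 1 / 3)^4
}

#' Analytic gradient of the three-hole potential
#'
#' @inheritParams three_hole_potential
#' @return A two-column matrix `(dV/dx, dV/dy)`.
#' @export
three_hole_gradient <- function(x, y) {
  e1 <- exp(-x^2 - (y - 1 / 3)^2)
  e2 <- exp(-x^2 - (y - 5 / 3)^2)
  e3 <- exp(-(x - 1)^2 - y^2)
  e4 <- exp(-(x + 1)^2 - y^2)
  dx <- -6 * x * e1 + 6 * x * e2 + 10 * (x - 1) * e3 + 10 * (x + 1) * e4 +
    0.8 * x^3
  dy <- -6 * (y - 1 / 3) * e1 + 6 * (y - 5 / 3) * e2 + 10 * y * e3 +
    10 * y * e4 + 0.8 * (y - 1 / 3)^3
  cbind(dx, dy)
}

#' Lennard-Jones energy and forces for the 2D heptamer
#'
#' Pairwise 12-6 Lennard-Jones interactions with `epsilon = sigma = 1`, plus
#' an optional half-harmonic restraint on each particle's distance from the
#' cluster centroid beyond `r_conf` (spring constant `k_conf`); the restraint
#' keeps the cluster bound at high temperature without perturbing bound
#' states.
#'
#' @param coords A 7 x 2 coordinate matrix.
#' @param r_conf,k_conf Confinement onset radius and spring constant; set
#'   `k_conf = 0` to disable.
#' @return A list with `energy` (scalar) and `forces` (7 x 2, equal to minus
#'   the gradient).
#' @export
lj7_energy_forces <- function(coords, r_conf = 3, k_conf = 0) {
  coords <- as.matrix(coords)
  .lj7_energy_forces_cpp(coords, r_conf, k_conf)
}

# Relaxed hexagonal LJ7 minimum (center particle + 6-ring at the LJ pair
# minimum distance 2^(1/6)); used as the default LJ7 starting structure.
lj7_hexagon <- function() {
  ang <- 2 * pi * (0:5) / 6
  r <- 2^(1 / 6)
  rbind(c(0, 0), cbind(r * cos(ang), r * sin(ang)))
}

#' Define a simulation protocol
#'
#' Defaults mirror the benchmark setups: the three-hole run uses a time step
#' of 0.001, thermal energy `kT = 1`, friction 0.5 and records every 50
#' steps (5e7 steps = 1e6 frames); LJ7 runs use a time step of 0.005,
#' friction 1, recording every 100 steps (1e7 steps = 1e5 snapshots per
#' temperature).
#'
#' @param system `"three_hole"` or `"lj7"`.
#' @param n_steps Number of integration steps.
#' @param dt Time step.
#' @param kT Thermal energy.
#' @param gamma Friction coefficient (inverse time).
#' @param stride Recording interval in steps.
#' @param seed Optional integer seed.
#' @return An object of class `"sim_protocol"`.
#' @export
sim_protocol <- function(system = c("three_hole", "lj7"),
                         n_steps = NULL, dt = NULL, kT = NULL,
                         gamma = NULL, stride = NULL, seed = NULL) {
  system <- match.arg(system)
  def <- switch(system,
    three_hole = list(n_steps = 5e7, dt = 0.001, kT = 1, gamma = 0.5,
                      stride = 50L),
    lj7 = list(n_steps = 1e7, dt = 0.005, kT = 0.2, gamma = 1,
               stride = 100L))
  p <- list(system = system,
            n_steps = n_steps %||% def$n_steps,
            dt = dt %||% def$dt,
            kT = kT %||% def$kT,
            gamma = gamma %||% def$gamma,
            stride = as.integer(stride %||% def$stride),
            seed = seed)
  stopifnot(p$dt > 0, p$kT >= 0, p$gamma > 0, p$stride >= 1L,
            p$n_steps >= p$stride)
  structure(p, class = "sim_protocol")
}

#' Number of recorded frames implied by a protocol
#'
#' @param protocol A [sim_protocol()].
#' @return `floor(n_steps / stride)`.
#' @export
n_frames <- function(protocol) {
  stopifnot(inherits(protocol, "sim_protocol"))
  floor(protocol$n_steps / protocol$stride)
}

#' Construct a feature trajectory
#'
#' The container for time-ordered descriptor matrices: rows are frames,
#' columns features. `segments` holds the lengths of contiguous runs (lagged
#' pairs never cross segment boundaries); `temperature` is the steerable
#' temperature tag of the trajectory (1 at the lowest training temperature).
#'
#' @param frames Numeric matrix, one row per frame.
#' @param frame_interval Physical time between recorded frames.
#' @param temperature Steerable temperature tag (scalar).
#' @param segments Integer vector of contiguous-segment lengths summing to
#'   `nrow(frames)`.
#' @param coords Optional raw coordinate matrix aligned with `frames` (kept
#'   for backmapping, e.g. LJ7 configurations).
#' @return An object of class `"feature_trajectory"`.
#' @export
feature_trajectory <- function(frames, frame_interval = 1, temperature = 1,
                               segments = nrow(frames), coords = NULL) {
  frames <- as.matrix(frames)
  if (!all(is.finite(frames))) stop("frames must be finite")
  segments <- as.integer(segments)
  if (sum(segments) != nrow(frames))
    stop("segment lengths must sum to the number of frames")
  structure(list(frames = frames, frame_interval = frame_interval,
                 temperature = temperature, segments = segments,
                 coords = coords),
            class = "feature_trajectory")
}

#' @export
print.feature_trajectory <- function(x, ...) {
  cat(sprintf(
    "feature trajectory: %d frames x %d features, interval %g, T tag %g, %d segment(s)\n",
    nrow(x$frames), ncol(x$frames), x$frame_interval, x$temperature,
    length(x$segments)))
  invisible(x)
}

#' Run a Langevin simulation
#'
#' Underdamped Langevin dynamics (BAOAB splitting, unit mass) on the system
#' named by the protocol. Three-hole trajectories record the particle's
#' (x, y) position; LJ7 trajectories record sorted smooth coordination
#' numbers as descriptors and keep the raw coordinates for backmapping.
#'
#' @param protocol A [sim_protocol()].
#' @param x0 Optional initial condition (length-2 vector, or 7 x 2 matrix for
#'   LJ7). Defaults: the left deep well (-1, 0); the relaxed hexagon.
#' @param seed Optional integer seed (overrides `protocol$seed`).
#' @param r0 Coordination switching radius for LJ7 descriptors (default
#'   1.5 sigma).
#' @return A [feature_trajectory()].
#' @export
simulate_langevin <- function(protocol, x0 = NULL, seed = NULL, r0 = 1.5) {
  stopifnot(inherits(protocol, "sim_protocol"))
  seed <- seed %||% protocol$seed
  with_seed(seed, {
    if (protocol$system == "three_hole") {
      x0 <- x0 %||% c(-1, 0)
      frames <- .sim_three_hole_cpp(protocol$n_steps, protocol$dt,
                                    protocol$kT, protocol$gamma,
                                    protocol$stride, x0[1], x0[2])
      colnames(frames) <- c("x", "y")
      feature_trajectory(frames,
                         frame_interval = protocol$dt * protocol$stride,
                         temperature = protocol$kT)
    } else {
      x0 <- x0 %||% lj7_hexagon()
      coords <- .sim_lj7_cpp(protocol$n_steps, protocol$dt, protocol$kT,
                             protocol$gamma, protocol$stride, as.matrix(x0),
                             3, 5)
      feats <- .coordination_cpp(coords, r0, TRUE)
      colnames(feats) <- paste0("c", seq_len(7))
      feature_trajectory(feats,
                         frame_interval = protocol$dt * protocol$stride,
                         temperature = protocol$kT, coords = coords)
    }
  })
}

#' Smooth coordination numbers of an LJ7 configuration
#'
#' `c_i = sum_j 1 / (1 + (r_ij / r0)^8)`, the continuous form of the
#' standard switching function `(1-(r/r0)^8) / (1-(r/r0)^16)`.
#'
#' @param coords A 7 x 2 matrix, or an n x 14 matrix of flattened frames.
#' @param r0 Switching radius (default 1.5 sigma).
#' @param sorted Sort each frame's values in decreasing order?
#' @return A matrix with 7 columns (one row per frame).
#' @export
coordination_numbers <- function(coords, r0 = 1.5, sorted = FALSE) {
  coords <- as.matrix(coords)
  if (ncol(coords) == 2L && nrow(coords) == 7L)
    coords <- matrix(c(coords[, 1], coords[, 2]), 1L, 14L)
  .coordination_cpp(coords, r0, sorted)
}

#' Second and third central moments of coordination numbers
#'
#' The LJ7 order parameters: `mu2 = mean((c - mean(c))^2)` and
#' `mu3 = mean((c - mean(c))^3)` over the seven per-particle coordination
#' numbers; invariant under particle permutation.
#'
#' @param c_values A length-7 vector, or a matrix with 7 columns (one frame
#'   per row).
#' @return A two-column matrix `(mu2, mu3)`.
#' @export
coordination_moments <- function(c_values) {
  if (is.null(dim(c_values))) c_values <- matrix(c_values, nrow = 1L)
  stopifnot(ncol(c_values) == 7L)
  m <- rowMeans(c_values)
  d <- c_values - m
  cbind(mu2 = rowMeans(d^2), mu3 = rowMeans(d^3))
}
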