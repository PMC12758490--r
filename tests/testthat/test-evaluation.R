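# Histogram densities, symmetric KL, free-energy surfaces, MSM diagnostics.

hist2d_from_p <- function(p, epsilon = 1e-5) {
  b <- nrow(p)
  structure(list(edges = list(seq(0, 1, length.out = b + 1),
                              seq(0, 1, length.out = b + 1)),
                 p = p, epsilon = epsilon), class = "histogram2d")
}

test_that("histogram densities are floored, normalized and reference-binned", {
  h <- histogram_density(matrix(c(0.5, 0.5), 1),
                         reference = rbind(c(0, 0), c(1, 1)))
  expect_equal(sum(h$p), 1, tolerance = 1e-12)
  expect_equal(max(h$p), 1 / (1 + (1e4 - 1) * 1e-5), tolerance = 1e-9)
  expect_true(all(h$p >= 1e-5 / 1.2))  # floor survives renormalization

  g <- as.matrix(expand.grid(seq(0.005, 0.995, by = 0.01),
                             seq(0.005, 0.995, by = 0.01)))
  hu <- histogram_density(g, g)
  expect_lt(diff(range(hu$p)), 1e-6)  # near-uniform

  # out-of-range points are clipped into edge bins, count conserved
  ref <- as.matrix(expand.grid(seq(0, 1, 0.1), seq(0, 1, 0.1)))
  pts <- rbind(matrix(0.55, 50, 2), matrix(5, 30, 2), matrix(-5, 20, 2))
  hc <- histogram_density(pts, ref)
  occ <- sort(hc$p[hc$p > 1e-4], decreasing = TRUE)
  expect_length(occ, 3)
  expect_equal(occ / occ[1], c(50, 30, 20) / 50, tolerance = 1e-9)
  expect_equal(hc$p[100, 100], occ[2])  # the far corner took the 30 points
  expect_equal(hc$p[1, 1], occ[3])
  expect_equal(sum(occ) + (1e4 - 3) * min(hc$p), 1, tolerance = 1e-9)

  expect_error(histogram_density(matrix(1, 4, 2)), "degenerate")
})

test_that("symmetric KL is a premetric and matches the direct formula", {
  set.seed(1)
  a <- matrix(rnorm(2000), ncol = 2)
  b <- matrix(rnorm(2000, 0.5), ncol = 2)
  P <- histogram_density(a, a); Q <- histogram_density(b, a)
  expect_identical(symmetric_kl(P, P), 0)
  expect_gt(symmetric_kl(P, Q), 0)
  expect_equal(symmetric_kl(P, Q), symmetric_kl(Q, P), tolerance = 1e-12)

  # hand-computed two-cell case (remaining mass at the floor)
  eps <- 1e-5
  fill <- function(i, j) {
    p <- matrix(eps, 2, 2); p[i, j] <- 1 - 3 * eps; p
  }
  P2 <- hist2d_from_p(fill(1, 1)); Q2 <- hist2d_from_p(fill(2, 2))
  hand <- 2 * ((1 - 3 * eps) * log((1 - 3 * eps) / eps) +
                 eps * log(eps / (1 - 3 * eps)))
  expect_equal(symmetric_kl(P2, Q2), hand, tolerance = 1e-12)

  Qm <- histogram_density(b, b)
  expect_error(symmetric_kl(P, Qm), "binning mismatch")
})

test_that("free-energy surfaces are shifted log-probabilities", {
  p <- matrix(1 / 4, 2, 2)
  expect_lt(max(abs(fes(hist2d_from_p(p)))), 1e-12)
  # two-level system with probability ratio e^{-1}: free-energy gap = kT
  w <- c(1, exp(-1)); w <- w / sum(w)
  p2 <- matrix(c(w[1], w[2], 1e-5, 1e-5), 2, 2)
  f <- fes(hist2d_from_p(p2 / sum(p2)), kT = 1.7)
  expect_equal(f[2, 1] - f[1, 1], 1.7, tolerance = 1e-6)
  # renormalization constants cancel in free-energy differences
  f2 <- fes(hist2d_from_p(0.5 * p2 / sum(p2)), kT = 1.7)
  expect_equal(f[2, 1] - f[1, 1], f2[2, 1] - f2[1, 1], tolerance = 1e-12)
})

test_that("MSMs from canonical label sequences have known spectra", {
  alt <- rep(c(1L, 2L), 500)
  m <- build_msm(alt, lag = 1)
  expect_equal(m$transition, matrix(c(0, 1, 1, 0), 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(m$eigenvalues, c(1, -1), tolerance = 1e-12)
  expect_true(all(m$eigenvalues <= 1 + 1e-12 & m$eigenvalues >= -1 - 1e-12))

  set.seed(2)
  iid <- sample(1:2, 2e5, replace = TRUE)
  m2 <- build_msm(iid, lag = 1)
  expect_equal(m2$transition[1, 2], 0.5, tolerance = 0.02)
  expect_lt(abs(m2$eigenvalues[2]), 0.02)

  block <- rep(c(1L, 2L), each = 1e4)
  m3 <- build_msm(block, lag = 1)
  expect_gt(m3$eigenvalues[2], 0.999)
  expect_equal(m3$stationary, c(0.5, 0.5), tolerance = 1e-3)

  # lagged pairs never cross segment boundaries: two blocks as separate
  # segments have no inter-state transition at all
  m4 <- build_msm(block, lag = 1, segments = c(1e4, 1e4))
  expect_equal(m4$transition, diag(2), ignore_attr = TRUE)
})

test_that("implied timescales follow the eigenvalue formula", {
  # the leading (stationary) eigenvalue is excluded; negatives are skipped
  msm <- structure(list(eigenvalues = c(1, 0.8, exp(-1), -0.2), lag = 1,
                        n_states = 4), class = "msm_model")
  ts <- implied_timescales(msm, frame_interval = 1)
  expect_length(ts, 2)
  expect_equal(ts[1], -1 / log(0.8), tolerance = 1e-12)
  expect_equal(ts[1], 4.4814, tolerance = 1e-4)
  expect_equal(ts[2], 1, tolerance = 1e-12)  # lambda = e^-1: t = lag
  msm$lag <- 5
  expect_equal(implied_timescales(msm, frame_interval = 0.1)[2], 0.5,
               tolerance = 1e-12)
  # a second (near-)unit eigenvalue maps to infinity
  msm2 <- structure(list(eigenvalues = c(1, 1, 0.5), lag = 1,
                         n_states = 3), class = "msm_model")
  expect_identical(implied_timescales(msm2)[1], Inf)
})

test_that("GMRQ is bounded by k and attains its limits", {
  block <- rep(c(1L, 2L), each = 1e4)
  expect_equal(gmrq(block, lag = 1, k = 2), 2, tolerance = 1e-3)
  set.seed(3)
  iid <- sample(1:2, 2e5, replace = TRUE)
  expect_equal(gmrq(iid, lag = 1, k = 2), 1, tolerance = 0.02)
  expect_lte(gmrq(block, lag = 1, k = 2), 2)
})

test_that("state populations are normalized counts, order-invariant", {
  expect_equal(state_populations(c(1L, 1L, 2L)), c(2 / 3, 1 / 3))
  set.seed(4)
  lab <- sample(1:4, 500, replace = TRUE)
  expect_identical(state_populations(lab), state_populations(rev(lab)))
  expect_equal(sum(state_populations(lab)), 1)
  expect_error(state_populations(integer(0)), "empty")
})
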