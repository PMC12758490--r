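# Langevin simulators: potential/force correctness, frame-count contracts,
# seeded reproducibility, Boltzmann statistics.

test_that("three-hole gradient matches central finite differences", {
  set.seed(1)
  x <- runif(100, -2, 2); y <- runif(100, -1, 2.5)
  g <- three_hole_gradient(x, y)
  h <- 1e-6
  gx <- (three_hole_potential(x + h, y) - three_hole_potential(x - h, y)) /
    (2 * h)
  gy <- (three_hole_potential(x, y + h) - three_hole_potential(x, y - h)) /
    (2 * h)
  expect_lt(max(abs(g[, 1] - gx) / pmax(abs(gx), 1)), 1e-6)
  expect_lt(max(abs(g[, 2] - gy) / pmax(abs(gy), 1)), 1e-6)
})

test_that("the two deep minima are mirror images and the upper minimum is shallower", {
  descend <- function(p0) optim(p0, function(p)
    three_hole_potential(p[1], p[2]), function(p)
      as.numeric(three_hole_gradient(p[1], p[2])), method = "BFGS")
  left <- descend(c(-1, 0)); right <- descend(c(1, 0))
  expect_equal(left$par[1], -right$par[1], tolerance = 1e-5)
  expect_equal(left$par[2], right$par[2], tolerance = 1e-5)
  expect_equal(left$value, right$value, tolerance = 1e-10)
  upper <- descend(c(0, 1.5))
  expect_gt(abs(upper$par[2] - left$par[2]), 1)  # a distinct basin
  expect_gt(upper$value, left$value)             # lying above the deep wells
  expect_lt(max(abs(three_hole_gradient(upper$par[1], upper$par[2]))), 1e-5)
})

test_that("protocols encode the frame-count contract", {
  expect_identical(n_frames(sim_protocol("three_hole")), 1e6)
  expect_identical(n_frames(sim_protocol("lj7")), 1e5)
  p <- sim_protocol("three_hole", n_steps = 5030, stride = 50)
  expect_identical(n_frames(p), 100)
  traj <- simulate_langevin(p, seed = 1)
  expect_identical(nrow(traj$frames), 100L)
  expect_equal(traj$frame_interval, 0.05)
})

test_that("simulations are bit-reproducible under a seed", {
  p <- sim_protocol("three_hole", n_steps = 2e4)
  expect_identical(simulate_langevin(p, seed = 3)$frames,
                   simulate_langevin(p, seed = 3)$frames)
  q <- sim_protocol("lj7", n_steps = 1e4, kT = 0.3)
  expect_identical(simulate_langevin(q, seed = 4)$frames,
                   simulate_langevin(q, seed = 4)$frames)
  expect_false(identical(simulate_langevin(p, seed = 3)$frames,
                         simulate_langevin(p, seed = 5)$frames))
})

test_that("a frozen particle stays at the minimum", {
  m <- optim(c(-1, 0), function(p) three_hole_potential(p[1], p[2]),
             method = "BFGS")$par
  for (i in 1:4) {  # Newton-polish so the residual gradient is ~1e-12
    g <- as.numeric(three_hole_gradient(m[1], m[2]))
    h <- 1e-5
    H <- (rbind(three_hole_gradient(m[1] + h, m[2]),
                three_hole_gradient(m[1], m[2] + h)) -
            rbind(g, g)) / h
    m <- m - solve((H + t(H)) / 2, g)
  }
  traj <- simulate_langevin(sim_protocol("three_hole", n_steps = 5000,
                                         kT = 0), x0 = m, seed = 1)
  expect_lt(max(abs(sweep(traj$frames, 2, m))), 1e-8)
})

test_that("equilibrium occupancy follows the Boltzmann distribution", {
  traj <- simulate_langevin(sim_protocol("three_hole", n_steps = 4e6),
                            seed = 13)
  f <- traj$frames
  brk_x <- seq(-2.2, 2.2, length.out = 33)
  brk_y <- seq(-1.2, 2.6, length.out = 33)
  ix <- findInterval(f[, 1], brk_x, all.inside = TRUE)
  iy <- findInterval(f[, 2], brk_y, all.inside = TRUE)
  counts <- table(factor(ix, 1:32), factor(iy, 1:32))
  cx <- (brk_x[-1] + brk_x[-33]) / 2
  cy <- (brk_y[-1] + brk_y[-33]) / 2
  boltz <- exp(-outer(cx, cy, three_hole_potential))
  occ <- counts > 20
  expect_gt(cor(as.numeric(counts[occ]), boltz[occ]), 0.95)
  # x -> -x symmetry of the two deep basins
  left <- mean(f[, 1] < -0.5 & abs(f[, 2]) < 0.5)
  right <- mean(f[, 1] > 0.5 & abs(f[, 2]) < 0.5)
  expect_equal(left / (left + right), 0.5, tolerance = 0.12)
})

test_that("LJ pair minimum and forces are correct", {
  r0 <- 2^(1 / 6)
  hexa <- ibflow:::lj7_hexagon()
  # isolated pair at the LJ minimum distance; spectators mutually far apart
  spread <- cbind(seq(100, 500, by = 100), 0)
  ef <- lj7_energy_forces(rbind(c(0, 0), c(r0, 0), spread))
  expect_equal(ef$energy, -1, tolerance = 1e-3)
  expect_lt(max(abs(ef$forces[1:2, ])), 1e-3)
  # finite-difference force check on a compact random-ish configuration
  set.seed(2)
  coords <- hexa + matrix(rnorm(14, sd = 0.05), 7)
  ef <- lj7_energy_forces(coords, k_conf = 5)
  h <- 1e-7
  for (i in c(1, 4)) for (j in 1:2) {
    cp <- coords; cm <- coords
    cp[i, j] <- cp[i, j] + h; cm[i, j] <- cm[i, j] - h
    fd <- -(lj7_energy_forces(cp, k_conf = 5)$energy -
              lj7_energy_forces(cm, k_conf = 5)$energy) / (2 * h)
    expect_lt(abs(fd - ef$forces[i, j]) / max(abs(fd), 1), 1e-5)
  }
  expect_error(lj7_energy_forces(rbind(c(0, 0), c(0, 0), hexa[3:7, ])),
               "r = 0")
})

test_that("the relaxed hexagon is a local minimum of LJ7", {
  hexa <- ibflow:::lj7_hexagon()
  relax <- function(c0) optim(as.numeric(c0), function(v)
    lj7_energy_forces(matrix(v, 7))$energy, function(v)
      -as.numeric(lj7_energy_forces(matrix(v, 7))$forces),
    method = "BFGS", control = list(maxit = 500))
  ref <- relax(hexa)
  set.seed(5)
  for (k in 1:3) {
    pert <- relax(hexa + matrix(rnorm(14, sd = 0.03), 7))
    expect_equal(pert$value, ref$value, tolerance = 1e-6)
  }
})

test_that("frozen LJ7 dynamics keep coordination numbers constant", {
  # relax the ideal hexagon to the true minimum first (the ring compresses
  # slightly under ring-ring attraction)
  o <- optim(as.numeric(ibflow:::lj7_hexagon()), function(v)
    lj7_energy_forces(matrix(v, 7))$energy, function(v)
      -as.numeric(lj7_energy_forces(matrix(v, 7))$forces),
    method = "BFGS", control = list(maxit = 1000, reltol = 1e-15))
  traj <- simulate_langevin(sim_protocol("lj7", n_steps = 5000, kT = 0),
                            x0 = matrix(o$par, 7), seed = 1)
  rng <- apply(traj$frames, 2, function(v) diff(range(v)))
  expect_lt(max(rng), 1e-4)
})

test_that("mean LJ7 potential energy increases with temperature", {
  e_mean <- vapply(c(0.2, 0.35, 0.5), function(kT) {
    traj <- simulate_langevin(sim_protocol("lj7", n_steps = 2e5, kT = kT),
                              seed = 17)
    mean(apply(traj$coords, 1, function(v)
      lj7_energy_forces(matrix(v, 7))$energy))
  }, numeric(1))
  expect_true(all(diff(e_mean) > 0))
})

test_that("coordination moments are permutation invariant and vanish when equal", {
  expect_equal(unname(coordination_moments(rep(3.2, 7))), cbind(0, 0),
               ignore_attr = TRUE)
  c0 <- c(6, 3, 3, 3, 3, 3, 3)
  m <- coordination_moments(c0)
  mbar <- mean(c0)
  expect_equal(unname(m[1, 1]), mean((c0 - mbar)^2), tolerance = 1e-12)
  expect_equal(unname(m[1, 2]), mean((c0 - mbar)^3), tolerance = 1e-12)
  expect_gt(m[1, 2], 0)
  set.seed(1)
  cs <- runif(7, 2, 6)
  expect_equal(coordination_moments(cs),
               coordination_moments(sample(cs)), tolerance = 1e-12)
})
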