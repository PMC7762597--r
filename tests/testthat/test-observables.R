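test_that("orientation parameter implements the dead-band sign rule", {
  expect_identical(orientation_M(2, 0), 1L)
  expect_identical(orientation_M(0, 0.005), 0L)
  expect_identical(orientation_M(-0.2, 0), -1L)
  expect_identical(orientation_M(c(1, 0, -1), c(0, 0, 0), delta = 2), c(0L, 0L, 0L))
})

test_that("the 3D orientation variant degenerates for equal halves as documented", {
  cfg <- run_config(N = 20, D = 3, L = 60, n_equil = 1e4, n_attempts = 1e5,
                    record_every = 500, snapshot_every = 500)
  traj <- run_simulation(cfg, seed = 17)
  sts <- snapshot_states(traj)
  com <- t(vapply(sts, center_of_mass, numeric(3), part = "whole"))
  c1 <- t(vapply(sts, center_of_mass, numeric(3), part = "P1"))
  c2 <- t(vapply(sts, center_of_mass, numeric(3), part = "P2"))
  # equal halves: block centres are mirror vectors about the whole centre
  expect_equal(c1 - com, -(c2 - com), tolerance = 1e-12)
  expect_true(all(orientation_M_3d(c1, c2, com, delta = cfg$delta) == 0L))
  # with genuinely different centre distances it follows the sign rule
  w <- matrix(c(3, 0, 0), 1)
  o <- matrix(0, 1, 3)
  expect_identical(orientation_M_3d(w, o, o), 1L)
  expect_identical(orientation_M_3d(o, w, o), -1L)
})

test_that("autocorrelation curves reproduce closed forms", {
  t_E <- seq(0, 1e4, by = 10)
  const <- data.frame(t_E = t_E, x_cm = rep(2.5, length(t_E)))
  g0 <- autocorr_g(const, dt = c(10, 100, 1000))
  expect_equal(g0$g, c(0, 0, 0))

  v <- 0.3
  ball <- data.frame(t_E = t_E, x_cm = v * t_E)
  g2 <- autocorr_g(ball, dt = c(10, 50, 200))
  expect_equal(g2$g, (v * g2$dt)^2, tolerance = 1e-12)

  expect_error(autocorr_g(ball, dt = c(10, 2e4)), "span")
  expect_error(autocorr_g(ball, dt = 15), "stride")
})

test_that("g of a simple random walk is linear with unit coefficient", {
  set.seed(99)
  n <- 4e6
  x <- cumsum(sample(c(-1, 1), n, replace = TRUE))
  walk <- data.frame(t_E = seq_len(n), x_cm = x)
  g <- autocorr_g(walk, dt = c(1, 10, 100, 1000))
  expect_equal(g$g, g$dt, tolerance = 0.05)
  fit <- fit_exponent(autocorr_g(walk, dt = round(10^seq(0, 3, by = 0.25))))
  expect_equal(fit$nu, 1, tolerance = 0.05)
})

test_that("bead autocorrelation handles frozen and rigidly translating chains", {
  n_frames <- 200
  nb <- 10
  frozen <- matrix(rep(1:nb, each = n_frames), n_frames, nb)
  gB <- autocorr_gB(frozen, stride = 5, part = "both", dt = c(5, 50))
  expect_equal(gB$gB, c(0, 0))
  v <- 2
  moving <- frozen + v * seq(0, by = 5, length.out = n_frames)
  gB2 <- autocorr_gB(moving, stride = 5, part = "P1", dt = c(5, 50, 250))
  expect_equal(gB2$gB, (v * gB2$dt)^2)
})

test_that("bead curves dominate the mass-centre curve at small lags", {
  cfg <- run_config(N = 20, D = 3, L = 60, n_equil = 1e4, n_attempts = 4e5,
                    record_every = 100, bead_every = 100,
                    record_thermo = FALSE)
  traj <- run_simulation(cfg, seed = 23)
  dts <- c(100, 200, 500, 1000)
  g <- autocorr_g(traj, dt = dts)
  gB <- autocorr_gB(traj, part = "both", dt = dts)
  # internal modes add variance on top of the collective motion
  expect_true(all(gB$gB >= g$g))
})

test_that("swap detection follows the hysteresis state machine", {
  mk <- function(m, stride = 10) {
    # build an x_P1 - x_P2 series realising a given M sequence
    d <- ifelse(m == 1, 1, ifelse(m == -1, -1, 0))
    data.frame(t_E = seq(0, by = stride, length.out = length(m)),
               x_P1 = d, x_P2 = 0)
  }
  ev <- detect_swaps(mk(c(1, 1, -1, -1)), delta = 0.01)
  expect_equal(length(ev$times), 1)
  expect_equal(ev$times, 20)

  expect_equal(length(detect_swaps(mk(c(1, 0, 1, 0, 1)))$times), 0)

  ev2 <- detect_swaps(mk(c(1, 0, -1, 0, 1), stride = 1))
  expect_equal(length(ev2$times), 2)
  expect_equal(ev2$periods, 2)

  # plain crossing variant counts the same reversals here
  ev3 <- detect_swaps(mk(c(1, 0, -1, 0, 1), stride = 1), method = "crossing")
  expect_equal(length(ev3$times), 2)
})

test_that("swap detection commutes with global reflection", {
  set.seed(7)
  d <- cumsum(rnorm(5000))
  df <- data.frame(t_E = seq_along(d), x_P1 = d, x_P2 = 0)
  refl <- data.frame(t_E = seq_along(d), x_P1 = -d, x_P2 = 0)
  expect_equal(detect_swaps(df)$times, detect_swaps(refl)$times)
})

test_that("swap-period density has unit mass and recovers mixture modes", {
  expect_error(swap_period_density(numeric(0)), "no swap periods")

  one <- swap_period_density(rep(100, 5), fit_modes = FALSE)
  expect_equal(sum(one$mass), 1)
  expect_equal(one$mids, 2)

  set.seed(12)
  n <- 1e4
  comp <- sample(1:3, n, replace = TRUE, prob = c(0.2, 0.3, 0.5))
  mu <- c(1, 3, 5)  # in ln(period)
  periods <- exp(rnorm(n, mu[comp], 0.3))
  dens <- swap_period_density(periods, n_bins = 50)
  expect_equal(sum(dens$mass), 1, tolerance = 1e-12)
  expect_false(is.null(dens$modes))
  # modes are reported in log10; compare in ln
  expect_equal(dens$modes * log(10), mu, tolerance = 0.1)
})

test_that("long-run occupancy of M = +1 and M = -1 is symmetric for the athermal chain", {
  cfg <- run_config(N = 12, D = 3, L = 40, energy = athermal_energy(),
                    n_equil = 5e3, n_attempts = 3e5, record_every = 100,
                    record_thermo = FALSE)
  fplus <- vapply(1:6, function(s) {
    o <- run_simulation(cfg, seed = 900 + s)$obs
    m <- o$M[o$M != 0]
    mean(m == 1)
  }, numeric(1))
  se <- stats::sd(fplus) / sqrt(length(fplus))
  expect_lt(abs(mean(fplus) - 0.5), 3 * se + 0.02)
})
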