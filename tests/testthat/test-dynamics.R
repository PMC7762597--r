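test_that("chain initialisation produces valid states and fails by pigeonhole", {
  geom <- channel_geometry(D = 3, L = 600)
  st <- init_chain(10, geom)
  expect_true(is_valid_conformation(st, geom))
  expect_true(all(st$positions[, 2:3] == 2))
  expect_error(init_chain(700, geom), "cannot place")
  set.seed(1)
  grown <- init_chain(30, channel_geometry(3, 40), how = "grow")
  expect_true(is_valid_conformation(grown, channel_geometry(3, 40)))
})

test_that("move kinds are proposed proportionally to their object counts", {
  p <- move_kind_probs(100)
  expect_equal(unname(p["kink_jump"]), 98 / 199)
  expect_equal(unname(p["crankshaft"]), 97 / 199)
  expect_equal(sum(p), 1)
  p3 <- move_kind_probs(3)
  expect_equal(unname(p3["crankshaft"]), 0)
  expect_equal(unname(p3["kink_jump"]), 1 / 5)
})

test_that("Metropolis acceptance has the closed-form rate", {
  set.seed(4)
  expect_true(all(metropolis_accept(rep(0, 100))))
  expect_true(all(metropolis_accept(rep(-3, 100))))
  n <- 1e6
  f <- mean(metropolis_accept(rep(1, n)))
  p <- exp(-1)
  expect_lt(abs(f - p), 3 * sqrt(p * (1 - p) / n))
  # detailed-balance identity of the acceptance function itself
  dU <- seq(-4, 4, by = 0.25)
  a <- pmin(1, exp(-dU))
  b <- pmin(1, exp(dU)) * exp(-dU)
  expect_equal(a, b, tolerance = 1e-14)
})

test_that("reptation shifts coordinates while labels stay with indices", {
  st <- rod_state(6)
  fwd <- apply_reptation(st, "head", c(6L, 5L, 5L))
  expect_equal(fwd$positions[, 1], 1:6)
  expect_equal(fwd$labels, st$labels)
  back <- apply_reptation(fwd, "tail", c(0L, 5L, 5L))
  expect_equal(back$positions, st$positions)
  geom <- geom_wide()
  expect_equal(nrow(nonbonded_contacts(fwd, geom)), 0)
  expect_error(apply_reptation(st, "head", c(9L, 5L, 5L)), "neighbour")
})

test_that("reference proposals only move the beads they name and stay reversible", {
  geom <- channel_geometry(D = 4, L = 30)
  cfg <- run_config(N = 16, D = 4, L = 30, n_equil = 1000, n_attempts = 1000,
                    record_every = 1000)
  traj <- run_simulation(cfg, seed = 3)
  st <- traj$final_state
  set.seed(11)
  for (k in 1:200) {
    prop <- propose_move(st, geom)
    if (!prop$feasible || prop$kind == "reptation") next
    moved <- which(rowSums(prop$new_positions != st$positions) > 0)
    if (prop$kind == "kink_jump") expect_true(all(moved == prop$target))
    if (prop$kind == "crankshaft")
      expect_true(all(moved %in% c(prop$target, prop$target + 1)))
    if (prop$kind == "end_move") expect_true(all(moved == prop$target))
    # proposed state is itself valid
    expect_true(is_valid_conformation(chain_state(prop$new_positions), geom))
  }
})

test_that("the annealing schedule has the stated endpoints", {
  expect_equal(anneal_temperature(0, T_final = 1, c = 4, K = 100), 5)
  expect_equal(anneal_temperature(1e9, T_final = 1, c = 4, K = 100), 1,
               tolerance = 1e-6)
  expect_equal(anneal_temperature(0:10, c = 0, K = 100), rep(1, 11))
})

test_that("runs are reproducible and record the expected number of rows", {
  cfg <- run_config(N = 10, D = 3, L = 30, n_equil = 1000, n_attempts = 1e4,
                    record_every = 100)
  a <- run_simulation(cfg, seed = 123)
  b <- run_simulation(cfg, seed = 123)
  expect_identical(a$obs, b$obs)
  expect_identical(a$final_state$positions, b$final_state$positions)
  expect_equal(nrow(a$obs), 101)  # 1e4 / 100 + initial row
  expect_true(all(diff(a$obs$t_E) == 100))
  c2 <- run_simulation(cfg, seed = 124)
  expect_false(identical(a$obs, c2$obs))
})

test_that("athermal runs accept every geometrically valid proposal", {
  cfg <- run_config(N = 10, D = 3, L = 30, energy = athermal_energy(),
                    n_equil = 0, n_attempts = 2e4, record_every = 2e4)
  traj <- run_simulation(cfg, seed = 8)
  # every move that passed geometry checks is accepted (dU = 0 always);
  # rejections exist (geometry), but U stays identically zero
  expect_equal(traj$U_final, 0)
  expect_true(all(traj$obs$U == 0))
})

test_that("incremental energy bookkeeping matches full recomputation", {
  # validate_every makes the engine recompute U from scratch and abort on
  # any mismatch with the incrementally updated value
  cfg <- run_config(N = 20, D = 3, L = 40, n_equil = 5000, n_attempts = 1e4,
                    record_every = 1e4)
  expect_no_error(run_simulation(cfg, seed = 21, validate_every = 1))
})

test_that("every snapshot along a long run is a valid conformation", {
  cfg <- run_config(N = 30, D = 3, L = 100, n_equil = 1e4, n_attempts = 1e5,
                    record_every = 1e5, snapshot_every = 1000)
  traj <- run_simulation(cfg, seed = 31)
  for (st in snapshot_states(traj))
    expect_true(is_valid_conformation(st, cfg$geom))
})

test_that("equilibrate returns a valid state different from the rod", {
  geom <- channel_geometry(3, 60)
  cfg <- run_config(N = 20, D = 3, L = 60, n_equil = 2e4)
  st0 <- init_chain(20, geom)
  st <- equilibrate(st0, cfg, seed = 2)
  expect_true(is_valid_conformation(st, geom))
  expect_false(identical(st$positions, st0$positions))
})

test_that("the symmetric athermal chain shows no net drift", {
  cfg <- run_config(N = 20, D = 3, L = 100, energy = athermal_energy(),
                    n_equil = 1e4, n_attempts = 4e5, record_every = 1e3,
                    record_thermo = FALSE)
  nets <- vapply(1:6, function(s) {
    o <- run_simulation(cfg, seed = 50 + s)$obs
    o$x_cm[nrow(o)] - o$x_cm[1]
  }, numeric(1))
  # mean displacement compatible with zero at 3 sigma
  expect_lt(abs(mean(nets)), 3 * stats::sd(nets) / sqrt(length(nets)) + 1e-9)
})

test_that("single-step driver preserves validity and reports energy changes", {
  geom <- channel_geometry(3, 40)
  cfg <- run_config(N = 12, D = 3, L = 40, n_equil = 2e3)
  st <- equilibrate(init_chain(12, geom), cfg, seed = 1)
  set.seed(2)
  n_acc <- 0
  for (k in 1:300) {
    out <- mc_step(st, cfg)
    expect_true(is_valid_conformation(out$state, geom))
    if (out$accepted) n_acc <- n_acc + 1
    else expect_identical(out$state$positions, st$positions)
    # reported dU matches the independent recompute
    expect_equal(out$dU,
                 internal_energy(out$state, geom, cfg$energy) -
                   internal_energy(st, geom, cfg$energy))
    st <- out$state
  }
  expect_gt(n_acc, 0)
})
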