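test_that("phantom-chain entropy matches hand counts", {
  geom <- geom_wide()
  expect_equal(entropy_scm(chain_state(cbind(0L, 5L, 5L)), geom), 0)
  expect_equal(entropy_scm(rod_state(3), geom), log(6) + log(5))
  # rod lying against one wall: one neighbour blocked at every rebuild step
  wall_rod <- chain_state(cbind(0:2, 1L, 5L))
  expect_equal(entropy_scm(wall_rod, geom), log(5) + log(4))
})

test_that("per-part entropies split at the junction step and sum to the whole", {
  geom <- geom_wide()
  s <- entropy_scm(rod_state(4), geom, parts = TRUE)
  expect_equal(unname(s["S"]), unname(s["S_P1"] + s["S_P2"]))
  # N = 4: one P1 step (bead 1 -> 2), junction + last step belong to P2
  expect_equal(unname(s["S_P1"]), log(6))
  expect_equal(unname(s["S_P2"]), 2 * log(5))
})

test_that("entropy respects the unconfined upper bound and lattice symmetry", {
  geom <- channel_geometry(D = 15, L = 40)
  cfg <- run_config(N = 10, D = 15, L = 40, n_equil = 200,
                    n_attempts = 3000, record_every = 300,
                    snapshot_every = 300, energy = athermal_energy())
  traj <- run_simulation(cfg, seed = 9)
  bound <- log(6) + (cfg$N - 2) * log(5)
  for (st in snapshot_states(traj)) {
    s <- entropy_scm(st, geom)
    expect_lte(s, bound + 1e-12)
    # translation invariance away from walls
    shifted <- chain_state(sweep(st$positions, 2, c(3L, 0L, 0L), "+"))
    expect_equal(entropy_scm(shifted, geom), s)
    # mirror in x
    mir <- chain_state(cbind(-st$positions[, 1],
                             st$positions[, 2], st$positions[, 3]))
    expect_equal(entropy_scm(mir, geom), s)
  }
})

test_that("internal energy evaluates the contact matrix correctly", {
  geom <- geom_wide()
  expect_equal(internal_energy(rod_state(6), geom, all_p1_energy()), 0)
  # N = 4 square: one nonbonded contact (1,4)
  expect_equal(internal_energy(square_state(), geom, all_p1_energy()), -1)
  # with the block layout the (1,4) contact is mixed: zero by default
  expect_equal(internal_energy(square_state(), geom, energy_model()), 0)
  # mixed contacts split equally between parts
  u <- internal_energy(square_state(), geom,
                       energy_model(eps_P1P2 = -2), parts = TRUE)
  expect_equal(unname(u), c(-2, -1, -1))
})

test_that("Helmholtz identity A = U - T*S holds at every trajectory record", {
  cfg <- run_config(N = 12, D = 3, L = 30, n_equil = 2000,
                    n_attempts = 2e4, record_every = 500)
  traj <- run_simulation(cfg, seed = 5)
  o <- traj$obs
  expect_equal(o$A, o$U - cfg$energy$T * o$S, tolerance = 1e-12)
  expect_equal(o$A_P1, o$U_P1 - cfg$energy$T * o$S_P1, tolerance = 1e-12)
  expect_equal(o$A_P2, o$U_P2 - cfg$energy$T * o$S_P2, tolerance = 1e-12)
  expect_equal(helmholtz(0, 3.4012), -3.4012)
  expect_equal(helmholtz(-5, 0), -5)
  # only attractive contacts: U never positive
  expect_true(all(o$U <= 0))
})

test_that("engine-recorded S and U agree with the plain-R estimators", {
  cfg <- run_config(N = 14, D = 3, L = 30, n_equil = 2000, n_attempts = 1e4,
                    record_every = 1000, snapshot_every = 1000)
  traj <- run_simulation(cfg, seed = 77)
  sts <- snapshot_states(traj)
  for (k in seq_along(sts)) {
    expect_equal(traj$obs$S[k], entropy_scm(sts[[k]], cfg$geom))
    expect_equal(traj$obs$U[k],
                 internal_energy(sts[[k]], cfg$geom, cfg$energy))
  }
})

test_that("Flory coefficient follows the interchange-energy formula", {
  expect_identical(flory_chi(energy_model()), 2)
  expect_identical(flory_chi(energy_model(), "P2"), 0)
  expect_equal(flory_chi(energy_model(eps_P1P1 = -0.5)), 1)
})
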