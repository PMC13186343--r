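test_that("velocity initialization is Maxwell-Boltzmann with zero net momentum", {
  v <- init_velocities(1e4, T = 310, mass = 100, seed = 9)
  ke <- 0.5 * 100 * mean(rowSums(v^2)) * polysticker:::.mvv2e
  expect_equal(ke, 1.5 * kT_kcal(310), tolerance = 0.02)
  expect_lt(max(abs(colSums(v))), 1e-10)
  expect_identical(v, init_velocities(1e4, 310, 100, seed = 9))
})

test_that("two free complementary stickers within Rcut bond at p_on = 1", {
  p <- default_forcefield()
  sys <- two_sticker_system(rbind(c(50, 50, 50), c(60, 50, 50)))
  res <- attempt_bond_updates(sys$state, sys$topology, p, seed_bonds = 1,
                              step = 20)
  expect_equal(res$state$pairing, c(2L, 1L))
  expect_equal(res$events$kind, "form")
})

test_that("a bonded pair inside Rcut is never broken regardless of p_off", {
  p <- default_forcefield()
  sys <- two_sticker_system(rbind(c(50, 50, 50), c(55, 50, 50)))
  sys$state$pairing <- c(2L, 1L)
  for (step in seq(20, 400, by = 20)) {
    res <- attempt_bond_updates(sys$state, sys$topology, p, seed_bonds = step,
                                step = step)
    expect_equal(res$state$pairing, c(2L, 1L))
  }
})

test_that("a bonded pair beyond Rcut breaks with p_off = 1 and can reform only within Rcut", {
  p <- default_forcefield()
  sys <- two_sticker_system(rbind(c(50, 50, 50), c(64, 50, 50)))
  sys$state$pairing <- c(2L, 1L)
  res <- attempt_bond_updates(sys$state, sys$topology, p, seed_bonds = 3,
                              step = 20)
  expect_true(all(is.na(res$state$pairing)))
  expect_equal(res$events$kind, "break")
  # too far to re-form in the create pass of the same attempt
  expect_equal(nrow(res$events), 1L)
})

test_that("competing candidates are chosen uniformly at random under valency 1", {
  # A1 with two equidistant partners B1, B2, all mutually within Rcut
  p <- default_forcefield()
  sysA <- pack_system(list(list(build_chain(block_template("A", 1)), 1),
                           list(build_chain(block_template("B", 1)), 2)),
                      c(100, 100, 100), ab_rule(), min_separation = 1, seed = 1)
  sysA$state$pos <- rbind(c(50, 50, 50), c(60, 50, 50), c(50, 60, 50))
  sysA$state$img[] <- 0L
  picks <- vapply(1:4000, function(k) {
    r <- attempt_bond_updates(sysA$state, sysA$topology, p, seed_bonds = 77,
                              step = 20 * k)
    expect_true(sum(!is.na(r$state$pairing)) == 2L)
    r$state$pairing[1]
  }, 1L)
  f <- mean(picks == 2L)
  # binomial 3 sigma around 1/2
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("strict valency and pairing symmetry hold throughout a run", {
  sys <- two_type_system(n_each = 4, repeats = 4, box = 90, seed = 2)
  sys$state$vel <- init_velocities(nrow(sys$state$pos), seed = 3)
  p <- default_forcefield(Es_kT = 6, Ens_kT = 0.3)
  cfg <- simulation_config(n_steps = 4e3, dt = 15, thermo_every = 1e3,
                           seed_thermostat = 4, seed_bonds = 5)
  run <- run_simulation(sys$state, sys$topology, p, cfg)
  pr <- run$state$pairing
  paired <- which(!is.na(pr))
  expect_true(all(pr[pr[paired]] == paired))
  # event bookkeeping: active bonds = forms - breaks, stickers pair up evenly
  expect_equal(sum(!is.na(pr)) / 2,
               sum(run$events$kind == "form") - sum(run$events$kind == "break"))
  # saturation series is consistent with the event log replay
  at <- run$series$step
  rec <- pairing_at(rep(NA_integer_, length(pr)), run$events, at)
  expect_equal(vapply(rec, function(x) sum(!is.na(x)), 1L),
               run$series$n_paired)
})

test_that("events alternate form/break for any fixed sticker pair", {
  sys <- two_type_system(n_each = 4, repeats = 4, box = 80, seed = 12)
  sys$state$vel <- init_velocities(nrow(sys$state$pos), seed = 13)
  p <- default_forcefield(Es_kT = 3, Ens_kT = 0.3)
  cfg <- simulation_config(n_steps = 2e4, dt = 15, seed_thermostat = 14,
                           seed_bonds = 15)
  run <- run_simulation(sys$state, sys$topology, p, cfg)
  ev <- run$events
  key <- paste(pmin(ev$i, ev$j), pmax(ev$i, ev$j))
  for (k in unique(key)) {
    kinds <- ev$kind[key == k]
    expect_true(all(kinds == rep(c("form", "break"),
                                 length.out = length(kinds))))
  }
})

test_that("identical seeds give bit-identical trajectories", {
  sys <- two_type_system(n_each = 2, repeats = 4, box = 80, seed = 21)
  sys$state$vel <- init_velocities(nrow(sys$state$pos), seed = 22)
  p <- default_forcefield()
  cfg <- simulation_config(n_steps = 2e3, dt = 15, thermo_every = 500,
                           seed_thermostat = 23, seed_bonds = 24)
  r1 <- run_simulation(sys$state, sys$topology, p, cfg)
  r2 <- run_simulation(sys$state, sys$topology, p, cfg)
  expect_identical(r1$state$pos, r2$state$pos)
  expect_identical(r1$state$vel, r2$state$vel)
  expect_identical(r1$events, r2$events)
  cfg2 <- cfg; cfg2$seed_thermostat <- 99
  r3 <- run_simulation(sys$state, sys$topology, p, cfg2)
  expect_false(identical(r1$state$pos, r3$state$pos))
})

test_that("a zero-step run emits only the initial thermo row", {
  sys <- two_type_system(n_each = 1, repeats = 2, box = 60, seed = 31)
  p <- default_forcefield()
  cfg <- simulation_config(n_steps = 0, thermo_every = 100)
  run <- run_simulation(sys$state, sys$topology, p, cfg)
  expect_equal(nrow(run$thermo), 1L)
  expect_equal(run$thermo$step, 0)
})

test_that("oversized timesteps trigger the instability guard", {
  sys <- two_type_system(n_each = 2, repeats = 4, box = 60, seed = 41)
  sys$state$vel <- init_velocities(nrow(sys$state$pos), T = 31000, seed = 42)
  p <- default_forcefield()
  cfg <- simulation_config(n_steps = 1e3, dt = 3000, T = 31000,
                           seed_thermostat = 43, seed_bonds = 44)
  expect_error(run_simulation(sys$state, sys$topology, p, cfg), "instability")
})
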