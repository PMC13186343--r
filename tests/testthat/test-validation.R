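test_that("transition statistics on hand-countable series", {
  # alternating 0,1,0,1,...: both states equally occupied, every frame flips
  alt <- rep(c(0L, 1L), 50)
  ts <- transition_stats(alt)
  # occupancy estimators carry a O(1/n) edge effect on a finite series
  expect_equal(ts$result$pi_U, 0.5, tolerance = 0.02)
  expect_equal(ts$result$pi_B, 0.5, tolerance = 0.02)
  expect_equal(ts$result$P_UB, 1)
  expect_equal(ts$result$P_BU, 1)
  expect_equal(ts$result$flux_ratio, 50 / 49) # N_UB/N_BU edge effect
  # 0,0,1,1: one observed U->B, no B->U; the transition-pair estimator
  # weighs state U by its two observed departures: pi_U = N_U/(N_U+N_B) = 2/3
  ts2 <- transition_stats(c(0L, 0L, 1L, 1L))
  expect_equal(ts2$counts, list(N_UU = 1L, N_UB = 1L, N_BU = 0L, N_BB = 1L))
  expect_equal(ts2$result$pi_U, 2 / 3)
  expect_equal(ts2$result$P_UB, 0.5)
  expect_equal(ts2$result$P_BU, 0)
  expect_false(ts2$result$valid)
  expect_equal(ts2$result$flux_ratio, Inf)
  expect_error(transition_stats(rep(1L, 10)), "undefined K_eq")
})

test_that("flux identity: K_eq equals (P_BU/P_UB) x (N_UB/N_BU)", {
  set.seed(3)
  for (k in 1:20) {
    s <- as.integer(runif(500) < 0.4)
    if (all(s == s[1])) next
    ts <- transition_stats(s)
    with(ts$result, {
      if (valid) expect_equal(K_eq, (P_BU / P_UB) * (ts$counts$N_UB / ts$counts$N_BU),
                              tolerance = 1e-12)
    })
    # exact combinatorial invariant of a contiguous two-state series
    expect_lte(abs(ts$counts$N_UB - ts$counts$N_BU), 1L)
  }
})

test_that("two-particle runs are reproducible and alternate coherently", {
  tp1 <- run_two_particle(4, n_frames = 5000, box = c(80, 15, 15),
                          seed_thermostat = 5, seed_bonds = 6)
  tp2 <- run_two_particle(4, n_frames = 5000, box = c(80, 15, 15),
                          seed_thermostat = 5, seed_bonds = 6)
  expect_identical(tp1$series, tp2$series)
  expect_lte(abs(sum(diff(tp1$series) == 1) - sum(diff(tp1$series) == -1)), 1L)
  ts <- transition_stats(tp1$series)
  expect_true(ts$result$valid)
})

test_that("deep wells keep the pair almost permanently bonded", {
  tp <- run_two_particle(12, n_frames = 4000, box = c(80, 15, 15),
                         seed_thermostat = 7, seed_bonds = 8)
  first <- match(1L, tp$series)
  expect_gt(mean(tp$series[first:length(tp$series)]), 0.99)
})

test_that("zero-Es occupancy matches the Boltzmann phase-space fraction", {
  # oracle: the stationary bound fraction at Es = 0 is the Boltzmann weight
  # of the R < Rcut region (flat there, since the sticker well is zero and
  # LJ is excluded) against the LJ-weighted outside region, by brute-force
  # Monte-Carlo integration over the relative coordinate in the box
  p <- default_forcefield(Es_kT = 0, Ens_kT = 0.3)
  box <- c(300, 15, 15)
  set.seed(17)
  m <- 4e5
  dx <- (runif(m) - 0.5) * box[1]
  dy <- (runif(m) - 0.5) * box[2]
  dz <- (runif(m) - 0.5) * box[3]
  r <- sqrt(dx^2 + dy^2 + dz^2)
  inside <- r < p$Rcut_stick
  w_out <- exp(-lj_pair(pmax(r[!inside], 1e-9), p$Ens, p$sigma, p$Rmax)$energy /
                 kT_kcal(310))
  pi_B_oracle <- sum(inside) / (sum(inside) + sum(w_out))
  tp <- run_two_particle(0, n_frames = 3e5, seed_thermostat = 9,
                         seed_bonds = 10)
  expect_equal(mean(tp$series), pi_B_oracle, tolerance = 0.15)
})

test_that("detailed-balance report fits log K_eq against Es", {
  rep <- detailed_balance_report(c(2, 3.5, 5), n_frames = 4e4, seed = 21)
  expect_equal(nrow(rep$table), 3L)
  expect_lt(rep$fit$slope, -0.5)
  expect_gt(rep$fit$r_squared, 0.9)
  expect_true(all(abs(rep$table$N_UB - rep$table$N_BU) <= 1))
  expect_error(detailed_balance_report(c(2, 3), n_frames = 100), ">= 3 Es")
})
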