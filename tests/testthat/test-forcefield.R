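kT310 <- kT_kcal(310)

test_that("harmonic bond closed form", {
  hb <- harmonic_bond(10, Kb = 3, R0_bond = 10)
  expect_equal(hb$energy, 0)
  expect_equal(hb$force, 0)
  expect_equal(harmonic_bond(11, Kb = 3, R0_bond = 10)$energy, 3)
  # symmetric about the minimum
  expect_equal(harmonic_bond(10 + 0.37, 3, 10)$energy,
               harmonic_bond(10 - 0.37, 3, 10)$energy)
})

test_that("cosine bending closed form", {
  expect_equal(cosine_angle(0, kappa = 2)$energy, 0)
  expect_equal(cosine_angle(pi, kappa = 2)$energy, 4)
  expect_equal(cosine_angle(pi / 2, kappa = 2)$energy, 2)
})

test_that("truncated Lennard-Jones closed form", {
  Ens <- 0.3 * kT310
  expect_equal(lj_pair(10, Ens, sigma = 10)$energy, 0)
  at_min <- lj_pair(2^(1 / 6) * 10, Ens, sigma = 10)
  expect_equal(at_min$energy, -Ens)
  expect_equal(at_min$force, 0, tolerance = 1e-12)
  # beyond the 2.5 sigma cutoff the truncated potential is identically zero
  expect_equal(lj_pair(30, Ens, sigma = 10)$energy, 0)
  expect_error(lj_pair(0, Ens), "overlap")
})

test_that("shifted-harmonic sticker bond closed form", {
  Es <- 6 * kT310
  expect_equal(sticker_bond(11.22, Es)$energy, -Es)
  expect_equal(sticker_bond(12.72, Es)$energy, 0)
  expect_equal(sticker_bond(13.5, Es)$energy, 0)
  # midpoint of the well: ((d/2)^2 - d^2)/d^2 = -3/4
  expect_equal(sticker_bond((11.22 + 12.72) / 2, Es)$energy, -0.75 * Es)
})

test_that("neighbour enumeration matches a brute-force oracle", {
  box <- c(80, 80, 80)
  pos <- random_positions(100, 80, min_sep = 3, seed = 11)
  got <- build_neighbor_list(pos, cutoff = 25, box = box)
  d <- mi_dist(pos, box)
  want <- which(d <= 25 & upper.tri(d), arr.ind = TRUE)
  key <- function(m) sort(paste(m[, 1], m[, 2]))
  expect_equal(key(got), key(unname(want)))
  # two beads separated by more than the cutoff are not listed
  far <- matrix(c(5, 5, 5, 45, 5, 5), 2, 3, byrow = TRUE)
  expect_equal(nrow(build_neighbor_list(far, 25, box = box)), 0L)
  near <- matrix(c(5, 5, 5, 14, 5, 5), 2, 3, byrow = TRUE)
  expect_equal(nrow(build_neighbor_list(near, 25, box = box)), 1L)
})

test_that("straight three-bead chain at rest geometry leaves only the 1-3 LJ term", {
  sys <- pack_system(list(list(build_chain(block_template("spacer", 3)), 1)),
                     100, NULL, seed = 1)
  sys$state$pos <- rbind(c(40, 50, 50), c(50, 50, 50), c(60, 50, 50))
  sys$state$img[] <- 0L
  p <- forcefield_params(Ens = 0.3 * kT310)
  ef <- total_energy_forces(sys$state, sys$topology, p)
  expect_equal(ef$E_bond, 0, tolerance = 1e-12)
  expect_equal(ef$E_angle, 0, tolerance = 1e-12)
  expect_equal(ef$E_pair, lj_pair(20, 0.3 * kT310, 10)$energy)
  expect_equal(ef$E_potential, ef$E_bond + ef$E_pair + ef$E_angle)
})

test_that("forces are exact negative gradients (central differences)", {
  p <- default_forcefield(Es_kT = 6, Ens_kT = 0.3)
  h <- 1e-4
  for (cfg in 1:10) {
    sys <- two_type_system(n_each = 1, repeats = 2, box = 60, seed = cfg)
    # pair up the two closest complementary stickers when within reach
    iA <- sys$topology$stickers$A
    iB <- sys$topology$stickers$B
    d <- mi_dist(sys$state$pos, sys$state$box)
    dd <- d[iA, iB]
    if (min(dd) < p$Rcut_stick) {
      k <- which(dd == min(dd), arr.ind = TRUE)
      sys$state$pairing[iA[k[1]]] <- iB[k[2]]
      sys$state$pairing[iB[k[2]]] <- iA[k[1]]
    }
    ef <- total_energy_forces(sys$state, sys$topology, p)
    n <- nrow(sys$state$pos)
    num <- matrix(NA_real_, n, 3)
    for (i in seq_len(n)) for (k in 1:3) {
      sp <- sys$state; sp$pos[i, k] <- sp$pos[i, k] + h
      sm <- sys$state; sm$pos[i, k] <- sm$pos[i, k] - h
      num[i, k] <- -(total_energy_forces(sp, sys$topology, p)$E_potential -
                     total_energy_forces(sm, sys$topology, p)$E_potential) /
        (2 * h)
    }
    rel <- sqrt(sum((ef$forces - num)^2)) / sqrt(sum(ef$forces^2))
    expect_lt(rel, 1e-5)
    # Newton's third law
    expect_lt(max(abs(colSums(ef$forces))), 1e-10)
  }
})

test_that("pair energies are invariant under rigid translation and image shifts", {
  sys <- two_type_system(n_each = 2, repeats = 3, box = 100, seed = 5)
  p <- default_forcefield()
  e0 <- total_energy_forces(sys$state, sys$topology, p)
  shifted <- sys$state
  shifted$pos <- sweep(sys$state$pos, 2, c(13.1, -7.7, 31.9), "+")
  for (k in 1:3) {
    q <- floor(shifted$pos[, k] / shifted$box[k])
    shifted$pos[, k] <- shifted$pos[, k] - q * shifted$box[k]
    shifted$img[, k] <- shifted$img[, k] + as.integer(q)
  }
  e1 <- total_energy_forces(shifted, sys$topology, p)
  expect_equal(e1$E_potential, e0$E_potential, tolerance = 1e-9)
  expect_equal(e1$E_pair, e0$E_pair, tolerance = 1e-9)
})

test_that("forming a sticker bond adds -Es to E_bond and removes the pair's LJ", {
  Es <- 6 * kT310
  p <- default_forcefield(Es_kT = 6, Ens_kT = 0.3)
  pos <- rbind(c(50, 50, 50), c(50 + p$R0_stick, 50, 50))
  sys <- two_sticker_system(pos)
  free <- total_energy_forces(sys$state, sys$topology, p)
  sys$state$pairing <- c(2L, 1L)
  bound <- total_energy_forces(sys$state, sys$topology, p)
  expect_equal(bound$E_bond - free$E_bond, -Es)
  expect_equal(free$E_pair, lj_pair(p$R0_stick, p$Ens, p$sigma)$energy)
  expect_equal(bound$E_pair, 0)
})
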