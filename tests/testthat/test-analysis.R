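test_that("radius of gyration closed forms and invariances", {
  dumbbell <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(radius_of_gyration(dumbbell), 1)
  expect_equal(radius_of_gyration(matrix(c(5, 5, 5), 1)), 0)
  set.seed(1)
  cloud <- matrix(rnorm(300), 100, 3)
  expect_equal(radius_of_gyration(sweep(cloud, 2, c(10, -40, 7), "+")),
               radius_of_gyration(cloud))
})

test_that("Rg uses unwrapped coordinates via image flags", {
  # chain straddling the boundary: wrapped Rg would be wildly inflated
  pos <- rbind(c(95, 50, 50), c(5, 50, 50))
  img <- rbind(c(0L, 0L, 0L), c(1L, 0L, 0L))
  st <- polysticker:::new_state(pos, c(100, 100, 100), img = img)
  expect_equal(radius_of_gyration(st), 5)
})

test_that("sticker saturation counts paired stickers", {
  sys <- two_type_system(n_each = 2, repeats = 4, box = 100, seed = 2)
  expect_equal(sticker_saturation(sys$state, sys$topology), 0)
  iA <- sys$topology$stickers$A
  iB <- sys$topology$stickers$B
  sys$state$pairing[iA] <- iB
  sys$state$pairing[iB] <- iA
  expect_equal(sticker_saturation(sys$state, sys$topology), 1)
  sys$state$pairing[] <- NA_integer_
  sys$state$pairing[iA[1]] <- iB[1]
  sys$state$pairing[iB[1]] <- iA[1]
  expect_equal(sticker_saturation(sys$state, sys$topology),
               2 / length(c(iA, iB)))
  mono <- pack_system(list(list(build_chain(block_template("spacer", 2)), 2)),
                      60, NULL, seed = 1)
  expect_error(sticker_saturation(mono$state, mono$topology), "no stickers")
})

make_pairing <- function(topology, chain_edges) {
  # realize chain-level edges as sticker pairings (one bond per edge)
  pr <- rep(NA_integer_, length(topology$role))
  used <- logical(length(topology$role))
  st <- unlist(topology$stickers, use.names = FALSE)
  for (k in seq_len(nrow(chain_edges))) {
    i <- st[!used[st] & topology$chain[st] == chain_edges[k, 1]][1]
    j <- st[!used[st] & topology$chain[st] == chain_edges[k, 2]][1]
    stopifnot(!is.na(i), !is.na(j))
    pr[i] <- j; pr[j] <- i
    used[c(i, j)] <- TRUE
  }
  pr
}

test_that("cluster components match hand-built bond graphs", {
  sys <- two_type_system(n_each = 2, repeats = 4, box = 120, seed = 3)
  # no bonds: all chains are monomers
  expect_equal(cluster_components(sys$state, sys$topology), rep(1L, 4))
  # chains 1-2 bonded, 2-3 bonded, chain 4 free -> sizes {3, 1}
  sys$state$pairing <- make_pairing(sys$topology,
                                    rbind(c(1L, 3L), c(3L, 2L)))
  expect_equal(sort(cluster_components(sys$state, sys$topology)), c(1L, 3L))
})

test_that("component sizes equal brute-force reachability on random graphs", {
  for (trial in 1:100) {
    set.seed(trial)
    n <- sample(2:60, 1)
    m <- sample(0:(2 * n), 1)
    edges <- cbind(sample(n, m, replace = TRUE), sample(n, m, replace = TRUE))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
    got <- sort(as.integer(igraph::components(g)$csize))
    expect_equal(got, sort(bf_components(n, edges)))
  }
})

test_that("ACO closed forms", {
  # N = 4, sizes {2,1,1}: ACO = (4+1+1)/4 = 1.5, normalized 0.375
  a <- aco(c(2, 1, 1), 4)
  expect_equal(a$aco, 1.5)
  expect_equal(a$aco_norm, 0.375)
  # all monomers -> 1/N; one big cluster -> 1
  expect_equal(aco(rep(1, 40), 40)$aco_norm, 1 / 40)
  expect_equal(aco(40, 40)$aco_norm, 1)
  expect_error(aco(c(2, 1), 4), "invalid input")
})

test_that("ACO never decreases when two clusters merge", {
  set.seed(7)
  for (k in 1:50) {
    sizes <- sample(1:8, sample(2:10, 1), replace = TRUE)
    n <- sum(sizes)
    merged <- c(sizes[-(1:2)], sizes[1] + sizes[2])
    expect_gte(aco(merged, n)$aco, aco(sizes, n)$aco)
  }
})

test_that("dissociation events are counted per window", {
  ev <- data.frame(step = c(1e5, 2e5, 5e5, 9e5, 9.5e5, 1.2e6, 1.9e6),
                   kind = c(rep("break", 5), "break", "break"),
                   i = 1L, j = 2L)
  ds <- dissociation_series(ev, window = 1e6, n_steps = 2e6)
  expect_equal(ds$n_break, c(5L, 2L))
  empty <- dissociation_series(ev[0, ], window = 1e6, n_steps = 3e6)
  expect_equal(empty$n_break, c(0L, 0L, 0L))
})

test_that("radial profile integrates back to the bead counts", {
  sys <- two_type_system(n_each = 2, repeats = 4, box = 100, seed = 9)
  rp <- radial_profile(sys$state, sys$topology, chains = 1:4,
                       breaks = seq(0, 50, 10))
  expect_equal(sum(rp$n_sticker) + sum(rp$n_spacer), 4 * 20)
  expect_true(all(rp$rho_sticker >= 0) && all(rp$rho_spacer >= 0))
  expect_error(radial_profile(sys$state, sys$topology, integer(0)),
               "empty cluster")
})

test_that("radial density is flat for uniform beads in a ball", {
  set.seed(11)
  n <- 4000
  r <- 40 * runif(n)^(1 / 3)
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  pos <- 200 + r * u # far from boundaries of a 400-box
  mono <- pack_system(list(list(build_chain(block_template("spacer", 1)), n)),
                      400, NULL, min_separation = 0.1, seed = 1)
  st <- mono$state
  st$pos <- pos
  st$img[] <- 0L
  rp <- radial_profile(st, mono$topology, chains = seq_len(n),
                       breaks = seq(0, 40, 10))
  expect_equal(sum(rp$n_spacer), n) # every bead lands in some shell
  rho <- rp$rho_spacer[rp$r_hi <= 40] # shells fully inside the ball
  expect_lt(max(abs(rho - mean(rho))) / mean(rho), 0.25)
})

test_that("MSD closed forms: static and ballistic trajectories", {
  nf <- 50
  static <- list(steps = seq_len(nf) * 10,
                 pos = array(3.21, dim = c(nf, 4, 3)))
  m <- msd_diffusion(static, dt = 10, t_damp = 1)
  expect_true(all(m$msd == 0))
  expect_equal(m$D, 0)
  t <- seq_len(nf)
  v <- 0.01
  ball <- array(0, dim = c(nf, 1, 3))
  ball[, 1, 1] <- v * t * 10
  m2 <- msd_diffusion(list(steps = t * 10, pos = ball), dt = 1, t_damp = 1)
  # MSD = v^2 t^2 exactly
  expect_equal(m2$msd, v^2 * (m2$lag_fs)^2, tolerance = 1e-12)
  expect_error(msd_diffusion(list(steps = 1, pos = array(0, c(1, 1, 3))),
                             dt = 10), "2 frames")
})

test_that("linear fit agrees with brute-force normal equations", {
  lf <- linear_fit(1:10, 2 * (1:10) + 1)
  expect_equal(lf$slope, 2)
  expect_equal(lf$intercept, 1)
  expect_equal(lf$r_squared, 1)
  expect_equal(linear_fit(1:5, rep(3, 5))$slope, 0)
  set.seed(13)
  x <- rnorm(5); y <- rnorm(5)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  lf2 <- linear_fit(x, y)
  expect_equal(lf2$intercept, beta[1], tolerance = 1e-12)
  expect_equal(lf2$slope, beta[2], tolerance = 1e-12)
  expect_error(linear_fit(1:2, 1:2), "3 paired points")
  expect_error(linear_fit(rep(1, 5), 1:5), "zero variance")
})
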