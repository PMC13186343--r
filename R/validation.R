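# Detailed-balance validation of the stochastic bond scheme and the
# phase-transition titration of the specific energy.

#' Two-sticker bond-state trajectory in a pseudo-1D box
#'
#' Two complementary stickers diffuse in an elongated periodic box under
#' Langevin dynamics with bond attempts every \code{bond_attempt_every}
#' steps; the bond state (0/1) is sampled once per attempt. The elongated
#' geometry accelerates the diffusive encounter rate; the box volume only
#' shifts the equilibrium-constant prefactor, not its scaling with Es.
#'
#' @param Es_kT specific energy in units of kT
#' @param n_frames number of sampled frames (= bond attempts)
#' @param seed_thermostat,seed_bonds seeds
#' @param box box edges (A); default 300 x 15 x 15
#' @param T temperature (K)
#' @param dt timestep (fs)
#' @param t_damp damping time (fs)
#' @param Ens_kT non-specific LJ depth in kT (acts between the two stickers
#'   while unbonded)
#' @param mass bead mass (g/mol)
#' @return list: integer 0/1 \code{series}, the sampled \code{steps}, the
#'   final \code{state}, and the \code{params}/\code{config} used
#' @export
run_two_particle <- function(Es_kT, n_frames = 1e5, seed_thermostat = 1,
                             seed_bonds = 2, box = c(300, 15, 15), T = 310,
                             dt = 15, t_damp = 500, Ens_kT = 0.3,
                             mass = 100) {
  stopifnot(Es_kT >= 0)
  rule <- complementarity_rule(list(c("A", "B")))
  a <- build_chain(block_template("A", 1L))
  b <- build_chain(block_template("B", 1L))
  sys <- pack_system(list(list(a, 1L), list(b, 1L)), box, rule,
                     min_separation = 20, seed = seed_thermostat)
  # deterministic, well-separated starting positions along the long axis
  sys$state$pos <- rbind(c(box[1] / 4, box[2] / 2, box[3] / 2),
                         c(3 * box[1] / 4, box[2] / 2, box[3] / 2))
  sys$state$img[] <- 0L
  sys$state$vel <- init_velocities(2, T, mass, seed = seed_thermostat)
  params <- default_forcefield(T = T, Es_kT = Es_kT, Ens_kT = Ens_kT)
  config <- simulation_config(n_steps = n_frames * 20, dt = dt, T = T,
                              t_damp = t_damp, mass = mass,
                              bond_attempt_every = 20L,
                              seed_thermostat = seed_thermostat,
                              seed_bonds = seed_bonds,
                              sample_series = TRUE)
  run <- run_simulation(sys$state, sys$topology, params, config)
  list(series = as.integer(run$series$n_paired > 0),
       steps = run$series$step, state = run$state, params = params,
       config = config)
}

#' Transition statistics and detailed-balance estimators
#'
#' Classifies successive frame pairs of a 0/1 bond-state series as UU, UB,
#' BU or BB and forms the stationary probabilities pi_U = N_U/(N_U + N_B),
#' pi_B = N_B/(N_U + N_B), transition rates P_U->B = N_UB/N_U,
#' P_B->U = N_BU/N_B (with N_U = N_UU + N_UB, N_B = N_BB + N_BU), the
#' equilibrium constant K_eq = pi_U/pi_B and the flux ratio
#' (pi_U P_U->B)/(pi_B P_B->U), which detailed balance requires to be 1.
#'
#' @param series integer/logical vector of bond states per sampled frame
#' @return list: \code{counts} (N_UU, N_UB, N_BU, N_BB) and \code{result}
#'   (pi_U, pi_B, P_UB, P_BU, K_eq, flux_ratio, se_log_K, valid);
#'   \code{valid} is FALSE when a transition direction was never observed
#'   (flux ratio then degenerates to 0 or Inf)
#' @export
transition_stats <- function(series) {
  series <- as.integer(series)
  if (length(series) < 2L) stop("series must have length >= 2")
  if (all(series == series[1]))
    stop("undefined K_eq: series never leaves one state")
  a <- series[-length(series)]
  b <- series[-1]
  N_UU <- sum(a == 0 & b == 0); N_UB <- sum(a == 0 & b == 1)
  N_BU <- sum(a == 1 & b == 0); N_BB <- sum(a == 1 & b == 1)
  N_U <- N_UU + N_UB; N_B <- N_BB + N_BU
  pi_U <- N_U / (N_U + N_B); pi_B <- N_B / (N_U + N_B)
  P_UB <- if (N_U > 0) N_UB / N_U else NA_real_
  P_BU <- if (N_B > 0) N_BU / N_B else NA_real_
  flux <- (pi_U * P_UB) / (pi_B * P_BU) # algebraically N_UB / N_BU
  valid <- N_UB > 0 && N_BU > 0
  se_log_K <- if (valid) sqrt(1 / N_UB + 1 / N_BU) else NA_real_
  list(counts = list(N_UU = N_UU, N_UB = N_UB, N_BU = N_BU, N_BB = N_BB),
       result = list(pi_U = pi_U, pi_B = pi_B, P_UB = P_UB, P_BU = P_BU,
                     K_eq = pi_U / pi_B, flux_ratio = flux,
                     se_log_K = se_log_K, valid = valid))
}

#' Detailed-balance report across specific energies
#'
#' Runs the two-particle experiment at each Es, collects the equilibrium
#' constants and flux ratios, and fits log K_eq against Es/kT. Boltzmann
#' consistency of the bond scheme predicts log-linearity; the fitted slope
#' approaches -1 from above as the wells deepen (the finite harmonic-well
#' width contributes a +log(Es)/2 entropic term).
#'
#' @param Es_kT vector (>= 3) of specific energies in kT
#' @param n_frames sampled frames per Es
#' @param seed base seed; each Es uses an offset pair of seeds
#' @param ... further arguments for [run_two_particle()]
#' @return \code{ssp_db_report}: per-Es data frame \code{table}, the
#'   [linear_fit()] of log K_eq vs Es/kT as \code{fit}
#' @export
detailed_balance_report <- function(Es_kT, n_frames = 1e5, seed = 1, ...) {
  if (length(Es_kT) < 3L) stop("need >= 3 Es values")
  rows <- lapply(seq_along(Es_kT), function(k) {
    tp <- run_two_particle(Es_kT[k], n_frames = n_frames,
                           seed_thermostat = seed + 1000 * k,
                           seed_bonds = seed + 1000 * k + 500, ...)
    ts <- tryCatch(transition_stats(tp$series), error = function(e) NULL)
    if (is.null(ts)) # series never left one state: no K_eq at this Es
      ts <- list(counts = list(N_UU = NA, N_UB = NA, N_BU = NA, N_BB = NA),
                 result = list(pi_U = NA, pi_B = NA, P_UB = NA, P_BU = NA,
                               K_eq = NA, flux_ratio = NA, se_log_K = NA,
                               valid = FALSE))
    c(list(Es_kT = Es_kT[k]), ts$counts, ts$result)
  })
  tab <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r[c("Es_kT", "N_UU", "N_UB", "N_BU", "N_BB", "pi_U",
                      "pi_B", "P_UB", "P_BU", "K_eq", "flux_ratio",
                      "se_log_K", "valid")])))
  ok <- tab$valid & !is.na(tab$K_eq) & is.finite(log(tab$K_eq))
  if (any(!ok))
    warning(sprintf("excluding Es = %s from the fit (undefined K_eq)",
                    paste(tab$Es_kT[!ok], collapse = ", ")))
  fit <- linear_fit(tab$Es_kT[ok], log(tab$K_eq[ok]))
  structure(list(table = tab, fit = fit), class = "ssp_db_report")
}

#' @export
print.ssp_db_report <- function(x, ...) {
  cat("detailed-balance report\n")
  print(x$table[, c("Es_kT", "K_eq", "flux_ratio")], row.names = FALSE)
  cat(sprintf("log K_eq vs Es/kT: slope %.4f (95%% CI %.4f..%.4f), R^2 %.5f\n",
              x$fit$slope, x$fit$slope_ci[1], x$fit$slope_ci[2],
              x$fit$r_squared))
  invisible(x)
}

#' Phase-transition titration of the specific energy
#'
#' Starting each point from the same preformed state, runs the system at a
#' grid of Es values and time-averages the normalized average cluster
#' occupancy, sticker saturation and dissociation counts over the
#' post-equilibration part of each run. The phase threshold is reported as
#' the Es at which the normalized ACO crosses 0.5 (linear interpolation).
#'
#' @param state preformed \code{ssp_state} (e.g. the final state of a
#'   clustering run)
#' @param topology combined \code{ssp_topology}
#' @param config an \code{ssp_config}; \code{n_steps} is the per-Es run
#'   length
#' @param Es_grid_kT increasing grid of specific energies (kT)
#' @param Ens_kT non-specific energy (kT)
#' @param equil_frac fraction of each run discarded as equilibration
#' @param n_samples pairing snapshots per run used for the ACO average
#' @param window dissociation-count window (steps)
#' @return \code{ssp_titration}: per-Es data frame \code{table} (aco_norm,
#'   saturation, mean dissociation count per window, equilibrated flag) and
#'   \code{threshold_kT}
#' @export
phase_titration <- function(state, topology, config, Es_grid_kT,
                            Ens_kT = 0.3, equil_frac = 0.1,
                            n_samples = 60, window = 1e6) {
  stopifnot(all(diff(Es_grid_kT) > 0))
  n_steps <- config$n_steps
  rows <- vector("list", length(Es_grid_kT))
  for (k in seq_along(Es_grid_kT)) {
    params <- default_forcefield(T = config$T, Es_kT = Es_grid_kT[k],
                                 Ens_kT = Ens_kT)
    cfg <- config
    cfg$seed_thermostat <- config$seed_thermostat + 97 * k
    cfg$seed_bonds <- config$seed_bonds + 97 * k + 13
    run <- run_simulation(state, topology, params, cfg)
    at <- state$step + round(seq(1 / n_samples, 1, length.out = n_samples) *
                               n_steps)
    pr <- pairing_at(state$pairing, run$events, at)
    aco_t <- vapply(pr, function(p) {
      st <- state; st$pairing <- p
      cluster_stats(st, topology)$aco_norm
    }, 1.0)
    keep <- at > state$step + equil_frac * n_steps
    sat_keep <- run$series$step > state$step + equil_frac * n_steps
    nst <- length(unlist(topology$stickers))
    diss <- dissociation_series(run$events, window = window,
                                n_steps = state$step + n_steps)
    last3 <- at >= state$step + (2 / 3) * n_steps
    trend <- linear_fit(at[last3], aco_t[last3])
    rows[[k]] <- data.frame(
      Es_kT = Es_grid_kT[k],
      aco_norm = mean(aco_t[keep]),
      saturation = mean(run$series$n_paired[sat_keep]) / nst,
      diss_per_window = mean(diss$n_break),
      equilibrated = abs(trend$slope) * n_steps < 0.2)
  }
  tab <- do.call(rbind, rows)
  threshold <- NA_real_
  cross <- which(diff(tab$aco_norm >= 0.5) == 1)
  if (length(cross)) {
    i <- cross[1]
    threshold <- tab$Es_kT[i] + (0.5 - tab$aco_norm[i]) *
      diff(tab$Es_kT[i:(i + 1)]) / diff(tab$aco_norm[i:(i + 1)])
  } else if (all(tab$aco_norm >= 0.5)) threshold <- tab$Es_kT[1]
  structure(list(table = tab, threshold_kT = threshold),
            class = "ssp_titration")
}

#' @export
print.ssp_titration <- function(x, ...) {
  cat("specific-energy titration\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("normalized-ACO 0.5 crossing: Es ~ %.2f kT\n", x$threshold_kT))
  invisible(x)
}
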