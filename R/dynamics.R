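#' Simulation configuration
#'
#' @param n_steps number of integration steps to run
#' @param dt timestep (fs); typical values 15-30 fs
#' @param T temperature (K)
#' @param t_damp Langevin damping time (fs); \code{Inf} (or
#'   \code{langevin = FALSE}) disables the thermostat, giving NVE dynamics
#' @param mass per-bead mass (g/mol)
#' @param bond_attempt_every cadence (steps) of the stochastic bond
#'   create/break pass
#' @param seed_thermostat,seed_bonds independent integer seeds for the
#'   thermostat noise and the bond engine
#' @param thermo_every emit a thermodynamic output row every this many steps
#'   (0 = none beyond what the caller requests)
#' @param dump_every store an unwrapped-coordinate trajectory frame every
#'   this many steps (0 = no trajectory)
#' @param restart_every write a restart file every this many steps when
#'   \code{run_simulation(..., restart_path =)} is given (0 = only at the end)
#' @param sample_series record the number of paired stickers after every
#'   bond-attempt step
#' @param langevin logical, thermostat on/off
#' @param bond_moves logical, stochastic bond engine on/off
#' @param skin Verlet-list skin (A)
#' @return an \code{ssp_config}
#' @export
simulation_config <- function(n_steps, dt = 15, T = 310, t_damp = 500,
                              mass = 100, bond_attempt_every = 20L,
                              seed_thermostat = 1, seed_bonds = 2,
                              thermo_every = 0, dump_every = 0,
                              restart_every = 0, sample_series = TRUE,
                              langevin = TRUE, bond_moves = TRUE, skin = 3) {
  stopifnot(dt > 0, bond_attempt_every >= 1, mass > 0, T > 0, t_damp > 0)
  structure(list(n_steps = n_steps, dt = dt, T = T, t_damp = t_damp,
                 mass = mass, bond_attempt_every = as.integer(bond_attempt_every),
                 seed_thermostat = seed_thermostat, seed_bonds = seed_bonds,
                 thermo_every = thermo_every, dump_every = dump_every,
                 restart_every = restart_every, sample_series = sample_series,
                 langevin = langevin, bond_moves = bond_moves, skin = skin),
            class = "ssp_config")
}

#' Maxwell-Boltzmann velocity initialization
#'
#' Draws per-component Gaussian velocities at temperature \code{T} and
#' removes the centre-of-mass momentum.
#'
#' @param n number of beads
#' @param T temperature (K)
#' @param mass bead mass (g/mol)
#' @param seed integer seed
#' @return n x 3 velocity matrix (A/fs)
#' @export
init_velocities <- function(n, T = 310, mass = 100, seed = 1) {
  stopifnot(T > 0, n >= 1)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  sd <- sqrt(.kB * T / (mass * .mvv2e))
  v <- matrix(rnorm(3 * n, sd = sd), n, 3)
  sweep(v, 2, colMeans(v))
}

#' Run Langevin dynamics with stochastic sticker bonding
#'
#' Main loop: force evaluation, a BAOAB Langevin step, and -- every
#' \code{bond_attempt_every} steps -- a break pass (bonded pairs at
#' R >= Rcut break with probability p_off) followed by a create pass
#' (complementary unpaired pairs at R <= Rcut, visited in uniformly random
#' order, bond with probability p_on under strict valency 1). Runs are fully
#' reproducible given the two seeds; randomness is keyed on the absolute
#' step number, so a run resumed from a restart file continues the original
#' trajectory bit-for-bit.
#'
#' @param state an \code{ssp_state}
#' @param topology combined \code{ssp_topology}
#' @param params \code{ssp_params}
#' @param config \code{ssp_config}
#' @param restart_path if non-NULL, write restart files here (suffixed with
#'   the step number when \code{restart_every > 0})
#' @return \code{ssp_run} list: final \code{state}; \code{thermo} data frame
#'   (step, E_bond, E_pair, E_angle, E_potential, KE, T_inst, saturation);
#'   \code{events} data frame of bond events (step, kind, i, j);
#'   \code{series} data frame of paired-sticker counts per attempt step;
#'   \code{trajectory} (steps + unwrapped frames) when \code{dump_every > 0}
#' @export
run_simulation <- function(state, topology, params, config,
                           restart_path = NULL) {
  stopifnot(inherits(state, "ssp_state"), inherits(config, "ssp_config"))
  etopo <- topo_for_engine(topology)
  n_steps <- config$n_steps
  chunk <- if (!is.null(restart_path) && config$restart_every > 0)
    config$restart_every else n_steps
  done <- 0
  thermo <- list(); events <- list(); series <- list()
  traj_steps <- list(); traj <- list()
  first <- TRUE
  while (done < n_steps || first) {
    k <- min(chunk, n_steps - done)
    cfg <- unclass(config)
    cfg$n_steps <- k
    cfg$step0 <- state$step
    res <- md_run_cpp(state$pos, state$vel, state$img, state$pairing,
                      state$box, etopo, unclass(params), cfg)
    s <- res$state
    state <- new_state(s$pos, s$box, vel = s$vel, img = s$img,
                       pairing = s$pairing, step = s$step)
    th <- res$thermo
    if (!first && nrow(th) > 0) th <- th[-1, , drop = FALSE] # drop duplicated row
    thermo[[length(thermo) + 1L]] <- th
    events[[length(events) + 1L]] <- res$events
    series[[length(series) + 1L]] <- res$series
    if (config$dump_every > 0) {
      ts <- res$traj_steps
      if (!first && length(ts) > 0) {
        traj_steps[[length(traj_steps) + 1L]] <- ts[-1]
        traj[[length(traj) + 1L]] <- res$traj[-seq_len(3 * nrow(state$pos))]
      } else {
        traj_steps[[length(traj_steps) + 1L]] <- ts
        traj[[length(traj) + 1L]] <- res$traj
      }
    }
    done <- done + k
    first <- FALSE
    if (!is.null(restart_path)) {
      path <- if (config$restart_every > 0 && done < n_steps)
        sprintf("%s.%.0f", restart_path, state$step) else restart_path
      write_restart(state, path)
    }
  }
  thermo <- do.call(rbind, thermo)
  colnames(thermo) <- c("step", "E_bond", "E_pair", "E_angle", "E_potential",
                        "KE", "T_inst", "saturation")
  ev <- list(step = unlist(lapply(events, `[[`, "step")),
             kind = unlist(lapply(events, `[[`, "kind")),
             i = unlist(lapply(events, `[[`, "i")),
             j = unlist(lapply(events, `[[`, "j")))
  ev <- data.frame(step = ev$step,
                   kind = ifelse(ev$kind == 1, "form", "break"),
                   i = ev$i, j = ev$j, stringsAsFactors = FALSE)
  sr <- data.frame(step = unlist(lapply(series, `[[`, "step")),
                   n_paired = unlist(lapply(series, `[[`, "n_paired")))
  out <- list(state = state, thermo = as.data.frame(thermo), events = ev,
              series = sr)
  if (config$dump_every > 0) {
    steps <- unlist(traj_steps)
    n <- nrow(state$pos)
    arr <- array(unlist(traj), dim = c(3, n, length(steps)))
    out$trajectory <- list(steps = steps, pos = aperm(arr, c(3, 2, 1)))
  }
  class(out) <- "ssp_run"
  out
}

#' @export
print.ssp_run <- function(x, ...) {
  cat(sprintf("simulation run to step %s: %d thermo rows, %d bond events\n",
              format(x$state$step, big.mark = ","), nrow(x$thermo),
              nrow(x$events)))
  invisible(x)
}

#' One stochastic bond create/break pass
#'
#' Applies a single break-then-create attempt to a configuration, exactly as
#' the engine does at its fixed cadence; exposed for inspection and testing.
#' Deterministic given \code{seed_bonds} and \code{step}.
#'
#' @inheritParams run_simulation
#' @param seed_bonds bond-engine seed
#' @param step step counter the attempt is keyed on
#' @return list with the updated \code{state} and an \code{events} data frame
#' @export
attempt_bond_updates <- function(state, topology, params, seed_bonds = 2,
                                 step = 0) {
  res <- bond_update_cpp(state$pos, state$pairing, state$box,
                         topo_for_engine(topology), unclass(params),
                         seed_bonds, step)
  p <- as.integer(res$pairing)
  bad <- which(!is.na(p) & (is.na(p[p]) | p[p] != seq_along(p)))
  if (length(bad)) stop("internal consistency error: pairing table asymmetric")
  state$pairing <- p
  ev <- res$events
  list(state = state,
       events = data.frame(step = ev$step,
                           kind = ifelse(ev$kind == 1, "form", "break"),
                           i = ev$i, j = ev$j, stringsAsFactors = FALSE))
}
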