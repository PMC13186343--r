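# Observables: Rg, saturation, graph-based cluster statistics and ACO,
# dissociation kinetics, radial profiles, MSD/diffusion, regression helper.

#' Unwrap coordinates using image flags
#'
#' @param state an \code{ssp_state}
#' @return N x 3 matrix of unwrapped positions (A)
#' @export
unwrap_positions <- function(state) {
  state$pos + sweep(state$img, 2, state$box, `*`)
}

#' Radius of gyration
#'
#' Root-mean-square distance of beads from their centroid. Pass unwrapped
#' coordinates (see [unwrap_positions()]): wrapped coordinates corrupt Rg
#' whenever a chain straddles the periodic boundary.
#'
#' @param pos N x 3 matrix of (unwrapped) positions, or an \code{ssp_state}
#'   (which is unwrapped automatically)
#' @return Rg in A (0 for a single bead)
#' @export
radius_of_gyration <- function(pos) {
  if (inherits(pos, "ssp_state")) pos <- unwrap_positions(pos)
  if (nrow(pos) == 1L) return(0)
  d <- sweep(pos, 2, colMeans(pos))
  sqrt(mean(rowSums(d * d)))
}

#' Fraction of stickers currently bonded
#'
#' @param state an \code{ssp_state}
#' @param topology combined \code{ssp_topology}
#' @return fraction in [0, 1]
#' @export
sticker_saturation <- function(state, topology) {
  st <- unlist(topology$stickers, use.names = FALSE)
  if (length(st) == 0L) stop("sticker_saturation is undefined: no stickers")
  sum(!is.na(state$pairing[st])) / length(st)
}

#' Connected-component cluster sizes of the chain bond graph
#'
#' One node per chain, one edge per active inter-chain sticker bond
#' (intra-chain bonds create no edge); returns the multiset of connected
#' component sizes in chains.
#'
#' @param state an \code{ssp_state} (its pairing table defines the edges)
#' @param topology combined \code{ssp_topology}
#' @return integer vector of cluster sizes, one entry per cluster;
#'   \code{sum(sizes)} equals the chain count
#' @export
cluster_components <- function(state, topology) {
  nc <- topology$n_chains
  i <- which(!is.na(state$pairing) & seq_along(state$pairing) < state$pairing)
  ci <- topology$chain[i]
  cj <- topology$chain[state$pairing[i]]
  keep <- ci != cj
  g <- igraph::make_empty_graph(n = nc, directed = FALSE)
  if (any(keep))
    g <- igraph::add_edges(g, rbind(ci[keep], cj[keep]))
  as.integer(igraph::components(g)$csize)
}

#' Average cluster occupancy (ACO)
#'
#' With n_i clusters of size S_i chains and N chains total, the fraction of
#' chains in clusters of size S_i is f_i = n_i S_i / N and
#' ACO = sum_i f_i S_i = (1/N) sum_i n_i S_i^2 (chains). The normalized ACO
#' divides by N once more and lies in [1/N, 1]: 1/N for an all-monomer
#' system, 1 when every chain is in one cluster.
#'
#' @param sizes cluster sizes (one entry per cluster), e.g. from
#'   [cluster_components()]
#' @param n_total total chain count
#' @return list with \code{aco} (chains) and \code{aco_norm}
#' @export
aco <- function(sizes, n_total) {
  if (sum(sizes) != n_total)
    stop("invalid input: cluster sizes must sum to the total chain count")
  a <- sum(as.numeric(sizes)^2) / n_total
  list(aco = a, aco_norm = a / n_total)
}

#' Cluster statistics of a configuration
#'
#' @inheritParams cluster_components
#' @return \code{ssp_cluster_stats}: sizes \code{S}, counts \code{n},
#'   fractions \code{f}, \code{aco}, \code{aco_norm}, \code{n_total}
#' @export
cluster_stats <- function(state, topology) {
  sizes <- cluster_components(state, topology)
  tab <- table(sizes)
  S <- as.integer(names(tab))
  n <- as.integer(tab)
  N <- topology$n_chains
  a <- aco(sizes, N)
  structure(list(S = S, n = n, f = n * S / N, aco = a$aco,
                 aco_norm = a$aco_norm, n_total = N),
            class = "ssp_cluster_stats")
}

#' Sticker-bond dissociation counts per time window
#'
#' @param events bond-event data frame from [run_simulation()]
#' @param window window width in steps (default 1e6)
#' @param n_steps total span to cover (defaults to the last event step)
#' @return data frame with window start step and break-event count
#' @export
dissociation_series <- function(events, window = 1e6, n_steps = NULL) {
  if (is.null(n_steps)) n_steps <- if (nrow(events)) max(events$step) else window
  edges <- seq(0, ceiling(n_steps / window) * window, by = window)
  breaks <- events$step[events$kind == "break"]
  counts <- if (length(breaks))
    tabulate(findInterval(breaks, edges, left.open = FALSE,
                          rightmost.closed = FALSE), length(edges) - 1L)
  else rep(0L, length(edges) - 1L)
  data.frame(window_start = edges[-length(edges)], n_break = counts)
}

# unwrap a set of chains into one connected periodic image by breadth-first
# traversal over chain connectivity + active sticker bonds, choosing
# minimum-image displacements edge by edge
unwrap_cluster <- function(state, topology, chains) {
  members <- which(topology$chain %in% chains)
  idx <- match(seq_len(topology$n_beads), members) # global -> local
  adj <- vector("list", length(members))
  add_edge <- function(a, b) {
    la <- idx[a]; lb <- idx[b]
    adj[[la]] <<- c(adj[[la]], lb)
    adj[[lb]] <<- c(adj[[lb]], la)
  }
  bm <- topology$bonds
  inb <- !is.na(idx[bm[, 1]]) & !is.na(idx[bm[, 2]])
  for (b in which(inb)) add_edge(bm[b, 1], bm[b, 2])
  sp <- which(!is.na(state$pairing) & seq_along(state$pairing) < state$pairing)
  for (i in sp) {
    j <- state$pairing[i]
    if (!is.na(idx[i]) && !is.na(idx[j])) add_edge(i, j)
  }
  pos <- state$pos[members, , drop = FALSE]
  out <- matrix(NA_real_, length(members), 3)
  box <- state$box
  visited <- rep(FALSE, length(members))
  for (s in seq_along(members)) {
    if (visited[s]) next
    out[s, ] <- pos[s, ]
    visited[s] <- TRUE
    queue <- s
    while (length(queue)) {
      a <- queue[[1]]; queue <- queue[-1]
      for (b in adj[[a]]) {
        if (visited[b]) next
        d <- pos[b, ] - out[a, ]
        d <- d - box * round(d / box)
        out[b, ] <- out[a, ] + d
        visited[b] <- TRUE
        queue <- c(queue, b)
      }
    }
  }
  list(pos = out, members = members)
}

#' Radial density profile of stickers and spacers within a cluster
#'
#' The member chains are unwrapped into a single connected image, and
#' per-shell number densities of sticker and spacer beads are computed about
#' the cluster centre of mass.
#'
#' @param state an \code{ssp_state}
#' @param topology combined \code{ssp_topology}
#' @param chains chain ids forming the cluster
#' @param breaks radial bin edges (A) from the centre of mass; the last bin
#'   is extended to cover all members if needed
#' @return data frame: bin edges, sticker and spacer counts and number
#'   densities (beads/A^3)
#' @export
radial_profile <- function(state, topology, chains, breaks = seq(0, 100, 10)) {
  if (length(chains) == 0L) stop("invalid input: empty cluster")
  uw <- unwrap_cluster(state, topology, chains)
  com <- colMeans(uw$pos)
  r <- sqrt(rowSums(sweep(uw$pos, 2, com)^2))
  if (max(r) >= max(breaks)) breaks <- c(breaks, max(r) * (1 + 1e-9))
  is_sticker <- topology$role[uw$members] != "spacer"
  bin <- findInterval(r, breaks, rightmost.closed = TRUE)
  nb <- length(breaks) - 1L
  cnt_st <- tabulate(bin[is_sticker], nb)
  cnt_sp <- tabulate(bin[!is_sticker], nb)
  vol <- 4 / 3 * pi * diff(breaks^3)
  data.frame(r_lo = breaks[-length(breaks)], r_hi = breaks[-1],
             n_sticker = cnt_st, n_spacer = cnt_sp,
             rho_sticker = cnt_st / vol, rho_spacer = cnt_sp / vol)
}

#' Mean squared displacement and diffusion coefficient
#'
#' Origin-averaged MSD over (approximately) logarithmically spaced lag
#' times from an unwrapped-coordinate trajectory, with a linear fit
#' MSD = 6 D t over the diffusive regime (lags beyond \code{fit_min_fs},
#' default 10 damping times, to exclude the ballistic regime).
#'
#' @param trajectory list with \code{steps} and \code{pos} (frames x N x 3,
#'   unwrapped), as produced by [run_simulation()] with \code{dump_every}
#' @param dt timestep (fs) used in the run
#' @param select bead indices to average over (default all)
#' @param t_damp damping time (fs), sets the default fit window
#' @param fit_min_fs lower edge of the fit window (fs)
#' @param n_lags number of lag times
#' @return \code{ssp_msd} list: \code{lag_fs}, \code{msd}, \code{D}
#'   (A^2/fs), and the \code{fit} (a [linear_fit()] result on the diffusive
#'   window)
#' @export
msd_diffusion <- function(trajectory, dt, select = NULL, t_damp = 500,
                          fit_min_fs = 10 * t_damp, n_lags = 40) {
  steps <- trajectory$steps
  if (length(steps) < 2L) stop("invalid input: trajectory needs >= 2 frames")
  if (length(unique(round(diff(steps)))) != 1L)
    stop("invalid input: trajectory frames must be evenly spaced")
  every <- diff(steps)[1]
  pos <- trajectory$pos
  if (is.null(select)) select <- seq_len(dim(pos)[2])
  nf <- dim(pos)[1]
  lags <- unique(pmax(1L, round(exp(seq(log(1), log(nf - 1L),
                                        length.out = n_lags)))))
  msd <- vapply(lags, function(l) {
    d <- pos[(1 + l):nf, select, , drop = FALSE] -
      pos[1:(nf - l), select, , drop = FALSE]
    mean(d[, , 1]^2 + d[, , 2]^2 + d[, , 3]^2)
  }, 1.0)
  lag_fs <- lags * every * dt
  win <- lag_fs >= fit_min_fs & lag_fs <= max(lag_fs)
  if (sum(win) < 3L) win <- lag_fs >= stats::median(lag_fs)
  fit <- linear_fit(lag_fs[win], msd[win])
  structure(list(lag_fs = lag_fs, msd = msd, D = fit$slope / 6, fit = fit),
            class = "ssp_msd")
}

#' Least-squares linear fit
#'
#' @param x,y numeric vectors (>= 3 points; x must have positive variance)
#' @return list: \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{p_value} (two-sided t-test on the slope), \code{slope_se},
#'   \code{slope_ci} (95 percent)
#' @export
linear_fit <- function(x, y) {
  if (length(x) < 3L || length(x) != length(y))
    stop("invalid input: need >= 3 paired points")
  if (stats::var(x) == 0) stop("invalid input: x has zero variance")
  fit <- lm(y ~ x)
  # summary.lm warns on numerically perfect fits; those are fine here
  sm <- suppressWarnings(summary(fit))
  ci <- tryCatch(suppressWarnings(confint(fit)["x", ]),
                 error = function(e) c(NA, NA))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients["x", "Pr(>|t|)"]),
       slope_se = unname(sm$coefficients["x", "Std. Error"]),
       slope_ci = unname(ci))
}

#' Reconstruct sticker pairing tables at selected steps from an event log
#'
#' Replays form/break events on top of an initial pairing table, yielding
#' the pairing as it stood just after each requested step. Used to follow
#' cluster statistics through a run without storing full snapshots.
#'
#' @param pairing initial pairing (integer partner per bead, NA = none)
#' @param events event data frame (step, kind, i, j), step-sorted
#' @param at_steps steps at which to report
#' @return list of pairing vectors, one per requested step
#' @export
pairing_at <- function(pairing, events, at_steps) {
  out <- vector("list", length(at_steps))
  k <- 1L
  ne <- nrow(events)
  for (w in seq_along(at_steps)) {
    while (k <= ne && events$step[k] <= at_steps[w]) {
      i <- events$i[k]; j <- events$j[k]
      if (events$kind[k] == "form") {
        pairing[i] <- j; pairing[j] <- i
      } else {
        pairing[i] <- NA_integer_; pairing[j] <- NA_integer_
      }
      k <- k + 1L
    }
    out[[w]] <- pairing
  }
  out
}
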