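# System assembly: replicate chain topologies and place them in a periodic
# box as self-avoiding-ish random walks with a minimum-separation rejection.

new_state <- function(pos, box, vel = NULL, img = NULL, pairing = NULL,
                      step = 0) {
  n <- nrow(pos)
  if (is.null(vel)) vel <- matrix(0, n, 3)
  if (is.null(img)) img <- matrix(0L, n, 3)
  if (is.null(pairing)) pairing <- rep(NA_integer_, n)
  structure(list(box = as.numeric(box), pos = pos, img = img, vel = vel,
                 pairing = as.integer(pairing), step = step),
            class = "ssp_state")
}

#' @export
print.ssp_state <- function(x, ...) {
  cat(sprintf("system state: %d beads, box %.6g x %.6g x %.6g A, step %s, %d stickers paired\n",
              nrow(x$pos), x$box[1], x$box[2], x$box[3],
              format(x$step, big.mark = ","), sum(!is.na(x$pairing))))
  invisible(x)
}

# minimum-image squared distances from point p to rows of m
.mi_dist2 <- function(p, m, box) {
  d <- sweep(m, 2, p)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  rowSums(d * d)
}

#' Pack chain copies into a periodic box
#'
#' Each chain copy is grown as a random walk with step length \code{R0}
#' (the equilibrium bond length); a placement is rejected whenever a new
#' bead comes within \code{min_separation} (minimum image) of any bead of
#' another chain or a non-adjacent bead of its own chain. Packing is
#' deterministic for a given \code{seed}.
#'
#' @param chain_specs list of \code{list(topology =, count =)} entries (one
#'   per chain type); topologies come from [build_chain()]
#' @param box box edge lengths (A), length 3 (or a scalar for a cube)
#' @param rule an [complementarity_rule()] (may be NULL for systems without
#'   specific bonds)
#' @param min_separation minimum inter-bead distance (A); default the bead
#'   diameter, which avoids Lennard-Jones overlap blowups at step 0
#' @param seed integer seed for the packer's random stream
#' @param R0 bond step length (A)
#' @param region optional \code{c(xlo, xhi, ylo, yhi, zlo, zhi)} sub-box in
#'   which to place chains (used e.g. to prepare a dense preformed droplet)
#' @param max_attempts per-chain regrow attempts before failing
#' @return \code{list(state =, topology =)}: an \code{ssp_state} (velocities
#'   zero, no sticker pairs) and the combined \code{ssp_topology}
#' @export
pack_system <- function(chain_specs, box, rule = NULL, min_separation = 10,
                        seed = 1, R0 = 10, region = NULL,
                        max_attempts = 500L) {
  if (length(box) == 1L) box <- rep(box, 3)
  box <- as.numeric(box)
  stopifnot(length(box) == 3L, all(box > 0))
  if (length(chain_specs) &&
      (inherits(chain_specs[[1]], "ssp_topology") || !is.list(chain_specs[[1]])))
    chain_specs <- list(chain_specs)
  lo <- c(0, 0, 0); hi <- box
  if (!is.null(region)) {
    stopifnot(length(region) == 6L)
    lo <- region[c(1, 3, 5)]; hi <- region[c(2, 4, 6)]
  }

  # combined topology ---------------------------------------------------
  role <- character(0)
  bonds <- list(); angles <- list(); chain <- integer(0)
  chain_id <- 0L; offset <- 0L
  sizes <- integer(0)
  for (spec in chain_specs) {
    topo <- spec$topology %||% spec[[1]]
    count <- as.integer(spec$count %||% spec[[2]])
    stopifnot(inherits(topo, "ssp_topology"), count >= 1L)
    n <- length(topo$role)
    for (k in seq_len(count)) {
      chain_id <- chain_id + 1L
      role <- c(role, topo$role)
      chain <- c(chain, rep(chain_id, n))
      if (nrow(topo$bonds)) bonds[[length(bonds) + 1L]] <- topo$bonds + offset
      if (nrow(topo$angles)) angles[[length(angles) + 1L]] <- topo$angles + offset
      sizes <- c(sizes, n)
      offset <- offset + n
    }
  }
  n_total <- offset
  labels <- sort(unique(role[role != "spacer"]))
  topo_all <- structure(list(
    n_beads = n_total, role = role,
    bonds = if (length(bonds)) do.call(rbind, bonds) else matrix(integer(), 0, 2),
    angles = if (length(angles)) do.call(rbind, angles) else matrix(integer(), 0, 3),
    chain = chain, n_chains = chain_id,
    type = role_types(role, labels), type_labels = labels,
    comp = comp_matrix(labels, rule),
    stickers = setNames(lapply(labels, function(l) which(role == l)), labels)
  ), class = "ssp_topology")

  # geometry ------------------------------------------------------------
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  pos <- matrix(NA_real_, n_total, 3)
  placed <- 0L
  min2 <- min_separation^2
  bead_tries <- 50L
  start <- cumsum(c(1L, sizes))[seq_along(sizes)]
  for (ci in seq_along(sizes)) {
    n <- sizes[ci]
    ok_chain <- FALSE
    for (att in seq_len(max_attempts)) {
      pts <- matrix(NA_real_, n, 3)
      pts[1, ] <- lo + runif(3) * (hi - lo)
      ok <- placed == 0L ||
        min(.mi_dist2(pts[1, ], pos[seq_len(placed), , drop = FALSE], box)) >= min2
      if (ok && n > 1L) {
        for (b in 2:n) {
          hit <- FALSE
          for (try in seq_len(bead_tries)) {
            u <- rnorm(3); u <- u / sqrt(sum(u * u))
            cand <- pts[b - 1L, ] + R0 * u
            prev <- pts[seq_len(b - 2L), , drop = FALSE]
            clear <- (placed == 0L ||
              min(.mi_dist2(cand, pos[seq_len(placed), , drop = FALSE], box)) >= min2) &&
              (nrow(prev) == 0L || min(.mi_dist2(cand, prev, box)) >= min2)
            if (clear) { pts[b, ] <- cand; hit <- TRUE; break }
          }
          if (!hit) { ok <- FALSE; break }
        }
      }
      if (ok) { ok_chain <- TRUE; break }
    }
    if (!ok_chain)
      stop(sprintf("packing failed for chain %d after %d attempts: density too high for min_separation = %g",
                   ci, max_attempts, min_separation))
    pos[start[ci]:(start[ci] + n - 1L), ] <- pts
    placed <- placed + n
  }
  # wrap into [0, box)
  img <- matrix(0L, n_total, 3)
  for (k in 1:3) {
    q <- floor(pos[, k] / box[k])
    pos[, k] <- pos[, k] - q * box[k]
    img[, k] <- as.integer(q)
  }
  list(state = new_state(pos, box, img = img), topology = topo_all)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Re-embed a configuration in a different periodic box
#'
#' Reconstructs one compact periodic image of the configuration, re-centres
#' its centroid at the new box centre, and re-wraps. Used e.g. to take a
#' dense preformed droplet into a larger box before a titration. When a
#' topology is supplied the compact image is built by breadth-first
#' minimum-image traversal over the chain + sticker-bond connectivity
#' (required when bonds span the periodic boundary); otherwise the stored
#' image flags are used. The compact image must fit inside the new box.
#'
#' @param state an \code{ssp_state}
#' @param box new box edges (scalar or length 3)
#' @param topology optional combined \code{ssp_topology} enabling
#'   connectivity-based unwrapping
#' @return an \code{ssp_state} in the new box (step counter preserved)
#' @export
rebox_state <- function(state, box, topology = NULL) {
  if (length(box) == 1L) box <- rep(box, 3)
  if (is.null(topology)) {
    uw <- unwrap_positions(state)
  } else {
    u <- unwrap_cluster(state, topology, unique(topology$chain))
    uw <- u$pos # members cover all beads, already in bead order
  }
  ext <- apply(uw, 2, function(x) diff(range(x)))
  if (any(ext >= box))
    stop("unwrapped configuration does not fit in the new box")
  pos <- sweep(uw, 2, colMeans(uw) - box / 2)
  img <- matrix(0L, nrow(pos), 3)
  for (k in 1:3) {
    q <- floor(pos[, k] / box[k])
    pos[, k] <- pos[, k] - q * box[k]
    img[, k] <- as.integer(q)
  }
  new_state(pos, box, vel = state$vel, img = img, pairing = state$pairing,
            step = state$step)
}
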