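# LAMMPS-style "molecular" data files and the package's own restart format.
# Data files carry topology + wrapped coordinates + image flags for
# interoperability; restarts additionally carry velocities, the sticker
# pairing table and the step counter, and round-trip exactly.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a LAMMPS-style molecular data file
#'
#' Sections: header counts, box bounds, Masses, Atoms (id mol type x y z
#' ix iy iz), Bonds, Angles. Sticker-type labels and the force-field
#' constants are embedded as comment lines so that [read_data_file()] can
#' reconstruct the full parameterized system; other readers ignore them.
#' Output is deterministic: identical inputs give byte-identical files.
#'
#' @param state an \code{ssp_state}
#' @param topology combined \code{ssp_topology}
#' @param params \code{ssp_params}
#' @param path output file
#' @param mass per-bead mass written to the Masses section (g/mol)
#' @export
write_data_file <- function(state, topology, params, path, mass = 100) {
  n <- nrow(state$pos)
  stopifnot(length(topology$role) == n)
  labels <- topology$type_labels %||% character(0)
  types <- (topology$type %||% role_types(topology$role, labels)) + 1L
  ntypes <- length(labels) + 1L
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("LAMMPS data file via polysticker")
  w("# sticker types: %s",
    paste(c("1=spacer", if (length(labels))
      sprintf("%d=%s", seq_along(labels) + 1L, labels)), collapse = " "))
  w("# params: %s", paste(sprintf("%s=%s", names(unclass(params)),
                                  fmt_num(unlist(params))), collapse = " "))
  if (!is.null(topology$comp) && length(labels)) {
    pairs <- which(upper.tri(topology$comp) & topology$comp == 1, arr.ind = TRUE)
    diag_pairs <- which(diag(topology$comp) == 1)
    allow <- c(sprintf("%s-%s", labels[pairs[, 1]], labels[pairs[, 2]]),
               sprintf("%s-%s", labels[diag_pairs], labels[diag_pairs]))
    w("# complementary: %s", paste(allow, collapse = " "))
  }
  w("")
  w("%d atoms", n)
  w("%d bonds", nrow(topology$bonds))
  w("%d angles", nrow(topology$angles))
  w("%d atom types", ntypes)
  w("%d bond types", 1L)
  w("%d angle types", 1L)
  w("")
  w("0 %s xlo xhi", fmt_num(state$box[1]))
  w("0 %s ylo yhi", fmt_num(state$box[2]))
  w("0 %s zlo zhi", fmt_num(state$box[3]))
  w("")
  w("Masses")
  w("")
  for (t in seq_len(ntypes)) w("%d %s", t, fmt_num(mass))
  w("")
  w("Atoms # molecular")
  w("")
  writeLines(sprintf("%d %d %d %s %s %s %d %d %d", seq_len(n),
                     topology$chain, types,
                     fmt_num(state$pos[, 1]), fmt_num(state$pos[, 2]),
                     fmt_num(state$pos[, 3]),
                     state$img[, 1], state$img[, 2], state$img[, 3]), con)
  if (nrow(topology$bonds)) {
    writeLines(c("", "Bonds", "",
                 sprintf("%d 1 %d %d", seq_len(nrow(topology$bonds)),
                         topology$bonds[, 1], topology$bonds[, 2])), con)
  }
  if (nrow(topology$angles)) {
    writeLines(c("", "Angles", "",
                 sprintf("%d 1 %d %d %d", seq_len(nrow(topology$angles)),
                         topology$angles[, 1], topology$angles[, 2],
                         topology$angles[, 3])), con)
  }
  invisible(path)
}

parse_error <- function(path, lineno, msg) {
  stop(sprintf("parse error in %s at line %d: %s", path, lineno, msg),
       call. = FALSE)
}

#' Read a LAMMPS-style molecular data file
#'
#' @param path file written by [write_data_file()] (or a compatible
#'   molecular-style data file)
#' @return list with \code{state}, \code{topology} and (when the parameter
#'   comment block is present) \code{params}
#' @export
read_data_file <- function(path) {
  lines <- readLines(path)
  strip <- sub("\\s+$", "", sub("^\\s+", "", lines))
  # header comments
  labels <- character(0)
  params <- NULL
  comp_pairs <- list()
  for (ln in strip[startsWith(strip, "#")]) {
    if (grepl("^# sticker types:", ln)) {
      toks <- strsplit(sub("^# sticker types:\\s*", "", ln), "\\s+")[[1]]
      kv <- strsplit(toks, "=")
      for (p in kv) if (p[2] != "spacer") labels[as.integer(p[1]) - 1L] <- p[2]
    } else if (grepl("^# params:", ln)) {
      toks <- strsplit(sub("^# params:\\s*", "", ln), "\\s+")[[1]]
      kv <- strsplit(toks, "=")
      vals <- lapply(kv, function(p) as.numeric(p[2]))
      names(vals) <- vapply(kv, `[[`, "", 1)
      params <- do.call(forcefield_params, vals)
    } else if (grepl("^# complementary:", ln)) {
      toks <- strsplit(sub("^# complementary:\\s*", "", ln), "\\s+")[[1]]
      comp_pairs <- lapply(strsplit(toks, "-"), identity)
    }
  }
  num <- function(i) suppressWarnings(as.numeric(strsplit(strip[i], "\\s+")[[1]]))
  counts <- c(atoms = 0L, bonds = 0L, angles = 0L)
  box <- c(NA_real_, NA_real_, NA_real_)
  for (i in seq_along(strip)) {
    ln <- strip[i]
    if (grepl("^[0-9]+ atoms$", ln)) counts["atoms"] <- as.integer(num(i)[1])
    if (grepl("^[0-9]+ bonds$", ln)) counts["bonds"] <- as.integer(num(i)[1])
    if (grepl("^[0-9]+ angles$", ln)) counts["angles"] <- as.integer(num(i)[1])
    if (grepl("xlo xhi$", ln)) box[1] <- diff(num(i)[1:2])
    if (grepl("ylo yhi$", ln)) box[2] <- diff(num(i)[1:2])
    if (grepl("zlo zhi$", ln)) box[3] <- diff(num(i)[1:2])
  }
  if (counts["atoms"] < 1L) parse_error(path, 1L, "no atom count in header")
  if (anyNA(box)) parse_error(path, 1L, "missing box bounds")
  n <- counts["atoms"]
  section <- function(name, ncol_min, nrows) {
    at <- which(strip == name | startsWith(strip, paste0(name, " ")) |
                  startsWith(strip, paste0(name, "\t")) |
                  grepl(paste0("^", name, "\\s*#"), strip))
    if (length(at) == 0L) {
      if (nrows == 0L) return(NULL)
      parse_error(path, length(strip), paste("missing section", name))
    }
    at <- at[1]
    rows <- matrix(NA_real_, nrows, ncol_min)
    i <- at + 1L
    got <- 0L
    while (got < nrows) {
      if (i > length(strip)) parse_error(path, length(strip),
                                         paste("truncated section", name))
      if (nzchar(strip[i]) && !startsWith(strip[i], "#")) {
        v <- num(i)
        if (anyNA(v[seq_len(ncol_min)]))
          parse_error(path, i, paste("malformed row in section", name))
        got <- got + 1L
        rows[got, ] <- v[seq_len(ncol_min)]
      }
      i <- i + 1L
    }
    attr(rows, "line") <- at
    rows
  }
  atoms <- section("Atoms", 9L, n)
  ord <- order(atoms[, 1])
  atoms <- atoms[ord, , drop = FALSE]
  if (!all(atoms[, 1] == seq_len(n)))
    parse_error(path, attr(atoms, "line"), "atom ids are not 1..N")
  pos <- atoms[, 4:6, drop = FALSE]
  img <- matrix(as.integer(atoms[, 7:9]), n, 3)
  chain <- as.integer(atoms[, 2])
  types <- as.integer(atoms[, 3])
  role <- rep("spacer", n)
  st <- types > 1L
  role[st] <- labels[types[st] - 1L]
  if (anyNA(role)) role[is.na(role)] <- paste0("t", types[is.na(role)])
  bonds <- section("Bonds", 4L, counts["bonds"])
  angles <- section("Angles", 5L, counts["angles"])
  bm <- if (is.null(bonds)) matrix(integer(), 0, 2) else
    matrix(as.integer(bonds[, 3:4]), ncol = 2)
  am <- if (is.null(angles)) matrix(integer(), 0, 3) else
    matrix(as.integer(angles[, 3:5]), ncol = 3)
  if (nrow(bm) && (min(bm) < 1L || max(bm) > n))
    parse_error(path, attr(bonds, "line"), "bond references a missing atom id")
  if (nrow(am) && (min(am) < 1L || max(am) > n))
    parse_error(path, attr(angles, "line"), "angle references a missing atom id")
  labels_all <- sort(unique(role[role != "spacer"]))
  rule <- if (length(comp_pairs)) complementarity_rule(comp_pairs) else NULL
  topo <- structure(list(
    n_beads = n, role = role, bonds = bm, angles = am,
    chain = chain, n_chains = length(unique(chain)),
    type = role_types(role, labels_all), type_labels = labels_all,
    comp = comp_matrix(labels_all, rule),
    stickers = setNames(lapply(labels_all, function(l) which(role == l)),
                        labels_all)
  ), class = "ssp_topology")
  list(state = new_state(pos, box, img = img), topology = topo,
       params = params)
}

#' Write a restart file
#'
#' Versioned plain-text snapshot: box, step counter, positions, velocities,
#' image flags and the sticker pairing table, at full double precision. A
#' reloaded restart continues a seeded run bit-for-bit (randomness is keyed
#' on the absolute step number, not on hidden generator state).
#'
#' @param state an \code{ssp_state}
#' @param path output file
#' @export
write_restart <- function(state, path) {
  n <- nrow(state$pos)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "polysticker restart 1",
    sprintf("step %s", fmt_num(state$step)),
    sprintf("box %s %s %s", fmt_num(state$box[1]), fmt_num(state$box[2]),
            fmt_num(state$box[3])),
    sprintf("natoms %d", n),
    "positions",
    sprintf("%s %s %s", fmt_num(state$pos[, 1]), fmt_num(state$pos[, 2]),
            fmt_num(state$pos[, 3])),
    "velocities",
    sprintf("%s %s %s", fmt_num(state$vel[, 1]), fmt_num(state$vel[, 2]),
            fmt_num(state$vel[, 3])),
    "images",
    sprintf("%d %d %d", state$img[, 1], state$img[, 2], state$img[, 3]),
    "pairing",
    sprintf("%d", ifelse(is.na(state$pairing), 0L, state$pairing)),
    "end"), con)
  invisible(path)
}

#' Write coordinates in XYZ format
#'
#' One frame per snapshot, bead roles as element labels. Accepts a single
#' \code{ssp_state} (wrapped coordinates) or a trajectory from
#' [run_simulation()] (unwrapped coordinates, one frame per dump step).
#'
#' @param x an \code{ssp_state} or a \code{trajectory} list
#' @param topology combined \code{ssp_topology} (for the role labels)
#' @param path output file
#' @export
write_xyz <- function(x, topology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  emit <- function(pos, comment) {
    writeLines(c(sprintf("%d", nrow(pos)), comment,
                 sprintf("%s %.6f %.6f %.6f", topology$role,
                         pos[, 1], pos[, 2], pos[, 3])), con)
  }
  if (inherits(x, "ssp_state")) {
    emit(x$pos, sprintf("step %.0f", x$step))
  } else {
    for (f in seq_along(x$steps))
      emit(x$pos[f, , ], sprintf("step %.0f", x$steps[f]))
  }
  invisible(path)
}

#' Read a restart file
#'
#' @param path file written by [write_restart()]
#' @return an \code{ssp_state}
#' @export
read_restart <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L || lines[1] != "polysticker restart 1")
    stop("integrity error: not a polysticker restart file (version 1)")
  need <- function(pat, what) {
    i <- grep(pat, lines)
    if (length(i) != 1L)
      stop(sprintf("integrity error: restart lacks a %s section", what))
    i
  }
  step <- as.numeric(sub("^step ", "", lines[need("^step ", "step")]))
  box <- as.numeric(strsplit(sub("^box ", "", lines[need("^box ", "box")]),
                             " ")[[1]])
  n <- as.integer(sub("^natoms ", "", lines[need("^natoms ", "natoms")]))
  block <- function(name, n, ncol) {
    i <- need(paste0("^", name, "$"), name)
    if (i + n > length(lines))
      stop(sprintf("integrity error: truncated %s section", name))
    vals <- strsplit(lines[(i + 1L):(i + n)], " ")
    m <- matrix(as.numeric(unlist(vals)), n, ncol, byrow = TRUE)
    if (anyNA(m))
      stop(sprintf("integrity error: malformed %s section", name))
    m
  }
  pos <- block("positions", n, 3L)
  vel <- block("velocities", n, 3L)
  img <- matrix(as.integer(block("images", n, 3L)), n, 3L)
  pr <- as.integer(block("pairing", n, 1L))
  if (lines[length(lines)] != "end")
    stop("integrity error: restart file truncated (missing end marker)")
  pr[pr == 0L] <- NA_integer_
  new_state(pos, box, vel = vel, img = img, pairing = pr, step = step)
}
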