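#' Sticker-spacer block template
#'
#' A chain is built by repeating a block of bead roles. Each role is either
#' \code{"spacer"} or a sticker-type label (any other string, e.g. "A", "B").
#'
#' @param roles character vector of bead roles within one block
#' @param repeats number of block repeats forming the chain
#' @return an object of class \code{ssp_block}
#' @examples
#' block_template(c("A", "spacer", "spacer", "spacer", "spacer"), 10)
#' @export
block_template <- function(roles, repeats = 1L) {
  if (length(roles) == 0L || !is.character(roles) || anyNA(roles) ||
      any(!nzchar(roles)))
    stop("invalid template: `roles` must be a non-empty character vector")
  repeats <- as.integer(repeats)
  if (length(repeats) != 1L || is.na(repeats) || repeats < 1L)
    stop("invalid template: `repeats` must be a positive integer")
  structure(list(roles = roles, repeats = repeats), class = "ssp_block")
}

#' Build a linear chain topology from a block template
#'
#' The block is concatenated \code{repeats} times; consecutive beads are
#' joined by permanent harmonic bonds and every run of three consecutive
#' beads defines a bending angle.
#'
#' @param template an \code{ssp_block} from [block_template()]
#' @return an \code{ssp_topology} for a single chain: \code{role} (character
#'   per bead), \code{bonds} (Mx2 bead indices), \code{angles} (Kx3),
#'   \code{chain} (chain id per bead), and \code{stickers} (index list per
#'   sticker type)
#' @export
build_chain <- function(template) {
  if (!inherits(template, "ssp_block"))
    template <- do.call(block_template, template)
  role <- rep(template$roles, template$repeats)
  n <- length(role)
  bonds <- if (n > 1L) cbind(seq_len(n - 1L), 2:n) else
    matrix(integer(), 0L, 2L)
  angles <- if (n > 2L) cbind(seq_len(n - 2L), 2:(n - 1L), 3:n) else
    matrix(integer(), 0L, 3L)
  labels <- sort(unique(role[role != "spacer"]))
  stickers <- lapply(labels, function(l) which(role == l))
  names(stickers) <- labels
  structure(list(
    n_beads = n, role = role,
    bonds = bonds, angles = angles,
    chain = rep(1L, n), n_chains = 1L,
    stickers = stickers
  ), class = "ssp_topology")
}

#' Complementarity rule for specific sticker interactions
#'
#' Declares which (unordered) sticker-type pairs may form a specific bond.
#' The common heterotypic-only system is \code{complementarity_rule(list(c("A","B")))}:
#' A binds B but neither A-A nor B-B.
#'
#' @param pairs list of length-2 character vectors of sticker-type labels
#' @return an \code{ssp_rule}
#' @export
complementarity_rule <- function(pairs) {
  if (is.character(pairs)) pairs <- list(pairs)
  ok <- vapply(pairs, function(p) is.character(p) && length(p) == 2L, TRUE)
  if (length(pairs) == 0L || !all(ok))
    stop("`pairs` must be a list of length-2 character vectors")
  structure(list(pairs = pairs), class = "ssp_rule")
}

# complementarity matrix over the given sticker labels (symmetric 0/1)
comp_matrix <- function(labels, rule) {
  k <- length(labels)
  m <- matrix(0L, k, k, dimnames = list(labels, labels))
  if (k == 0L) return(m)
  if (!is.null(rule)) {
    for (p in rule$pairs) {
      if (!all(p %in% labels)) next
      m[p[1], p[2]] <- 1L
      m[p[2], p[1]] <- 1L
    }
  }
  m
}

# integer sticker types (0 = spacer, 1..K = position in `labels`)
role_types <- function(role, labels) {
  t <- match(role, labels)
  t[is.na(t)] <- 0L
  as.integer(t)
}

#' @export
print.ssp_topology <- function(x, ...) {
  cat(sprintf("sticker-spacer topology: %d beads, %d chains, %d bonds, %d angles\n",
              length(x$role), x$n_chains, nrow(x$bonds), nrow(x$angles)))
  ns <- vapply(x$stickers, length, 1L)
  if (length(ns))
    cat("stickers:", paste(sprintf("%s=%d", names(ns), ns), collapse = ", "), "\n")
  invisible(x)
}
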