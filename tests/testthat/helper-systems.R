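# fixtures built in code: small two-type sticker-spacer systems and random
# configurations used across tests

ab_rule <- function() complementarity_rule(list(c("A", "B")))

chain_A <- function(repeats = 10) {
  build_chain(block_template(c("A", "spacer", "spacer", "spacer", "spacer"),
                             repeats))
}
chain_B <- function(repeats = 10) {
  build_chain(block_template(c("B", "spacer", "spacer", "spacer", "spacer"),
                             repeats))
}

# n_each copies of each chain type packed in a cubic box
two_type_system <- function(n_each = 2, repeats = 4, box = 150, seed = 1,
                            min_separation = 10) {
  pack_system(list(list(chain_A(repeats), n_each),
                   list(chain_B(repeats), n_each)),
              box, ab_rule(), min_separation = min_separation, seed = seed)
}

# a bare two-sticker system with beads at given positions
two_sticker_system <- function(pos, box = c(100, 100, 100)) {
  sys <- pack_system(list(list(build_chain(block_template("A", 1)), 1),
                          list(build_chain(block_template("B", 1)), 1)),
                     box, ab_rule(), min_separation = 1, seed = 1)
  sys$state$pos <- pos
  sys$state$img[] <- 0L
  sys
}

# random non-overlapping bead positions (rejection sampling)
random_positions <- function(n, box, min_sep = 6, seed = 1) {
  set.seed(seed)
  pos <- matrix(NA_real_, n, 3)
  pos[1, ] <- runif(3) * box
  for (i in 2:n) {
    repeat {
      cand <- runif(3) * box
      d <- sweep(pos[seq_len(i - 1), , drop = FALSE], 2, cand)
      d <- d - round(sweep(d, 2, rep(box, length.out = 3), "/")) *
        rep(box, length.out = 3)[col(d)]
      if (min(rowSums(d^2)) >= min_sep^2) break
    }
    pos[i, ] <- cand
  }
  pos
}

# brute-force minimum-image distance matrix
mi_dist <- function(pos, box) {
  n <- nrow(pos)
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- pos[i, ] - pos[j, ]
    d <- d - box * round(d / box)
    out[i, j] <- out[j, i] <- sqrt(sum(d^2))
  }
  out
}

# brute-force connected components (BFS reachability oracle)
bf_components <- function(n, edges) {
  comp <- rep(NA_integer_, n)
  cid <- 0L
  adj <- vector("list", n)
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      for (b in adj[[a]]) if (is.na(comp[b])) { comp[b] <- cid; queue <- c(queue, b) }
    }
  }
  as.integer(table(comp))
}
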