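# Independent oracles used across the suite.

# Brute-force minimum substitution count for one alignment column on a
# binary tree: enumerate every labeling of the internal nodes (and of
# wildcard leaves) over the states observed in the column, count edges whose
# endpoints differ, and take the minimum.  Exponential; for <= 6 leaves only.
brute_force_fitch <- function(tree, states) {
  # states: character vector named by tip label; "-"/"X" are wildcards
  n_tip <- length(tree$tip.label)
  stopifnot(n_tip <= 6L)
  observed <- setdiff(unique(states), c("-", "X"))
  if (length(observed) == 0L) return(0L)
  n_node <- n_tip + tree$Nnode
  fixed <- rep(NA_character_, n_node)
  fixed[seq_len(n_tip)] <- states[tree$tip.label]
  free <- which(is.na(fixed) | fixed %in% c("-", "X"))
  grid <- expand.grid(rep(list(observed), length(free)),
                      stringsAsFactors = FALSE)
  edge <- tree$edge
  best <- Inf
  for (row in seq_len(nrow(grid))) {
    lab <- fixed
    lab[free] <- unlist(grid[row, ], use.names = FALSE)
    changes <- sum(lab[edge[, 1L]] != lab[edge[, 2L]])
    best <- min(best, changes)
  }
  as.integer(best)
}

# Adaptive-quadrature evaluation of the gamma-Poisson marginals.
quad_p0 <- function(x1, x2, alpha, d1, d2) {
  f <- function(r) stats::dgamma(r, shape = alpha, rate = alpha) *
    stats::dpois(x1, d1 * r) * stats::dpois(x2, d2 * r)
  stats::integrate(f, 0, Inf, rel.tol = 1e-10, abs.tol = 1e-12)$value
}

quad_p1 <- function(x1, x2, alpha, d1, d2) {
  g <- function(x, d) stats::integrate(function(r)
    stats::dgamma(r, shape = alpha, rate = alpha) * stats::dpois(x, d * r),
    0, Inf, rel.tol = 1e-10, abs.tol = 1e-12)$value
  g(x1, d1) * g(x2, d2)
}

# random binary tree with n tips labeled t1..tn
random_binary_tree <- function(n) {
  tr <- ape::rtree(n, rooted = TRUE)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}
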