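# Synthetic-data generators emulating the statistical structure the
# divergence analyses assume: gamma-distributed site rates, a fraction theta
# of sites with independently re-drawn rates between clusters, and
# hydropathy-profile groups with controllable separation.  All generators
# are pure functions of their arguments including the seed.

#' Simulate paired per-site substitution counts under the divergence model
#'
#' For each site, the divergent state F1 is drawn with probability `theta`;
#' site rates are Gamma(shape `alpha`, rate `alpha`) (mean 1), shared
#' between clusters under F0 and drawn independently under F1; counts are
#' Poisson with means `d1 * rate` and `d2 * rate`.
#'
#' @param n_sites Number of sites (>= 1).
#' @param params A [divergence_params()] (true generating values).
#' @param seed Integer seed; same seed, same output.
#' @return List with `x1`, `x2` (integer count vectors), `divergent`
#'   (logical true states) and `params`.
#' @export
simulate_count_pairs <- function(n_sites, params, seed) {
  stopifnot(inherits(params, "divergence_params"), n_sites >= 1L)
  withr_seed(seed, {
    divergent <- stats::runif(n_sites) < params$theta
    r_shared <- stats::rgamma(n_sites, shape = params$alpha, rate = params$alpha)
    r1 <- r_shared
    r2 <- r_shared
    nd <- sum(divergent)
    if (nd > 0L) {
      r1[divergent] <- stats::rgamma(nd, shape = params$alpha, rate = params$alpha)
      r2[divergent] <- stats::rgamma(nd, shape = params$alpha, rate = params$alpha)
    }
    list(x1 = stats::rpois(n_sites, params$d1 * r1),
         x2 = stats::rpois(n_sites, params$d2 * r2),
         divergent = divergent,
         params = params)
  })
}

# run code under a local RNG state seeded with `seed`
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate aligned cluster sequences under the two-state rate scheme
#'
#' One ancestral sequence is drawn from the equilibrium frequencies (the two
#' clusters are paralogs sharing it); each cluster then evolves down its own
#' tree under a Poisson-style equal-exchangeability substitution process: on
#' a branch of length t, a site with relative rate r experiences
#' Poisson(r * scale * t) substitution events, each replacing the residue
#' with a draw from the equilibrium frequencies. Per-site rates follow the
#' F0/F1 scheme of [simulate_count_pairs()]. No indels are generated, so the
#' output is already aligned.
#'
#' @param tree1,tree2 Binary `phylo` trees with branch lengths (leaf sets
#'   must be disjoint).
#' @param n_columns Number of alignment columns.
#' @param theta,alpha Divergence fraction and gamma shape of site rates.
#' @param depth_scale Length-2 multiplier of branch lengths per cluster
#'   (default `c(1, 1)`).
#' @param freqs Amino-acid equilibrium frequencies (default uniform over the
#'   20 standard residues; must sum to 1).
#' @param seed Integer seed.
#' @return List with `alignment` (an [aa_alignment()] of all leaves),
#'   `members1`, `members2` (leaf name vectors), `divergent` (true site
#'   states), `rates1`, `rates2` (true per-site rates).
#' @export
simulate_cluster_alignment <- function(tree1, tree2, n_columns, theta, alpha,
                                       depth_scale = c(1, 1),
                                       freqs = NULL, seed = 1L) {
  validate_cluster_tree(tree1); validate_cluster_tree(tree2)
  if (is.null(tree1$edge.length) || is.null(tree2$edge.length)) {
    stop("both trees need branch lengths", call. = FALSE)
  }
  if (length(intersect(tree1$tip.label, tree2$tip.label)) > 0L) {
    stop("cluster trees must have disjoint leaf sets", call. = FALSE)
  }
  stopifnot(n_columns >= 1L, theta >= 0, theta <= 1, alpha > 0,
            length(depth_scale) == 2L, all(depth_scale >= 0))
  if (is.null(freqs)) freqs <- rep(1 / 20, 20L)
  if (length(freqs) != 20L || abs(sum(freqs) - 1) > 1e-8 || any(freqs < 0)) {
    stop("freqs must be 20 non-negative values summing to 1", call. = FALSE)
  }

  withr_seed(seed, {
    divergent <- stats::runif(n_columns) < theta
    r_shared <- stats::rgamma(n_columns, shape = alpha, rate = alpha)
    rates1 <- r_shared; rates2 <- r_shared
    nd <- sum(divergent)
    if (nd > 0L) {
      rates1[divergent] <- stats::rgamma(nd, shape = alpha, rate = alpha)
      rates2[divergent] <- stats::rgamma(nd, shape = alpha, rate = alpha)
    }
    root_seq <- sample.int(20L, n_columns, replace = TRUE, prob = freqs)
    leaves1 <- evolve_sequences(tree1, root_seq, rates1 * depth_scale[1L], freqs)
    leaves2 <- evolve_sequences(tree2, root_seq, rates2 * depth_scale[2L], freqs)
    ids <- c(rownames(leaves1), rownames(leaves2))
    seqs <- apply(rbind(leaves1, leaves2), 1L, function(z)
      paste(AA_ALPHABET[z], collapse = ""))
    list(alignment = aa_alignment(ids, seqs),
         members1 = tree1$tip.label,
         members2 = tree2$tip.label,
         divergent = divergent,
         rates1 = rates1, rates2 = rates2)
  })
}

# evolve integer-coded sequences down a tree; returns leaves x columns matrix
evolve_sequences <- function(tree, root_seq, site_rates, freqs) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  n_col <- length(root_seq)
  seqs <- matrix(NA_integer_, n_node, n_col)
  edge <- stats::reorder(tree, "cladewise")$edge
  lens <- stats::reorder(tree, "cladewise")$edge.length
  root <- n_tip + 1L
  seqs[root, ] <- root_seq
  for (e in seq_len(nrow(edge))) {
    parent <- edge[e, 1L]; child <- edge[e, 2L]
    s <- seqs[parent, ]
    n_events <- stats::rpois(n_col, site_rates * lens[e])
    hit <- n_events > 0L
    if (any(hit)) {
      s[hit] <- sample.int(20L, sum(hit), replace = TRUE, prob = freqs)
    }
    seqs[child, ] <- s
  }
  out <- seqs[seq_len(n_tip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

#' Simulate hydropathy-profile groups with controllable separation
#'
#' On every informative column the group means are a random permutation of
#' `g` equally spaced levels centred on 0.5 and spanning `separation`, so
#' the two extreme groups differ by exactly `separation`, every pair of
#' groups differs by at least `separation / (g - 1)`, and each group carries
#' a distinct signature across columns (separable under magnitude- and
#' shape-based distances alike). Uninformative columns share the mean 0.5.
#' Gaussian noise with standard deviation `spread` is added and values are
#' clipped to \[0, 1\].
#'
#' @param sizes Integer vector of group sizes (each >= 2).
#' @param n_columns Number of profile columns.
#' @param separation Distance between the extreme group means on informative
#'   columns (must fit in \[0, 1\]: `separation <= 1`).
#' @param spread Within-group standard deviation (> 0).
#' @param frac_informative Fraction of columns that separate the groups
#'   (default 0.3).
#' @param seed Integer seed.
#' @return List with `profiles` (matrix, rows `g<k>_s<j>`), `labels`
#'   (factor), `informative` (logical per column), `group_means`.
#' @export
simulate_profile_groups <- function(sizes, n_columns, separation, spread,
                                    frac_informative = 0.3, seed = 1L) {
  stopifnot(all(sizes >= 2L), n_columns >= 1L, spread > 0,
            frac_informative >= 0, frac_informative <= 1)
  g <- length(sizes)
  if (separation < 0 || separation > 1) {
    stop("separation must lie in [0, 1] so group means fit the profile scale",
         call. = FALSE)
  }
  withr_seed(seed, {
    n_inf <- min(n_columns,
                 max(if (separation > 0) g else 0L,
                     round(frac_informative * n_columns)))
    informative <- rep(FALSE, n_columns)
    inf_cols <- sample.int(n_columns, n_inf)
    informative[inf_cols] <- TRUE
    group_means <- matrix(0.5, g, n_columns)
    if (n_inf > 0L && separation > 0 && g > 1L) {
      levels <- 0.5 + seq(-0.5, 0.5, length.out = g) * separation
      for (j in inf_cols) {
        group_means[, j] <- sample(levels)
      }
    }
    n <- sum(sizes)
    labels <- factor(rep(paste0("g", seq_len(g)), sizes))
    profiles <- group_means[rep(seq_len(g), sizes), , drop = FALSE] +
      matrix(stats::rnorm(n * n_columns, sd = spread), n, n_columns)
    profiles[profiles < 0] <- 0
    profiles[profiles > 1] <- 1
    rownames(profiles) <- paste0(labels, "_s", unlist(lapply(sizes, seq_len)))
    colnames(profiles) <- as.character(seq_len(n_columns))
    list(profiles = profiles, labels = labels, informative = informative,
         group_means = group_means)
  })
}
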