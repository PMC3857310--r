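test_that("Fitch counts reproduce hand-derived column scores", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  aln <- aa_alignment(c("A", "B", "C", "D"),
                      c("VVVM-", "VVLMV", "VLVMX", "VLLMV"))
  counts <- site_substitution_counts(tr, aln)
  expect_equal(unname(counts[1]), 0L)  # identical column
  expect_equal(unname(counts[2]), 1L)  # V,V,L,L on ((A,B),(C,D))
  expect_equal(unname(counts[3]), 2L)  # V,L,V,L
  expect_equal(unname(counts[4]), 0L)
  expect_equal(unname(counts[5]), 0L)  # gaps/X are wildcards, never a change
})

test_that("Fitch counts match brute-force enumeration on small trees", {
  set.seed(420)
  for (rep in 1:15) {
    n <- sample(3:6, 1)
    tr <- random_binary_tree(n)
    states <- sample(c("V", "L", "K", "-", "X"), n, replace = TRUE,
                     prob = c(0.3, 0.3, 0.2, 0.1, 0.1))
    names(states) <- tr$tip.label
    aln <- aa_alignment(tr$tip.label, states[tr$tip.label])
    got <- unname(site_substitution_counts(tr, aln)[1])
    expect_equal(got, brute_force_fitch(tr, states),
                 label = paste(states, collapse = ""))
  }
})

test_that("Fitch counts agree with phangorn on unambiguous columns", {
  skip_if_not_installed("phangorn")
  set.seed(421)
  tr <- random_binary_tree(6)
  mat <- matrix(sample(c("V", "L", "K", "A"), 6 * 30, replace = TRUE), 6, 30)
  rownames(mat) <- tr$tip.label
  aln <- aa_alignment(tr$tip.label, apply(mat, 1, paste, collapse = ""))
  ours <- sum(site_substitution_counts(tr, aln))
  pd <- phangorn::phyDat(mat, type = "AA")
  expect_equal(ours, phangorn::parsimony(tr, pd, method = "fitch"),
               ignore_attr = TRUE)
})

test_that("member subsets and missing leaves are handled", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  aln <- aa_alignment(c("A", "B", "C"), c("V", "V", "L"))
  expect_error(site_substitution_counts(tr, aln), "missing from alignment")
  expect_equal(unname(site_substitution_counts(tr, aln,
                                               members = c("A", "B", "C"))[1]),
               1L)
  expect_error(site_substitution_counts(tr, aln, members = c("A", "Z")),
               "not in tree")
})

test_that("pattern likelihoods match exact and quadrature values", {
  p <- divergence_params(0.5, 1, 1, 1)
  # alpha = 1, d1 = d2 = 1: P0(0,0) = int e^-r e^-2r dr = 1/3
  expect_equal(pattern_likelihood(0, 0, p, "F0"), 1 / 3, tolerance = 1e-12)
  # independent rates: (1/2) * (1/2)
  expect_equal(pattern_likelihood(0, 0, p, "F1"), 1 / 4, tolerance = 1e-12)

  # closed forms vs adaptive quadrature over a parameter/count grid
  for (alpha in c(0.3, 1, 2.7)) {
    for (d in c(0.4, 1.6)) {
      pp <- divergence_params(0.5, alpha, d, 1.1 * d)
      for (x in list(c(0, 0), c(1, 0), c(2, 3), c(5, 1))) {
        expect_lt(abs(pattern_likelihood(x[1], x[2], pp, "F0") -
                        quad_p0(x[1], x[2], alpha, d, 1.1 * d)), 1e-8)
        expect_lt(abs(pattern_likelihood(x[1], x[2], pp, "F1") -
                        quad_p1(x[1], x[2], alpha, d, 1.1 * d)), 1e-8)
      }
    }
  }
})

test_that("pattern likelihoods are proper distributions over count pairs", {
  grid <- expand.grid(x1 = 0:60, x2 = 0:60)
  for (state in c("F0", "F1")) {
    p <- divergence_params(0.5, 0.5, 1, 1.2)
    tot <- sum(pattern_likelihood(grid$x1, grid$x2, p, state))
    expect_gte(tot, 0.999)
    expect_lte(tot, 1 + 1e-12)
  }
})

test_that("the shared-rate likelihood degenerates to a Poisson product", {
  p_inf <- divergence_params(0.5, 1e6, 1.3, 0.8)
  for (x in list(c(0, 0), c(2, 1), c(4, 3))) {
    expect_equal(pattern_likelihood(x[1], x[2], p_inf, "F0"),
                 stats::dpois(x[1], 1.3) * stats::dpois(x[2], 0.8),
                 tolerance = 1e-4)
  }
})

test_that("divergence parameter validation rejects bad values", {
  expect_error(divergence_params(-0.1, 1, 1), "theta")
  expect_error(divergence_params(1.1, 1, 1), "theta")
  expect_error(divergence_params(0.5, 0, 1), "alpha")
  expect_error(divergence_params(0.5, 1, 0), "d1 and d2")
  p <- divergence_params(0.5, 1, 1)
  expect_error(pattern_likelihood(-1, 0, p, "F0"), "non-negative")
  expect_error(pattern_likelihood(0.5, 0, p, "F0"), "non-negative")
})

test_that("identical clusters give theta = 0 with all-zero posteriors", {
  sim <- simulate_count_pairs(400, divergence_params(0, 0.5, 1, 1), seed = 422)
  fit <- fit_type1_divergence(sim$x1, sim$x1)
  expect_lt(fit$params$theta, 1e-6)
  expect_equal(fit$delta, 0)
  expect_equal(unname(fit$posterior), rep(0, 400))
  expect_true(fit$boundary)
})

test_that("theta is recovered from simulated divergent counts", {
  sim <- simulate_count_pairs(1000, divergence_params(0.7, 0.5, 1, 1),
                              seed = 423)
  fit <- fit_type1_divergence(sim$x1, sim$x2)
  expect_gte(fit$params$theta, 0.6)
  expect_lte(fit$params$theta, 0.8)
  expect_true(fit$significant)
  expect_true(is.finite(fit$se_theta) && fit$se_theta > 0)
  expect_gte(fit$delta, 0)
  expect_equal(fit$p_boundary, fit$p_value / 2)
})

test_that("the fit is invariant to cluster order and site permutation", {
  sim <- simulate_count_pairs(500, divergence_params(0.5, 0.6, 1.2, 0.8),
                              seed = 424)
  fit_ab <- fit_type1_divergence(sim$x1, sim$x2)
  fit_ba <- fit_type1_divergence(sim$x2, sim$x1)
  expect_equal(fit_ab$delta, fit_ba$delta, tolerance = 1e-4)
  expect_equal(fit_ab$params$theta, fit_ba$params$theta, tolerance = 1e-3)
  expect_equal(fit_ab$params$d1, fit_ba$params$d2, tolerance = 1e-3)

  perm <- sample(500)
  fit_perm <- fit_type1_divergence(sim$x1[perm], sim$x2[perm])
  expect_equal(fit_perm$params$theta, fit_ab$params$theta)
  expect_equal(fit_perm$delta, fit_ab$delta)
})

test_that("site posterior profiles satisfy their algebraic identities", {
  sim <- simulate_count_pairs(600, divergence_params(0.6, 0.5, 1, 1),
                              seed = 425)
  fit <- fit_type1_divergence(sim$x1, sim$x2)
  prof <- site_posterior_profile(fit, cutoff_posterior = 0.7)
  expect_true(all(prof$posterior >= 0 & prof$posterior <= 1))
  expect_equal(prof$ratio, prof$posterior / (1 - prof$posterior),
               tolerance = 1e-12)
  # posterior cutoff 0.7 corresponds to odds 7/3 (about 2.33)
  expect_equal(attr(prof, "cutoff_ratio"), 7 / 3)
  expect_equal(prof$above_cutoff, prof$posterior > 0.7)
  # baseline posterior is the posterior of the modal count pattern
  key <- paste(prof$x1, prof$x2)
  modal <- names(which.max(table(key)))
  expect_equal(fit$baseline_posterior,
               prof$posterior[match(modal, key)])
})

test_that("pairwise comparisons cover every cluster pair", {
  counts <- list(
    c1 = simulate_count_pairs(300, divergence_params(0, 0.5, 1, 1), seed = 426)$x1,
    c2 = simulate_count_pairs(300, divergence_params(0, 0.5, 1, 1), seed = 427)$x1,
    c3 = simulate_count_pairs(300, divergence_params(0, 0.5, 1, 1), seed = 428)$x1)
  tab <- pairwise_divergence(counts)
  expect_equal(nrow(tab), 3L)
  expect_setequal(paste(tab$cluster_a, tab$cluster_b),
                  c("c1 c2", "c1 c3", "c2 c3"))
  expect_true(all(tab$theta >= 0 & tab$theta <= 1))
  expect_equal(length(attr(tab, "fits")), 3L)
})
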