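test_that("the four profile distances match their definitions", {
  X <- rbind(a = c(0, 1, 0), b = c(1, 0, 0))
  expect_equal(as.vector(profile_distance(X, "cityblock")), 2)
  expect_equal(as.vector(profile_distance(X, "euclidean")), sqrt(2))

  # identical profiles: distance 0 under every metric
  Y <- rbind(p = c(0.2, 0.7, 0.4), q = c(0.2, 0.7, 0.4))
  for (m in c("cityblock", "correlation", "cosine", "euclidean")) {
    expect_equal(as.vector(profile_distance(Y, m)), 0, tolerance = 1e-12)
  }

  # exactly anti-linear profiles: Pearson -1, correlation distance 2
  Z <- rbind(p = c(1, 2, 3), q = c(3, 2, 1))
  expect_equal(as.vector(profile_distance(Z, "correlation")), 2)

  # cosine on orthogonal profiles is 1
  expect_equal(as.vector(profile_distance(X, "cosine")), 1)
})

test_that("profile distances are symmetric, non-negative and zero-diagonal", {
  set.seed(402)
  X <- matrix(runif(8 * 15), 8, 15)
  for (m in c("cityblock", "correlation", "cosine", "euclidean")) {
    D <- as.matrix(profile_distance(X, m))
    expect_equal(D, t(D))
    expect_true(all(D >= 0))
    expect_equal(unname(diag(D)), rep(0, 8))
  }
})

test_that("degenerate profiles get distance 1 with a warning, not an error", {
  X <- rbind(flat = c(0.5, 0.5, 0.5), v = c(0.1, 0.9, 0.4))
  expect_warning(d <- profile_distance(X, "correlation"), "zero-variance")
  expect_equal(as.vector(d), 1)
  X0 <- rbind(zero = c(0, 0, 0), v = c(0.1, 0.9, 0.4))
  expect_warning(d0 <- profile_distance(X0, "cosine"), "zero-norm")
  expect_equal(as.vector(d0), 1)
})

test_that("average linkage reproduces the hand-worked agglomeration", {
  D <- matrix(c(0, 1, 4, 1, 0, 2, 4, 2, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- linkage_average(as.dist(D))
  # merge (A,B) at 1, then ({A,B},C) at mean(4,2) = 3
  expect_equal(hc$height, c(1, 3))
  coph <- as.matrix(stats::cophenetic(hc))
  expect_equal(coph["A", "B"], 1)
  expect_equal(coph["A", "C"], 3)
  expect_equal(coph["B", "C"], 3)

  # all pairwise distances equal: every merge at that height
  De <- matrix(2, 4, 4); diag(De) <- 0
  expect_equal(linkage_average(as.dist(De))$height, rep(2, 3))

  expect_error(linkage_average(stats::dist(matrix(1, 1, 1))), "at least 2")
})

test_that("average linkage heights are monotone and label-order invariant", {
  set.seed(403)
  X <- matrix(runif(10 * 6), 10, 6, dimnames = list(letters[1:10], NULL))
  hc <- linkage_average(profile_distance(X, "euclidean"))
  expect_true(all(diff(hc$height) >= -1e-12))
  # permuting the input rows permutes labels but not the height multiset
  perm <- sample(10)
  hc2 <- linkage_average(profile_distance(X[perm, ], "euclidean"))
  expect_equal(sort(hc$height), sort(hc2$height))
  # the cophenetic matrix is ultrametric: d(i,k) <= max(d(i,j), d(j,k))
  C <- as.matrix(stats::cophenetic(hc))
  for (i in 1:8) for (j in (i + 1):9) for (k in (j + 1):10) {
    expect_lte(C[i, k], max(C[i, j], C[j, k]) + 1e-12)
  }
})

test_that("cophenetic correlation equals a direct Pearson computation", {
  D <- matrix(c(0, 1, 4, 1, 0, 2, 4, 2, 0), 3, 3)
  hc <- linkage_average(as.dist(D))
  # direct Pearson on the two 3-vectors of pair distances
  expect_equal(cophenetic_correlation(hc, as.dist(D)),
               stats::cor(c(1, 4, 2), c(1, 3, 3)))
  expect_equal(cophenetic_correlation(hc, as.dist(D)), 0.7559289,
               tolerance = 1e-6)

  # ultrametric input: tree reproduces the distances exactly, r = 1
  U <- matrix(c(0, 1, 3, 3, 1, 0, 3, 3, 3, 3, 0, 2, 3, 3, 2, 0), 4, 4)
  hcu <- linkage_average(as.dist(U))
  expect_equal(cophenetic_correlation(hcu, as.dist(U)), 1)

  # oracle equivalence on random instances
  set.seed(404)
  for (rep in 1:10) {
    X <- matrix(runif(7 * 5), 7, 5)
    d <- profile_distance(X, sample(c("cityblock", "euclidean"), 1))
    hc <- linkage_average(d)
    expect_equal(cophenetic_correlation(hc, d),
                 stats::cor(as.vector(d), as.vector(stats::cophenetic(hc))))
  }

  # fewer than two distinct pairs: undefined, flagged
  D2 <- matrix(c(0, 1, 1, 0), 2, 2)
  hc2 <- linkage_average(as.dist(D2))
  expect_warning(r <- cophenetic_correlation(hc2, as.dist(D2)), "undefined")
  expect_true(is.na(r))
})

test_that("inconsistency coefficients follow the depth-2 definition", {
  # chain dendrogram with link heights 1 then 3: comparison set {3, 1},
  # mean 2, sample sd sqrt(2)  =>  Y = 1/sqrt(2), the 0.707 baseline
  D <- matrix(c(0, 1, 3, 3, 1, 0, 3, 3, 3, 3, 0, 3, 3, 3, 3, 0), 4, 4)
  hc <- linkage_average(as.dist(D))
  Y <- inconsistency_coefficients(hc, depth = 2)
  expect_equal(Y[2], 1 / sqrt(2))
  # leaf-only link: comparison set of one height => 0
  expect_equal(Y[1], 0)
  # set with equal heights (3, 3): zero sd => 0
  expect_equal(Y[3], 0)
})

test_that("two-height comparison sets never exceed the 0.707 baseline", {
  # property: for any chain link, Y is exactly 0 or 1/sqrt(2), so the
  # supremum over two-element comparison sets is the 0.707 baseline
  set.seed(405)
  for (rep in 1:10) {
    X <- matrix(runif(9 * 4), 9, 4)
    hc <- linkage_average(profile_distance(X, "euclidean"))
    Y <- inconsistency_coefficients(hc, depth = 2)
    chain <- vapply(seq_len(nrow(hc$merge)), function(k)
      sum(hc$merge[k, ] > 0) == 1L, logical(1L))
    expect_true(all(abs(Y[chain]) < 1 / sqrt(2) + 1e-12))
    expect_true(all(Y >= 0 | abs(Y) < 1e-12))
  }
})

test_that("inconsistency and cutting match the frozen independent oracle", {
  # expected values computed with an independent reference implementation of
  # the same MATLAB-convention statistic on this exact instance
  set.seed(7)
  X <- matrix(runif(12 * 6), 12, 6)
  hc <- linkage_average(profile_distance(X, "euclidean"))
  expect_equal(inconsistency_coefficients(hc, 2),
               c(0, 0, 0, 1.119838, 0.7071068, 0, 0.7071068, 1.102618,
                 0.7071068, 0.915644, 0.7071068),
               tolerance = 1e-6)
  expect_equal(inconsistency_coefficients(hc, 3),
               c(0, 0, 0, 1.119838, 0.7071068, 0, 1.422752, 1.226495,
                 0.8858745, 1.285275, 1.194543),
               tolerance = 1e-6)
  got <- cut_by_inconsistency(hc, cutoff = 0.9, depth = 2)
  oracle <- c(7, 2, 3, 2, 3, 1, 4, 1, 5, 1, 6, 4)  # reference labeling
  # same partition up to label permutation (identical co-membership)
  expect_equal(outer(got, got, "=="), outer(oracle, oracle, "=="),
               ignore_attr = TRUE)
})

test_that("the inconsistency cut isolates well-separated tight groups", {
  sim <- simulate_profile_groups(c(3, 3, 3), 60, separation = 0.6,
                                 spread = 0.05, seed = 406)
  truth <- as.integer(sim$labels)
  for (m in c("cityblock", "correlation", "cosine", "euclidean")) {
    hc <- linkage_average(profile_distance(sim$profiles, m))
    cl <- cut_by_inconsistency(hc, cutoff = 0.8, depth = 2)
    # exact recovery of the generating partition
    expect_equal(unname(cl), truth, label = m)
  }
  # a consistent link (Y = 0.7071 < 0.8) is never split
  D <- matrix(c(0, 1, 3, 3, 1, 0, 3, 3, 3, 3, 0, 3, 3, 3, 3, 0), 4, 4)
  hc <- linkage_average(as.dist(D))
  expect_equal(max(cut_by_inconsistency(hc, cutoff = 0.8, depth = 2)), 1L)
})

test_that("cluster_profiles reports all four metrics coherently", {
  sim <- simulate_profile_groups(c(3, 3), 40, separation = 0.5,
                                 spread = 0.04, seed = 407)
  res <- cluster_profiles(sim$profiles)
  expect_named(res, c("cityblock", "correlation", "cosine", "euclidean"))
  for (m in names(res)) {
    expect_s3_class(res[[m]]$hclust, "hclust")
    expect_true(res[[m]]$cophenetic_correlation >= -1 &&
                  res[[m]]$cophenetic_correlation <= 1)
    expect_equal(length(res[[m]]$inconsistency), nrow(sim$profiles) - 1L)
  }
})
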