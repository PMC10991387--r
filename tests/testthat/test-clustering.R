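test_that("affinity kernel geometry behaves as expected", {
  set.seed(1)
  pts <- rbind(matrix(rnorm(30 * 2), 30, 2),
               matrix(rnorm(30 * 2, mean = 20), 30, 2))
  a <- affinity_matrix(pts, mu = 0.3, k_neighbours = 10)
  expect_true(isSymmetric(unname(a)))
  expect_true(all(a >= 0))
  within <- a[1:30, 1:30][upper.tri(matrix(0, 30, 30))]
  between <- a[1:30, 31:60]
  expect_lt(max(between), 1e-6 * median(within))
  # near-identical points have maximal affinity in their row
  pts2 <- rbind(pts[1, ] + 1e-9, pts)
  a2 <- affinity_matrix(pts2, 0.3, 10)
  expect_equal(unname(which.max(a2[1, -1])), 1L)
  expect_equal(attr(a, "mu"), 0.3)
  expect_error(affinity_matrix(pts[1:5, ], k_neighbours = 10), "neighbours")
})

test_that("the unnormalized Laplacian is PSD with a zero eigenvalue", {
  set.seed(2)
  a <- affinity_matrix(matrix(rnorm(80), 40, 2), 0.3, 10)
  lap <- diag(rowSums(a)) - a
  ev <- eigen(lap, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  expect_lt(abs(min(ev)), 1e-8)
})

test_that("spectral clustering recovers block and blob structure", {
  # block-diagonal affinity: zero eigenvalues count the components
  a <- matrix(0, 18, 18)
  a[1:5, 1:5] <- 1; a[6:12, 6:12] <- 1; a[13:18, 13:18] <- 1
  lap <- diag(rowSums(a)) - a
  ev <- eigen(lap, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-8), 3L)
  cl <- suppressWarnings(spectral_cluster(a, 3, seed = 1))
  truth <- rep(1:3, c(5, 7, 6))
  expect_equal(unname(rand_indices(cl, truth)["adjusted_rand"]), 1)

  set.seed(3)
  blobs <- planted_cluster_loadings(n_per = 50, k = 2, separation = 10)
  cl2 <- spectral_cluster(affinity_matrix(blobs$points, 0.3, 10), 2,
                          seed = 2)
  expect_equal(unname(rand_indices(cl2, blobs$labels)["adjusted_rand"]), 1)

  # permutation equivariance
  set.seed(4)
  perm <- sample(100)
  cl3 <- spectral_cluster(affinity_matrix(blobs$points[perm, ], 0.3, 10), 2,
                          seed = 2)
  expect_equal(unname(rand_indices(cl3, blobs$labels[perm])["adjusted_rand"]),
               1)
})

test_that("Calinski-Harabasz matches direct evaluation and ranks structure", {
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1), c(10, 10), c(11, 10), c(10, 11))
  lab <- c(1, 1, 1, 2, 2, 2)
  grand <- colMeans(pts)
  c1 <- colMeans(pts[1:3, ]); c2 <- colMeans(pts[4:6, ])
  w <- sum(sweep(pts[1:3, ], 2, c1)^2) + sum(sweep(pts[4:6, ], 2, c2)^2)
  b <- 3 * sum((c1 - grand)^2) + 3 * sum((c2 - grand)^2)
  expect_equal(calinski_harabasz(pts, lab), (b / 1) / (w / 4))

  set.seed(5)
  bad <- sample(lab)
  while (identical(bad, lab) || length(unique(bad)) < 2) bad <- sample(lab)
  expect_gt(calinski_harabasz(pts, lab), calinski_harabasz(pts, bad))

  degenerate <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  expect_identical(calinski_harabasz(degenerate, c(1, 1, 2, 2)), Inf)
  expect_error(calinski_harabasz(pts, rep(1, 6)), "2 clusters")
})

test_that("Rand indices follow the pair-counting definitions", {
  expect_equal(unname(rand_indices(c(1, 2, 3), c(3, 1, 2))), c(1, 1))
  expect_equal(unname(rand_indices(c(1, 1, 2, 2), c(1, 2, 2, 2))["rand"]),
               0.5)
  set.seed(6)
  a <- sample(3, 1000, replace = TRUE)
  b <- sample(3, 1000, replace = TRUE)
  expect_lt(abs(rand_indices(a, b)["adjusted_rand"]), 0.02)
  expect_error(rand_indices(1:3, 1:4), "length")
})

test_that("cluster stability separates structure from noise", {
  set.seed(7)
  blobs <- planted_cluster_loadings(n_per = 40, k = 3, separation = 8)
  st <- cluster_stability(blobs$points, 3, n_resamples = 30,
                          subsample_frac = 0.8, seed = 8, n_restarts = 20)
  expect_equal(median(st$adjusted_rand), 1)

  cloud <- matrix(rnorm(240), 120, 2)
  st0 <- cluster_stability(cloud, 3, n_resamples = 30, seed = 9,
                           n_restarts = 20)
  expect_lt(median(st0$adjusted_rand), 0.5)
  expect_lt(median(st0$adjusted_rand), median(st$adjusted_rand))
})

test_that("diagnostic enrichment chi-squared matches the direct formula", {
  asg <- rep(1, 40)
  diag4 <- factor(rep(c("TD", "ASD", "ADHD", "OCD"), each = 10))
  out <- cluster_enrichment(asg, diag4)
  expect_equal(out$statistic, 0)
  expect_equal(out$df, 3L)

  # 20/10/5/5 against a uniform cohort: X^2 = 15, df = 3
  asg2 <- c(rep(1, 40), rep(2, 40))
  dg <- factor(c(rep(c("TD", "ASD", "ADHD", "OCD"), c(20, 10, 5, 5)),
                 rep(c("TD", "ASD", "ADHD", "OCD"), c(0, 10, 15, 15))))
  out2 <- cluster_enrichment(asg2, dg)
  expect_equal(out2$statistic[1], 15)
  expect_equal(out2$df[1], 3L)
  expect_equal(out2$p[1], pchisq(15, 3, lower.tail = FALSE))
})

test_that("covariate ANOVA reduces to known identities", {
  vals <- c(1, 2, 3, 1, 2, 3)
  expect_equal(unname(cluster_covariate_anova(vals,
                                              c(1, 1, 1, 2, 2, 2))["F"]), 0)
  set.seed(10)
  v <- rnorm(40)
  g <- rep(1:2, each = 20)
  a <- cluster_covariate_anova(v, g)
  t2 <- t.test(v ~ g, var.equal = TRUE)$statistic^2
  expect_equal(unname(a["F"]), unname(t2), tolerance = 1e-10)
  expect_equal(unname(a[c("df1", "df2")]), c(1, 38))

  # power at a 1 SD shift, n = 50 per group
  hits <- 0L
  for (r in 1:30) {
    set.seed(100 + r)
    v2 <- c(rnorm(50), rnorm(50, mean = 1))
    hits <- hits + (cluster_covariate_anova(v2, rep(1:2, each = 50))["p"] <
                      0.01)
  }
  expect_gt(hits / 30, 0.9)
})

test_that("CH-based selection finds a planted cluster count", {
  set.seed(11)
  blobs <- planted_cluster_loadings(n_per = 40, k = 3, separation = 6)
  sel <- choose_cluster_count(blobs$points, 2:6, seed = 12, n_restarts = 20)
  expect_equal(sel$chosen_k, 3L)
  expect_equal(dim(sel$assignments), c(120L, 5L))
})
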