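test_that("standardization centres and scales with the n-1 denominator", {
  expect_equal(unname(standardize_block(cbind(c(1, 2, 3)))[, 1]),
               c(-1, 0, 1))
  set.seed(1)
  x <- matrix(rnorm(50 * 4, mean = 3, sd = 2), 50, 4)
  s <- standardize_block(x)
  expect_equal(colMeans(s), rep(0, 4), ignore_attr = TRUE)
  expect_equal(apply(s, 2, sd), rep(1, 4), ignore_attr = TRUE)
  expect_equal(unclass(standardize_block(s)), unclass(s),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(standardize_block(cbind(rep(2, 5))), "constant")
})

test_that("Spearman screen keeps monotone features and behaves at the null", {
  set.seed(2)
  n <- 500
  scores <- matrix(rnorm(n * 3), n, 3)
  fc <- matrix(rnorm(n * 400), n, 400)
  fc[, 1] <- exp(scores[, 2])  # perfectly monotone with score 2
  sel <- select_features(fc, scores, 0.05)
  expect_true(sel$keep[1])
  expect_equal(sel$p[1, 2], 0)
  # union rule over 3 independent scores: 1 - 0.95^3 of null features kept
  null_frac <- mean(sel$keep[-1])
  expect_gt(null_frac, 1 - 0.95^3 - 0.05)
  expect_lt(null_frac, 1 - 0.95^3 + 0.05)
  # stricter threshold masks are nested
  sel01 <- select_features(fc, scores, 0.01)
  expect_true(all(sel$keep[sel01$keep]))
  expect_lt(sum(sel01$keep), sum(sel$keep))
  fc[, 2] <- 1
  expect_warning(select_features(fc, scores, 0.05), "constant")
})

test_that("CCA matches oracles and its variates satisfy the definition", {
  set.seed(3)
  # 1-D case reduces to |Pearson r|
  x1 <- matrix(rnorm(40), 40, 1); y1 <- 0.5 * x1 + rnorm(40)
  expect_equal(fit_cca(x1, y1)$cor, abs(cor(x1, y1)[1]), tolerance = 1e-10)

  for (i in 1:5) {
    x <- matrix(rnorm(50 * 5), 50, 5)
    y <- matrix(rnorm(50 * 3), 50, 3)
    fit <- fit_cca(x, y)
    expect_equal(fit$cor, cca_oracle(scale(x), scale(y)), tolerance = 1e-8)
    expect_equal(fit$cor, cancor(scale(x), scale(y))$cor, tolerance = 1e-8)
    # variates: unit variance, in-block orthogonality, paired correlation
    expect_equal(apply(fit$x_variates, 2, var), rep(1, 3),
                 ignore_attr = TRUE)
    cc <- cor(fit$x_variates)
    expect_equal(cc, diag(3), tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(diag(cor(fit$x_variates, fit$y_variates)), fit$cor,
                 tolerance = 1e-8)
    # sign convention: dominant behaviour coefficient positive
    for (k in 1:3)
      expect_gt(fit$y_coeffs[which.max(abs(fit$y_coeffs[, k])), k], 0)
  }
})

test_that("canonical correlations are invariant to affine recoding of scores", {
  set.seed(4)
  x <- matrix(rnorm(60 * 4), 60, 4)
  y <- matrix(rnorm(60 * 3), 60, 3)
  base <- fit_cca(x, y)$cor
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  expect_equal(fit_cca(x, y %*% q)$cor, base, tolerance = 1e-8)
  aff <- y %*% matrix(c(2, 0.5, 0, 0, 1, -1, 0.3, 0, 2), 3, 3)
  aff <- sweep(aff, 2, c(10, -2, 5), `+`)
  expect_equal(fit_cca(x, aff)$cor, base, tolerance = 1e-8)
})

test_that("rank-deficient and p >= n blocks error unless ridge is enabled", {
  set.seed(5)
  x <- matrix(rnorm(20 * 30), 20, 30)
  y <- matrix(rnorm(20 * 3), 20, 3)
  expect_error(fit_cca(x, y), "ridge|few subjects")
  fit <- fit_cca(x, y, ridge = 0.5)
  expect_true(all(fit$cor <= 1 & fit$cor >= 0))
  xdup <- cbind(x[, 1], x[, 1], x[, 2:3])
  expect_error(fit_cca(xdup[1:15, ], y[1:15, ]), "rank|ridge|few")
})

test_that("permutation p-values hit the resolution floor on strong signal", {
  set.seed(6)
  n <- 200
  u <- rnorm(n)
  x <- matrix(rnorm(n * 10, sd = 0.4), n, 10) + u %o% rep(0.3, 10)
  y <- matrix(rnorm(n * 3, sd = 0.6), n, 3) + u %o% c(0.8, 0.1, 0.1)
  pt <- permutation_test(x, y, n_perm = 199, seed = 7)
  expect_equal(pt$p[1], 1 / 200)
  expect_s3_class(pt, "permutation_result")
  # sequential Wilks statistic: observed values consistent with correlations
  expect_equal(pt$observed[3], 1 - pt$cor[3]^2, tolerance = 1e-10)
  expect_equal(pt$observed[1], prod(1 - pt$cor^2), tolerance = 1e-10)
  # determinism
  pt2 <- permutation_test(x, y, n_perm = 199, seed = 7)
  expect_identical(pt$p, pt2$p)
  expect_identical(pt$null_draws, pt2$null_draws)
  expect_warning(permutation_test(x, y, n_perm = 50, seed = 1), "coarse")
})

test_that("Procrustes recovers planted rotations exactly", {
  set.seed(8)
  ref <- matrix(rnorm(20 * 3), 20, 3)
  expect_equal(procrustes_align(ref, ref)$rotation, diag(3),
               tolerance = 1e-12)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  out <- procrustes_align(ref %*% q, ref)
  expect_lt(norm(out$rotated - ref, "F"), 1e-10)
  flip <- diag(c(1, -1, -1))
  out2 <- procrustes_align(ref %*% flip, ref)
  expect_equal(out2$rotation, flip, tolerance = 1e-10)
  expect_error(procrustes_align(ref * 0, ref), "degenerate")
})

test_that("bootstrap stability flags a strong planted loading and is reproducible", {
  scheme <- compact_scheme()
  cmp <- default_component(3, 28, rho = 0.8, n_support = 1)
  sp <- cohort_spec(n_subjects = 300, scheme = scheme,
                    components = list(cmp), noise_sd_features = 0.3)
  ch <- generate_cohort(sp, seed = 41)
  cfg <- pipeline_config()
  prep <- ccanet:::prepare_cohort(ch$fc, ch$phenotype, cfg, score_cols3)
  fit <- fit_cca(prep$x, prep$scores)
  st <- bootstrap_stability(prep$x, prep$scores, fit, n_boot = 300, seed = 42)
  support <- which(ch$truth$a[, 1] != 0)
  expect_true(all(st$stable_x[support, 1]))
  expect_lt(mean(st$stable_x[-support, 1]), 0.25)
  expect_identical(st$stable_x,
                   abs(st$z_x) > 1.96)
  st2 <- bootstrap_stability(prep$x, prep$scores, fit, n_boot = 300,
                             seed = 42)
  expect_identical(st$z_x, st2$z_x)
})

test_that("the planted component is recovered multivariately at n = 400", {
  scheme <- restrict_parcellation(default_parcellation(), "cerebellum")
  sp <- cohort_spec(n_subjects = 400, scheme = scheme)
  cfg <- pipeline_config()
  for (sd in c(51, 52)) {
    ch <- generate_cohort(sp, seed = sd)
    prep <- ccanet:::prepare_cohort(ch$fc, ch$phenotype, cfg, score_cols3)
    sel <- select_features(prep$x, prep$scores, cfg$p_thresh)
    fit <- fit_cca(prep$x[, sel$keep], prep$scores)
    # fitted strength expresses the planted rho
    expect_gt(fit$cor[1], 0.7)
    expect_lt(fit$cor[1], 0.9)
    # behaviour weights recovered as a direction
    w <- ch$truth$w[, 1]
    cos_w <- abs(sum(fit$y_coeffs[, 1] * w)) /
      sqrt(sum(fit$y_coeffs[, 1]^2))
    expect_gt(cos_w, 0.9)
    # the x-variate recovers the latent even though single coefficients
    # are noisy at this p/n
    expect_gt(abs(cor(fit$x_variates[, 1], ch$truth$u[, 1])), 0.9)
  }
})
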