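test_that("default parcellation has the expected structure", {
  s <- default_parcellation()
  expect_equal(count_rois(s), 48L)
  expect_equal(length(roi_pair_ids(s)), 48L * 47L / 2L)
  expect_equal(sum(s$structure == "cerebrum"), 34L)
  cb <- restrict_parcellation(s, "cerebellum")
  expect_equal(count_rois(cb), 14L)
  expect_equal(length(unique(cb$macro_network)), 7L)
  expect_equal(length(unique(s$macro_network)), 14L)
  expect_false(anyDuplicated(s$roi_name) > 0L)
})

test_that("parcellation TSV round-trips and validation catches defects", {
  s <- default_parcellation()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_parcellation(s, path)
  expect_equal(read_parcellation(path), s, ignore_attr = TRUE)
  bad <- s
  bad$label_id[2] <- 5L
  expect_error(validate_parcellation(bad), "contiguous")
  expect_error(validate_parcellation(s[, -3]), "missing columns")
})

test_that("feature vectorization follows upper-triangle order and round-trips", {
  s3 <- toy_scheme(3)
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.1
  m[1, 3] <- m[3, 1] <- 0.2
  m[2, 3] <- m[3, 2] <- 0.3
  v <- vectorize_features(m, s3)
  expect_equal(unname(v), c(0.1, 0.2, 0.3))
  expect_equal(names(v), paste0(s3$roi_name[c(1, 1, 2)], "__",
                                s3$roi_name[c(2, 3, 3)]))

  s6 <- toy_scheme(6)
  set.seed(1)
  r <- matrix(rnorm(36), 6, 6)
  r <- r + t(r); diag(r) <- 0
  expect_equal(unname(devectorize_features(vectorize_features(r, s6), s6)),
               unname(r))
  expect_error(vectorize_features(matrix(0, 4, 4), s6), "scheme has")
})

test_that("QC censors on FD or DVARS exceedance and applies the 1/3 rule", {
  ts <- roi_timeseries("s1", matrix(rnorm(300), 100, 3))
  clean <- apply_qc(ts, list(fd = rep(0, 100), dvars = rep(0, 100)))
  expect_true(clean$qc_pass)
  expect_equal(clean$n_censored, 0L)

  fd <- rep(0, 100); fd[1:40] <- 0.6
  bad <- apply_qc(ts, list(fd = fd, dvars = rep(0, 100)))
  expect_equal(bad$n_censored, 40L)
  expect_false(bad$qc_pass)
  expect_equal(sum(bad$censor_mask), 60L)

  # censoring is a union: order of the FD / DVARS checks cannot matter
  dvars <- rep(0, 100); dvars[30:50] <- 0.7
  both <- apply_qc(ts, list(fd = fd, dvars = dvars))
  expect_equal(both$n_censored, sum(fd > 0.5 | dvars > 0.5))

  expect_error(apply_qc(ts, list(fd = rep(0, 50), dvars = rep(0, 50))),
               "length")
})

test_that("Pearson matrix is computed over retained frames only", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 4, 3))
  ts <- roi_timeseries("s1", x)
  expect_equal(pearson_matrix(ts)["a", "b"], 0.8)

  dup <- roi_timeseries("s2", cbind(a = rnorm(10), b = 0))
  dup$values[, 2] <- dup$values[, 1]
  expect_equal(pearson_matrix(dup)[1, 2], 1)
  neg <- roi_timeseries("s3", cbind(a = 1:10, b = -(1:10)))
  expect_equal(pearson_matrix(neg)[1, 2], -1)

  # a censored outlier must not contaminate the correlation
  y <- cbind(a = c(1, 2, 3, 4, 100), b = c(1, 2, 4, 3, -50))
  cen <- roi_timeseries("s4", y, censor_mask = c(rep(TRUE, 4), FALSE))
  expect_equal(pearson_matrix(cen)["a", "b"], 0.8)

  flat <- roi_timeseries("s5", cbind(a = rnorm(10), b = rep(2, 10)))
  expect_error(pearson_matrix(flat), "b")
})

test_that("partial correlation matches Eq-style inversion oracles", {
  expect_equal(partial_from_pearson(diag(3)), diag(3), ignore_attr = TRUE)

  sig <- matrix(0.5, 3, 3); diag(sig) <- 1
  p <- partial_from_pearson(sig)
  expect_equal(p[row(p) != col(p)], rep(0.5 / (1 + 0.5), 6))

  # residual-regression definition on random 3-6 variable matrices
  set.seed(11)
  for (d in 3:6) {
    x <- matrix(rnorm(200 * d), 200, d)
    pm <- partial_from_pearson(cor(x))
    for (i in 1:(d - 1)) for (j in (i + 1):d)
      expect_equal(pm[i, j], partial_cor_residual(x, i, j), tolerance = 1e-10)
  }

  sing <- matrix(1, 3, 3)
  expect_error(partial_from_pearson(sing), "ridge")
  expect_silent(partial_from_pearson(sing, ridge = 0.1))
})

test_that("partial correlations recover a sparse precision zero pattern", {
  set.seed(21)
  d <- 6
  prec <- diag(d)
  prec[1, 2] <- prec[2, 1] <- -0.4
  prec[3, 4] <- prec[4, 3] <- -0.3
  x <- matrix(rnorm(5000 * d), 5000, d) %*% chol(solve(prec))
  pm <- partial_from_pearson(cor(x))
  zero_pairs <- rbind(c(1, 3), c(1, 4), c(1, 5), c(2, 5), c(3, 6), c(5, 6))
  for (k in seq_len(nrow(zero_pairs)))
    expect_lt(abs(pm[zero_pairs[k, 1], zero_pairs[k, 2]]), 0.05)
  expect_gt(pm[1, 2], 0.3)  # planted edge carries the sign of -prec
})

test_that("Fisher transform is exact, odd and monotone with zero diagonal", {
  m <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  z <- fisher_transform(m)
  expect_equal(z[1, 2], 0.5 * log(3))
  expect_equal(z[1, 2], 0.5493, tolerance = 1e-4)
  expect_equal(diag(z), c(0, 0))

  m2 <- matrix(c(1, -0.9, -0.9, 1), 2, 2)
  expect_equal(fisher_transform(m2)[1, 2], -1.4722, tolerance = 1e-4)

  r <- seq(-0.95, 0.95, by = 0.05)
  zz <- atanh(r)
  expect_true(all(diff(zz) > 0))
  expect_equal(atanh(-r), -zz)

  expect_error(fisher_transform(matrix(c(1, 1, 1, 1), 2, 2)), "infinite")
})

test_that("fc_feature_table runs the full per-scan chain", {
  s <- toy_scheme(5)
  set.seed(3)
  ts_list <- lapply(1:4, function(i) {
    x <- matrix(rnorm(60 * 5), 60, 5)
    colnames(x) <- s$roi_name
    roi_timeseries(paste0("sub", i), x)
  })
  fc <- fc_feature_table(ts_list, s)
  expect_equal(dim(fc), c(4L, 10L))
  expect_equal(rownames(fc), paste0("sub", 1:4))
  # row 1 equals the hand-chained computation
  expected <- vectorize_features(
    fisher_transform(partial_from_pearson(pearson_matrix(ts_list[[1]]))), s)
  expect_equal(fc[1, ], expected)
})
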