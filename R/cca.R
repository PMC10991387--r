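#' Thresholded canonical correlation analysis with resampling inference
#'
#' The brain-behaviour model: find paired linear combinations of FC features
#' (X block) and behaviour scores (Y block) that are maximally correlated.
#' Weakly behaviour-correlated FC features are removed first by a Spearman
#' screen; variate significance is assessed by permutation (sequential Wilks'
#' lambda); coefficient stability by bootstrap resampling with orthogonal
#' Procrustes alignment of each redraw to the original solution, summarised
#' as z = coefficient / bootstrap SD with |z| > 1.96 flagging stability.
#'
#' @name cca_inference
NULL

#' Column-standardize a data block
#'
#' Centres each column to mean 0 and scales to SD 1 (denominator n - 1).
#'
#' @param values Subjects x columns numeric matrix.
#' @return Matrix with attributes `center` and `scale`.
#' @export
standardize_block <- function(values) {
  values <- as.matrix(values)
  ctr <- colMeans(values)
  scl <- apply(values, 2L, stats::sd)
  if (any(scl == 0)) {
    bad <- which(scl == 0)
    nm <- if (!is.null(colnames(values))) colnames(values)[bad] else bad
    stop("constant column cannot be standardized: ", paste(nm, collapse = ", "))
  }
  out <- sweep(sweep(values, 2L, ctr), 2L, scl, `/`)
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Spearman screen of FC features against behaviour scores
#'
#' For each (feature, score) pair computes Spearman's rho and its t-derived
#' two-tailed p-value (t = rho * sqrt((n-2)/(1-rho^2)), df = n - 2). A
#' feature is kept when it passes the threshold against ANY score (union
#' rule), so features relevant to each canonical variate survive.
#'
#' @param fc Subjects x features matrix.
#' @param scores Subjects x scores matrix.
#' @param p_thresh Per-test p-value threshold (0.05 default; 0.01 the
#'   stricter variant).
#' @return A `selection_mask` list: `keep` (logical per feature), `rho`, `p`
#'   (features x scores), `p_thresh`.
#' @export
select_features <- function(fc, scores, p_thresh = 0.05) {
  fc <- as.matrix(fc); scores <- as.matrix(scores)
  n <- nrow(fc)
  stopifnot(nrow(scores) == n, p_thresh > 0, p_thresh < 1)
  if (n < 10L) stop("need at least 10 subjects for the Spearman screen")
  const <- apply(fc, 2L, function(v) length(unique(v)) == 1L)
  if (any(const))
    warning(sum(const), " constant feature(s) dropped from selection")
  r_fc <- apply(fc, 2L, rank)
  r_sc <- apply(scores, 2L, rank)
  rho <- suppressWarnings(stats::cor(r_fc, r_sc))  # Pearson on ranks
  rho[const, ] <- NA_real_
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  keep <- apply(p < p_thresh, 1L, any)
  keep[const | is.na(keep)] <- FALSE
  structure(list(keep = keep, rho = rho, p = p, p_thresh = p_thresh),
            class = "selection_mask")
}

# Core CCA on already-centred/standardized blocks via QR + SVD.
# Returns coefficients scaled so each variate has unit sample variance.
.cca_core <- function(xs, ys, ridge = 0) {
  n <- nrow(xs)
  k <- min(ncol(xs), ncol(ys))
  if (ridge == 0) {
    qx <- qr(xs); qy <- qr(ys)
    if (qx$rank < ncol(xs) || qy$rank < ncol(ys))
      stop("rank-deficient block: use a stricter feature selection ",
           "threshold or a positive ridge")
    sv <- svd(crossprod(qr.Q(qx), qr.Q(qy)), nu = k, nv = k)
    a <- backsolve(qr.R(qx), sv$u[, seq_len(k), drop = FALSE]) * sqrt(n - 1)
    b <- backsolve(qr.R(qy), sv$v[, seq_len(k), drop = FALSE]) * sqrt(n - 1)
    # qr() pivots neither block (LINPACK default), so rows are in input order
    cors <- pmin(sv$d[seq_len(k)], 1)
  } else {
    sxx <- crossprod(xs) / (n - 1) + diag(ridge, ncol(xs))
    syy <- crossprod(ys) / (n - 1) + diag(ridge, ncol(ys))
    sxy <- crossprod(xs, ys) / (n - 1)
    isx <- .mat_inv_sqrt(sxx); isy <- .mat_inv_sqrt(syy)
    sv <- svd(isx %*% sxy %*% isy, nu = k, nv = k)
    a <- isx %*% sv$u[, seq_len(k), drop = FALSE]
    b <- isy %*% sv$v[, seq_len(k), drop = FALSE]
    # rescale to unit empirical variance of the variates
    a <- sweep(a, 2L, apply(xs %*% a, 2L, stats::sd), `/`)
    b <- sweep(b, 2L, apply(ys %*% b, 2L, stats::sd), `/`)
    cors <- abs(diag(stats::cor(xs %*% a, ys %*% b)))
  }
  list(a = a, b = b, cors = cors)
}

.mat_inv_sqrt <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) <= 0) stop("block covariance not positive definite")
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Fit a canonical correlation analysis
#'
#' Standardizes both blocks, solves the CCA generalized eigenproblem in its
#' numerically stable QR/SVD formulation, and orients each variate so the
#' behaviour coefficient largest in magnitude is positive. Coefficients are
#' reported on the standardized inputs; variates have unit sample variance.
#'
#' @param x Subjects x FC-features matrix (already screened).
#' @param y Subjects x behaviour-scores matrix.
#' @param ridge Nonnegative ridge added to both block covariances for the
#'   regularized fallback when subjects do not comfortably exceed columns.
#' @return A `cca_result`: `x_coeffs`, `y_coeffs`, `x_variates`,
#'   `y_variates`, `cor` (canonical correlations, descending), the
#'   standardization parameters of both blocks, and `K = ncol(y)`.
#' @export
fit_cca <- function(x, y, ridge = 0) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  stopifnot(nrow(y) == n)
  if (anyNA(x) || anyNA(y)) stop("missing values in CCA blocks")
  if (ridge == 0 && n < ncol(x) + ncol(y) + 2)
    stop("too few subjects (", n, ") for ", ncol(x), " + ", ncol(y),
         " columns; enable ridge or select fewer features")
  xs <- standardize_block(x)
  ys <- standardize_block(y)
  core <- .cca_core(xs, ys, ridge)
  k <- length(core$cors)
  # sign convention: dominant behaviour coefficient positive per variate
  flip <- vapply(seq_len(k), function(j) {
    bj <- core$b[, j]
    sign(bj[which.max(abs(bj))]) < 0
  }, logical(1L))
  core$a[, flip] <- -core$a[, flip, drop = FALSE]
  core$b[, flip] <- -core$b[, flip, drop = FALSE]
  rownames(core$a) <- colnames(x)
  rownames(core$b) <- colnames(y)
  structure(list(
    x_coeffs = core$a, y_coeffs = core$b,
    x_variates = xs %*% core$a, y_variates = ys %*% core$b,
    cor = core$cors, K = k,
    x_center = attr(xs, "center"), x_scale = attr(xs, "scale"),
    y_center = attr(ys, "center"), y_scale = attr(ys, "scale"),
    ridge = ridge
  ), class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat("CCA fit:", nrow(x$x_coeffs), "FC features x", nrow(x$y_coeffs),
      "behaviour scores,", x$K, "variates\n")
  cat("canonical correlations:",
      paste(sprintf("%.3f", x$cor), collapse = ", "), "\n")
  invisible(x)
}

#' Permutation test of canonical-variate significance
#'
#' Rows of the behaviour block are shuffled `n_perm` times and the CCA refit
#' on the FIXED selected feature set. The statistic for variate k is the
#' sequential Wilks' lambda_k = prod_{j >= k} (1 - r_j^2); the p-value counts
#' permuted lambdas at least as extreme (smaller or equal), with the +1
#' correction, so a result beyond every permutation reports 1/(n_perm + 1).
#'
#' @param x,y The blocks as passed to [fit_cca()].
#' @param n_perm Number of shuffles (default 10000).
#' @param seed RNG seed.
#' @param statistic `"wilks"` (sequential, the default) or `"maxcor"` (first
#'   canonical correlation per variate position).
#' @param ridge Passed through to the CCA core.
#' @return A `permutation_result`: `p` per variate, observed statistics,
#'   null draws (n_perm x K), `n_perm`, `seed`.
#' @export
permutation_test <- function(x, y, n_perm = 10000L, seed = 1L,
                             statistic = c("wilks", "maxcor"), ridge = 0) {
  statistic <- match.arg(statistic)
  if (n_perm < 100L) warning("n_perm < 100 gives a very coarse p-value")
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  xs <- standardize_block(x)
  ys <- standardize_block(y)
  obs <- .cca_core(xs, ys, ridge)$cors
  k <- length(obs)
  stat_of <- function(r) {
    if (statistic == "wilks") rev(cumprod(rev(1 - r^2))) else r
  }
  obs_stat <- stat_of(obs)
  null_draws <- matrix(NA_real_, n_perm, k)
  set.seed(seed)
  if (ridge == 0) {
    qx <- qr(xs)
    Qx <- qr.Q(qx)
    for (b in seq_len(n_perm)) {
      yp <- ys[sample.int(n), , drop = FALSE]
      r <- pmin(svd(crossprod(Qx, qr.Q(qr(yp))), nu = 0, nv = 0)$d[seq_len(k)], 1)
      null_draws[b, ] <- stat_of(r)
    }
  } else {
    for (b in seq_len(n_perm)) {
      yp <- ys[sample.int(n), , drop = FALSE]
      null_draws[b, ] <- stat_of(.cca_core(xs, yp, ridge)$cors)
    }
  }
  exceed <- if (statistic == "wilks") {
    colSums(null_draws <= matrix(obs_stat, n_perm, k, byrow = TRUE))
  } else {
    colSums(null_draws >= matrix(obs_stat, n_perm, k, byrow = TRUE))
  }
  p <- (1 + exceed) / (n_perm + 1)
  structure(list(p = p, observed = obs_stat, cor = obs,
                 null_draws = null_draws, statistic = statistic,
                 n_perm = n_perm, seed = seed),
            class = "permutation_result")
}

#' Orthogonal Procrustes alignment of resampled coefficients
#'
#' Finds the orthogonal matrix R minimising ||boot R - ref||_F via the SVD of
#' t(boot) ref, and applies it. In the bootstrap, the x and y coefficient
#' matrices are stacked vertically so both blocks share one rotation,
#' resolving the rotational and sign indeterminacy of CCA solutions.
#'
#' @param boot Coefficient matrix (rows = coefficients, cols = variates).
#' @param ref Reference matrix of the same shape.
#' @return List with `rotated` (boot %*% rotation) and `rotation` (K x K
#'   orthogonal).
#' @export
procrustes_align <- function(boot, ref) {
  boot <- as.matrix(boot); ref <- as.matrix(ref)
  if (!all(dim(boot) == dim(ref))) stop("boot and ref shapes differ")
  m <- crossprod(boot, ref)
  if (all(m == 0)) stop("degenerate Procrustes problem: zero cross-product")
  sv <- svd(m)
  rotation <- sv$u %*% t(sv$v)
  list(rotated = boot %*% rotation, rotation = rotation)
}

#' Bootstrap stability z-scores for canonical coefficients
#'
#' Subjects are resampled with replacement `n_boot` times; the CCA is refit
#' on the fixed feature set, each redraw's stacked coefficient matrix is
#' Procrustes-aligned to the original solution, and the per-coefficient SD
#' across aligned redraws divides the original coefficient to give z. A draw
#' yielding a rank-deficient block is redrawn (count reported).
#'
#' @param x,y The blocks as passed to [fit_cca()].
#' @param result The original [fit_cca()] result (the alignment reference).
#' @param n_boot Number of bootstrap draws (default 10000).
#' @param seed RNG seed.
#' @param z_thresh Stability threshold on |z| (default 1.96).
#' @param ridge Passed through to the CCA core.
#' @return A `stability_result`: `z_x`, `z_y`, `sd_x`, `sd_y`,
#'   `stable_x`, `stable_y` (|z| > z_thresh), `n_boot`, `n_redraws`, `seed`.
#' @export
bootstrap_stability <- function(x, y, result, n_boot = 10000L, seed = 1L,
                                z_thresh = 1.96, ridge = 0) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  px <- ncol(x); py <- ncol(y)
  k <- result$K
  ref <- rbind(result$x_coeffs, result$y_coeffs)
  draws <- array(NA_real_, c(px + py, k, n_boot))
  n_redraws <- 0L
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      fit <- tryCatch({
        xs <- standardize_block(x[idx, , drop = FALSE])
        ys <- standardize_block(y[idx, , drop = FALSE])
        .cca_core(xs, ys, ridge)
      }, error = function(e) NULL)
      if (!is.null(fit)) break
      n_redraws <- n_redraws + 1L
      if (n_redraws > 100L * n_boot) stop("bootstrap keeps drawing ",
                                          "rank-deficient resamples")
    }
    draws[, , b] <- procrustes_align(rbind(fit$a, fit$b), ref)$rotated
  }
  sds <- apply(draws, c(1L, 2L), stats::sd)
  z <- ref / sds
  zx <- z[seq_len(px), , drop = FALSE]
  zy <- z[px + seq_len(py), , drop = FALSE]
  structure(list(
    z_x = zx, z_y = zy,
    sd_x = sds[seq_len(px), , drop = FALSE],
    sd_y = sds[px + seq_len(py), , drop = FALSE],
    stable_x = abs(zx) > z_thresh, stable_y = abs(zy) > z_thresh,
    z_thresh = z_thresh, n_boot = n_boot, n_redraws = n_redraws, seed = seed
  ), class = "stability_result")
}
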