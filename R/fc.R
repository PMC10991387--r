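#' Functional-connectivity feature construction
#'
#' Converts per-subject ROI time series into Fisher-z partial-correlation
#' feature vectors: motion-based volume censoring, Pearson correlation over
#' retained frames, inversion to partial correlations via the precision
#' matrix, Fisher transformation, and vectorization of the upper triangle in
#' parcellation order.
#'
#' @name fc
NULL

#' ROI time-series container
#'
#' @param subject_id Subject identifier.
#' @param values Numeric matrix, timepoints x ROIs.
#' @param censor_mask Logical vector per timepoint; `TRUE` = retained.
#'   Defaults to all retained.
#' @return A `roi_timeseries` list.
#' @export
roi_timeseries <- function(subject_id, values,
                           censor_mask = rep(TRUE, nrow(values))) {
  values <- as.matrix(values)
  if (nrow(values) == 0L) stop("empty time series for subject ", subject_id)
  if (length(censor_mask) != nrow(values))
    stop("censor_mask length (", length(censor_mask),
         ") does not match timepoints (", nrow(values), ")")
  if (sum(censor_mask) >= 2L && anyNA(values[censor_mask, , drop = FALSE]))
    stop("missing values among retained timepoints for subject ", subject_id)
  structure(list(subject_id = subject_id, values = values,
                 censor_mask = as.logical(censor_mask)),
            class = "roi_timeseries")
}

#' Motion-based volume censoring and scan-level QC
#'
#' A timepoint is censored when framewise displacement exceeds `fd_thresh`
#' (mm) or DVARS exceeds `dvars_thresh` (percent). The scan fails QC when the
#' censored fraction exceeds `max_censored_frac` (one third by default).
#'
#' @param ts A [roi_timeseries()].
#' @param motion List or data frame with numeric `fd` and `dvars` vectors,
#'   one value per timepoint.
#' @param fd_thresh Framewise-displacement threshold in mm (default 0.5).
#' @param dvars_thresh DVARS threshold in percent (default 0.5).
#' @param max_censored_frac Maximum tolerated censored fraction (default 1/3).
#' @return The time series with its censor mask updated, plus elements
#'   `qc_pass` (logical), `censored_fraction`, and `n_censored`.
#' @export
apply_qc <- function(ts, motion, fd_thresh = 0.5, dvars_thresh = 0.5,
                     max_censored_frac = 1 / 3) {
  stopifnot(fd_thresh > 0, dvars_thresh > 0, max_censored_frac > 0)
  n <- nrow(ts$values)
  if (n == 0L) stop("empty time series")
  fd <- as.numeric(motion$fd)
  dvars <- as.numeric(motion$dvars)
  if (length(fd) != n || length(dvars) != n)
    stop("motion trace length (fd ", length(fd), ", dvars ", length(dvars),
         ") does not match timepoints (", n, ")")
  if (any(fd < 0) || any(dvars < 0)) stop("motion traces must be nonnegative")
  censored <- fd > fd_thresh | dvars > dvars_thresh
  ts$censor_mask <- ts$censor_mask & !censored
  ts$n_censored <- sum(censored)
  ts$censored_fraction <- ts$n_censored / n
  ts$qc_pass <- ts$censored_fraction <= max_censored_frac
  ts
}

#' Pearson correlation matrix over retained timepoints
#'
#' @param ts A [roi_timeseries()]; only frames with `censor_mask = TRUE`
#'   enter the correlation.
#' @return A symmetric correlation matrix with attribute `kind = "pearson"`
#'   and ROI column names preserved.
#' @export
pearson_matrix <- function(ts) {
  x <- ts$values[ts$censor_mask, , drop = FALSE]
  if (nrow(x) < 3L)
    stop("need at least 3 retained timepoints, have ", nrow(x))
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    nm <- if (!is.null(colnames(x))) colnames(x)[bad] else bad
    stop("zero-variance ROI over retained timepoints: ",
         paste(nm, collapse = ", "))
  }
  sigma <- stats::cor(x)
  attr(sigma, "kind") <- "pearson"
  sigma
}

#' Partial correlations from a Pearson correlation matrix
#'
#' Inverts the correlation matrix Sigma to the precision matrix
#' U = Sigma^-1 and rescales its negated off-diagonals:
#' Pi_ij = -U_ij / sqrt(U_ii U_jj), with unit diagonal. Each entry is the
#' correlation between ROIs i and j after removing the linear influence of
#' every other ROI. An optional ridge adds `ridge * I` to Sigma before
#' inversion for short, rank-deficient series.
#'
#' @param sigma Pearson correlation matrix.
#' @param ridge Nonnegative ridge added to the diagonal before inversion
#'   (default 0: hard error on a singular matrix).
#' @param tol Smallest acceptable eigenvalue when `ridge = 0`.
#' @return Partial correlation matrix, attribute `kind = "partial"`.
#' @export
partial_from_pearson <- function(sigma, ridge = 0, tol = 1e-10) {
  stopifnot(ridge >= 0)
  sigma <- as.matrix(sigma)
  if (ridge > 0) sigma <- sigma + diag(ridge, nrow(sigma))
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= tol)
    stop("correlation matrix is singular (min eigenvalue ",
         format(min(ev), digits = 3),
         "); use a positive ridge or a longer time series")
  upsilon <- solve(sigma)
  d <- sqrt(diag(upsilon))
  pi_mat <- -upsilon / tcrossprod(d)
  diag(pi_mat) <- 1
  pi_mat <- (pi_mat + t(pi_mat)) / 2
  attr(pi_mat, "kind") <- "partial"
  pi_mat
}

#' Fisher z-transform of a correlation matrix
#'
#' Elementwise z = atanh(r) on the off-diagonals; the diagonal is set to 0 by
#' convention and never emitted as a feature.
#'
#' @param pi_mat Partial (or Pearson) correlation matrix with off-diagonals
#'   strictly inside (-1, 1).
#' @return Matrix of Fisher z values, attribute `kind = "fisher_z"`.
#' @export
fisher_transform <- function(pi_mat) {
  pi_mat <- as.matrix(pi_mat)
  off <- pi_mat[row(pi_mat) != col(pi_mat)]
  if (any(abs(off) >= 1))
    stop("off-diagonal correlation with |r| >= 1: Fisher z is infinite")
  z <- atanh(pi_mat)
  diag(z) <- 0
  attr(z, "kind") <- "fisher_z"
  z
}

#' Vectorize a connectivity matrix to the canonical feature order
#'
#' Extracts the upper triangle (i < j) row-major in parcellation order; the
#' inverse `devectorize_features` rebuilds the symmetric matrix (diagonal 0).
#'
#' @param mat Symmetric n x n matrix whose size matches the scheme.
#' @param scheme A parcellation data frame.
#' @return `vectorize_features`: named numeric vector (names are
#'   "ROIi__ROIj" pair ids). `devectorize_features`: symmetric matrix.
#' @export
vectorize_features <- function(mat, scheme) {
  n <- count_rois(scheme)
  if (!all(dim(mat) == c(n, n)))
    stop("matrix is ", nrow(mat), "x", ncol(mat),
         " but scheme has ", n, " ROIs")
  idx <- upper_tri_pairs(n)
  v <- mat[idx]
  names(v) <- roi_pair_ids(scheme)
  v
}

#' @rdname vectorize_features
#' @param v Feature vector of length n(n-1)/2.
#' @export
devectorize_features <- function(v, scheme) {
  n <- count_rois(scheme)
  if (length(v) != n * (n - 1L) / 2L)
    stop("feature vector length ", length(v), " does not match scheme (",
         n * (n - 1L) / 2L, " pairs)")
  m <- matrix(0, n, n, dimnames = list(scheme$roi_name, scheme$roi_name))
  idx <- upper_tri_pairs(n)
  m[idx] <- v
  m[idx[, c(2L, 1L)]] <- v
  m
}

#' Build an FC feature table from per-subject time series
#'
#' Runs the full per-scan chain (Pearson, partial, Fisher z, vectorize) and
#' stacks subjects into the feature table consumed by harmonization and CCA.
#'
#' @param ts_list List of [roi_timeseries()] objects.
#' @param scheme Parcellation scheme; ROI count must match the series.
#' @param ridge Ridge passed to [partial_from_pearson()].
#' @return An `fc_table`: numeric matrix subjects x features with subject ids
#'   as row names and pair ids as column names.
#' @export
fc_feature_table <- function(ts_list, scheme, ridge = 0) {
  feats <- vapply(ts_list, function(ts) {
    sigma <- pearson_matrix(ts)
    vectorize_features(fisher_transform(partial_from_pearson(sigma, ridge)),
                       scheme)
  }, numeric(count_rois(scheme) * (count_rois(scheme) - 1L) / 2L))
  out <- t(feats)
  rownames(out) <- vapply(ts_list, `[[`, character(1L), "subject_id")
  class(out) <- c("fc_table", class(out))
  out
}

#' Read / write an FC feature table TSV
#'
#' First column `subject_id`, remaining columns the "ROIi__ROIj" feature ids
#' in canonical order.
#'
#' @param fc Subjects x features matrix with dimnames.
#' @param path File path.
#' @export
write_fc_table <- function(fc, path) {
  df <- data.frame(subject_id = rownames(fc), fc, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fc_table
#' @export
read_fc_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (names(df)[1L] != "subject_id")
    stop("FC table must start with a 'subject_id' column, found '",
         names(df)[1L], "'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df$subject_id)
  class(m) <- c("fc_table", class(m))
  m
}

#' Read per-subject ROI time-series and motion TSVs
#'
#' Time series: header row of ROI names, one row per timepoint. Motion: a
#' TSV with columns `fd` and `dvars`.
#'
#' @param path File path.
#' @param subject_id Subject identifier to attach.
#' @export
read_roi_timeseries <- function(path, subject_id) {
  df <- utils::read.delim(path, check.names = FALSE)
  roi_timeseries(subject_id, as.matrix(df))
}

#' @rdname read_roi_timeseries
#' @export
read_motion_trace <- function(path) {
  df <- utils::read.delim(path)
  missing <- setdiff(c("fd", "dvars"), names(df))
  if (length(missing) > 0L)
    stop("motion trace is missing columns: ", paste(missing, collapse = ", "))
  list(fd = df$fd, dvars = df$dvars)
}
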