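#' Cross-cohort replication of canonical variates
#'
#' A variate replicates when its behaviour coefficient vector and its FC
#' coefficient vector both correlate strongly with those of a variate fitted
#' in an independent cohort. Because the two cohorts are screened separately,
#' FC vectors are first collapsed to the bilateral macro-network parcellation
#' and restricted to stable features common to both cohorts. Correlations are
#' Pearson, with t = r * sqrt((n-2)/(1-r^2)), df = n - 2, and two-tailed p
#' from the t distribution. Sign flips between cohorts are rotation
#' artifacts of CCA, so magnitudes decide replication.
#'
#' @name replication
NULL

#' t statistic and p-value for a Pearson correlation
#'
#' @param r Pearson correlation.
#' @param n Vector length the correlation was computed over.
#' @return Named vector `c(r, t, df, p)` with df = n - 2 and two-tailed p.
#' @export
cor_t_stat <- function(r, n) {
  df <- n - 2
  stopifnot(df >= 1)
  t <- r * sqrt(df / (1 - r^2))
  c(r = r, t = t, df = df,
    p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' Correlate two coefficient vectors
#'
#' @param v_a,v_b Equal-length numeric vectors (length >= 3, nonconstant).
#' @return Named vector `c(r, t, df, p)`.
#' @export
correlate_coefficient_vectors <- function(v_a, v_b) {
  if (length(v_a) != length(v_b)) stop("vectors differ in length")
  if (length(v_a) < 3L) stop("need at least 3 entries to correlate")
  if (stats::sd(v_a) == 0 || stats::sd(v_b) == 0)
    stop("constant coefficient vector")
  cor_t_stat(stats::cor(v_a, v_b), length(v_a))
}

#' Collapse an FC coefficient vector to macro-network pairs
#'
#' Every ROI-pair feature maps to the unordered pair of its endpoints' macro
#' networks (self-pairs allowed, e.g. two default-mode subregions); the
#' collapsed coefficient is the mean of its constituents and a collapsed
#' entry is stable when at least one constituent is stable (`rule =
#' "majority"` requires more than half).
#'
#' @param coeffs Numeric coefficient vector over the scheme's ROI pairs (in
#'   canonical order).
#' @param stable Logical stability flag per coefficient.
#' @param scheme The parcellation the coefficients were computed under.
#' @param feature_idx Optional integer indices of `coeffs` within the full
#'   pair ordering (for screened fits that kept a subset); default assumes
#'   the full set.
#' @param rule Stability aggregation rule, `"any"` (default) or
#'   `"majority"`.
#' @return A data frame with columns `key` (macro-pair label), `value`
#'   (mean coefficient), `n_constituents`, `stable`.
#' @export
collapse_networks <- function(coeffs, stable, scheme, feature_idx = NULL,
                              rule = c("any", "majority")) {
  rule <- match.arg(rule)
  n <- count_rois(scheme)
  pairs <- upper_tri_pairs(n)
  if (is.null(feature_idx)) feature_idx <- seq_len(nrow(pairs))
  if (length(coeffs) != length(feature_idx) ||
      length(stable) != length(feature_idx))
    stop("coeffs/stable length does not match feature_idx")
  if (any(feature_idx < 1L | feature_idx > nrow(pairs)))
    stop("feature index outside the scheme's pair range")
  macro <- scheme$macro_network
  mi <- macro[pairs[feature_idx, 1L]]
  mj <- macro[pairs[feature_idx, 2L]]
  key <- ifelse(mi <= mj, paste(mi, mj, sep = " x "),
                paste(mj, mi, sep = " x "))
  agg_val <- tapply(coeffs, key, mean)
  agg_n <- tapply(stable, key, length)
  agg_st <- if (rule == "any") tapply(stable, key, any) else
    tapply(stable, key, function(s) mean(s) > 0.5)
  out <- data.frame(key = names(agg_val), value = as.numeric(agg_val),
                    n_constituents = as.integer(agg_n),
                    stable = as.logical(agg_st), row.names = NULL)
  class(out) <- c("collapsed_features", "data.frame")
  out
}

#' Stable collapsed features common to two cohorts
#'
#' @param a,b `collapsed_features` data frames from [collapse_networks()].
#' @return Character vector of keys stable in both.
#' @export
common_stable_features <- function(a, b) {
  intersect(a$key[a$stable], b$key[b$stable])
}

#' Match canonical variates across two cohorts
#'
#' Computes the all-pairs correlation matrix of behaviour coefficient vectors
#' between cohorts, and for each variate pair the correlation of collapsed FC
#' coefficient vectors over the stable features common to that pair. A pair
#' is declared replicated when both |r| values exceed their thresholds. FC
#' correlations over fewer than 3 common stable features are skipped
#' (recorded as NA with the count).
#'
#' @param cca_a,cca_b `cca_result` objects of the two cohorts (same number
#'   of behaviour scores; the instruments may differ in one role).
#' @param stab_a,stab_b Matching `stability_result` objects.
#' @param scheme_a,scheme_b Parcellation schemes (usually identical).
#' @param idx_a,idx_b Integer indices of each cohort's selected features
#'   within the full pair ordering.
#' @param behaviour_thresh,fc_thresh Replication thresholds on |r|
#'   (defaults 0.9 and 0.5).
#' @param rule Stability collapsing rule, see [collapse_networks()].
#' @return A `replication_result`: `behaviour` and `fc` data frames of
#'   per-pair (r, t, df, p), `n_common` matrix, and `replicated` logical
#'   matrix.
#' @export
match_cvs <- function(cca_a, cca_b, stab_a, stab_b, scheme_a, scheme_b,
                      idx_a = NULL, idx_b = NULL, behaviour_thresh = 0.9,
                      fc_thresh = 0.5, rule = "any") {
  ka <- cca_a$K; kb <- cca_b$K
  if (nrow(cca_a$y_coeffs) != nrow(cca_b$y_coeffs))
    stop("cohorts have different numbers of behaviour scores")
  beh <- expand.grid(cv_a = seq_len(ka), cv_b = seq_len(kb))
  beh_stats <- t(apply(beh, 1L, function(rw)
    correlate_coefficient_vectors(cca_a$y_coeffs[, rw[1L]],
                                  cca_b$y_coeffs[, rw[2L]])))
  behaviour <- cbind(beh, as.data.frame(beh_stats))

  coll_a <- lapply(seq_len(ka), function(j)
    collapse_networks(cca_a$x_coeffs[, j], stab_a$stable_x[, j], scheme_a,
                      idx_a, rule))
  coll_b <- lapply(seq_len(kb), function(j)
    collapse_networks(cca_b$x_coeffs[, j], stab_b$stable_x[, j], scheme_b,
                      idx_b, rule))

  fc <- behaviour
  fc[, c("r", "t", "df", "p")] <- NA_real_
  n_common <- matrix(0L, ka, kb)
  for (rw in seq_len(nrow(fc))) {
    i <- fc$cv_a[rw]; j <- fc$cv_b[rw]
    keys <- common_stable_features(coll_a[[i]], coll_b[[j]])
    n_common[i, j] <- length(keys)
    if (length(keys) >= 3L) {
      va <- coll_a[[i]]$value[match(keys, coll_a[[i]]$key)]
      vb <- coll_b[[j]]$value[match(keys, coll_b[[j]]$key)]
      if (stats::sd(va) > 0 && stats::sd(vb) > 0)
        fc[rw, c("r", "t", "df", "p")] <-
          correlate_coefficient_vectors(va, vb)
    }
  }
  rep_mat <- matrix(FALSE, ka, kb)
  for (rw in seq_len(nrow(fc)))
    rep_mat[fc$cv_a[rw], fc$cv_b[rw]] <-
      !is.na(fc$r[rw]) && abs(behaviour$r[rw]) > behaviour_thresh &&
      abs(fc$r[rw]) > fc_thresh
  structure(list(behaviour = behaviour, fc = fc, n_common = n_common,
                 replicated = rep_mat, collapsed_a = coll_a,
                 collapsed_b = coll_b,
                 thresholds = c(behaviour = behaviour_thresh,
                                fc = fc_thresh)),
            class = "replication_result")
}

#' @export
print.replication_result <- function(x, ...) {
  cat("Replication across", nrow(x$replicated), "x", ncol(x$replicated),
      "canonical-variate pairs\n")
  best <- which.max(abs(x$behaviour$r))
  cat(sprintf("best behaviour-vector match: CV %d vs CV %d, r = %.3f\n",
              x$behaviour$cv_a[best], x$behaviour$cv_b[best],
              x$behaviour$r[best]))
  cat("replicated pairs:", sum(x$replicated), "\n")
  invisible(x)
}
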