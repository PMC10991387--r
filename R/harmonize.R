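#' Site harmonization and covariate residualization
#'
#' Multi-site cohorts carry scanner- and site-specific location/scale shifts
#' in every connectivity feature. `combat_adjust()` removes them with the
#' parametric empirical-Bayes location/scale model: per-feature
#' standardization given the protected covariates, per-site additive (gamma)
#' and multiplicative (delta^2) effect estimates shrunk toward a normal /
#' inverse-gamma prior by iterative conditional updates, then
#' back-transformation. `residualize_covariates()` then regresses out nuisance
#' covariates (sex, viewing condition) by per-feature OLS; age is deliberately
#' not part of the default design so that age differences remain testable
#' between subject clusters downstream.
#'
#' @name harmonization
NULL

#' Empirical-Bayes site adjustment of an FC feature table
#'
#' @param fc Subjects x features numeric matrix.
#' @param site Factor (or coercible) of site labels, one per subject; every
#'   site must contain at least 2 subjects.
#' @param preserve Optional design matrix (subjects x covariates, no
#'   intercept) of effects to protect during standardization; their fitted
#'   contribution is removed before site estimation and re-added afterwards.
#'   Default: intercept only.
#' @param conv Convergence tolerance of the EB conditional updates.
#' @return List with `adjusted` (matrix, same shape as `fc`) and `model`, a
#'   `harmonization_model` holding grand means, covariate coefficients,
#'   per-site gamma/delta2 before and after shrinkage, and the prior
#'   hyperparameters per site.
#' @export
combat_adjust <- function(fc, site, preserve = NULL, conv = 1e-4) {
  fc <- as.matrix(fc)
  n <- nrow(fc)
  site <- factor(site)
  if (length(site) != n) stop("site vector length does not match subjects")
  counts <- table(site)
  if (any(counts < 2L))
    stop("sites with a single subject cannot be harmonized: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  n_site <- nlevels(site)
  p <- ncol(fc)

  const_feat <- apply(fc, 2L, stats::sd) == 0
  if (any(const_feat))
    warning(sum(const_feat), " constant feature(s) passed through unchanged")
  work <- !const_feat

  if (!is.null(preserve)) {
    preserve <- as.matrix(preserve)
    if (nrow(preserve) != n) stop("preserve design rows must match subjects")
  }

  if (n_site == 1L) {
    # nothing to harmonize: one batch defines the reference distribution
    model <- structure(list(
      sites = levels(site), counts = as.vector(counts),
      grand_mean = colMeans(fc[, work, drop = FALSE]),
      covariate_coefs = NULL, var_pooled = NULL,
      gamma_hat = NULL, delta_hat = NULL,
      gamma_star = NULL, delta_star = NULL, priors = NULL,
      constant_features = which(const_feat)
    ), class = "harmonization_model")
    return(list(adjusted = fc, model = model))
  }

  batch_design <- stats::model.matrix(~ site - 1)
  design <- cbind(batch_design, preserve)
  if (qr(design)$rank < ncol(design))
    stop("combined site + protected design is rank deficient")

  Y <- fc[, work, drop = FALSE]
  beta <- solve(crossprod(design), crossprod(design, Y))
  site_idx <- seq_len(n_site)
  grand_mean <- colSums(beta[site_idx, , drop = FALSE] *
                          (as.vector(counts) / n))
  resid <- Y - design %*% beta
  var_pooled <- colSums(resid^2) / n

  stand_mean <- matrix(grand_mean, n, sum(work), byrow = TRUE)
  if (!is.null(preserve))
    stand_mean <- stand_mean +
      preserve %*% beta[-site_idx, , drop = FALSE]
  Z <- (Y - stand_mean) / matrix(sqrt(var_pooled), n, sum(work), byrow = TRUE)

  gamma_hat <- rowsum(Z, site) / as.vector(counts)
  delta_hat <- t(vapply(levels(site), function(s)
    apply(Z[site == s, , drop = FALSE], 2L, stats::var), numeric(sum(work))))

  gamma_bar <- rowMeans(gamma_hat)
  tau2 <- apply(gamma_hat, 1L, stats::var)
  d_mean <- rowMeans(delta_hat)
  d_var <- apply(delta_hat, 1L, stats::var)
  a_prior <- (2 * d_var + d_mean^2) / d_var
  b_prior <- (d_mean * d_var + d_mean^3) / d_var

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (s in seq_len(n_site)) {
    ni <- as.vector(counts)[s]
    Zi <- Z[site == levels(site)[s], , drop = FALSE]
    g_old <- gamma_hat[s, ]
    d_old <- delta_hat[s, ]
    change <- 1
    while (change > conv) {
      g_new <- (ni * tau2[s] * gamma_hat[s, ] + d_old * gamma_bar[s]) /
        (ni * tau2[s] + d_old)
      sum2 <- colSums(sweep(Zi, 2L, g_new)^2)
      d_new <- (0.5 * sum2 + b_prior[s]) / (ni / 2 + a_prior[s] - 1)
      change <- max(abs(g_new - g_old) / abs(g_old),
                    abs(d_new - d_old) / d_old)
      g_old <- g_new
      d_old <- d_new
    }
    gamma_star[s, ] <- g_old
    delta_star[s, ] <- d_old
  }

  Z_adj <- (Z - gamma_star[site, , drop = FALSE]) /
    sqrt(delta_star[site, , drop = FALSE])
  adjusted <- fc
  adjusted[, work] <- Z_adj *
    matrix(sqrt(var_pooled), n, sum(work), byrow = TRUE) + stand_mean

  model <- structure(list(
    sites = levels(site), counts = as.vector(counts),
    grand_mean = as.vector(grand_mean),
    covariate_coefs = if (is.null(preserve)) NULL else
      beta[-site_idx, , drop = FALSE],
    var_pooled = var_pooled,
    gamma_hat = gamma_hat, delta_hat = delta_hat,
    gamma_star = gamma_star, delta_star = delta_star,
    priors = list(gamma_bar = gamma_bar, tau2 = tau2,
                  a_prior = a_prior, b_prior = b_prior),
    constant_features = which(const_feat)
  ), class = "harmonization_model")

  list(adjusted = adjusted, model = model)
}

#' Regress nuisance covariates out of FC features
#'
#' Per-feature ordinary least squares on the supplied design (an intercept is
#' always added); returns the residuals, so features come back mean-centred.
#'
#' @param fc Subjects x features numeric matrix.
#' @param covars Design matrix or data frame of covariates (subjects x q),
#'   e.g. sex and viewing condition. Factors are expanded to indicators.
#' @return Matrix of residuals, same shape and dimnames as `fc`.
#' @export
residualize_covariates <- function(fc, covars) {
  fc <- as.matrix(fc)
  if (is.data.frame(covars))
    covars <- stats::model.matrix(~ ., data = covars)[, -1L, drop = FALSE]
  covars <- as.matrix(covars)
  if (nrow(covars) != nrow(fc)) stop("covariate rows must match subjects")
  X <- cbind(`(Intercept)` = 1, covars)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("covariate design is rank deficient")
  res <- fc - X %*% qr.coef(qx, fc)
  dimnames(res) <- dimnames(fc)
  res
}
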