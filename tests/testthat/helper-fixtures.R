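# Fixtures are built in code; no data files.

# Minimal valid scheme with n ROIs, one macro network per ROI pair of
# hemispheres; for odd n the last network gets a single (L) label.
toy_scheme <- function(n_rois) {
  nets <- paste0("N", seq_len(ceiling(n_rois / 2)))
  network <- rep(nets, each = 2L)[seq_len(n_rois)]
  hemi <- rep(c("L", "R"), length.out = n_rois)
  scheme <- data.frame(
    label_id = seq_len(n_rois),
    roi_name = paste(network, hemi, sep = "_"),
    structure = "cerebellum",
    network_name = network,
    hemisphere = hemi,
    macro_network = network,
    stringsAsFactors = FALSE
  )
  class(scheme) <- c("parcellation", "data.frame")
  scheme
}

# 8-ROI compact scheme used for identifiable-coefficient regimes.
compact_scheme <- function() {
  s <- restrict_parcellation(default_parcellation(), "cerebellum")[1:8, ]
  s$label_id <- 1:8
  class(s) <- c("parcellation", "data.frame")
  s
}

# Two vectors with an exact Pearson correlation r (n = 3 needs the
# quadratic contrast as the orthogonal direction).
vectors_with_exact_r <- function(r, n) {
  base <- seq_len(n)
  za <- as.vector(scale(base))
  orth <- stats::resid(stats::lm(base^2 ~ base))
  zo <- as.vector(scale(orth))
  list(a = za, b = r * za + sqrt(1 - r^2) * zo)
}

# Planted Gaussian clusters: centre separation measured in units of the
# clusters' radial SD (sqrt(2) * per-dim SD in 2D).
planted_cluster_loadings <- function(n_per = 40L, k = 3L, separation = 6) {
  sep <- separation * sqrt(2)
  theta <- 2 * pi * seq_len(k) / k
  radius <- sep / sqrt(2 * (1 - cos(2 * pi / k)))
  centres <- cbind(radius * cos(theta), radius * sin(theta))
  labels <- rep(seq_len(k), each = n_per)
  pts <- centres[labels, ] + matrix(stats::rnorm(2 * k * n_per), k * n_per, 2)
  list(points = pts, labels = labels)
}

# Residual-regression definition of partial correlation: correlate the
# residuals of i and j after regressing each on all remaining variables.
partial_cor_residual <- function(x, i, j) {
  others <- setdiff(seq_len(ncol(x)), c(i, j))
  if (length(others) == 0L) return(stats::cor(x[, i], x[, j]))
  ri <- stats::resid(stats::lm(x[, i] ~ x[, others]))
  rj <- stats::resid(stats::lm(x[, j] ~ x[, others]))
  stats::cor(ri, rj)
}

# Random SPD correlation matrix of dimension d.
random_corr <- function(d, n = 50L * d) {
  x <- matrix(stats::rnorm(n * d), n, d)
  stats::cor(x)
}

# Brute-force CCA oracle: eigenvalues of Sxx^-1 Sxy Syy^-1 Syx.
cca_oracle <- function(x, y) {
  sxx <- stats::cov(x); syy <- stats::cov(y); sxy <- stats::cov(x, y)
  ev <- eigen(solve(sxx) %*% sxy %*% solve(syy) %*% t(sxy))$values
  sqrt(pmax(Re(ev), 0))[seq_len(min(ncol(x), ncol(y)))]
}

score_cols3 <- c("attention", "social", "oc")
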