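#' Spectral clustering of subjects in canonical-loading space
#'
#' Subjects are clustered on their loading values for the statistically
#' significant canonical variates: a scaled-exponential affinity kernel with
#' local bandwidths, the unnormalized graph Laplacian L = D - A, k-means on
#' the eigenvectors of the k smallest eigenvalues, Calinski-Harabasz
#' selection of the cluster count, and Rand-index stability under
#' subsampling. Post-hoc tests ask whether clusters are enriched for a
#' diagnostic category (chi-squared) or differ on covariates (one-way ANOVA).
#'
#' @name clustering
NULL

#' Scaled-exponential affinity matrix
#'
#' With Euclidean distances d_ij, local scale
#' eps_ij = (mean distance of i to its k nearest neighbours + same for j +
#' d_ij) / 3, the affinity is A_ij = exp(-d_ij^2 / (2 (mu eps_ij)^2)),
#' symmetrized by averaging. Self-affinity is set to the row maximum. The
#' neighbour count excludes the point itself.
#'
#' @param loadings Subjects x variates matrix of loading values.
#' @param mu Kernel dampening coefficient (default 0.3).
#' @param k_neighbours Neighbourhood width (default 10).
#' @return Symmetric nonnegative affinity matrix with attributes `mu` and
#'   `k_neighbours`.
#' @export
affinity_matrix <- function(loadings, mu = 0.3, k_neighbours = 10L) {
  loadings <- as.matrix(loadings)
  n <- nrow(loadings)
  if (n <= k_neighbours)
    stop("need more subjects (", n, ") than neighbours (", k_neighbours, ")")
  d <- as.matrix(stats::dist(loadings))
  knn_mean <- apply(d, 1L, function(row)
    mean(sort(row[-which.min(row)])[seq_len(k_neighbours)]))
  # row[-which.min(row)] drops the self-distance (0) once
  eps <- (outer(knn_mean, knn_mean, `+`) + d) / 3
  floor_eps <- sqrt(.Machine$double.eps)
  if (any(eps[row(eps) != col(eps)] < floor_eps)) {
    warning("duplicate subjects produced a zero kernel scale; flooring")
    eps <- pmax(eps, floor_eps)
  }
  a <- exp(-d^2 / (2 * (mu * eps)^2))
  a <- (a + t(a)) / 2
  diag(a) <- apply(a, 1L, max)
  attr(a, "mu") <- mu
  attr(a, "k_neighbours") <- k_neighbours
  a
}

#' Spectral clustering via the unnormalized Laplacian
#'
#' Builds L = D - A with D_ii = sum_j A_ij, takes the eigenvectors of the k
#' smallest eigenvalues, and clusters their rows by k-means with multiple
#' restarts (best within-cluster sum of squares kept). Deterministic given
#' the seed.
#'
#' @param a Affinity matrix from [affinity_matrix()].
#' @param k Number of clusters (2 <= k < subjects).
#' @param seed RNG seed for the k-means restarts.
#' @param n_restarts k-means restarts (default 50).
#' @return Integer vector of cluster assignments in 1..k.
#' @export
spectral_cluster <- function(a, k, seed = 1L, n_restarts = 50L) {
  a <- as.matrix(a)
  n <- nrow(a)
  stopifnot(k >= 2L, k < n)
  lap <- diag(rowSums(a)) - a
  e <- eigen(lap, symmetric = TRUE)
  if (sum(e$values < 1e-8) > k)
    warning("affinity graph has more than k near-disconnected components; ",
            "the eigen-gap is ambiguous")
  vecs <- e$vectors[, n - seq_len(k) + 1L, drop = FALSE]  # k smallest
  set.seed(seed)
  km <- stats::kmeans(vecs, centers = k, nstart = n_restarts,
                      iter.max = 100L)
  as.integer(km$cluster)
}

#' Calinski-Harabasz index
#'
#' CH = (trace(B)/(k-1)) / (trace(W)/(n-k)) with between- and within-cluster
#' scatter about the centroids. Zero within-cluster scatter returns `Inf`.
#'
#' @param data Subjects x dims matrix the clustering was computed on.
#' @param assignments Cluster labels.
#' @return Scalar CH index.
#' @export
calinski_harabasz <- function(data, assignments) {
  data <- as.matrix(data)
  n <- nrow(data)
  cl <- as.integer(factor(assignments))
  k <- max(cl)
  if (k < 2L) stop("CH index needs at least 2 clusters")
  if (any(tabulate(cl, k) == 0L)) stop("empty cluster")
  grand <- colMeans(data)
  w <- 0; b <- 0
  for (g in seq_len(k)) {
    rows <- data[cl == g, , drop = FALSE]
    ctr <- colMeans(rows)
    w <- w + sum(sweep(rows, 2L, ctr)^2)
    b <- b + nrow(rows) * sum((ctr - grand)^2)
  }
  if (w == 0) return(Inf)
  (b / (k - 1)) / (w / (n - k))
}

#' Rand and adjusted Rand indices
#'
#' Pair-counting agreement between two labelings; the adjusted index corrects
#' for the expected agreement by chance.
#'
#' @param labels_a,labels_b Two labelings of the same subjects.
#' @return Named vector `c(rand = ..., adjusted_rand = ...)`.
#' @export
rand_indices <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("labelings differ in length")
  n <- length(labels_a)
  tab <- table(labels_a, labels_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  # Rand: (agreements both-together + both-apart) over all pairs
  rand <- (total + 2 * sum_ij - sum_a - sum_b) / total
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  ari <- if (max_index == expected) 1 else
    (sum_ij - expected) / (max_index - expected)
  c(rand = rand, adjusted_rand = ari)
}

#' Clustering stability under subsampling
#'
#' Each resample draws a fraction of subjects without replacement,
#' re-clusters them, and compares the new labels to the original assignment
#' restricted to the drawn subjects. Degenerate resamples (an empty cluster
#' after re-clustering) are redrawn.
#'
#' @param loadings Subjects x variates matrix.
#' @param k Cluster count.
#' @param n_resamples Number of resamples (default 10000).
#' @param subsample_frac Fraction drawn per resample (default 0.8).
#' @param seed RNG seed.
#' @param mu,k_neighbours,n_restarts Passed to the affinity / clustering
#'   steps.
#' @return List with `rand` and `adjusted_rand` vectors (one per resample)
#'   plus the original `assignments`.
#' @export
cluster_stability <- function(loadings, k, n_resamples = 10000L,
                              subsample_frac = 0.8, seed = 1L, mu = 0.3,
                              k_neighbours = 10L, n_restarts = 50L) {
  loadings <- as.matrix(loadings)
  n <- nrow(loadings)
  m <- round(subsample_frac * n)
  if (m <= 5L * k) stop("subsample keeps too few subjects (", m,
                        ") for k = ", k)
  base <- spectral_cluster(affinity_matrix(loadings, mu, k_neighbours), k,
                           seed = seed, n_restarts = n_restarts)
  ri <- numeric(n_resamples); ari <- numeric(n_resamples)
  set.seed(seed)
  for (b in seq_len(n_resamples)) {
    repeat {
      idx <- sample.int(n, m)
      sub <- tryCatch(
        spectral_cluster(
          affinity_matrix(loadings[idx, , drop = FALSE], mu,
                          min(k_neighbours, m - 1L)),
          k, seed = seed + b, n_restarts = n_restarts),
        error = function(e) NULL)
      if (!is.null(sub) && length(unique(sub)) == k) break
    }
    agree <- rand_indices(base[idx], sub)
    ri[b] <- agree["rand"]; ari[b] <- agree["adjusted_rand"]
  }
  list(rand = ri, adjusted_rand = ari, assignments = base)
}

#' Cluster-count selection over a range of k
#'
#' Clusters at each k in `k_range`, records the CH index, and reports the
#' CH-maximising k.
#'
#' @param loadings Subjects x variates matrix.
#' @param k_range Candidate cluster counts (default 2:10).
#' @inheritParams cluster_stability
#' @return List with `assignments` (matrix, subjects x length(k_range)),
#'   `ch_index` per k, and `chosen_k`.
#' @export
choose_cluster_count <- function(loadings, k_range = 2:10, seed = 1L,
                                 mu = 0.3, k_neighbours = 10L,
                                 n_restarts = 50L) {
  loadings <- as.matrix(loadings)
  a <- affinity_matrix(loadings, mu, k_neighbours)
  ch <- numeric(length(k_range))
  asg <- matrix(NA_integer_, nrow(loadings), length(k_range),
                dimnames = list(rownames(loadings), paste0("k", k_range)))
  for (i in seq_along(k_range)) {
    # scanning k below the component count is expected here; the eigen-gap
    # warning is only informative for a single chosen k
    asg[, i] <- suppressWarnings(
      spectral_cluster(a, k_range[i], seed = seed, n_restarts = n_restarts))
    ch[i] <- calinski_harabasz(loadings, asg[, i])
  }
  list(assignments = asg, ch_index = stats::setNames(ch, paste0("k", k_range)),
       chosen_k = k_range[which.max(ch)])
}

#' Diagnostic-category enrichment of clusters
#'
#' Per cluster, a chi-squared goodness-of-fit of the observed category counts
#' against expectations proportional to the whole-cohort category mix
#' (df = categories - 1).
#'
#' @param assignments Cluster labels per subject.
#' @param diagnosis Diagnostic category per subject (e.g. TD/ASD/ADHD/OCD).
#' @return Data frame with one row per cluster: `cluster`, `statistic`,
#'   `df`, `p`.
#' @export
cluster_enrichment <- function(assignments, diagnosis) {
  diagnosis <- factor(diagnosis)
  cohort_prop <- prop.table(table(diagnosis))
  if (any(cohort_prop == 0)) stop("a diagnostic category has zero count")
  out <- lapply(sort(unique(assignments)), function(cl) {
    obs <- table(factor(diagnosis[assignments == cl],
                        levels = levels(diagnosis)))
    expected <- sum(obs) * cohort_prop
    stat <- sum((obs - expected)^2 / expected)
    df <- nlevels(diagnosis) - 1L
    data.frame(cluster = cl, statistic = stat, df = df,
               p = stats::pchisq(stat, df, lower.tail = FALSE))
  })
  do.call(rbind, out)
}

#' One-way ANOVA of a covariate across clusters
#'
#' Fixed-effects one-way ANOVA of `values` (e.g. age, IQ, mean framewise
#' displacement) on the cluster factor.
#'
#' @param values Numeric covariate per subject.
#' @param assignments Cluster labels per subject.
#' @return Named vector `c(F, df1, df2, p)`.
#' @export
cluster_covariate_anova <- function(values, assignments) {
  g <- factor(assignments)
  if (nlevels(g) < 2L) stop("need at least 2 clusters")
  if (any(table(g) < 2L)) stop("every cluster needs at least 2 values")
  fit <- stats::aov(values ~ g)
  s <- summary(fit)[[1L]]
  c(F = s$`F value`[1L], df1 = s$Df[1L], df2 = s$Df[2L],
    p = s$`Pr(>F)`[1L])
}
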