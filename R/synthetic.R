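#' Synthetic cohorts with planted canonical structure
#'
#' Generates one or two cohorts whose FC features and behaviour scores share
#' latent canonical components of known strength, on top of site batch
#' effects, sex and viewing-condition effects, and a four-category diagnosis
#' mixture — so that every pipeline stage can be validated against ground
#' truth. Generation can emit either the FC feature table directly or
#' per-subject ROI time series whose partial-correlation structure is
#' modulated by the same latents.
#'
#' @name synthetic_data
NULL

#' Specification of a synthetic cohort
#'
#' The latent model: for each component k, a standard-normal latent u_k per
#' subject drives both blocks. Behaviour scores are
#' `sum_k rho_k * w_k * u_k + noise` (then diagnosis-linked mean shifts);
#' FC features are `sum_k a_k * u_k + noise` plus site scale/offset and
#' sex/viewing effects. With unit-norm `w_k` and behaviour noise SD
#' `sqrt(1 - rho_1^2)`, the population canonical correlation of the leading
#' component is close to `rho_1`.
#'
#' @param n_subjects Cohort size (default 400).
#' @param scheme Parcellation (default the 48-label scheme).
#' @param level `"features"` or `"timeseries"`.
#' @param n_timepoints Timepoints when `level = "timeseries"` (default 200).
#' @param components List of components, each `list(w = , a = , rho = )` with
#'   `w` over scores and `a` over features, both unit norm, `rho` in [0, 1)
#'   strictly decreasing across components. Default: one component with
#'   `rho = 0.8`, behaviour weights concentrated on the first score (keeping
#'   pairwise score correlations below 0.3), and 40 support features with
#'   alternating signs.
#' @param score_names Behaviour score names (default attention, social, oc;
#'   add `"sensory"` for the four-score variant).
#' @param noise_sd_features Feature noise SD (default 0.25).
#' @param noise_sd_behaviour Behaviour noise SD (default `sqrt(1 - rho_1^2)`).
#' @param sites Site labels (default 2 sites).
#' @param site_prob Site membership probabilities.
#' @param site_offsets,site_scales Additive and multiplicative site effects
#'   applied to every feature (defaults 0/+0.1 and 1/1.2).
#' @param sex_effect,viewing_effect Effect sizes added to fixed
#'   half-feature subsets for male sex and the second viewing condition.
#' @param diagnosis_prob TD/ASD/ADHD/OCD mixture (default approximating the
#'   original cohort: 0.19/0.36/0.34/0.11).
#' @param diagnosis_shift Score shift applied to each diagnosis' hallmark
#'   score (ASD: social, ADHD: attention, OCD: oc; default 0.5).
#' @param clusters Optional planted subject clusters:
#'   `list(centres = matrix clusters x components, prob = )`; centres shift
#'   the latent u vector.
#' @param ts_coupling Strength of the latent modulation of the ROI covariance
#'   at timeseries level (default 0.12).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 400L,
                        scheme = default_parcellation(),
                        level = c("features", "timeseries"),
                        n_timepoints = 200L,
                        components = NULL,
                        score_names = c("attention", "social", "oc"),
                        noise_sd_features = 0.25,
                        noise_sd_behaviour = NULL,
                        sites = c("siteA", "siteB"),
                        site_prob = NULL,
                        site_offsets = c(0, 0.1),
                        site_scales = c(1, 1.2),
                        sex_effect = 0.1,
                        viewing_effect = 0.1,
                        diagnosis_prob = c(TD = 0.19, ASD = 0.36,
                                           ADHD = 0.34, OCD = 0.11),
                        diagnosis_shift = 0.5,
                        clusters = NULL,
                        ts_coupling = 0.12) {
  level <- match.arg(level)
  n_features <- count_rois(scheme) * (count_rois(scheme) - 1L) / 2L
  n_scores <- length(score_names)
  if (is.null(components))
    components <- list(planted_component(scheme, n_scores))
  for (cmp in components) {
    stopifnot(length(cmp$w) == n_scores, length(cmp$a) == n_features,
              cmp$rho >= 0, cmp$rho < 1)
  }
  rhos <- vapply(components, `[[`, numeric(1L), "rho")
  if (length(rhos) > 1L && any(diff(rhos) >= 0))
    stop("component strengths rho must be strictly decreasing")
  components <- lapply(components, function(cmp) {
    cmp$w <- cmp$w / sqrt(sum(cmp$w^2))
    cmp$a <- cmp$a / sqrt(sum(cmp$a^2))
    cmp
  })
  if (is.null(noise_sd_behaviour))
    noise_sd_behaviour <- sqrt(1 - rhos[1L]^2)
  if (is.null(site_prob)) site_prob <- rep(1 / length(sites), length(sites))
  stopifnot(length(site_offsets) == length(sites),
            length(site_scales) == length(sites),
            abs(sum(diagnosis_prob) - 1) < 1e-8)
  if (!is.null(clusters)) {
    clusters$centres <- as.matrix(clusters$centres)
    stopifnot(ncol(clusters$centres) == length(components),
              abs(sum(clusters$prob) - 1) < 1e-8)
  }
  structure(list(
    n_subjects = n_subjects, scheme = scheme, level = level,
    n_timepoints = n_timepoints, components = components,
    score_names = score_names, noise_sd_features = noise_sd_features,
    noise_sd_behaviour = noise_sd_behaviour, sites = sites,
    site_prob = site_prob, site_offsets = site_offsets,
    site_scales = site_scales, sex_effect = sex_effect,
    viewing_effect = viewing_effect, diagnosis_prob = diagnosis_prob,
    diagnosis_shift = diagnosis_shift, clusters = clusters,
    ts_coupling = ts_coupling
  ), class = "cohort_spec")
}

#' Network-structured planted component
#'
#' Builds a component whose FC support is concentrated in a handful of
#' macro-network pairs (the way real connectivity effects are organised),
#' with a common sign within each pair and alternating signs across pairs,
#' unit norm overall. Behaviour weights are concentrated on the first score
#' so that pairwise score correlations stay low.
#'
#' @param scheme Parcellation defining the macro-network pair structure.
#' @param n_scores Number of behaviour scores.
#' @param rho Component strength (default 0.8).
#' @param n_pairs Number of macro-network pairs carrying signal (default 4).
#' @export
planted_component <- function(scheme, n_scores, rho = 0.8, n_pairs = 4L) {
  n <- count_rois(scheme)
  pairs <- upper_tri_pairs(n)
  mi <- scheme$macro_network[pairs[, 1L]]
  mj <- scheme$macro_network[pairs[, 2L]]
  key <- ifelse(mi <= mj, paste(mi, mj, sep = " x "),
                paste(mj, mi, sep = " x "))
  counts <- table(key)
  eligible <- sort(names(counts)[counts >= 4L])
  if (length(eligible) < 1L) eligible <- sort(names(counts))
  n_pairs <- min(n_pairs, length(eligible))
  chosen <- eligible[unique(round(seq(1L, length(eligible),
                                      length.out = n_pairs)))]
  a <- numeric(nrow(pairs))
  for (i in seq_along(chosen))
    a[key == chosen[i]] <- if (i %% 2L == 1L) 1 else -1
  a <- a / sqrt(sum(a^2))
  w <- c(0.97, 0.20, 0.14, rep(0.1, max(0L, n_scores - 3L)))[seq_len(n_scores)]
  w <- w / sqrt(sum(w^2))
  list(w = w, a = a, rho = rho, network_pairs = chosen)
}

#' Evenly spread planted component
#'
#' Behaviour weights concentrated on the first score; 40 support features
#' spread evenly through the feature vector with alternating signs; both
#' vectors unit norm.
#'
#' @param n_scores,n_features Block dimensions.
#' @param rho Component strength (default 0.8).
#' @param n_support Number of nonzero FC loadings (default 40).
#' @export
default_component <- function(n_scores, n_features, rho = 0.8,
                              n_support = 40L) {
  w <- c(0.97, 0.20, 0.14, rep(0.1, max(0L, n_scores - 3L)))[seq_len(n_scores)]
  w <- w / sqrt(sum(w^2))
  n_support <- min(n_support, n_features)
  support <- unique(round(seq(1L, n_features, length.out = n_support)))
  a <- numeric(n_features)
  a[support] <- rep_len(c(1, -1), length(support))
  a <- a / sqrt(sum(a^2))
  list(w = w, a = a, rho = rho)
}

#' Generate a synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @param seed RNG seed; same seed, same cohort.
#' @return List with `fc` (feature level) or `ts_list` plus `motion`
#'   (timeseries level), `phenotype` data frame, and `truth` (latents,
#'   component vectors, cluster labels).
#' @export
generate_cohort <- function(spec, seed = 1L) {
  set.seed(seed)
  n <- spec$n_subjects
  k <- length(spec$components)
  n_features <- count_rois(spec$scheme) * (count_rois(spec$scheme) - 1L) / 2L
  n_scores <- length(spec$score_names)
  subject_id <- sprintf("sub-%04d", seq_len(n))

  u <- matrix(stats::rnorm(n * k), n, k)
  cluster_labels <- rep(1L, n)
  if (!is.null(spec$clusters)) {
    cluster_labels <- sample.int(nrow(spec$clusters$centres), n,
                                 replace = TRUE, prob = spec$clusters$prob)
    u <- u + spec$clusters$centres[cluster_labels, , drop = FALSE]
  }

  w <- vapply(spec$components, `[[`, numeric(n_scores), "w")
  a <- vapply(spec$components, `[[`, numeric(n_features), "a")
  w <- matrix(w, n_scores, k); a <- matrix(a, n_features, k)
  rho <- vapply(spec$components, `[[`, numeric(1L), "rho")

  site <- factor(sample(spec$sites, n, replace = TRUE, prob = spec$site_prob),
                 levels = spec$sites)
  sex <- stats::rbinom(n, 1L, 0.7)  # male-majority, as in NDD cohorts
  viewing <- factor(sample(c("movie", "rest"), n, replace = TRUE),
                    levels = c("movie", "rest"))
  diagnosis <- factor(sample(names(spec$diagnosis_prob), n, replace = TRUE,
                             prob = spec$diagnosis_prob),
                      levels = names(spec$diagnosis_prob))
  age <- stats::rnorm(n, 12.2, 3.2)
  iq <- stats::rnorm(n, 103, 17)
  mean_fd <- abs(stats::rnorm(n, 0.15, 0.08))

  scores <- u %*% (t(w) * rho) +
    matrix(stats::rnorm(n * n_scores, sd = spec$noise_sd_behaviour),
           n, n_scores)
  colnames(scores) <- spec$score_names
  shift <- spec$diagnosis_shift
  hallmark <- c(ASD = "social", ADHD = "attention", OCD = "oc")
  for (dg in names(hallmark))
    if (hallmark[dg] %in% colnames(scores))
      scores[diagnosis == dg, hallmark[dg]] <-
        scores[diagnosis == dg, hallmark[dg]] + shift

  phenotype <- data.frame(
    subject_id = subject_id, scores,
    sex = sex, site = site, viewing = viewing, age = age,
    diagnosis = diagnosis, iq = iq, mean_fd = mean_fd,
    stringsAsFactors = FALSE
  )
  truth <- list(w = w, a = a, rho = rho, u = u,
                cluster_labels = cluster_labels, seed = seed)

  signal <- u %*% (t(a))  # n x features latent signal

  if (spec$level == "features") {
    fc <- signal + matrix(stats::rnorm(n * n_features,
                                       sd = spec$noise_sd_features),
                          n, n_features)
    # covariate effects on fixed feature subsets, then site location/scale
    half1 <- seq_len(n_features) %% 2L == 1L
    half2 <- seq_len(n_features) %% 3L == 1L
    fc[, half1] <- fc[, half1] + spec$sex_effect * sex
    fc[, half2] <- fc[, half2] +
      spec$viewing_effect * (viewing == "rest")
    fc <- fc * spec$site_scales[as.integer(site)] +
      spec$site_offsets[as.integer(site)]
    dimnames(fc) <- list(subject_id, roi_pair_ids(spec$scheme))
    class(fc) <- c("fc_table", class(fc))
    return(list(fc = fc, phenotype = phenotype, truth = truth))
  }

  # timeseries level: latent-modulated ROI covariance per subject
  n_rois <- count_rois(spec$scheme)
  base <- .base_roi_covariance(spec$scheme)
  ts_list <- vector("list", n)
  scaled_down <- 0L
  for (s in seq_len(n)) {
    pert <- devectorize_features(spec$ts_coupling * signal[s, ], spec$scheme)
    sig <- base + pert
    ev_min <- min(eigen(sig, symmetric = TRUE, only.values = TRUE)$values)
    while (ev_min <= 0.05) {
      pert <- pert / 2
      sig <- base + pert
      ev_min <- min(eigen(sig, symmetric = TRUE, only.values = TRUE)$values)
      scaled_down <- scaled_down + 1L
    }
    ch <- chol(sig)
    x <- matrix(stats::rnorm(spec$n_timepoints * n_rois),
                spec$n_timepoints, n_rois) %*% ch
    colnames(x) <- spec$scheme$roi_name
    ts_list[[s]] <- roi_timeseries(subject_id[s], x)
  }
  if (scaled_down > 0L)
    warning(scaled_down, " covariance perturbation(s) scaled down to stay ",
            "positive definite")
  list(ts_list = ts_list, phenotype = phenotype, truth = truth)
}

# Within-macro-network baseline correlation 0.3, unit variances.
.base_roi_covariance <- function(scheme, within = 0.3) {
  same <- outer(scheme$macro_network, scheme$macro_network, `==`)
  sig <- ifelse(same, within, 0)
  diag(sig) <- 1
  sig
}

#' Generate twin cohorts sharing planted components
#'
#' Cohort A follows the spec exactly; cohort B shares the component
#' directions, perturbed by `divergence` (0 = identical truth, 1 =
#' independent directions). Cohort B's third behaviour score is re-expressed
#' through a different instrument: the emitted score correlates with the
#' instrument-A score at `cross_instrument_r`.
#'
#' @param spec A [cohort_spec()]; both cohorts use its size and noise levels.
#' @param divergence Fraction in [0, 1] mixing a random direction into
#'   cohort B's loading and weight vectors.
#' @param cross_instrument_r Correlation between the two instruments
#'   measuring the third score (default 0.51).
#' @param seed RNG seed.
#' @return List `a`, `b` (each as [generate_cohort()] output) and `truth`
#'   (the shared component record plus cohort B's perturbed vectors).
#' @export
generate_twin_cohorts <- function(spec, divergence = 0,
                                  cross_instrument_r = 0.51, seed = 1L) {
  stopifnot(divergence >= 0, divergence <= 1)
  cohort_a <- generate_cohort(spec, seed = seed)

  set.seed(seed + 1000L)
  spec_b <- spec
  spec_b$components <- lapply(spec$components, function(cmp) {
    if (divergence > 0) {
      ga <- stats::rnorm(length(cmp$a)); ga <- ga / sqrt(sum(ga^2))
      gw <- stats::rnorm(length(cmp$w)); gw <- gw / sqrt(sum(gw^2))
      cmp$a <- (1 - divergence) * cmp$a + divergence * ga
      cmp$w <- (1 - divergence) * cmp$w + divergence * gw
      cmp$a <- cmp$a / sqrt(sum(cmp$a^2))
      cmp$w <- cmp$w / sqrt(sum(cmp$w^2))
    }
    cmp
  })
  cohort_b <- generate_cohort(spec_b, seed = seed + 2000L)

  # instrument substitution on the third score of cohort B
  if (length(spec$score_names) >= 3L) {
    set.seed(seed + 3000L)
    s3 <- cohort_b$phenotype[[spec$score_names[3L]]]
    z3 <- (s3 - mean(s3)) / stats::sd(s3)
    noise <- stats::rnorm(length(s3))
    cohort_b$phenotype[[spec$score_names[3L]]] <-
      cross_instrument_r * z3 + sqrt(1 - cross_instrument_r^2) * noise
    if (spec$score_names[3L] == "oc")
      names(cohort_b$phenotype)[names(cohort_b$phenotype) == "oc"] <- "oc_alt"
  }
  list(a = cohort_a, b = cohort_b,
       truth = list(shared = cohort_a$truth,
                    b_components = spec_b$components,
                    divergence = divergence,
                    cross_instrument_r = cross_instrument_r))
}

#' Generate a synthetic motion trace
#'
#' Baseline framewise displacement from a folded normal, with spikes above
#' the 0.5 mm censoring threshold at the requested per-frame probability;
#' DVARS spikes co-occur with FD spikes.
#'
#' @param n_timepoints Trace length.
#' @param spike_fraction Per-frame spike probability in [0, 1].
#' @param seed RNG seed.
#' @return List with `fd` (mm) and `dvars` (percent) vectors.
#' @export
generate_motion_traces <- function(n_timepoints, spike_fraction = 0,
                                   seed = 1L) {
  stopifnot(spike_fraction >= 0, spike_fraction <= 1)
  set.seed(seed)
  fd <- abs(stats::rnorm(n_timepoints, 0.1, 0.05))
  fd <- pmin(fd, 0.45)  # baseline stays below the 0.5 mm threshold
  dvars <- pmin(abs(stats::rnorm(n_timepoints, 0.2, 0.05)), 0.45)
  spikes <- stats::runif(n_timepoints) < spike_fraction
  fd[spikes] <- 0.5 + abs(stats::rnorm(sum(spikes), 0.3, 0.1))
  dvars[spikes] <- 0.5 + abs(stats::rnorm(sum(spikes), 0.3, 0.1))
  list(fd = fd, dvars = dvars)
}
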