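#' Pipeline orchestration
#'
#' `run_pipeline()` chains the stages — harmonization, Spearman screening,
#' CCA, permutation significance, bootstrap stability, spectral clustering of
#' significant variates, and (given a second cohort) replication scoring —
#' under a single declarative configuration with per-stage seeds, and can
#' serialize results plus a manifest sufficient to reproduce the run.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' Defaults follow the analysis conventions this pipeline implements: Spearman
#' screen at p < 0.05 (0.01 as the stricter variant), 10,000 permutations,
#' bootstraps and stability resamples, |z| > 1.96 stability, affinity kernel
#' mu = 0.3 with neighbourhood width 10, cluster counts 2..10, variate
#' significance alpha = 0.05. Resampling sizes are the knobs to scale down
#' for quick runs; every value is echoed in the run manifest.
#'
#' @param score_cols Behaviour score columns of the phenotype table.
#' @param score_cols_b Score columns of the second cohort (same roles;
#'   default identical).
#' @param covar_cols Covariate columns regressed out after harmonization
#'   (age is deliberately absent).
#' @param harmonize,residualize,do_cluster Stage toggles.
#' @param protect Optional phenotype columns protected inside harmonization.
#' @param p_thresh Spearman screen threshold.
#' @param n_perm,n_boot,n_resamples Resampling sizes.
#' @param alpha Variate significance level.
#' @param z_thresh Coefficient stability threshold.
#' @param statistic Permutation statistic, `"wilks"` or `"maxcor"`.
#' @param ridge Ridge for the CCA core (0 = hard error on rank deficiency).
#' @param mu,k_neighbours,k_range,subsample_frac,n_restarts Clustering
#'   parameters.
#' @param behaviour_thresh,fc_thresh Replication thresholds on |r|.
#' @param seeds Named list of per-stage seeds (perm, boot, cluster).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(score_cols = c("attention", "social", "oc"),
                            score_cols_b = score_cols,
                            covar_cols = c("sex", "viewing"),
                            harmonize = TRUE, residualize = TRUE,
                            do_cluster = TRUE,
                            protect = NULL,
                            p_thresh = 0.05, n_perm = 10000L,
                            n_boot = 10000L, n_resamples = 10000L,
                            alpha = 0.05, z_thresh = 1.96,
                            statistic = "wilks", ridge = 0,
                            mu = 0.3, k_neighbours = 10L, k_range = 2:10,
                            subsample_frac = 0.8, n_restarts = 50L,
                            behaviour_thresh = 0.9, fc_thresh = 0.5,
                            seeds = list(perm = 101L, boot = 202L,
                                         cluster = 303L)) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Prepare one cohort's blocks
#'
#' Drops subjects missing any used behaviour score (count reported),
#' harmonizes sites, and residualizes nuisance covariates.
#'
#' @param fc Subjects x features matrix.
#' @param phenotype Phenotype data frame (row order matching `fc`).
#' @param config A [pipeline_config()].
#' @param score_cols Score columns for this cohort.
#' @return List `x` (processed features), `scores`, `phenotype`,
#'   `n_excluded`, `harmonization` model.
#' @keywords internal
prepare_cohort <- function(fc, phenotype, config, score_cols) {
  missing_cols <- setdiff(c(score_cols, if (config$harmonize) "site",
                            if (config$residualize) config$covar_cols),
                          names(phenotype))
  if (length(missing_cols) > 0L)
    stop("phenotype table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  complete <- stats::complete.cases(phenotype[, score_cols, drop = FALSE])
  n_excluded <- sum(!complete)
  if (n_excluded > 0L)
    message(n_excluded, " subject(s) excluded for missing behaviour scores")
  fc <- fc[complete, , drop = FALSE]
  phenotype <- phenotype[complete, , drop = FALSE]

  harm <- NULL
  if (config$harmonize) {
    preserve <- if (!is.null(config$protect))
      stats::model.matrix(~ ., phenotype[, config$protect,
                                         drop = FALSE])[, -1L, drop = FALSE]
    res <- combat_adjust(fc, phenotype$site, preserve = preserve)
    fc <- res$adjusted
    harm <- res$model
  }
  if (config$residualize)
    fc <- residualize_covariates(fc,
                                 phenotype[, config$covar_cols, drop = FALSE])
  list(x = fc, scores = as.matrix(phenotype[, score_cols, drop = FALSE]),
       phenotype = phenotype, n_excluded = n_excluded, harmonization = harm)
}

#' Analyse one cohort
#'
#' Screen, fit, permute, bootstrap, and cluster the significant variates.
#'
#' @inheritParams prepare_cohort
#' @return A `cohort_analysis` list: `selection`, `cca`, `permutation`,
#'   `stability`, `significant` (variate indices), `clustering` (with
#'   `chosen_k`, assignments, stability distributions, enrichment,
#'   covariate ANOVAs), plus the prepared blocks.
#' @export
analyse_cohort <- function(fc, phenotype, config = pipeline_config(),
                           score_cols = config$score_cols) {
  prep <- prepare_cohort(fc, phenotype, config, score_cols)
  sel <- select_features(prep$x, prep$scores, config$p_thresh)
  x_sel <- prep$x[, sel$keep, drop = FALSE]
  cca <- fit_cca(x_sel, prep$scores, ridge = config$ridge)
  perm <- permutation_test(x_sel, prep$scores, n_perm = config$n_perm,
                           seed = config$seeds$perm,
                           statistic = config$statistic,
                           ridge = config$ridge)
  stab <- bootstrap_stability(x_sel, prep$scores, cca,
                              n_boot = config$n_boot,
                              seed = config$seeds$boot,
                              z_thresh = config$z_thresh,
                              ridge = config$ridge)
  significant <- which(perm$p < config$alpha)

  clustering <- NULL
  if (config$do_cluster && length(significant) >= 1L &&
      nrow(prep$x) > config$k_neighbours) {
    loadings <- cca$x_variates[, significant, drop = FALSE]
    sel_k <- choose_cluster_count(loadings, k_range = config$k_range,
                                  seed = config$seeds$cluster,
                                  mu = config$mu,
                                  k_neighbours = config$k_neighbours,
                                  n_restarts = config$n_restarts)
    stab_k <- cluster_stability(loadings, sel_k$chosen_k,
                                n_resamples = config$n_resamples,
                                subsample_frac = config$subsample_frac,
                                seed = config$seeds$cluster,
                                mu = config$mu,
                                k_neighbours = config$k_neighbours,
                                n_restarts = config$n_restarts)
    assignments <- stab_k$assignments
    enrich <- if ("diagnosis" %in% names(prep$phenotype) &&
                  nlevels(factor(prep$phenotype$diagnosis)) >= 2L)
      cluster_enrichment(assignments, prep$phenotype$diagnosis)
    anovas <- lapply(intersect(c("age", "iq", "mean_fd"),
                               names(prep$phenotype)), function(v)
      c(covariate = v,
        cluster_covariate_anova(prep$phenotype[[v]], assignments)))
    clustering <- list(chosen_k = sel_k$chosen_k,
                       ch_index = sel_k$ch_index,
                       assignments = assignments,
                       rand = stab_k$rand,
                       adjusted_rand = stab_k$adjusted_rand,
                       enrichment = enrich, anovas = anovas)
  }
  structure(list(selection = sel, cca = cca, permutation = perm,
                 stability = stab, significant = significant,
                 clustering = clustering, blocks = prep,
                 feature_idx = which(sel$keep), config = config),
            class = "cohort_analysis")
}

#' Run the full pipeline on one or two cohorts
#'
#' @param cohort_a List with `fc` and `phenotype` (e.g. from
#'   [generate_cohort()]).
#' @param cohort_b Optional second cohort for replication.
#' @param config A [pipeline_config()].
#' @param scheme Parcellation scheme (for network collapsing in
#'   replication).
#' @param out_dir Optional directory; when given, results and a manifest are
#'   written there.
#' @return List with `a`, optionally `b` (`cohort_analysis` objects) and
#'   `replication` (a `replication_result`), plus `manifest`.
#' @export
run_pipeline <- function(cohort_a, cohort_b = NULL,
                         config = pipeline_config(),
                         scheme = default_parcellation(), out_dir = NULL) {
  a <- analyse_cohort(cohort_a$fc, cohort_a$phenotype, config,
                      config$score_cols)
  b <- NULL; repl <- NULL
  if (!is.null(cohort_b)) {
    b <- analyse_cohort(cohort_b$fc, cohort_b$phenotype, config,
                        config$score_cols_b)
    repl <- match_cvs(a$cca, b$cca, a$stability, b$stability,
                      scheme, scheme,
                      idx_a = a$feature_idx, idx_b = b$feature_idx,
                      behaviour_thresh = config$behaviour_thresh,
                      fc_thresh = config$fc_thresh)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("ccanet")),
    config = config[setdiff(names(config), "k_range")],
    k_range = range(config$k_range),
    n_subjects = c(a = nrow(a$blocks$x),
                   b = if (!is.null(b)) nrow(b$blocks$x) else NA_integer_),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  out <- list(a = a, b = b, replication = repl, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_results(out, out_dir)
  invisible(out)
}

#' Serialize pipeline results
#'
#' Writes `results.json` (canonical correlations, p-values, stability
#' masks, clustering summaries, replication matrices), per-cohort TSV
#' coefficient tables, cluster assignment TSVs, and `manifest.json`.
#'
#' @param results Output of [run_pipeline()].
#' @param out_dir Directory (created if needed).
#' @export
write_pipeline_results <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summarize <- function(an, tag) {
    utils::write.table(
      data.frame(feature = rownames(an$cca$x_coeffs), an$cca$x_coeffs,
                 stable = an$stability$stable_x),
      file.path(out_dir, paste0("fc_coefficients_", tag, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(score = rownames(an$cca$y_coeffs), an$cca$y_coeffs,
                 z = an$stability$z_y),
      file.path(out_dir, paste0("behaviour_coefficients_", tag, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(an$clustering))
      utils::write.table(
        data.frame(subject_id = rownames(an$blocks$x),
                   cluster = an$clustering$assignments),
        file.path(out_dir, paste0("clusters_", tag, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    list(canonical_correlations = an$cca$cor,
         permutation_p = an$permutation$p,
         significant = an$significant,
         n_selected_features = sum(an$selection$keep),
         n_excluded = an$blocks$n_excluded,
         chosen_k = if (!is.null(an$clustering)) an$clustering$chosen_k,
         median_ari = if (!is.null(an$clustering))
           stats::median(an$clustering$adjusted_rand),
         enrichment = if (!is.null(an$clustering)) an$clustering$enrichment)
  }
  payload <- list(a = summarize(results$a, "a"))
  if (!is.null(results$b)) payload$b <- summarize(results$b, "b")
  if (!is.null(results$replication))
    payload$replication <- list(
      behaviour = results$replication$behaviour,
      fc = results$replication$fc,
      replicated = results$replication$replicated)
  jsonlite::write_json(payload, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  jsonlite::write_json(results$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

#' Read a phenotype CSV
#'
#' Strict header validation; subjects missing any of the named score columns
#' are dropped with a message (the count mirrors the cohort-construction
#' exclusion rule).
#'
#' @param path CSV path.
#' @param score_cols Required score columns.
#' @return Data frame with complete scores.
#' @export
read_phenotype <- function(path, score_cols = c("attention", "social", "oc")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("subject_id", score_cols), names(df))
  if (length(missing_cols) > 0L)
    stop("phenotype table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  complete <- stats::complete.cases(df[, score_cols, drop = FALSE])
  if (any(!complete))
    message(sum(!complete), " subject(s) dropped for missing scores")
  df[complete, , drop = FALSE]
}
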