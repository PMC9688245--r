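#' Planted-feature recovery study
#'
#' Repeatedly generates the default synthetic cohort (nine informative
#' questionnaire items among 428 features), runs the feature-selection
#' ensemble on the pooled data set, and counts how many planted features the
#' final subset recovers. The defaults mirror the most aggressive
#' configuration (10% threshold, intersection).
#'
#' @param n_seeds number of independent cohorts (default 20).
#' @param base_seed cohort seed for the first replicate; replicate i uses
#'   `base_seed + i - 1`.
#' @param threshold,combination ensemble configuration.
#' @param n_samples cohort size (default 1240).
#' @return data frame with one row per seed: `seed`, `n_recovered` (of the
#'   planted features), `subset_size`; the planted feature names are in
#'   attribute `planted`.
#' @export
planted_recovery_study <- function(n_seeds = 20L, base_seed = 1L,
                                   threshold = 0.10,
                                   combination = "intersection",
                                   n_samples = 1240L) {
  planted <- planted_features()
  config <- ensemble_config(threshold, combination)
  out <- lapply(seq_len(n_seeds), function(i) {
    seed <- base_seed + i - 1L
    cohort <- generate_cohort(cohort_spec(n_samples = n_samples, seed = seed))
    data <- build_dataset(cohort, "All")
    X <- suppressWarnings(preprocess(data$table))$matrix
    subset <- run_fs_ensemble(X, data$y, config, seed = seed)
    data.frame(seed = seed,
               n_recovered = sum(planted %in% subset$features),
               subset_size = length(subset$features))
  })
  res <- do.call(rbind, out)
  attr(res, "planted") <- planted
  res
}

#' Does feature selection beat the no-selection baseline?
#'
#' For several independent default cohorts, scores a Gaussian naive Bayes
#' with repeated stratified CV twice on the pooled data set: on the features
#' chosen by the 10%-intersection ensemble, and on all features. The
#' empirical expectation is that fewer, well-chosen features detect falls
#' better than the full 428-column table.
#'
#' @param n_seeds independent cohorts (default 5).
#' @param base_seed first cohort seed.
#' @param repetitions CV repetitions per arm (default 3).
#' @param threshold,combination ensemble configuration for the selection arm.
#' @return data frame with per-seed mean F1 of the selected-feature and
#'   all-feature arms.
#' @export
selection_benefit_study <- function(n_seeds = 5L, base_seed = 1L,
                                    repetitions = 3L, threshold = 0.10,
                                    combination = "intersection") {
  config <- ensemble_config(threshold, combination)
  out <- lapply(seq_len(n_seeds), function(i) {
    seed <- base_seed + i - 1L
    cohort <- generate_cohort(cohort_spec(seed = seed))
    data <- build_dataset(cohort, "All")
    X <- suppressWarnings(preprocess(data$table))$matrix
    subset <- run_fs_ensemble(X, data$y, config, seed = seed)
    sel <- repeated_cv_evaluate("gnb", list(),
                                X = X[, subset$features, drop = FALSE],
                                y = data$y, repetitions = repetitions,
                                seed = seed)
    all <- repeated_cv_evaluate("gnb", list(), X = X, y = data$y,
                                repetitions = repetitions, seed = seed)
    data.frame(seed = seed, f1_selected = sel$mean[["f1"]],
               f1_all = all$mean[["f1"]],
               recall_selected = sel$mean[["recall"]],
               recall_all = all$mean[["recall"]],
               n_selected = length(subset$features))
  })
  do.call(rbind, out)
}

#' Type-I-error calibration of the permutation test
#'
#' Generates label-independent cohorts (all loadings zero), runs the
#' permutation test on the cross-validated F1 of a Gaussian naive Bayes,
#' and reports the empirical rate of `p <= alpha`. Under the null the
#' p-values are uniform up to the add-one discretization, so the rate
#' should match `alpha` within Monte-Carlo error.
#'
#' @param n_seeds independent null cohorts (default 50).
#' @param n_permutations permutations per test (default 200).
#' @param base_seed first seed.
#' @param n_samples,n_features size of each null cohort (default 120 x 8, a
#'   deliberately small design so the study stays cheap).
#' @param prevalence positive-class rate of the null cohorts (default 0.35:
#'   balanced enough that the cross-validated F1 of the null model is not
#'   pinned at 0, which would tie every permutation and collapse the
#'   p-values to 1 instead of exercising their null distribution).
#' @param alpha nominal level (default 0.05).
#' @return list with `p_values`, `type_i_rate`, `alpha`.
#' @export
permutation_calibration_study <- function(n_seeds = 50L,
                                          n_permutations = 200L,
                                          base_seed = 1L, n_samples = 120L,
                                          n_features = 8L, prevalence = 0.35,
                                          alpha = 0.05) {
  p_values <- vapply(seq_len(n_seeds), function(i) {
    seed <- base_seed + i - 1L
    spec <- cohort_spec(n_samples = n_samples,
                        faller_prevalence = prevalence,
                        block_widths = c(noise = n_features),
                        informative_features = numeric(0),
                        seed = seed)
    cohort <- generate_cohort(spec)
    data <- build_dataset(cohort, "noise")
    X <- suppressWarnings(preprocess(data$table))$matrix
    evaluator <- function(Xe, ye) {
      fid <- stratified_folds(ye, 5L, seed)
      mean(fold_f1("gnb", list(), Xe, ye, fid))
    }
    permutation_test(evaluator, X, data$y,
                     n_permutations = n_permutations, seed = seed)$p_value
  }, numeric(1))
  list(p_values = p_values, type_i_rate = mean(p_values <= alpha),
       alpha = alpha)
}
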