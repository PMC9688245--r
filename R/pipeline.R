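#' Define the experiment grid
#'
#' Enumerates data set x model x ensemble-configuration cells. Threshold 1.0
#' (the no-selection baseline) appears once per data set and model; the
#' sub-unit thresholds are crossed with the four combination rules.
#'
#' @param datasets data-set names (default [dataset_names()]).
#' @param models model families (default all four).
#' @param thresholds subset of `c(1.0, 0.50, 0.25, 0.10)`.
#' @param combinations subset of the four combination rules.
#' @param repetitions CV repetitions per cell (default 3; use 10 for a
#'   full-scale run).
#' @param folds CV folds (default 5).
#' @param permutations label permutations for the per-data-set winners
#'   (default 99; use 1000 for a full-scale run; 0 disables the test).
#' @param fit_scope `"global"` fits imputation/standardization on all rows
#'   of a data set before CV (the most literal reading of the protocol);
#'   `"per_fold"` re-fits them inside every training fold (leakage-free).
#' @param nested re-run the feature-selection ensemble inside every
#'   training fold (default FALSE: selection on the full data before CV).
#' @param seed base seed for folds and ReliefF probes.
#' @param grids optional named list `family -> candidate data frame`
#'   overriding [default_grid()].
#' @return an object of class `experiment_grid`.
#' @export
experiment_grid <- function(datasets = dataset_names(),
                            models = c("gnb", "dt", "knn", "svm"),
                            thresholds = c(1.0, 0.50, 0.25, 0.10),
                            combinations = c("union", "union2", "union3",
                                             "intersection"),
                            repetitions = 3L, folds = 5L, permutations = 99L,
                            fit_scope = c("global", "per_fold"),
                            nested = FALSE, seed = 1L, grids = list()) {
  fit_scope <- match.arg(fit_scope)
  configs <- list()
  for (t in thresholds) {
    if (abs(t - 1.0) < 1e-12) {
      configs <- c(configs, list(ensemble_config(1.0)))
    } else {
      configs <- c(configs, lapply(combinations, function(cmb)
        ensemble_config(t, cmb)))
    }
  }
  cells <- expand.grid(config = seq_along(configs), model = models,
                       dataset = datasets, stringsAsFactors = FALSE)
  structure(list(datasets = datasets, models = models, configs = configs,
                 cells = cells, repetitions = repetitions, folds = folds,
                 permutations = permutations, fit_scope = fit_scope,
                 nested = nested, seed = seed, grids = grids),
            class = "experiment_grid")
}

candidate_grid <- function(grid, family) {
  if (!is.null(grid$grids[[family]])) grid$grids[[family]] else
    default_grid(family)
}

#' Evaluate one data set / model / ensemble configuration cell
#'
#' Selection (under `fit_scope = "global"`, `nested = FALSE`): preprocess the
#' data set, run the feature-selection ensemble, grid-search the model's
#' hyperparameters on the selected features, then score with repeated
#' stratified CV. With `nested = TRUE` preprocessing and selection are
#' re-fitted inside every training fold; with `fit_scope = "per_fold"` only
#' preprocessing is.
#'
#' @param data a `list(table, y)` as returned by [build_dataset()].
#' @param family model family.
#' @param config an [ensemble_config()].
#' @param grid an [experiment_grid()] carrying the run settings.
#' @param cell_seed seed for this cell.
#' @return list with `report` (a `cv_report`, or NULL if the configuration
#'   is infeasible), `subset` (a `final_subset`), `skipped`, `note`.
#' @export
evaluate_cell <- function(data, family, config, grid, cell_seed = 1L) {
  y <- data$y
  pp <- suppressWarnings(preprocess(data$table))
  X <- pp$matrix
  subset <- run_fs_ensemble(X, y, config, seed = cell_seed)
  if (attr(subset, "empty")) {
    return(list(report = NULL, subset = subset, skipped = TRUE,
                note = "empty final subset; configuration infeasible"))
  }
  feats <- subset$features
  gs <- grid_search_cv(family, X[, feats, drop = FALSE], y,
                       grid = candidate_grid(grid, family),
                       folds = grid$folds, seed = cell_seed)
  prep <- NULL
  if (grid$nested || grid$fit_scope == "per_fold") {
    nested <- grid$nested
    raw <- data$table
    prep <- function(train_rows) {
      ppf <- suppressWarnings(preprocess(raw, reference_rows = train_rows))
      f <- if (nested) {
        sel <- run_fs_ensemble(ppf$matrix[train_rows, , drop = FALSE],
                               y[train_rows], config, seed = cell_seed)
        sel$features
      } else {
        intersect(feats, colnames(ppf$matrix))
      }
      list(X = ppf$matrix, features = f)
    }
  }
  report <- repeated_cv_evaluate(family, gs$best,
                                 X = X[, feats, drop = FALSE], y = y,
                                 repetitions = grid$repetitions,
                                 folds = grid$folds, seed = cell_seed,
                                 prep = prep)
  list(report = report, subset = subset, skipped = FALSE, note = "")
}

#' Run the full experiment grid on a cohort
#'
#' One `cv_report` per grid cell; infeasible cells (empty final subsets) are
#' recorded as skipped, and a data set whose block is absent from the cohort
#' is reported per data set rather than aborting the run. Deterministic
#' given the grid's seed.
#'
#' @param cohort an `ms_cohort` (or a directory path written by
#'   [write_cohort()]).
#' @param grid an [experiment_grid()].
#' @return a `grid_results` data frame: one row per cell with the metric
#'   means/SDs, feature counts and notes; the selected subsets and reports
#'   are in attributes `subsets` and `reports` keyed by row id.
#' @export
run_grid <- function(cohort, grid) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "ms_cohort"), inherits(grid, "experiment_grid"))
  rows <- list()
  subsets <- list()
  reports <- list()
  for (ds in grid$datasets) {
    data <- tryCatch(build_dataset(cohort, ds), error = function(e) e)
    if (inherits(data, "error")) {
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = ds, model = NA_character_, threshold = NA_real_,
        combination = NA_character_, n_samples = NA_integer_,
        n_features = NA_integer_, f1_mean = NA_real_, f1_sd = NA_real_,
        recall_mean = NA_real_, recall_sd = NA_real_,
        precision_mean = NA_real_, precision_sd = NA_real_,
        specificity_mean = NA_real_, specificity_sd = NA_real_,
        kappa_mean = NA_real_, kappa_sd = NA_real_, p_value = NA_real_,
        skipped = TRUE, note = conditionMessage(data),
        stringsAsFactors = FALSE)
      next
    }
    for (mi in seq_along(grid$models)) {
      family <- grid$models[mi]
      for (ci in seq_along(grid$configs)) {
        config <- grid$configs[[ci]]
        cell_seed <- grid$seed + 1000L * mi + ci
        cell <- evaluate_cell(data, family, config, grid, cell_seed)
        key <- sprintf("%s|%s|%g|%s", ds, family, config$threshold,
                       config$combination)
        subsets[[key]] <- cell$subset
        if (!is.null(cell$report)) reports[[key]] <- cell$report
        m <- if (cell$skipped) {
          stats::setNames(rep(NA_real_, 10),
                          c(t(outer(c("f1", "recall", "precision",
                                      "specificity", "kappa"),
                                    c("mean", "sd"), paste, sep = "_"))))
        } else {
          r <- cell$report
          stats::setNames(as.numeric(rbind(r$mean, r$sd)),
                          c(t(outer(names(r$mean), c("mean", "sd"),
                                    paste, sep = "_"))))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          dataset = ds, model = family, threshold = config$threshold,
          combination = config$combination, n_samples = length(data$y),
          n_features = length(cell$subset$features),
          f1_mean = m[["f1_mean"]], f1_sd = m[["f1_sd"]],
          recall_mean = m[["recall_mean"]], recall_sd = m[["recall_sd"]],
          precision_mean = m[["precision_mean"]],
          precision_sd = m[["precision_sd"]],
          specificity_mean = m[["specificity_mean"]],
          specificity_sd = m[["specificity_sd"]],
          kappa_mean = m[["kappa_mean"]], kappa_sd = m[["kappa_sd"]],
          p_value = NA_real_, skipped = cell$skipped, note = cell$note,
          stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  results <- add_winner_permutation_p(results, cohort, grid)
  structure(results, class = c("grid_results", "data.frame"),
            subsets = subsets, reports = reports)
}

# Permutation p-values are computed for the per-data-set winners only
# (re-tuning all non-winning cells 1000x would be disproportionate).
add_winner_permutation_p <- function(results, cohort, grid) {
  if (grid$permutations < 1L) return(results)
  best <- select_best(results)
  for (i in seq_len(nrow(best))) {
    b <- best[i, ]
    data <- build_dataset(cohort, b$dataset)
    pp <- suppressWarnings(preprocess(data$table))
    config <- if (abs(b$threshold - 1.0) < 1e-12) ensemble_config(1.0) else
      ensemble_config(b$threshold, b$combination)
    subset <- run_fs_ensemble(pp$matrix, data$y, config, seed = grid$seed)
    feats <- subset$features
    gs <- grid_search_cv(b$model, pp$matrix[, feats, drop = FALSE], data$y,
                         grid = candidate_grid(grid, b$model),
                         folds = grid$folds, seed = grid$seed)
    evaluator <- function(X, y) {
      fid <- stratified_folds(y, grid$folds, grid$seed)
      mean(fold_f1(b$model, as.list(gs$best), X, y, fid))
    }
    pt <- permutation_test(evaluator, pp$matrix[, feats, drop = FALSE],
                           data$y, n_permutations = grid$permutations,
                           seed = grid$seed)
    hit <- which(results$dataset == b$dataset & results$model == b$model &
                   results$threshold == b$threshold &
                   (results$combination == b$combination |
                      (is.na(results$combination) & is.na(b$combination))))
    results$p_value[hit] <- pt$p_value
  }
  results
}

#' Select the best configuration per data set
#'
#' The winner maximizes mean F1; equal F1 goes to the configuration with
#' fewer selected features; any residual tie falls back to the documented
#' deterministic order (model families GNB, DT, kNN, SVM, then the grid's
#' enumeration order).
#'
#' @param results a `grid_results` data frame from [run_grid()].
#' @return data frame with the winning row per data set.
#' @export
select_best <- function(results) {
  stopifnot(is.data.frame(results))
  model_rank <- c(gnb = 1L, dt = 2L, knn = 3L, svm = 4L)
  class(results) <- "data.frame"   # winners are plain rows, not grid_results
  out <- list()
  for (ds in unique(results$dataset)) {
    rows <- results[results$dataset == ds & !results$skipped, , drop = FALSE]
    if (!nrow(rows)) {
      warning("data set ", ds, " has no evaluable configuration; ",
              "absent from the selection")
      next
    }
    ord <- order(-rows$f1_mean, rows$n_features,
                 model_rank[rows$model], seq_len(nrow(rows)))
    out[[ds]] <- rows[ord[1L], , drop = FALSE]
  }
  sel <- do.call(rbind, out)
  rownames(sel) <- NULL
  sel
}

#' Write / read grid results as a tidy TSV
#'
#' @param results a `grid_results` (or selection) data frame.
#' @param path TSV file path.
#' @return `path` (write) or the re-parsed data frame (read).
#' @export
write_results_tsv <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t",
                     row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_results_tsv
#' @export
read_results_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = "NA",
                    stringsAsFactors = FALSE)
}

#' Render a plain-text report of the best configurations
#'
#' One block per data set: winning model, threshold, combination, feature
#' count, metric means with SDs, permutation p-value, and the winner's
#' feature list with per-filter provenance when available.
#'
#' @param selection output of [select_best()].
#' @param results the full `grid_results` (optional, for provenance).
#' @return character vector of report lines, invisibly; also printed.
#' @export
report_selection <- function(selection, results = NULL) {
  subsets <- if (!is.null(results)) attr(results, "subsets") else NULL
  lines <- character(0)
  for (i in seq_len(nrow(selection))) {
    b <- selection[i, ]
    lines <- c(lines, sprintf(
      "%s (n=%d): %s | threshold %s | %s | %d feature(s)",
      b$dataset, b$n_samples, toupper(b$model),
      sprintf("%g%%", 100 * b$threshold),
      ifelse(is.na(b$combination), "-", b$combination), b$n_features))
    lines <- c(lines, sprintf(
      "  F1 %.2f+-%.2f  recall %.1f%%  precision %.1f%%  specificity %.1f%%  kappa %.2f  p %s",
      b$f1_mean, b$f1_sd, 100 * b$recall_mean, 100 * b$precision_mean,
      100 * b$specificity_mean, b$kappa_mean,
      ifelse(is.na(b$p_value), "-", format(b$p_value, digits = 3))))
    key <- sprintf("%s|%s|%g|%s", b$dataset, b$model, b$threshold,
                   b$combination)
    if (!is.null(subsets[[key]])) {
      feats <- subsets[[key]]$features
      lines <- c(lines, paste0("  features: ", paste(feats, collapse = ", ")))
    }
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
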