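# Mode with deterministic tie-break toward the smaller value.
mode_value <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  tab <- table(x)
  cands <- as.numeric(names(tab)[tab == max(tab)])
  min(cands)
}

#' Fit an imputation plan on reference rows
#'
#' Type-aware single imputation: metric features are imputed with the
#' reference median (even counts: mean of the two central order statistics),
#' ordinal features with the reference mode (ties broken toward the smaller
#' code). The EDSS total score uses knowledge-based imputation
#' (`edss_knowledge`): a missing total is recomputed from the functional
#' scores via [edss_total_from_functional()], and a missing functional score
#' with an observed total is imputed with the mode of that score among
#' reference subjects sharing the same total, falling back to the plain mode
#' when the stratum is empty or the total is itself missing.
#'
#' Statistics are fitted on `reference_rows` only, so the plan can be applied
#' to held-out rows without information leakage.
#'
#' @param table a [feature_table()].
#' @param reference_rows integer or logical row index of the rows statistics
#'   are learned from (default: all rows).
#' @return an object of class `imputation_plan`.
#' @export
fit_impute <- function(table, reference_rows = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(reference_rows)) reference_rows <- seq_len(nrow(table$values))
  ref <- table$values[reference_rows, , drop = FALSE]
  meta <- table$meta
  n_obs <- colSums(!is.na(ref))
  if (any(n_obs == 0)) {
    stop("feature(s) fully missing in the reference rows: ",
         paste(meta$feature[n_obs == 0], collapse = ", "))
  }
  rule <- ifelse(meta$edss_role == "total", "edss_knowledge",
                 ifelse(meta$scale == "ordinal", "mode", "median"))
  stat <- vapply(seq_along(meta$feature), function(j) {
    obs <- ref[, j][!is.na(ref[, j])]
    if (rule[j] == "median") stats::median(obs) else mode_value(obs)
  }, numeric(1))
  names(stat) <- meta$feature
  names(rule) <- meta$feature

  edss <- NULL
  if (any(meta$edss_role == "total")) {
    total_col <- meta$feature[meta$edss_role == "total"]
    func_cols <- meta$feature[meta$edss_role == "functional"]
    totals <- ref[, total_col]
    strata <- sort(unique(totals[!is.na(totals)]))
    stratum_modes <- lapply(strata, function(t0) {
      rows <- which(!is.na(totals) & totals == t0)
      vapply(func_cols, function(f) mode_value(ref[rows, f]), numeric(1))
    })
    names(stratum_modes) <- as.character(strata)
    edss <- list(total = total_col, functional = func_cols,
                 stratum_modes = stratum_modes)
  }
  structure(list(rule = rule, stat = stat, edss = edss), class = "imputation_plan")
}

#' Apply a fitted imputation plan
#'
#' Observed cells are preserved exactly; every missing cell is filled
#' according to the plan. Rows whose EDSS columns are entirely missing are
#' an error (there is nothing knowledge-based to build on).
#'
#' @param plan an `imputation_plan` from [fit_impute()].
#' @param table a [feature_table()] with the same features the plan was
#'   fitted on.
#' @return the completed `feature_table` (empty mask).
#' @export
apply_impute <- function(plan, table) {
  stopifnot(inherits(plan, "imputation_plan"), inherits(table, "feature_table"))
  if (!setequal(names(plan$rule), table$meta$feature)) {
    stop("plan and table features differ")
  }
  values <- table$values
  if (!is.null(plan$edss)) {
    values <- impute_edss_values(plan, values)
  }
  for (f in colnames(values)) {
    miss <- is.na(values[, f])
    if (any(miss)) values[miss, f] <- plan$stat[[f]]
  }
  out <- table
  out$values <- values
  out$mask[] <- FALSE
  feature_table(out$values, out$mask, out$meta)
}

# EDSS-specific pass, applied before the generic median/mode fill:
#  1. a missing functional score is imputed with the same-total stratum mode
#     when the row's total is observed (plain mode otherwise);
#  2. a missing total is then recomputed from the (now complete) functional
#     scores with the documented surrogate rule.
impute_edss_values <- function(plan, values) {
  e <- plan$edss
  cols <- c(e$functional, e$total)
  edss_part <- values[, cols, drop = FALSE]
  all_missing <- rowSums(!is.na(edss_part)) == 0
  if (any(all_missing)) {
    stop("row(s) with an entirely missing EDSS block: ",
         paste(which(all_missing), collapse = ", "))
  }
  totals <- values[, e$total]
  for (f in e$functional) {
    miss <- which(is.na(values[, f]))
    for (i in miss) {
      imputed <- NA_real_
      if (!is.na(totals[i])) {
        sm <- plan$edss$stratum_modes[[as.character(totals[i])]]
        if (!is.null(sm)) imputed <- sm[[f]]
      }
      if (is.na(imputed)) imputed <- plan$stat[[f]]
      values[i, f] <- imputed
    }
  }
  miss_total <- which(is.na(totals))
  if (length(miss_total)) {
    values[miss_total, e$total] <- edss_total_from_functional(
      values[miss_total, e$functional, drop = FALSE])
  }
  values
}

#' Knowledge-based imputation of an EDSS block
#'
#' Convenience wrapper: fits the plan on `reference_rows` and applies it to
#' the whole table. See [fit_impute()] for the rules.
#'
#' @inheritParams fit_impute
#' @return the completed `feature_table`.
#' @export
impute_edss <- function(table, reference_rows = NULL) {
  apply_impute(fit_impute(table, reference_rows), table)
}
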