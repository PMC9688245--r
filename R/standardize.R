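#' Fit a per-feature z-score standardizer
#'
#' Location is the reference mean, scale the population (divide-by-n)
#' standard deviation, so the reference rows themselves come out with mean 0
#' and SD 1 exactly. Ordinal items are treated as quasi-metric: their codes
#' are standardized like any other number. Features that are constant on the
#' reference rows have no usable scale; they are flagged and dropped at
#' transform time with a warning.
#'
#' @param table a fully imputed [feature_table()].
#' @param reference_rows rows the statistics are learned from (default all).
#' @return an object of class `standardizer` with fields `mu`, `sigma`,
#'   `constant` (names of dropped features).
#' @export
fit_standardize <- function(table, reference_rows = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (any(table$mask)) stop("standardize expects an imputed table")
  if (is.null(reference_rows)) reference_rows <- seq_len(nrow(table$values))
  ref <- table$values[reference_rows, , drop = FALSE]
  mu <- colMeans(ref)
  centered <- sweep(ref, 2, mu)
  sigma <- sqrt(colMeans(centered^2))
  constant <- colnames(ref)[sigma == 0]
  structure(list(mu = mu, sigma = sigma, constant = constant),
            class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param std a `standardizer` from [fit_standardize()].
#' @param table a fully imputed `feature_table` with the same features.
#' @return the standardized `feature_table`; constant features are dropped
#'   with a warning.
#' @export
apply_standardize <- function(std, table) {
  stopifnot(inherits(std, "standardizer"), inherits(table, "feature_table"))
  if (any(table$mask)) stop("standardize expects an imputed table")
  if (!setequal(names(std$mu), colnames(table$values))) {
    stop("standardizer and table features differ")
  }
  keep <- setdiff(colnames(table$values), std$constant)
  if (length(std$constant)) {
    warning("dropping constant feature(s): ",
            paste(std$constant, collapse = ", "))
  }
  if (!length(keep)) stop("no non-constant features left")
  values <- sweep(table$values[, keep, drop = FALSE], 2, std$mu[keep])
  values <- sweep(values, 2, std$sigma[keep], "/")
  feature_table(values, meta = table$meta[match(keep, table$meta$feature), ,
                                          drop = FALSE])
}

#' Standardize a table in one step
#'
#' @inheritParams fit_standardize
#' @return list with `standardizer` and the transformed `table`.
#' @export
standardize <- function(table, reference_rows = NULL) {
  std <- fit_standardize(table, reference_rows)
  list(standardizer = std, table = apply_standardize(std, table))
}

#' Impute and standardize in one step
#'
#' The statistics of both stages are fitted on `reference_rows` and applied
#' to every row, which is what the cross-validation engine needs for
#' leakage-free (`per_fold`) preprocessing; with the default
#' `reference_rows = NULL` the fit uses all rows (`global` scope).
#'
#' @inheritParams fit_standardize
#' @param table a [feature_table()], possibly with missing cells.
#' @return list with `matrix` (samples x retained features, ready for the
#'   rankers and classifiers), `plan`, and `standardizer`.
#' @export
preprocess <- function(table, reference_rows = NULL) {
  plan <- fit_impute(table, reference_rows)
  imputed <- apply_impute(plan, table)
  std <- fit_standardize(imputed, reference_rows)
  out <- apply_standardize(std, imputed)
  list(matrix = ft_matrix(out), plan = plan, standardizer = std)
}
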