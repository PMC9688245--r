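#' Feature table: samples x features with a missingness mask
#'
#' The basic data container of the package. It holds a numeric value matrix
#' (ordinal items are stored as their integer codes), a logical mask of the
#' same shape marking missing cells, and per-feature metadata describing the
#' measurement block, the scale (`metric` or `ordinal`), the number of
#' ordinal levels, and the role a feature plays in the EDSS block
#' (`functional`, `total`, or `none`).
#'
#' Cells under a `TRUE` mask carry no information: any stored value there is
#' ignored by every consumer in the package.
#'
#' @param values numeric matrix (samples x features) with column names.
#' @param mask logical matrix of the same shape; `TRUE` marks a missing cell.
#'   Defaults to all-observed.
#' @param meta data frame with one row per feature and columns `feature`,
#'   `block`, `scale`, `levels`, `edss_role`. Missing optional columns are
#'   filled with defaults (`levels = NA`, `edss_role = "none"`).
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, mask = NULL, meta = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(colnames(values))) {
    stop("`values` must have column (feature) names")
  }
  if (anyDuplicated(colnames(values))) {
    stop("feature names must be unique")
  }
  if (is.null(mask)) {
    mask <- matrix(FALSE, nrow(values), ncol(values),
                   dimnames = dimnames(values))
  }
  if (!is.logical(mask) || !identical(dim(mask), dim(values))) {
    stop("`mask` must be a logical matrix with the same shape as `values`")
  }
  # canonical form: a cell is missing iff masked iff NA, so equality of two
  # tables is plain equality of their components
  mask <- mask | is.na(values)
  values[mask] <- NA_real_
  if (is.null(meta)) {
    meta <- data.frame(feature = colnames(values),
                       block = NA_character_,
                       scale = "metric",
                       stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(meta))
  required <- c("feature", "block", "scale")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop("feature metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!("levels" %in% names(meta))) meta$levels <- NA_integer_
  if (!("edss_role" %in% names(meta))) meta$edss_role <- "none"
  if (!setequal(meta$feature, colnames(values)) ||
      nrow(meta) != ncol(values)) {
    stop("metadata rows must match the value columns one-to-one")
  }
  meta <- meta[match(colnames(values), meta$feature), , drop = FALSE]
  rownames(meta) <- NULL
  bad_scale <- setdiff(unique(meta$scale), c("metric", "ordinal"))
  if (length(bad_scale)) {
    stop("unknown scale(s): ", paste(bad_scale, collapse = ", "))
  }
  needs_levels <- meta$scale == "ordinal" & meta$edss_role != "total"
  if (any(needs_levels & (is.na(meta$levels) | meta$levels < 2))) {
    bad <- meta$feature[needs_levels & (is.na(meta$levels) | meta$levels < 2)]
    stop("ordinal feature(s) without a valid level count: ",
         paste(bad, collapse = ", "))
  }
  structure(list(values = values, mask = mask, meta = meta),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$mask)))
  blocks <- table(x$meta$block)
  cat("blocks:", paste(sprintf("%s[%d]", names(blocks), blocks), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Subset a feature table by rows and/or feature names
#'
#' @param table a [feature_table()].
#' @param rows integer or logical row index (default: all rows).
#' @param features character vector of feature names (default: all).
#' @return a `feature_table` restricted to the requested rows and features.
#' @export
ft_subset <- function(table, rows = NULL, features = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(rows)) rows <- seq_len(nrow(table$values))
  if (is.null(features)) features <- colnames(table$values)
  unknown <- setdiff(features, colnames(table$values))
  if (length(unknown)) {
    stop("unknown feature(s): ", paste(unknown, collapse = ", "))
  }
  feature_table(table$values[rows, features, drop = FALSE],
                table$mask[rows, features, drop = FALSE],
                table$meta[match(features, table$meta$feature), , drop = FALSE])
}

#' Column-bind feature tables that share the same samples
#'
#' Duplicated feature names (e.g. the EDSS columns shared between the Basic
#' and EDSS blocks) are kept once, from their first occurrence.
#'
#' @param ... `feature_table` objects with equal row counts.
#' @return a single `feature_table`.
#' @export
ft_cbind <- function(...) {
  tables <- list(...)
  if (length(tables) == 1L && is.list(tables[[1]]) &&
      !inherits(tables[[1]], "feature_table")) {
    tables <- tables[[1]]
  }
  stopifnot(all(vapply(tables, inherits, logical(1), "feature_table")))
  n <- unique(vapply(tables, function(t) nrow(t$values), integer(1)))
  if (length(n) != 1L) stop("all tables must have the same number of samples")
  values <- do.call(cbind, lapply(tables, `[[`, "values"))
  mask <- do.call(cbind, lapply(tables, `[[`, "mask"))
  meta <- do.call(rbind, lapply(tables, `[[`, "meta"))
  keep <- !duplicated(colnames(values))
  feature_table(values[, keep, drop = FALSE], mask[, keep, drop = FALSE],
                meta[keep, , drop = FALSE])
}

#' Extract the observed value matrix of a fully imputed table
#'
#' @param table a `feature_table` with no missing cells.
#' @return the numeric value matrix.
#' @export
ft_matrix <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (any(table$mask)) {
    stop("table still contains missing cells; impute first")
  }
  table$values
}
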