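#' Write a cohort to a directory of plain-text files
#'
#' One CSV per block (header = feature names, empty cell = missing value),
#' `labels.csv` with the binary fall label and the latent severity, a
#' tab-separated `features.tsv` sidecar (feature, block, scale, levels,
#' edss_role), and a machine-readable `spec.json` echo of the generating
#' parameters. Values are written with 17 significant digits so doubles
#' survive the round trip exactly.
#'
#' @param cohort an `ms_cohort` from [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ms_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (b in names(cohort$blocks)) {
    tab <- cohort$blocks[[b]]
    chr <- apply(tab$values, 2, function(col) {
      out <- sprintf("%.17g", col)
      out[is.na(col)] <- ""
      out
    })
    chr <- matrix(chr, nrow = nrow(tab$values),
                  dimnames = list(NULL, colnames(tab$values)))
    utils::write.csv(as.data.frame(chr, check.names = FALSE),
                     file.path(dir, paste0(b, ".csv")),
                     row.names = FALSE, quote = TRUE)
  }
  labels <- data.frame(y = cohort$y,
                       severity = sprintf("%.17g", cohort$severity))
  utils::write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  meta <- do.call(rbind, lapply(cohort$blocks, `[[`, "meta"))
  rownames(meta) <- NULL
  utils::write.table(meta, file.path(dir, "features.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  spec <- cohort$spec
  echo <- list(n_samples = spec$n_samples,
               faller_prevalence = spec$faller_prevalence,
               beta = spec$beta,
               block_widths = as.list(spec$block_widths),
               informative_features = as.list(spec$informative_features),
               ordinal_levels = as.list(spec$ordinal_levels),
               missingness = spec$missingness,
               seed = spec$seed)
  jsonlite::write_json(echo, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' Validates the sidecar against the block CSVs: every feature must have a
#' metadata row with a known scale, and block widths must match.
#'
#' @param dir directory containing the cohort files.
#' @return an `ms_cohort`.
#' @export
read_cohort <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  sidecar_path <- file.path(dir, "features.tsv")
  labels_path <- file.path(dir, "labels.csv")
  if (!file.exists(sidecar_path) || !file.exists(labels_path)) {
    stop("directory ", dir, " does not contain a cohort ",
         "(features.tsv / labels.csv missing)")
  }
  meta_all <- utils::read.table(sidecar_path, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE,
                                colClasses = c(feature = "character",
                                               block = "character",
                                               scale = "character",
                                               levels = "integer",
                                               edss_role = "character"),
                                na.strings = "NA")
  labels <- utils::read.csv(labels_path)
  block_files <- list.files(dir, pattern = "\\.csv$", full.names = FALSE)
  block_files <- setdiff(block_files, "labels.csv")
  if (!length(block_files)) stop("directory ", dir, " contains no block CSVs")
  blocks <- list()
  for (f in block_files) {
    b <- sub("\\.csv$", "", f)
    df <- utils::read.csv(file.path(dir, f), check.names = FALSE,
                          colClasses = "character")
    values <- vapply(df, function(col) {
      col[col == ""] <- NA_character_
      as.numeric(col)
    }, numeric(nrow(df)))
    if (nrow(df) == 1L) values <- matrix(values, 1, dimnames = list(NULL, names(df)))
    colnames(values) <- names(df)
    bm <- meta_all[meta_all$block == b, , drop = FALSE]
    missing_meta <- setdiff(colnames(values), bm$feature)
    if (length(missing_meta)) {
      stop("sidecar has no metadata for feature(s) ",
           paste(missing_meta, collapse = ", "), " of block ", b)
    }
    if (nrow(bm) != ncol(values)) {
      stop("sidecar width mismatch for block ", b, ": ", nrow(bm),
           " metadata rows vs ", ncol(values), " columns")
    }
    if (any(is.na(bm$scale) | bm$scale == "")) {
      stop("sidecar lacks a scale for feature(s) ",
           paste(bm$feature[is.na(bm$scale) | bm$scale == ""], collapse = ", "))
    }
    blocks[[b]] <- feature_table(values, is.na(values), bm)
  }
  spec <- NULL
  spec_path <- file.path(dir, "spec.json")
  if (file.exists(spec_path)) {
    e <- jsonlite::read_json(spec_path, simplifyVector = TRUE)
    spec <- cohort_spec(
      n_samples = e$n_samples,
      faller_prevalence = e$faller_prevalence,
      beta = e$beta,
      block_widths = unlist(e$block_widths),
      informative_features = unlist(e$informative_features),
      ordinal_levels = if (length(e$ordinal_levels)) unlist(e$ordinal_levels) else NULL,
      missingness = if (length(e$missingness)) e$missingness else NULL,
      seed = e$seed)
  }
  order_hint <- intersect(c(names(canonical_block_widths()),
                            sort(names(blocks))), names(blocks))
  blocks <- blocks[unique(c(order_hint, names(blocks)))]
  structure(list(blocks = blocks, y = as.integer(labels$y),
                 severity = as.numeric(labels$severity), spec = spec),
            class = "ms_cohort")
}
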