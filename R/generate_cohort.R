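#' Derive an EDSS-like total score from the eight functional-system scores
#'
#' Deterministic monotone surrogate for the clinical scoring rules: with the
#' functional scores expressed on their clinical 0-based scale
#' (`code - 1`), the total is the maximum functional score plus half a point
#' for every further score of at least 2, i.e.
#' `max(v) + 0.5 * max(0, sum(v >= 2) - 1)`. It is a documented stand-in,
#' not the certified Neurostatus algorithm, but it is monotone in every
#' functional score and is applied consistently by the generator and the
#' knowledge-based imputer.
#'
#' @param codes numeric matrix (or vector) of functional-score codes in
#'   `1..levels`; rows are subjects.
#' @return numeric vector of total scores on the clinical 0-based scale.
#' @export
edss_total_from_functional <- function(codes) {
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = 1)
  v <- codes - 1
  apply(v, 1, function(r) max(r) + 0.5 * max(0, sum(r >= 2) - 1))
}

# Cut a latent continuous variable into L equiprobable ordinal codes 1..L.
cut_to_ordinal <- function(z, levels, sd_z) {
  breaks <- c(-Inf, stats::qnorm(seq_len(levels - 1) / levels, sd = sd_z), Inf)
  as.integer(cut(z, breaks = breaks, labels = FALSE))
}

block_feature_names <- function(block, width) {
  switch(block,
    Basic = c("T25FW", "TwoMWT", edss_functional_names(), "EDSS_Score"),
    EDSS = c(edss_functional_names(), "EDSS_Score"),
    MSWS12 = paste0("Q", seq_len(width), "_MSWS12"),
    EMIQ = paste0("Q", seq_len(width), "_EMIQ"),
    sprintf("%s_%03d", block, seq_len(width))
  )
}

#' Generate a synthetic multi-block gait cohort
#'
#' Draws a cohort from the single-latent-factor model described in
#' [cohort_spec()]: latent severity per subject, a Bernoulli fall label
#' whose log-odds are linear in severity, informative features as noisy
#' severity readouts, noise features otherwise, equiprobable-threshold
#' ordinal items, a derived EDSS-like total score
#' ([edss_total_from_functional()]), and blockwise MCAR-plus-severity
#' missingness. Generation is fully deterministic given the spec (which
#' includes the seed); the caller's RNG state is left untouched.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `ms_cohort`: a list with `blocks` (named list
#'   of [feature_table()]s, one per block; the EDSS block is a column view of
#'   Basic), `y` (integer 0/1 labels, 1 = faller), `severity` (latent
#'   severity, kept for diagnostics), and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  n <- spec$n_samples
  s <- stats::rnorm(n)
  alpha <- solve_label_intercept(spec$faller_prevalence, spec$beta)
  y <- stats::rbinom(n, 1L, stats::plogis(alpha + spec$beta * s))
  if (length(unique(y)) < 2L) {
    stop("degenerate cohort: only one class drawn; increase n_samples")
  }

  loadings <- spec$informative_features
  gen_blocks <- setdiff(names(spec$block_widths), "EDSS")
  blocks <- list()
  for (b in gen_blocks) {
    width <- spec$block_widths[[b]]
    feats <- block_feature_names(b, width)
    values <- matrix(NA_real_, n, width, dimnames = list(NULL, feats))
    meta <- data.frame(feature = feats, block = b, scale = "metric",
                       levels = NA_integer_, edss_role = "none",
                       stringsAsFactors = FALSE)
    for (j in seq_along(feats)) {
      f <- feats[j]
      if (f == "EDSS_Score") next  # derived below
      lambda <- if (f %in% names(loadings)) loadings[[f]] else 0
      z <- lambda * s + stats::rnorm(n)
      lv <- spec$ordinal_levels[f]
      if (!is.na(lv)) {
        values[, j] <- cut_to_ordinal(z, as.integer(lv),
                                      sd_z = sqrt(lambda^2 + 1))
        meta$scale[j] <- "ordinal"
        meta$levels[j] <- as.integer(lv)
      } else {
        values[, j] <- z
      }
    }
    if ("EDSS_Score" %in% feats) {
      fs <- edss_functional_names()
      values[, "EDSS_Score"] <-
        edss_total_from_functional(values[, fs, drop = FALSE])
      j <- match("EDSS_Score", feats)
      meta$scale[j] <- "ordinal"          # quasi-metric ordered score
      meta$levels[j] <- NA_integer_       # half-step scale, no fixed code range
      meta$edss_role[j] <- "total"
      meta$edss_role[match(fs, feats)] <- "functional"
    }
    miss <- spec$missingness[[b]]
    if (is.null(miss)) miss <- list(mcar = 0, slope = 0)
    p_miss <- pmin(0.95, pmax(0, miss$mcar + stats::plogis(miss$slope * s) - 0.5))
    mask <- matrix(stats::runif(n * width) < rep(p_miss, width), n, width,
                   dimnames = list(NULL, feats))
    blocks[[b]] <- feature_table(values, mask, meta)
  }
  if ("EDSS" %in% names(spec$block_widths)) {
    edss_feats <- block_feature_names("EDSS", spec$block_widths[["EDSS"]])
    edss <- ft_subset(blocks[["Basic"]], features = edss_feats)
    edss$meta$block <- "EDSS"
    blocks <- append(blocks, list(EDSS = edss), after = match("Basic", names(blocks)))
  }
  structure(list(blocks = blocks, y = as.integer(y), severity = s, spec = spec),
            class = "ms_cohort")
}

#' @export
print.ms_cohort <- function(x, ...) {
  cat(sprintf("<ms_cohort> %d subjects, %d fallers (%.1f%%), %d blocks\n",
              length(x$y), sum(x$y), 100 * mean(x$y), length(x$blocks)))
  invisible(x)
}

#' Assemble one of the analysis data sets from a cohort
#'
#' `"All"` concatenates every block except EDSS (whose columns are already
#' part of Basic); any other name returns that block. Subjects missing an
#' entire constituent block are dropped from that data set's analysis only
#' (complete-case per data set), so each data set can have its own sample
#' size, as in real multi-instrument cohorts where not every assessment is
#' available for every patient.
#'
#' @param cohort an `ms_cohort`.
#' @param name one of [dataset_names()] (or any block name of a custom
#'   cohort).
#' @param drop_empty_rows drop subjects with an entirely missing block
#'   (default TRUE).
#' @return list with `table` (a [feature_table()]), `y`, and `rows` (the
#'   retained row indices of the cohort).
#' @export
build_dataset <- function(cohort, name, drop_empty_rows = TRUE) {
  stopifnot(inherits(cohort, "ms_cohort"))
  if (name == "All") {
    parts <- cohort$blocks[setdiff(names(cohort$blocks), "EDSS")]
    tab <- ft_cbind(parts)
    block_ok <- vapply(parts, function(t) rowSums(!t$mask) > 0,
                       logical(length(cohort$y)))
    observed <- rowSums(block_ok) == length(parts)
  } else {
    if (!name %in% names(cohort$blocks)) {
      stop("cohort has no block named '", name, "'")
    }
    tab <- cohort$blocks[[name]]
    observed <- rowSums(!tab$mask) > 0
  }
  rows <- seq_along(cohort$y)
  if (drop_empty_rows) {
    rows <- rows[observed]
    tab <- ft_subset(tab, rows = observed)
  }
  list(table = tab, y = cohort$y[rows], rows = rows)
}
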