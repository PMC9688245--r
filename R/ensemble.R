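#' Thresholds and combination rules of the feature-selection ensemble
#'
#' @param threshold fraction of each ranked list to keep: one of
#'   `1.0, 0.50, 0.25, 0.10`. `1.0` is the no-selection baseline.
#' @param combination one of `"union"`, `"union2"`, `"union3"`,
#'   `"intersection"`; ignored (and stored as `NA`) at threshold 1.0.
#' @return an object of class `ensemble_config`.
#' @export
ensemble_config <- function(threshold, combination = NULL) {
  allowed_t <- c(1.0, 0.50, 0.25, 0.10)
  if (!isTRUE(any(abs(threshold - allowed_t) < 1e-12))) {
    stop("threshold must be one of 1.0, 0.50, 0.25, 0.10")
  }
  if (abs(threshold - 1.0) < 1e-12) {
    combination <- NA_character_
  } else {
    combination <- match.arg(combination,
                             c("union", "union2", "union3", "intersection"))
  }
  structure(list(threshold = threshold, combination = combination),
            class = "ensemble_config")
}

round_half_away <- function(x) floor(x + 0.5)

#' Keep the top fraction of a ranked list
#'
#' Keeps the top `m` features with `m = max(1, round(threshold * p))`,
#' rounding half away from zero; `threshold = 1` keeps all `p`.
#'
#' @param ranked a `ranked_list`.
#' @param threshold fraction in the allowed set of [ensemble_config()].
#' @return character vector of selected feature names (rank order).
#' @export
apply_threshold <- function(ranked, threshold) {
  stopifnot(inherits(ranked, "ranked_list"), nrow(ranked) >= 1L)
  p <- nrow(ranked)
  if (abs(threshold - 1.0) < 1e-12) return(ranked$feature)
  m <- max(1L, round_half_away(threshold * p))
  ranked$feature[seq_len(min(m, p))]
}

#' Combine four filter subsets into a final subset
#'
#' Membership-count semantics: `union` keeps a feature present in at least
#' one subset, `union2` in at least two, `union3` in at least three,
#' `intersection` in all four. An empty result is allowed but flagged
#' (attribute `empty`), so downstream code can record the configuration as
#' infeasible instead of failing.
#'
#' @param subsets list of exactly four character vectors of feature names.
#' @param combination combination rule.
#' @return an object of class `final_subset`: a list with `features`
#'   (ordered by descending membership count, then name) and `provenance`
#'   (per-feature membership counts over the four filters).
#' @export
combine_subsets <- function(subsets,
                            combination = c("union", "union2", "union3",
                                            "intersection")) {
  combination <- match.arg(combination)
  if (length(subsets) != 4L) stop("exactly four filter subsets are required")
  subsets <- lapply(subsets, unique)
  all_feats <- sort(unique(unlist(subsets)))
  counts <- rowSums(vapply(subsets, function(s) all_feats %in% s,
                           logical(length(all_feats))))
  names(counts) <- all_feats
  need <- switch(combination, union = 1L, union2 = 2L, union3 = 3L,
                 intersection = 4L)
  keep <- all_feats[counts >= need]
  keep <- keep[order(-counts[keep], keep)]
  prov <- data.frame(feature = names(counts), count = as.integer(counts),
                     row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(names(subsets)) && length(all_feats)) {
    for (m in names(subsets)) prov[[m]] <- prov$feature %in% subsets[[m]]
  }
  structure(list(features = keep, provenance = prov,
                 combination = combination),
            class = "final_subset", empty = length(keep) == 0L)
}

#' @export
print.final_subset <- function(x, ...) {
  cat(sprintf("<final_subset> %s: %d feature(s)%s\n", x$combination,
              length(x$features),
              if (attr(x, "empty")) " [EMPTY - infeasible]" else ""))
  if (length(x$features)) cat(paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

#' Run the feature-selection ensemble
#'
#' Rank with all four filter methods, apply the threshold to each ranked
#' list, then combine the four filter subsets — threshold first, combination
#' second. At threshold 1.0 the final subset is simply all features.
#'
#' @param X numeric matrix (samples x features), preprocessed (no missing
#'   cells).
#' @param y binary labels.
#' @param config an [ensemble_config()].
#' @param max_bins,relieff_k,relieff_probes,seed,mrmr_form ranker settings,
#'   see [rank_all()]. The MRMR greedy depth is capped at the per-filter
#'   subset size implied by the threshold (the greedy prefix is all the
#'   threshold can see).
#' @return a `final_subset`.
#' @export
run_fs_ensemble <- function(X, y, config, max_bins = 10L, relieff_k = 10L,
                            relieff_probes = NULL, seed = 1L,
                            mrmr_form = "difference") {
  stopifnot(inherits(config, "ensemble_config"))
  p <- ncol(X)
  if (abs(config$threshold - 1.0) < 1e-12) {
    feats <- colnames(X)
    prov <- data.frame(feature = feats, count = 4L,
                       stringsAsFactors = FALSE)
    return(structure(list(features = feats, provenance = prov,
                          combination = NA_character_),
                     class = "final_subset", empty = p == 0L))
  }
  m <- max(1L, round_half_away(config$threshold * p))
  rankings <- rank_all(X, y, max_bins = max_bins, relieff_k = relieff_k,
                       relieff_probes = relieff_probes, seed = seed,
                       mrmr_max_rank = m, mrmr_form = mrmr_form)
  subsets <- lapply(rankings, apply_threshold, threshold = config$threshold)
  combine_subsets(subsets, config$combination)
}
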