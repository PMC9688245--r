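#' Discretize a numeric vector for the count-based rankers
#'
#' Features with at most `max_bins` distinct values (ordinal codes, binary
#' indicators, standardized Likert items) are used at their native values;
#' anything else is cut into equal-frequency bins at the empirical deciles.
#' Tied quantiles collapse bins, so fewer than `max_bins` bins can result.
#'
#' @param x numeric vector without missing values.
#' @param max_bins maximum number of bins (default 10).
#' @return integer codes in `1..B`.
#' @export
discretize_ef <- function(x, max_bins = 10L) {
  u <- sort(unique(x))
  if (length(u) <= max_bins) {
    return(match(x, u))
  }
  breaks <- unique(stats::quantile(x, probs = seq(0, 1, length.out = max_bins + 1),
                                   names = FALSE, type = 7))
  if (length(breaks) < 2L) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = breaks, include.lowest = TRUE, labels = FALSE))
}

entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

new_ranked_list <- function(feature, score, method, settings = list()) {
  ord <- order(-score, feature, na.last = TRUE)
  # NA scores (features beyond a partial greedy ranking) keep their given order
  if (anyNA(score)) {
    obs <- which(!is.na(score))
    ord <- c(obs[order(-score[obs], feature[obs])], which(is.na(score)))
  }
  out <- data.frame(rank = seq_along(feature),
                    feature = feature[ord],
                    score = score[ord],
                    stringsAsFactors = FALSE)
  structure(out, class = c("ranked_list", "data.frame"),
            method = method, settings = settings)
}

#' @export
print.ranked_list <- function(x, n = 10, ...) {
  cat(sprintf("<ranked_list> method=%s, %d features\n",
              attr(x, "method"), nrow(x)))
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat("...\n")
  invisible(x)
}

check_ranker_input <- function(X, y) {
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  if (anyNA(X)) stop("rankers require a table without missing cells")
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("y must have one label per row of X")
  if (!all(y %in% c(0L, 1L)) || length(unique(y)) < 2L) {
    stop("y must be binary with both classes present")
  }
  y
}

# Discretized codes for every column, as a list plus a dense indicator
# matrix used for vectorized joint counts.
discretize_matrix <- function(X, max_bins) {
  codes <- lapply(seq_len(ncol(X)), function(j) discretize_ef(X[, j], max_bins))
  n_bins <- vapply(codes, max, integer(1))
  offsets <- cumsum(c(0L, n_bins[-length(n_bins)]))
  total <- sum(n_bins)
  n <- nrow(X)
  Z <- matrix(0, n, total)
  idx_col <- unlist(lapply(seq_along(codes), function(j) offsets[j] + codes[[j]]))
  Z[cbind(rep.int(seq_len(n), length(codes)), idx_col)] <- 1
  list(codes = codes, Z = Z, group = rep.int(seq_along(codes), n_bins),
       n_bins = n_bins)
}

# Mutual information (bits) of every discretized feature with one discrete
# target vector, computed in a single cross-product.
mi_all_vs_target <- function(disc, target) {
  n <- nrow(disc$Z)
  lev <- sort(unique(target))
  Tm <- matrix(0, n, length(lev))
  Tm[cbind(seq_len(n), match(target, lev))] <- 1
  C <- crossprod(disc$Z, Tm)                   # total_bins x levels
  pj <- C / n
  plogp <- ifelse(pj > 0, pj * log2(pj), 0)
  h_joint <- -rowsum(rowSums(plogp), disc$group)[, 1]
  pb <- colSums(disc$Z) / n
  h_feat <- -rowsum(ifelse(pb > 0, pb * log2(pb), 0), disc$group)[, 1]
  h_target <- entropy_bits(tabulate(match(target, lev)))
  h_feat + h_target - h_joint
}

#' Rank features by the Pearson chi-square statistic
#'
#' Each feature is scored by `sum((O - E)^2 / E)` over the cells of its
#' discretized-level x label contingency table. Continuous features are
#' discretized into equal-frequency bins ([discretize_ef()]); a feature with
#' a single level scores 0. Ties are broken lexicographically by feature
#' name.
#'
#' @param X numeric matrix (samples x features) with column names, no
#'   missing cells.
#' @param y binary labels (1 = positive class).
#' @param max_bins bins for continuous features (default 10).
#' @return a `ranked_list` (best feature first).
#' @export
rank_chi_square <- function(X, y, max_bins = 10L) {
  y <- check_ranker_input(X, y)
  scores <- vapply(seq_len(ncol(X)), function(j) {
    code <- discretize_ef(X[, j], max_bins)
    if (max(code) < 2L) return(0)
    O <- table(code, y)
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    sum((O - E)^2 / E)
  }, numeric(1))
  new_ranked_list(colnames(X), scores, "chi_square",
                  list(max_bins = max_bins))
}

#' Rank features by information gain
#'
#' Score is `H(y) - H(y | X_j)` in bits over the discretized feature; a
#' constant feature scores 0.
#'
#' @inheritParams rank_chi_square
#' @return a `ranked_list`.
#' @export
rank_info_gain <- function(X, y, max_bins = 10L) {
  y <- check_ranker_input(X, y)
  disc <- discretize_matrix(X, max_bins)
  scores <- mi_all_vs_target(disc, y)
  new_ranked_list(colnames(X), unname(scores), "info_gain",
                  list(max_bins = max_bins))
}

#' Rank features by minimum-redundancy maximum-relevance (MRMR)
#'
#' Greedy forward ordering on discretized data: the first feature maximizes
#' `I(X_j; y)`; each following feature maximizes relevance minus the mean
#' mutual information with the already-selected set (the difference form,
#' MID). `form = "quotient"` switches to the MIQ objective
#' `relevance / mean redundancy`. The reported score is the value of the
#' greedy objective at selection time. Ties are broken lexicographically by
#' feature name and counted in the `ties` attribute.
#'
#' With `max_rank < ncol(X)` the greedy ordering stops after `max_rank`
#' selections — the greedy prefix is identical to the full ordering — and
#' the remaining features are appended ordered by relevance with an `NA`
#' score.
#'
#' @inheritParams rank_chi_square
#' @param max_rank number of greedy selection steps (default: all features).
#' @param form `"difference"` (default) or `"quotient"`.
#' @return a `ranked_list` in greedy selection order.
#' @export
rank_mrmr <- function(X, y, max_bins = 10L, max_rank = NULL,
                      form = c("difference", "quotient")) {
  form <- match.arg(form)
  y <- check_ranker_input(X, y)
  p <- ncol(X)
  if (p < 2L) stop("MRMR needs at least two features")
  if (is.null(max_rank)) max_rank <- p
  max_rank <- min(max_rank, p)
  disc <- discretize_matrix(X, max_bins)
  feats <- colnames(X)
  relevance <- unname(mi_all_vs_target(disc, y))

  selected <- integer(0)
  sel_scores <- numeric(0)
  red_sum <- numeric(p)
  remaining <- seq_len(p)
  n_ties <- 0L
  pick_best <- function(obj, cand) {
    best <- max(obj)
    tied <- cand[obj >= best - 1e-12]
    if (length(tied) > 1L) n_ties <<- n_ties + 1L
    tied[order(feats[tied])][1L]
  }
  for (step in seq_len(max_rank)) {
    if (step == 1L) {
      obj <- relevance[remaining]
    } else {
      mean_red <- red_sum[remaining] / length(selected)
      obj <- if (form == "difference") {
        relevance[remaining] - mean_red
      } else {
        relevance[remaining] / pmax(mean_red, .Machine$double.eps)
      }
    }
    j <- pick_best(obj, remaining)
    selected <- c(selected, j)
    sel_scores <- c(sel_scores, obj[match(j, remaining)])
    remaining <- setdiff(remaining, j)
    if (length(remaining) && step < max_rank) {
      red_sum <- red_sum + mi_all_vs_target(disc, disc$codes[[j]])
    }
  }
  if (length(remaining)) {
    tail_ord <- remaining[order(-relevance[remaining], feats[remaining])]
    feature_order <- c(feats[selected], feats[tail_ord])
    score <- c(sel_scores, rep(NA_real_, length(tail_ord)))
  } else {
    feature_order <- feats[selected]
    score <- sel_scores
  }
  if (n_ties > 0L) {
    message("rank_mrmr: ", n_ties,
            " tie(s) broken lexicographically by feature name")
  }
  out <- data.frame(rank = seq_along(feature_order), feature = feature_order,
                    score = score, stringsAsFactors = FALSE)
  structure(out, class = c("ranked_list", "data.frame"), method = "mrmr",
            settings = list(max_bins = max_bins, form = form,
                            max_rank = max_rank),
            ties = n_ties)
}

#' Rank features by ReliefF weights
#'
#' For each probe instance the `k` nearest hits (same class) and `k` nearest
#' misses (other class) are found under Manhattan distance on
#' range-normalized features. Each feature's weight accumulates the mean
#' absolute miss-difference minus the mean absolute hit-difference, divided
#' by the number of probes. With `n_probes = NULL` (default) every instance
#' is a probe and the result is deterministic without randomness; otherwise
#' probes are sampled with the given seed. A class with fewer than `k + 1`
#' members reduces `k` for that class with a warning.
#'
#' @inheritParams rank_chi_square
#' @param k_neighbors neighbors per class (default 10).
#' @param n_probes number of probe instances (default: all).
#' @param seed RNG seed used only when sampling probes.
#' @return a `ranked_list` of ReliefF weights.
#' @export
rank_relieff <- function(X, y, k_neighbors = 10L, n_probes = NULL, seed = 1L) {
  y <- check_ranker_input(X, y)
  n <- nrow(X)
  p <- ncol(X)
  rng <- apply(X, 2, function(col) diff(range(col)))
  Xn <- sweep(X, 2, apply(X, 2, min))
  pos <- rng > 0
  Xn[, pos] <- sweep(Xn[, pos, drop = FALSE], 2, rng[pos], "/")
  Xn[, !pos] <- 0

  class_sizes <- table(factor(y, levels = c(0L, 1L)))
  k_class <- pmin(k_neighbors, as.integer(class_sizes) - 1L)
  names(k_class) <- names(class_sizes)
  if (any(k_class < k_neighbors)) {
    warning("class with fewer than k+1 members; k reduced to ",
            paste(k_class, collapse = "/"))
  }
  if (any(k_class < 1L)) stop("each class needs at least 2 members")

  if (is.null(n_probes) || n_probes >= n) {
    probes <- seq_len(n)
  } else {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    probes <- sort(sample.int(n, n_probes))
  }

  D <- as.matrix(stats::dist(Xn, method = "manhattan"))
  idx_by_class <- split(seq_len(n), y)
  W <- numeric(p)
  for (i in probes) {
    same <- setdiff(idx_by_class[[as.character(y[i])]], i)
    other <- idx_by_class[[as.character(1L - y[i])]]
    kh <- k_class[[as.character(y[i])]]
    km <- min(k_neighbors, length(other))
    # distances rounded so exact ties (common on discrete data) are broken
    # by sample index, independent of floating-point column order
    hits <- same[order(round(D[i, same], 9), same)][seq_len(kh)]
    misses <- other[order(round(D[i, other], 9), other)][seq_len(km)]
    diff_h <- abs(Xn[hits, , drop = FALSE] -
                    matrix(Xn[i, ], kh, p, byrow = TRUE))
    diff_m <- abs(Xn[misses, , drop = FALSE] -
                    matrix(Xn[i, ], km, p, byrow = TRUE))
    W <- W + colMeans(diff_m) - colMeans(diff_h)
  }
  W <- W / length(probes)
  new_ranked_list(colnames(X), W, "relieff",
                  list(k_neighbors = k_neighbors,
                       n_probes = length(probes), seed = seed))
}

#' Run all four filter rankers
#'
#' @inheritParams rank_chi_square
#' @param relieff_k,relieff_probes,seed ReliefF settings.
#' @param mrmr_max_rank optional cap on the MRMR greedy depth.
#' @param mrmr_form MRMR objective form.
#' @return named list of `ranked_list`s
#'   (`chi_square`, `info_gain`, `mrmr`, `relieff`).
#' @export
rank_all <- function(X, y, max_bins = 10L, relieff_k = 10L,
                     relieff_probes = NULL, seed = 1L,
                     mrmr_max_rank = NULL, mrmr_form = "difference") {
  list(chi_square = rank_chi_square(X, y, max_bins),
       info_gain = rank_info_gain(X, y, max_bins),
       mrmr = rank_mrmr(X, y, max_bins, max_rank = mrmr_max_rank,
                        form = mrmr_form),
       relieff = rank_relieff(X, y, k_neighbors = relieff_k,
                              n_probes = relieff_probes, seed = seed))
}
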