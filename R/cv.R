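#' Stratified fold assignment
#'
#' Indices of each class are shuffled and dealt round-robin over the folds,
#' so every fold's class counts differ from perfect proportionality by at
#' most one sample per class.
#'
#' @param y binary labels.
#' @param folds number of folds (default 5).
#' @param seed RNG seed (the caller's RNG state is untouched).
#' @return integer vector of fold ids in `1..folds`, one per sample.
#' @export
stratified_folds <- function(y, folds = 5L, seed = 1L) {
  y <- as.integer(y)
  if (min(table(y)) < folds) {
    stop("each class needs at least `folds` members to stratify")
  }
  assignment <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      assignment[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assignment
}

fold_f1 <- function(family, params, X, y, fold_id) {
  vapply(sort(unique(fold_id)), function(f) {
    train <- fold_id != f
    model <- fit_classifier(family, X[train, , drop = FALSE], y[train], params)
    pred <- predict_classifier(model, X[!train, , drop = FALSE])
    suppressWarnings(compute_metrics(y[!train], pred)[["f1"]])
  }, numeric(1))
}

#' Grid search with stratified cross-validated F1
#'
#' Exhaustively evaluates every candidate of the grid by its mean F1 over
#' stratified folds (the same folds for every candidate) and returns the
#' argmax. Ties are broken toward the earliest candidate, i.e. the simplest
#' model under the documented ordering of [default_grid()].
#'
#' @param family model family.
#' @param X,y training data (no missing cells, standardized).
#' @param grid data frame of candidates (default: [default_grid()]).
#' @param folds number of folds (default 5).
#' @param seed seed for the fold assignment.
#' @return list with `best` (one-row data frame), `results` (the grid with a
#'   `mean_f1` column), and `fold_id`.
#' @export
grid_search_cv <- function(family, X, y, grid = default_grid(family),
                           folds = 5L, seed = 1L) {
  fold_id <- stratified_folds(y, folds, seed)
  mean_f1 <- vapply(seq_len(nrow(grid)), function(i) {
    mean(fold_f1(family, as.list(grid[i, , drop = FALSE]), X, y, fold_id))
  }, numeric(1))
  best_i <- which.max(mean_f1)   # first maximum = simplest candidate
  results <- grid
  results$mean_f1 <- mean_f1
  list(best = grid[best_i, , drop = FALSE], results = results,
       fold_id = fold_id)
}

#' Repeated stratified cross-validation report
#'
#' Runs `repetitions` rounds of stratified k-fold cross-validation, each
#' with a fresh fold assignment derived from `seed + repetition`. Within a
#' repetition the out-of-fold predictions are pooled and the metric set is
#' computed once; the report gives mean and SD of each metric over the
#' repetitions.
#'
#' For leakage-free evaluation pass `prep`: a function of the training row
#' indices returning `list(X = <full n x p matrix>, features = <character>)`,
#' called once per fold with only that fold's training rows — preprocessing
#' statistics (and, if the caller wishes, feature selection) are then
#' re-fitted inside each fold.
#'
#' @param family model family.
#' @param params hyperparameters for the family (e.g. `$best` of
#'   [grid_search_cv()]).
#' @param X numeric matrix; ignored when `prep` is given.
#' @param y binary labels.
#' @param repetitions number of CV repetitions (default 10).
#' @param folds folds per repetition (default 5).
#' @param seed base seed; repetition r uses `seed + r`.
#' @param prep optional per-fold preprocessing/selection hook (see above).
#' @return an object of class `cv_report`: list with `mean`, `sd` (named
#'   metric vectors), `per_rep` (repetitions x metrics matrix), `params`,
#'   `family`, `n_features`, `repetitions`, `folds`, `seed`.
#' @export
repeated_cv_evaluate <- function(family, params, X = NULL, y,
                                 repetitions = 10L, folds = 5L, seed = 1L,
                                 prep = NULL) {
  stopifnot(repetitions >= 1L)
  n <- length(y)
  per_rep <- matrix(NA_real_, repetitions, 5,
                    dimnames = list(NULL, c("f1", "recall", "precision",
                                            "specificity", "kappa")))
  n_features <- if (!is.null(X)) ncol(X) else NA_integer_
  for (r in seq_len(repetitions)) {
    fold_id <- stratified_folds(y, folds, seed + r)
    pred <- integer(n)
    for (f in seq_len(folds)) {
      train <- which(fold_id != f)
      test <- which(fold_id == f)
      if (is.null(prep)) {
        Xf <- X
      } else {
        pp <- prep(train)
        Xf <- pp$X[, pp$features, drop = FALSE]
        n_features <- length(pp$features)
      }
      model <- fit_classifier(family, Xf[train, , drop = FALSE], y[train],
                              params)
      pred[test] <- predict_classifier(model, Xf[test, , drop = FALSE])
    }
    per_rep[r, ] <- suppressWarnings(compute_metrics(y, pred))
  }
  structure(list(mean = colMeans(per_rep),
                 sd = apply(per_rep, 2, stats::sd),
                 per_rep = per_rep,
                 params = params, family = family,
                 n_features = n_features,
                 repetitions = repetitions, folds = folds, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s, %d features, %d x %d-fold CV\n",
              x$family, x$n_features, x$repetitions, x$folds))
  m <- rbind(mean = x$mean, sd = x$sd)
  print(round(m, 4))
  invisible(x)
}
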