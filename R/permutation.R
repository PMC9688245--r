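#' Permutation-test significance of a cross-validated score
#'
#' Compares the observed score of an evaluator (typically the mean
#' cross-validated F1 of a fixed model configuration) with its distribution
#' under random label permutations, which removes any dependency between
#' features and labels. The p-value uses the add-one rule
#' `p = (1 + #\{null >= observed\}) / (n_permutations + 1)`, so it is never
#' exactly zero. Hyperparameters chosen on the observed labels are reused
#' across permutations rather than re-tuned.
#'
#' @param evaluator function `(X, y) -> scalar score`.
#' @param X feature matrix.
#' @param y binary labels.
#' @param n_permutations number of label permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @return an object of class `permutation_result`: list with `observed`,
#'   `null_scores`, `p_value`, `n_permutations`.
#' @export
permutation_test <- function(evaluator, X, y, n_permutations = 1000L,
                             seed = 1L) {
  if (n_permutations < 1L) stop("n_permutations must be at least 1")
  observed <- evaluator(X, y)
  stopifnot(is.numeric(observed), length(observed) == 1L)
  null_scores <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      evaluator(X, y[sample.int(length(y))])
    }, numeric(1))
  })
  p_value <- (1 + sum(null_scores >= observed)) / (n_permutations + 1)
  structure(list(observed = observed, null_scores = null_scores,
                 p_value = p_value, n_permutations = n_permutations),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed=%.4f, p=%.4g (%d permutations)\n",
              x$observed, x$p_value, x$n_permutations))
  invisible(x)
}
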