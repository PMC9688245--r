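#' Binary classification metrics for imbalanced data
#'
#' Computes F1, recall (sensitivity), precision, specificity and Cohen's
#' kappa from the confusion matrix, with the faller class (`1`) as positive.
#' A ratio with a zero denominator (e.g. precision of an all-negative
#' predictor) is returned as 0 with a warning.
#'
#' @param y_true,y_pred equal-length binary vectors (0/1).
#' @return named numeric vector with elements `f1`, `recall`, `precision`,
#'   `specificity`, `kappa`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have the same length")
  }
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  stopifnot(all(y_true %in% 0:1), all(y_pred %in% 0:1))
  tp <- sum(y_true == 1L & y_pred == 1L)
  fp <- sum(y_true == 0L & y_pred == 1L)
  fn <- sum(y_true == 1L & y_pred == 0L)
  tn <- sum(y_true == 0L & y_pred == 0L)
  n <- tp + fp + fn + tn

  safe_ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); returning 0")
      return(0)
    }
    num / den
  }
  precision <- safe_ratio(tp, tp + fp, "precision")
  recall <- safe_ratio(tp, tp + fn, "recall")
  specificity <- safe_ratio(tn, tn + fp, "specificity")
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  p_o <- (tp + tn) / n
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (1 - p_e == 0) {
    warning("kappa undefined (chance agreement 1); returning 0")
    0
  } else {
    (p_o - p_e) / (1 - p_e)
  }
  c(f1 = f1, recall = recall, precision = precision,
    specificity = specificity, kappa = kappa)
}
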