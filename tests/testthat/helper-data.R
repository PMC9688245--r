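# Small fixtures built in code.

# Random integer-coded matrix whose values the equal-frequency discretizer
# passes through unchanged (at most `levels` distinct values per column).
random_discrete_matrix <- function(n, p, levels = 3L, seed = 1L) {
  set.seed(seed)
  X <- matrix(sample.int(levels, n * p, replace = TRUE), n, p)
  colnames(X) <- sprintf("f%02d", seq_len(p))
  X
}

random_labels <- function(n, seed = 1L, prob = 0.4) {
  set.seed(seed)
  y <- rbinom(n, 1, prob)
  # guarantee both classes
  if (sum(y) == 0) y[1] <- 1L
  if (sum(y) == n) y[1] <- 0L
  y
}

# A tiny feature table with a hand-set missingness pattern.
tiny_table <- function() {
  values <- cbind(m1 = c(1, 2, 10, NA, 5),
                  o1 = c(3, 3, 1, 2, NA))
  meta <- data.frame(feature = c("m1", "o1"), block = "b",
                     scale = c("metric", "ordinal"),
                     levels = c(NA, 4L), edss_role = "none",
                     stringsAsFactors = FALSE)
  feature_table(values, is.na(values), meta)
}

# EDSS-style block: 8 functional scores (codes 1..6) plus derived total.
edss_block <- function(codes, total = NULL) {
  stopifnot(ncol(codes) == 8)
  fn <- paste0("EDSS_", c("Visual", "Brainstem", "Pyramidal", "Cerebellar",
                          "Sensory", "Bowel_Bladder", "Cognition_Fatigue",
                          "Ambulation"))
  colnames(codes) <- fn
  if (is.null(total)) total <- edss_total_from_functional(codes)
  values <- cbind(codes, EDSS_Score = total)
  meta <- data.frame(feature = colnames(values), block = "EDSS",
                     scale = "ordinal",
                     levels = c(rep(6L, 8), NA),
                     edss_role = c(rep("functional", 8), "total"),
                     stringsAsFactors = FALSE)
  feature_table(values, is.na(values), meta)
}
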