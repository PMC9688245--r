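# Independent brute-force oracles: direct formula evaluation with explicit
# loops, sharing no code with the package implementations.

oracle_chi2 <- function(x, y) {
  xs <- sort(unique(x))
  ys <- sort(unique(y))
  if (length(xs) < 2L) return(0)
  n <- length(x)
  stat <- 0
  for (a in xs) {
    for (b in ys) {
      O <- sum(x == a & y == b)
      E <- sum(x == a) * sum(y == b) / n
      stat <- stat + (O - E)^2 / E
    }
  }
  stat
}

oracle_entropy <- function(v) {
  h <- 0
  for (a in unique(v)) {
    p <- sum(v == a) / length(v)
    h <- h - p * log2(p)
  }
  h
}

oracle_mi <- function(a, b) {
  h_ab <- 0
  n <- length(a)
  for (u in unique(a)) {
    for (v in unique(b)) {
      p <- sum(a == u & b == v) / n
      if (p > 0) h_ab <- h_ab - p * log2(p)
    }
  }
  oracle_entropy(a) + oracle_entropy(b) - h_ab
}

oracle_info_gain <- function(x, y) oracle_mi(x, y)

# Exhaustive evaluation of the greedy MRMR objective (difference form).
oracle_mrmr_order <- function(X, y) {
  p <- ncol(X)
  feats <- colnames(X)
  rel <- sapply(seq_len(p), function(j) oracle_mi(X[, j], y))
  selected <- integer(0)
  scores <- numeric(0)
  remaining <- seq_len(p)
  while (length(remaining)) {
    obj <- sapply(remaining, function(j) {
      if (!length(selected)) return(rel[j])
      red <- mean(sapply(selected, function(s) oracle_mi(X[, j], X[, s])))
      rel[j] - red
    })
    best <- max(obj)
    tied <- remaining[obj >= best - 1e-12]
    pick <- tied[order(feats[tied])][1]
    scores <- c(scores, obj[match(pick, remaining)])
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  list(order = feats[selected], scores = scores)
}

# Plain-loop ReliefF with the same algorithmic conventions (range
# normalization, manhattan distance, index tie-break, exhaustive probes).
oracle_relieff <- function(X, y, k) {
  n <- nrow(X)
  p <- ncol(X)
  Xn <- X
  for (j in seq_len(p)) {
    r <- max(X[, j]) - min(X[, j])
    Xn[, j] <- if (r > 0) (X[, j] - min(X[, j])) / r else 0
  }
  W <- numeric(p)
  for (i in seq_len(n)) {
    d <- sapply(seq_len(n), function(l) sum(abs(Xn[l, ] - Xn[i, ])))
    same <- setdiff(which(y == y[i]), i)
    other <- which(y != y[i])
    kh <- min(k, length(same))
    km <- min(k, length(other))
    # same tie convention as the implementation: round, then index order
    hits <- same[order(round(d[same], 9), same)][seq_len(kh)]
    misses <- other[order(round(d[other], 9), other)][seq_len(km)]
    for (j in seq_len(p)) {
      W[j] <- W[j] + mean(abs(Xn[misses, j] - Xn[i, j])) -
        mean(abs(Xn[hits, j] - Xn[i, j]))
    }
  }
  W / n
}

oracle_metrics <- function(y_true, y_pred) {
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_along(y_true)) {
    if (y_true[i] == 1 && y_pred[i] == 1) tp <- tp + 1
    if (y_true[i] == 0 && y_pred[i] == 1) fp <- fp + 1
    if (y_true[i] == 1 && y_pred[i] == 0) fn <- fn + 1
    if (y_true[i] == 0 && y_pred[i] == 0) tn <- tn + 1
  }
  n <- length(y_true)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kap <- if (pe < 1) (po - pe) / (1 - pe) else 0
  c(f1 = f1, recall = rec, precision = prec, specificity = spec, kappa = kap)
}

# Membership-count combination by explicit per-feature counting.
oracle_combine <- function(subsets, need) {
  feats <- unique(unlist(subsets))
  keep <- character(0)
  for (f in feats) {
    cnt <- 0
    for (s in subsets) if (f %in% s) cnt <- cnt + 1
    if (cnt >= need) keep <- c(keep, f)
  }
  sort(keep)
}
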