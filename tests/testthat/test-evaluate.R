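test_that("metrics match hand computations and identities", {
  y <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  perfect <- compute_metrics(y, y)
  expect_equal(unname(perfect), rep(1, 5))

  # TP=3 FP=1 FN=1 TN=5: p_o = 0.8, p_e = 0.52, kappa = 0.28/0.48 = 7/12
  y_true <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  y_pred <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  m <- compute_metrics(y_true, y_pred)
  expect_equal(m[["precision"]], 0.75)
  expect_equal(m[["recall"]], 0.75)
  expect_equal(m[["f1"]], 0.75)
  expect_equal(m[["specificity"]], 5 / 6)
  expect_equal(m[["kappa"]], 7 / 12)

  # all-negative prediction on mixed truth
  expect_warning(m0 <- compute_metrics(c(1, 0, 0), c(0, 0, 0)), "precision")
  expect_equal(m0[["recall"]], 0)
  expect_equal(m0[["precision"]], 0)
  expect_equal(m0[["specificity"]], 1)

  expect_error(compute_metrics(c(1, 0), c(1, 0, 0)), "length")
})

test_that("metrics agree with the brute-force confusion-matrix oracle", {
  set.seed(123)
  for (i in 1:300) {
    n <- sample(3:40, 1)
    y_true <- rbinom(n, 1, runif(1, 0.1, 0.9))
    y_pred <- rbinom(n, 1, runif(1, 0.1, 0.9))
    got <- suppressWarnings(compute_metrics(y_true, y_pred))
    want <- oracle_metrics(y_true, y_pred)
    expect_equal(got, want, tolerance = 1e-12)
    # F1 is the harmonic mean of precision and recall where defined
    if (got[["precision"]] + got[["recall"]] > 0) {
      expect_equal(got[["f1"]],
                   2 * got[["precision"]] * got[["recall"]] /
                     (got[["precision"]] + got[["recall"]]))
    }
    expect_gte(got[["kappa"]], -1)
    expect_lte(got[["kappa"]], 1)
  }
})

test_that("stratified folds preserve the class fraction within one sample", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(60:200, 1)
    y <- rbinom(n, 1, runif(1, 0.15, 0.5))
    if (min(table(y)) < 5) next
    fid <- stratified_folds(y, 5, seed)
    expect_setequal(unique(fid), 1:5)
    for (f in 1:5) {
      n_f <- sum(fid == f)
      pos_f <- sum(y[fid == f])
      expect_lte(abs(pos_f - n_f * mean(y)), 1 + 1e-9)
    }
  }
  expect_error(stratified_folds(c(1L, 0L, 0L, 0L, 0L, 0L), 5), "stratify")
})

test_that("grid search returns the argmax and breaks ties to simpler models", {
  set.seed(42)
  # linearly separable data: kNN reaches fold-mean F1 = 1
  n <- 60
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(a = y * 4 + rnorm(n, sd = 0.2), b = rnorm(n))
  gs <- grid_search_cv("knn", X, y, folds = 5, seed = 1)
  expect_equal(max(gs$results$mean_f1), 1.0)

  # singleton grid -> that candidate
  g1 <- data.frame(weights = "uniform", metric = "euclidean", k = 3,
                   stringsAsFactors = FALSE)
  gs1 <- grid_search_cv("knn", X, y, grid = g1, folds = 5, seed = 1)
  expect_identical(gs1$best, g1)

  # two equivalent candidates (inert parameter change on separable data):
  # deterministic tie-break to the first (simpler) candidate, stable reruns
  g2 <- data.frame(weights = c("uniform", "distance"),
                   metric = "euclidean", k = 3, stringsAsFactors = FALSE)
  gs2a <- grid_search_cv("knn", X, y, grid = g2, folds = 5, seed = 7)
  gs2b <- grid_search_cv("knn", X, y, grid = g2, folds = 5, seed = 7)
  expect_identical(gs2a$best$weights, "uniform")
  expect_identical(gs2a, gs2b)
})

test_that("default grids enumerate the documented candidate sets", {
  dt <- default_grid("dt")
  expect_equal(nrow(dt), 2 * 9 * 26)
  expect_setequal(unique(dt$criterion), c("gini", "entropy"))
  expect_equal(range(dt$max_depth), c(2, 10))
  expect_equal(range(dt$min_leaf), c(5, 30))
  knn <- default_grid("knn")
  expect_equal(nrow(knn), 2 * 2 * 9)
  svm <- default_grid("svm")
  expect_equal(nrow(svm), 4 * 6)
  expect_setequal(unique(svm$cost), c(0.1, 1, 10, 100))
  expect_setequal(unique(svm$gamma), 10^(-5:0))
  expect_equal(nrow(default_grid("gnb")), 1)
})

test_that("each classifier family fits, predicts, and separates easy data", {
  set.seed(11)
  n <- 80
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(a = y * 3 + rnorm(n, sd = 0.3), b = rnorm(n))
  params <- list(gnb = list(),
                 dt = list(criterion = "gini", max_depth = 3, min_leaf = 5),
                 knn = list(weights = "distance", metric = "manhattan", k = 5),
                 svm = list(cost = 10, gamma = 0.1))
  for (fam in names(params)) {
    model <- fit_classifier(fam, X, y, params[[fam]])
    pred <- predict_classifier(model, X)
    expect_true(all(pred %in% 0:1), info = fam)
    expect_gte(suppressWarnings(compute_metrics(y, pred)[["f1"]]), 0.9)
  }
})

test_that("repeated CV is reproducible and degenerates to SD 0 on fixed folds", {
  set.seed(2)
  n <- 100
  y <- rbinom(n, 1, 0.3)
  X <- cbind(a = y + rnorm(n), b = rnorm(n))
  r1 <- repeated_cv_evaluate("gnb", list(), X, y, repetitions = 3, seed = 5)
  r2 <- repeated_cv_evaluate("gnb", list(), X, y, repetitions = 3, seed = 5)
  expect_identical(r1, r2)
  expect_true(all(r1$sd >= 0))
  expect_true(all(r1$mean >= -1 & r1$mean <= 1))

  # single repetition pools one fold assignment; repeating the identical
  # evaluation leaves nothing to vary
  per <- replicate(3, repeated_cv_evaluate("gnb", list(), X, y,
                                           repetitions = 1,
                                           seed = 9)$mean[["f1"]])
  expect_equal(sd(per), 0)
})

test_that("permutation test obeys the add-one rule at its boundaries", {
  # evaluator that always prefers the true labels: observed beats all nulls
  X <- matrix(0, 40, 1, dimnames = list(NULL, "f"))
  y <- rep(c(0L, 1L), 20)
  ev_true <- function(Xe, ye) if (identical(ye, y)) 1 else 0
  pt <- permutation_test(ev_true, X, y, n_permutations = 1000, seed = 1)
  expect_equal(pt$p_value, 1 / 1001)

  # constant evaluator: every null ties the observed score -> p = 1
  ev_const <- function(Xe, ye) 0.5
  pt2 <- permutation_test(ev_const, X, y, n_permutations = 200, seed = 1)
  expect_equal(pt2$p_value, 1.0)

  expect_error(permutation_test(ev_const, X, y, n_permutations = 0), "least")
})
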