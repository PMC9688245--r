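#' Model families and their hyperparameter grids
#'
#' The four reference classifiers: Gaussian naive Bayes (`gnb`, no tuned
#' parameters), CART decision tree (`dt`: split criterion gini/entropy,
#' maximum depth 2..10, minimum samples at a leaf 5..30), k-nearest
#' neighbors (`knn`: uniform/distance weights, euclidean/manhattan metric,
#' 2..10 neighbors) and an RBF-kernel support vector machine (`svm`:
#' C in {0.1, 1, 10, 100}, gamma in {1e-5 .. 1}, log-10 steps).
#'
#' Candidates are enumerated from simple to complex, and grid search breaks
#' F1 ties toward the earliest candidate. The simplicity ordering is:
#' decision tree by increasing depth, then decreasing leaf size, gini before
#' entropy; kNN by decreasing neighbor count (smoother first), uniform
#' before distance weights, euclidean before manhattan; SVM by increasing C,
#' then increasing gamma.
#'
#' @param family one of `"gnb"`, `"dt"`, `"knn"`, `"svm"`.
#' @return data frame of hyperparameter candidates, one row each.
#' @export
default_grid <- function(family = c("gnb", "dt", "knn", "svm")) {
  family <- match.arg(family)
  switch(family,
    gnb = data.frame(row.names = "1")[1, 0, drop = FALSE],
    dt = expand.grid(criterion = c("gini", "entropy"),
                     min_leaf = seq(30L, 5L, -1L),
                     max_depth = 2:10,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[
                       , c("criterion", "max_depth", "min_leaf")],
    knn = expand.grid(metric = c("euclidean", "manhattan"),
                      weights = c("uniform", "distance"),
                      k = 10:2,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[
                        , c("weights", "metric", "k")],
    svm = expand.grid(gamma = 10^(-5:0), cost = c(0.1, 1, 10, 100),
                      KEEP.OUT.ATTRS = FALSE)[, c("cost", "gamma")]
  )
}

#' Fit one of the reference classifiers
#'
#' @param family model family, see [default_grid()].
#' @param X numeric training matrix (standardized features).
#' @param y binary training labels.
#' @param params one-row data frame (or list) of hyperparameters for the
#'   family; empty for `gnb`.
#' @return a fitted model object of class `fallfs_model`.
#' @export
fit_classifier <- function(family, X, y, params = list()) {
  family <- match.arg(family, c("gnb", "dt", "knn", "svm"))
  y <- factor(as.integer(y), levels = c(0L, 1L))
  fit <- switch(family,
    gnb = e1071::naiveBayes(x = as.data.frame(X), y = y),
    dt = {
      df <- as.data.frame(X)
      names(df) <- paste0("V", seq_len(ncol(X)))   # rpart-safe names
      df$.y <- y
      split <- if (identical(as.character(params$criterion), "entropy"))
        "information" else "gini"
      rpart::rpart(.y ~ ., data = df, method = "class",
                   parms = list(split = split),
                   control = rpart::rpart.control(
                     maxdepth = params$max_depth,
                     minbucket = params$min_leaf,
                     minsplit = 2L * params$min_leaf,
                     cp = 0, xval = 0))
    },
    knn = list(X = X, y = y, k = params$k,
               weights = as.character(params$weights),
               metric = as.character(params$metric)),
    svm = e1071::svm(X, y, kernel = "radial", cost = params$cost,
                     gamma = params$gamma, scale = FALSE)
  )
  structure(list(family = family, fit = fit, p = ncol(X)),
            class = "fallfs_model")
}

# Weighted kNN prediction (supports manhattan distance and inverse-distance
# weights, which no installed kNN implementation offers together).
predict_knn <- function(fit, X) {
  train <- fit$X
  k <- min(fit$k, nrow(train))
  pow <- if (fit$metric == "euclidean") 2 else 1
  y01 <- as.integer(as.character(fit$y))
  apply(X, 1, function(x) {
    d <- colSums(abs(t(train) - x)^pow)^(1 / pow)
    ord <- order(d, seq_along(d))
    nb <- ord[seq_len(k)]
    if (fit$weights == "uniform") {
      w <- rep(1, k)
    } else if (any(d[nb] == 0)) {
      w <- as.numeric(d[nb] == 0)   # exact matches dominate
    } else {
      w <- 1 / d[nb]
    }
    v1 <- sum(w * (y01[nb] == 1L))
    v0 <- sum(w * (y01[nb] == 0L))
    as.integer(v1 > v0)             # vote tie goes to the majority class
  })
}

#' Predict binary labels with a fitted classifier
#'
#' @param model a `fallfs_model` from [fit_classifier()].
#' @param X numeric matrix of new samples on the training feature scale.
#' @return integer vector of 0/1 predictions.
#' @export
predict_classifier <- function(model, X) {
  stopifnot(inherits(model, "fallfs_model"))
  if (ncol(X) != model$p) stop("feature count differs from training")
  out <- switch(model$family,
    gnb = predict(model$fit, as.data.frame(X)),
    dt = {
      df <- as.data.frame(X)
      names(df) <- paste0("V", seq_len(ncol(X)))
      predict(model$fit, df, type = "class")
    },
    knn = return(predict_knn(model$fit, X)),
    svm = predict(model$fit, X)
  )
  as.integer(as.character(out))
}
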