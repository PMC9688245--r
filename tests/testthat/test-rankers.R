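test_that("chi-square statistic matches hand-computed and degenerate cases", {
  # 2x2 counts [[10,0],[0,10]]: all E = 5, statistic = 4 * 25/5 = 20
  X <- cbind(perfect = rep(c(0, 1), each = 10),
             const = rep(1, 20))
  y <- rep(c(0L, 1L), each = 10)
  r <- rank_chi_square(X, y)
  expect_equal(r$score[r$feature == "perfect"], 20)
  expect_equal(r$score[r$feature == "const"], 0)
  expect_equal(r$feature[1], "perfect")
})

test_that("chi-square of an independent feature stays below the null quantile", {
  set.seed(77)
  n <- 50000
  X <- cbind(noise = rnorm(n))
  y <- rbinom(n, 1, 0.3)
  r <- rank_chi_square(X, y)
  # feature is discretized into 10 bins -> df = (10-1)(2-1) = 9
  expect_lt(r$score[1], qchisq(0.999, df = 9))
})

test_that("information gain matches the entropy formula", {
  # perfect predictor of a balanced label: H(y) = 1 bit, H(y|x) = 0
  X <- cbind(perfect = rep(c(0, 1), each = 8), const = rep(3, 16))
  y <- rep(c(0L, 1L), each = 8)
  r <- rank_info_gain(X, y)
  expect_equal(r$score[r$feature == "perfect"], 1.0)
  expect_equal(r$score[r$feature == "const"], 0.0)

  # 3-level feature, joint counts {(a,0):2,(a,1):2,(b,0):4,(c,1):4}
  x3 <- c(rep("a", 4), rep("b", 4), rep("c", 4))
  y3 <- c(0L, 0L, 1L, 1L, rep(0L, 4), rep(1L, 4))
  X3 <- cbind(f = as.integer(factor(x3)))
  # hand: H(y) = 1; H(y|x) = (4/12)*1 + (4/12)*0 + (4/12)*0 = 1/3
  expect_equal(rank_info_gain(X3, y3)$score[1], 1 - 1 / 3)
})

test_that("MRMR orders a duplicated informative feature after a weak one", {
  set.seed(5)
  n <- 400
  y <- rep(c(0L, 1L), each = n / 2)
  A <- y + rbinom(n, 1, 0.05)          # strongly informative
  B <- ifelse(rbinom(n, 1, 0.7) == 1, y, rbinom(n, 1, 0.5))  # weaker
  X <- cbind(A = A %% 2, A2 = A %% 2, B = B)
  r <- rank_mrmr(X, y)
  # brute-force greedy evaluation agrees
  oracle <- oracle_mrmr_order(X, y)
  expect_identical(r$feature, oracle$order)
  expect_identical(r$feature, c("A", "B", "A2"))
})

test_that("MRMR ties on identical features break lexicographically", {
  x <- rep(c(1, 2), 10)
  X <- cbind(c3 = x, a1 = x, b2 = x)
  y <- rep(c(0L, 1L), 10)
  expect_message(r <- rank_mrmr(X, y), "tie")
  expect_identical(r$feature, c("a1", "b2", "c3"))
})

test_that("MRMR greedy prefix is unchanged by max_rank truncation", {
  X <- random_discrete_matrix(60, 8, levels = 4, seed = 31)
  y <- random_labels(60, seed = 32)
  full <- rank_mrmr(X, y)
  part <- rank_mrmr(X, y, max_rank = 3)
  expect_identical(part$feature[1:3], full$feature[1:3])
  expect_equal(part$score[1:3], full$score[1:3])
  expect_true(all(is.na(part$score[4:8])))
})

test_that("ReliefF rewards a label-copy feature and zeroes constants", {
  # 6-point configuration evaluated by the loop oracle as well
  X <- cbind(copy = c(0, 0, 0, 1, 1, 1),
             noise = c(0.1, 0.9, 0.4, 0.6, 0.2, 0.8),
             const = rep(5, 6))
  y <- c(0L, 0L, 0L, 1L, 1L, 1L)
  r <- rank_relieff(X, y, k_neighbors = 2)
  w <- setNames(r$score, r$feature)
  expect_equal(unname(w["const"]), 0)
  expect_gt(w["copy"], 0)
  expect_identical(r$feature[1], "copy")
  expect_equal(unname(w[c("copy", "noise", "const")]),
               unname(oracle_relieff(X, y, 2)[c(1, 2, 3)]), tolerance = 1e-12)
})

test_that("ReliefF weights under permuted labels scatter around zero", {
  n <- 600
  weights <- c()
  for (seed in 1:20) {
    set.seed(seed)
    X <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(NULL, paste0("f", 1:5)))
    y <- sample(rep(c(0L, 1L), each = n / 2))
    r <- rank_relieff(X, y, k_neighbors = 10)
    weights <- c(weights, r$score)
  }
  # weights scatter around zero: at most a normal-tail fraction beyond 3 SD
  # (SD estimated from the simulation itself), and the grand mean is tiny
  expect_lte(mean(abs(weights) > 3 * sd(weights)), 0.02)
  expect_lt(abs(mean(weights)), 2 * sd(weights))
})

test_that("ReliefF reduces k with a warning when a class is small", {
  X <- cbind(f = c(0, 0, 1, 1, 1, 1, 1, 1))
  y <- c(0L, 0L, rep(1L, 6))
  expect_warning(rank_relieff(X, y, k_neighbors = 5), "reduced")
})

test_that("all four rankers match brute-force scoring on small instances", {
  for (case in 1:8) {
    set.seed(100 + case)
    n <- sample(10:40, 1)
    p <- sample(2:6, 1)
    X <- random_discrete_matrix(n, p, levels = sample(2:4, 1),
                                seed = 100 + case)
    y <- random_labels(n, seed = 200 + case)

    chi <- rank_chi_square(X, y)
    for (f in colnames(X)) {
      expect_equal(chi$score[chi$feature == f], oracle_chi2(X[, f], y),
                   tolerance = 1e-9, info = paste("chi2", case, f))
    }
    ig <- rank_info_gain(X, y)
    for (f in colnames(X)) {
      expect_equal(ig$score[ig$feature == f], oracle_info_gain(X[, f], y),
                   tolerance = 1e-9, info = paste("ig", case, f))
    }
    mr <- rank_mrmr(X, y)
    orc <- oracle_mrmr_order(X, y)
    expect_identical(mr$feature, orc$order, info = paste("mrmr", case))
    expect_equal(mr$score, orc$scores, tolerance = 1e-9,
                 info = paste("mrmr scores", case))
    rf <- rank_relieff(X, y, k_neighbors = 3)
    w_oracle <- oracle_relieff(X, y, 3)
    expect_equal(setNames(rf$score, rf$feature)[colnames(X)],
                 setNames(w_oracle, colnames(X)), tolerance = 1e-9,
                 info = paste("relieff", case))
  }
})

test_that("shuffling feature columns permutes every ranking identically", {
  X <- random_discrete_matrix(50, 6, levels = 4, seed = 7)
  y <- random_labels(50, seed = 8)
  perm <- c(4, 1, 6, 3, 2, 5)
  Xp <- X[, perm]
  for (fun in list(rank_chi_square, rank_info_gain,
                   function(a, b) rank_mrmr(a, b),
                   function(a, b) rank_relieff(a, b, k_neighbors = 3))) {
    r1 <- fun(X, y)
    r2 <- fun(Xp, y)
    expect_identical(r1$feature, r2$feature)
    expect_equal(r1$score, r2$score, tolerance = 1e-12)
  }
})

test_that("a strongly planted feature is ranked first by all four methods", {
  firsts <- matrix(FALSE, 40, 4,
                   dimnames = list(NULL, c("chi_square", "info_gain",
                                           "mrmr", "relieff")))
  for (i in 1:40) {
    spec <- cohort_spec(n_samples = 1240, block_widths = c(blk = 51),
                        informative_features = c(blk_001 = 2),
                        seed = 300 + i)
    cohort <- generate_cohort(spec)
    d <- build_dataset(cohort, "blk")
    X <- suppressWarnings(preprocess(d$table))$matrix
    rk <- rank_all(X, d$y, mrmr_max_rank = 1, seed = i)
    for (m in colnames(firsts)) {
      firsts[i, m] <- rk[[m]]$feature[1] == "blk_001"
    }
  }
  for (m in colnames(firsts)) {
    expect_gte(mean(firsts[, m]), 0.95)
  }
})

test_that("rankers reject missing cells and degenerate labels", {
  X <- cbind(a = c(1, NA, 3), b = c(1, 2, 3))
  expect_error(rank_chi_square(X, c(0L, 1L, 0L)), "missing")
  X2 <- cbind(a = 1:4, b = 4:1)
  expect_error(rank_info_gain(X2, c(1L, 1L, 1L, 1L)), "both classes")
})
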