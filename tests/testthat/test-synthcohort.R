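test_that("default cohort has the canonical multi-block structure", {
  cohort <- generate_cohort(cohort_spec(n_samples = 200, seed = 11))
  widths <- canonical_block_widths()
  expect_setequal(names(cohort$blocks), names(widths))
  for (b in names(widths)) {
    expect_identical(ncol(cohort$blocks[[b]]$values), unname(widths[[b]]))
  }
  # pooled non-EDSS blocks carry exactly 428 feature columns
  all_tab <- build_dataset(cohort, "All", drop_empty_rows = FALSE)$table
  expect_identical(ncol(all_tab$values), 428L)
  # the EDSS block is a column view of Basic (same values, same mask)
  basic <- cohort$blocks$Basic
  edss <- cohort$blocks$EDSS
  expect_true(all(colnames(edss$values) %in% colnames(basic$values)))
  expect_identical(edss$values, basic$values[, colnames(edss$values)])
})

test_that("generation is deterministic and label classes are both present", {
  spec <- cohort_spec(n_samples = 150, seed = 42)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$blocks, b$blocks)
  expect_identical(a$y, b$y)
  expect_gt(sum(a$y), 0)
  expect_gt(sum(1 - a$y), 0)
})

test_that("zero missingness rates give an all-observed cohort", {
  blocks <- names(canonical_block_widths())
  miss <- stats::setNames(
    rep(list(list(mcar = 0, slope = 0)), length(blocks) - 1L),
    setdiff(blocks, "EDSS"))
  cohort <- generate_cohort(cohort_spec(n_samples = 120, missingness = miss,
                                        seed = 5))
  for (b in names(cohort$blocks)) {
    expect_false(any(cohort$blocks[[b]]$mask), info = b)
  }
})

test_that("empirical prevalence matches the target within 3 binomial SE", {
  n <- 20000L
  target <- 0.139
  cohort <- generate_cohort(cohort_spec(
    n_samples = n, block_widths = c(noise = 4),
    informative_features = numeric(0), seed = 9))
  se <- sqrt(target * (1 - target) / n)   # binomial SE ~ 0.00245
  expect_lt(abs(mean(cohort$y) - target), 3 * se)
})

test_that("ordinal items are valid codes and EDSS total obeys the surrogate rule", {
  cohort <- generate_cohort(cohort_spec(n_samples = 100, seed = 3))
  msws <- cohort$blocks$MSWS12
  obs <- msws$values[!msws$mask]
  expect_true(all(obs %in% 1:5))
  emiq <- cohort$blocks$EMIQ$values
  expect_true(all(emiq[!is.na(emiq)] %in% 1:4))
  basic <- cohort$blocks$Basic$values
  fn <- basic[, grep("^EDSS_(?!Score)", colnames(basic), perl = TRUE)]
  complete <- stats::complete.cases(cbind(fn, basic[, "EDSS_Score"]))
  expect_equal(basic[complete, "EDSS_Score"],
               edss_total_from_functional(fn[complete, , drop = FALSE]))
  # surrogate rule, by hand: max + 0.5 per extra score >= 2 (0-based scale)
  expect_equal(edss_total_from_functional(matrix(c(1, 1, 1, 1, 1, 1, 1, 1),
                                                 1)), 0)
  expect_equal(edss_total_from_functional(matrix(c(4, 3, 3, 1, 1, 1, 1, 1),
                                                 1)), 3 + 0.5 * 2)
})

test_that("informative features correlate with the label, noise does not", {
  # point-biserial correlation averaged over seeds: planted (lambda = 1)
  # metric features must exceed noise features
  r_inf <- c()
  r_noise <- c()
  for (seed in 1:20) {
    spec <- cohort_spec(n_samples = 1240,
                        block_widths = c(blk = 10),
                        informative_features = c(blk_001 = 1, blk_002 = 1),
                        seed = seed)
    cohort <- generate_cohort(spec)
    v <- cohort$blocks$blk$values
    r_inf <- c(r_inf, abs(cor(v[, 1:2], cohort$y)))
    r_noise <- c(r_noise, abs(cor(v[, 5:10], cohort$y)))
  }
  expect_gt(mean(r_inf), mean(r_noise))
  expect_gt(mean(r_inf), 0.2)
  expect_lt(mean(r_noise), 0.1)
})

test_that("at zero loading the mutual information with the label vanishes", {
  spec <- cohort_spec(n_samples = 50000, block_widths = c(blk = 6),
                      informative_features = numeric(0), seed = 21)
  cohort <- generate_cohort(spec)
  d <- build_dataset(cohort, "blk")
  X <- suppressWarnings(preprocess(d$table))$matrix
  ig <- rank_info_gain(X, d$y)
  # plug-in MI bias for a 10 x 2 table at n = 50000 is
  # (10-1)(2-1)/(2 n ln 2) ~ 1.3e-4 bits; allow ~10x for estimator spread
  expect_lt(max(ig$score), 1.5e-3)
})

test_that("severity-linked missingness hits more severe subjects", {
  spec <- cohort_spec(n_samples = 4000, block_widths = c(blk = 5),
                      informative_features = numeric(0),
                      missingness = list(blk = list(mcar = 0.02, slope = 1.5)),
                      seed = 8)
  cohort <- generate_cohort(spec)
  mask <- cohort$blocks$blk$mask
  s <- cohort$severity
  masked_any <- rowSums(mask) > 0
  expect_gt(mean(s[masked_any]), mean(s))
})

test_that("cohort round-trips through the CSV directory format", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(cohort_spec(n_samples = 40, seed = 2))
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_setequal(names(back$blocks), names(cohort$blocks))
  for (b in names(cohort$blocks)) {
    expect_identical(back$blocks[[b]]$values, cohort$blocks[[b]]$values,
                     info = b)
    expect_identical(back$blocks[[b]]$mask, cohort$blocks[[b]]$mask, info = b)
    expect_identical(back$blocks[[b]]$meta, cohort$blocks[[b]]$meta, info = b)
  }
  expect_identical(back$y, cohort$y)
  expect_equal(back$severity, cohort$severity)
})

test_that("reading rejects malformed or missing cohort directories", {
  dir <- withr::local_tempdir()
  expect_error(read_cohort(file.path(dir, "nope")), "no such directory")
  expect_error(read_cohort(dir), "features.tsv")
  cohort <- generate_cohort(cohort_spec(n_samples = 20, seed = 4))
  write_cohort(cohort, dir)
  sidecar <- file.path(dir, "features.tsv")
  meta <- read.table(sidecar, sep = "\t", header = TRUE)
  meta$scale[meta$feature == "T25FW"] <- ""
  write.table(meta, sidecar, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(dir), "T25FW")
})

test_that("invalid cohort specifications are rejected", {
  expect_error(cohort_spec(faller_prevalence = 0), "prevalence")
  expect_error(cohort_spec(faller_prevalence = 1.2), "prevalence")
  expect_error(cohort_spec(block_widths = c(a = 0)), "positive")
  expect_error(cohort_spec(block_widths = c(Basic = 12, EDSS = 9, GR_N = 82,
                                            GR_D = 82, ML_N = 84, ML_D = 84,
                                            ML_S_EO = 32, ML_S_EC = 32,
                                            MSWS12 = 12, EMIQ = 9)),
               "canonical")
  expect_error(cohort_spec(informative_features = c(Q1_EMIQ = Inf)),
               "finite")
})
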