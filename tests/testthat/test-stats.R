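test_that("normalize_to_baseline divides by the per-rabbit baseline mean", {
  ds <- data.frame(rabbit_id = 1, region = "MA",
                   day = c(0, 0, 5), is_baseline = c(TRUE, TRUE, FALSE),
                   val = c(10, 10, 12))
  nd <- normalize_to_baseline(ds, "val")
  expect_equal(nd$norm, c(1, 1, 1.2))
  expect_equal(mean(nd$norm[nd$is_baseline]), 1.0)
  ds2 <- rbind(ds, data.frame(rabbit_id = 2, region = "MA", day = 5,
                              is_baseline = FALSE, val = 7))
  expect_error(normalize_to_baseline(ds2, "val"), "no baseline")
  expect_error(normalize_to_baseline(ds, "nope"), "unknown parameter")
})

test_that("remove_outliers applies Tukey fences with type-7 quartiles", {
  r <- remove_outliers(c(1, 2, 3, 4, 100))
  expect_equal(r$removed_indices, 5L)
  expect_equal(r$kept, c(1, 2, 3, 4))
  expect_equal(r$fences, c(2 - 3, 4 + 3)) # Q1 2, Q3 4, 1.5 IQR = 3
  r2 <- remove_outliers(rep(5, 6))
  expect_length(r2$removed_indices, 0)
  r3 <- remove_outliers(c(1, 2, 3))
  expect_true(r3$skipped)
  expect_equal(r3$kept, c(1, 2, 3))
  set.seed(33)
  r4 <- remove_outliers(rnorm(100))
  expect_lte(length(r4$removed_indices), 5)
})

test_that("rm_test chooses RM-ANOVA or Friedman and is calibrated", {
  # identical columns: nothing to test
  m0 <- matrix(rep(c(1, 2, 3, 4, 5), 4), nrow = 5)
  expect_error(rm_test(m0), "degenerate")
  set.seed(11)
  m <- matrix(rnorm(8 * 4, mean = 10), 8, 4)
  res <- rm_test(m)
  expect_true(res$method %in% c("rm_anova", "friedman"))
  expect_true(res$p >= 0 && res$p <= 1)
  # strong late shift is detected decisively
  m2 <- m; m2[, 4] <- m2[, 4] + 10
  expect_lt(rm_test(m2)$p, 1e-3)
  # heavy-tailed data routes to Friedman
  set.seed(12)
  m3 <- matrix(rcauchy(8 * 4), 8, 4)
  expect_equal(rm_test(m3)$method, "friedman")
})

test_that("rm_test type-I error is near nominal under the null", {
  set.seed(123)
  rej <- mean(replicate(300, rm_test(matrix(rnorm(8 * 5), 8, 5))$p < 0.05))
  expect_gte(rej, 0.02); expect_lte(rej, 0.08)
})

test_that("correlate gates Pearson/Spearman on normality", {
  x <- 1:20
  res <- correlate(x, x^3) # monotone, y badly non-normal
  expect_equal(res$method, "spearman")
  expect_equal(res$r, 1.0)
  expect_equal(correlate(x, -(x + exp(x / 5)))$r, -1.0)
  set.seed(4)
  xn <- rnorm(50); yn <- 0.5 * xn + rnorm(50)
  expect_equal(correlate(xn, yn)$method, "pearson")
  expect_error(correlate(rep(1, 10), rnorm(10)), "constant")
  expect_error(correlate(1:3, 2:4), "4")
  # spearman invariant under monotone transforms
  a <- correlate(xn, yn, force_method = "spearman")$r
  b <- correlate(exp(xn), yn^3 * 0 + yn, force_method = "spearman")$r
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("multivariate_fit reports B, beta, R and flags collinearity", {
  set.seed(6)
  X <- matrix(rnorm(100 * 2), 100, 2, dimnames = list(NULL, c("x1", "x2")))
  y <- 2 * X[, 1] - 3 * X[, 2]
  fit <- suppressWarnings(multivariate_fit(X, y)) # exact fit warns in lm
  expect_equal(fit$coefficients$B, c(2, -3), tolerance = 1e-9)
  expect_equal(fit$R, 1.0, tolerance = 1e-9)
  Xd <- cbind(X, x3 = X[, 1])
  expect_error(multivariate_fit(Xd, y), "collinearity")
  Xc <- cbind(X, x3 = 1)
  expect_error(multivariate_fit(Xc, y), "constant")
  # null: standardized betas small, F rarely significant
  set.seed(7)
  nulls <- replicate(60, {
    Xn <- matrix(rnorm(200 * 3), 200, 3)
    fn <- multivariate_fit(Xn, rnorm(200))
    c(maxbeta = max(abs(fn$coefficients$beta)), sig = unname(fn$p) < 0.05)
  })
  expect_gte(mean(nulls["maxbeta", ] < 0.2), 0.9)
  expect_lte(mean(nulls["sig", ]), 0.15)
})

test_that("classify_phase maps trend directions to VRP/VEP/NORMAL", {
  mk <- function(slopes, ps) {
    structure(data.frame(parameter = c("bos", "bot", "fr", "fai", "ri", "ac"),
                         slope = slopes, se = 1, t = slopes, p = ps,
                         n = 50, window_lo = 1, window_hi = 19),
              class = c("trend_summary", "data.frame"))
  }
  expect_equal(as.character(classify_phase(
    mk(c(1, 0, 0, -1, -1, -1), c(0.01, 0.9, 0.9, 0.01, 0.01, 0.01)))), "VRP")
  expect_equal(as.character(classify_phase(
    mk(rep(-1, 6), rep(0.001, 6)))), "VEP")
  expect_equal(as.character(classify_phase(
    mk(rep(0.1, 6), rep(0.5, 6)))), "NORMAL")
  expect_equal(as.character(classify_phase(
    mk(c(1, -1, -1, -1, -1, -1), rep(0.001, 6)))), "INDETERMINATE")
  expect_error(classify_phase(mk(rep(0, 6), rep(1, 6))[-1, ]), "missing")
})

test_that("fit_trends recovers the drift direction on simulated data", {
  ds <- simulate_longitudinal_study(small_config(seed = 19))
  tr <- fit_trends(ds, c("bos", "bot", "fr", "fai", "ri", "ac"), c(1, 19))
  expect_s3_class(tr, "trend_summary")
  expect_gt(tr$slope[tr$parameter == "bos"], 0)
  expect_lt(tr$slope[tr$parameter == "ac"], 0)
  expect_error(fit_trends(ds, "bos", c(1, 2)), ">= 3 timepoints")
})

test_that("run_stats assembles tests, correlations and phases", {
  ds <- simulate_longitudinal_study(study_config(seed = 23))
  res <- run_stats(ds, parameters = c("bos", "ri", "ac"),
                   phase_windows = list(c(1, 19), c(20, 28)))
  expect_true(all(c("test", "region", "parameter", "statistic", "p",
                    "method") %in% names(res$tests)))
  expect_equal(sort(unique(res$tests$region)), c("MA", "MT", "MV"))
  expect_equal(res$phases[[1]]$label, "VRP")
  expect_equal(res$phases[[2]]$label, "VEP")
  expect_false(is.null(res$regressions$MA))
})
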