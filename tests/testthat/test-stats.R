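test_that("pearson_r: exact lines, formula oracle, zero-variance guard", {
  expect_equal(pearson_r(1:3, c(2, 4, 6))$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(1:3, c(6, 4, 2))$r, -1, tolerance = 1e-12)
  set.seed(21)
  x <- rnorm(10)
  y <- rnorm(10)
  pr <- pearson_r(x, y)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pr$r, r_direct, tolerance = 1e-12)
  t_stat <- r_direct * sqrt(8 / (1 - r_direct^2))
  expect_equal(pr$p_value, 2 * pt(-abs(t_stat), df = 8), tolerance = 1e-12)
  expect_warning(flat <- pearson_r(rep(1, 5), rnorm(5)), "zero variance")
  expect_true(is.na(flat$r))
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("kendall_tau: perfect orders and tie-corrected oracle", {
  expect_equal(kendall_tau(1:5, c(2, 3, 5, 7, 11))$tau, 1, tolerance = 1e-12)
  expect_equal(kendall_tau(1:5, 5:1)$tau, -1, tolerance = 1e-12)
  x <- c(1, 2, 2, 3, 4, 5)  # one tie in x
  y <- c(2, 1, 4, 3, 6, 5)
  expect_equal(kendall_tau(x, y)$tau, taub_pairs(x, y), tolerance = 1e-12)
  set.seed(22)
  for (i in 1:10) {
    a <- sample(1:4, 12, replace = TRUE)
    b <- sample(1:5, 12, replace = TRUE)
    if (length(unique(a)) > 1 && length(unique(b)) > 1)
      expect_equal(kendall_tau(a, b)$tau, taub_pairs(a, b), tolerance = 1e-12)
  }
  expect_warning(tied <- kendall_tau(rep(2, 6), 1:6), "all-tied")
  expect_true(is.na(tied$tau))
})

test_that("multiple regression: exact fit, null fit, pseudoinverse oracle", {
  x <- seq(0, 5, length.out = 30)
  exact <- suppressWarnings(
    multiple_regression(data.frame(y = 2 * x + 1, x = x), "y", "x"))
  expect_equal(exact$coefficients$estimate, c(1, 2), tolerance = 1e-9)
  expect_equal(exact$r_squared, 1, tolerance = 1e-9)

  set.seed(23)
  null_df <- data.frame(y = rnorm(2000), x1 = rnorm(2000), x2 = rnorm(2000))
  null_fit <- multiple_regression(null_df, "y", c("x1", "x2"))
  expect_lt(null_fit$r_squared, 0.01)

  set.seed(24)
  X <- matrix(rnorm(60 * 3), 60, 3)
  y <- X %*% c(0.5, -1.2, 2) + rnorm(60, sd = 0.3)
  df <- data.frame(y = c(y), a = X[, 1], b = X[, 2], c = X[, 3])
  fit <- multiple_regression(df, "y", c("a", "b", "c"))
  expect_equal(fit$coefficients$estimate, ols_pinv(X, c(y)),
               tolerance = 1e-10)
  # standardized beta = raw beta * sd(x) / sd(y)
  expect_equal(fit$coefficients$std_beta[2],
               fit$coefficients$estimate[2] * sd(df$a) / sd(df$y),
               tolerance = 1e-12)

  df$dup <- df$a * 2
  expect_error(multiple_regression(df, "y", c("a", "b", "dup")),
               "collinear.*dup")
  expect_error(multiple_regression(df, "y", "missing_col"), "not found")
})

test_that("simple linear fit recovers lines and matches the covariance ratio", {
  exact <- simple_linear_fit(1:10, 3 * (1:10) - 2)
  expect_equal(exact$slope, 3, tolerance = 1e-12)
  expect_equal(exact$intercept, -2, tolerance = 1e-12)
  expect_equal(exact$r, 1, tolerance = 1e-12)

  coh <- generate_cohort(cohort_config(n_eyes = 150, efficacy = 1,
                                       noise_sd_1m = 0, noise_sd_3m = 0,
                                       quantize_step = 0, seed = 25))
  x <- coh$rotation_deg
  y <- abs(coh$post3m_cyl_D)
  fit <- simple_linear_fit(x, y)
  expect_equal(fit$slope, cov(x, y) / var(x), tolerance = 1e-12)

  # duplicate x values: regression through the mean response at each x
  dup <- simple_linear_fit(c(1, 1, 2, 2), c(0, 2, 3, 5))
  expect_equal(dup$slope, 3, tolerance = 1e-12)   # means 1 -> 4
  expect_equal(dup$intercept, -2, tolerance = 1e-12)
})

test_that("ROC: hand-counted cases, tie handling, trapezoid and pROC agreement", {
  perfect <- roc_analysis(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$youden_max, 1)
  expect_gt(perfect$optimal_cutoff, 0.2)
  expect_lte(perfect$optimal_cutoff, 0.8)

  crossed <- roc_analysis(c(0.1, 0.2, 0.8, 0.9), c(1, 0, 1, 0))
  expect_equal(crossed$auc, 0.25)

  set.seed(26)
  scores <- round(rnorm(200), 1)  # rounding forces ties
  labels <- rbinom(200, 1, plogis(scores))
  r <- roc_analysis(scores, labels)
  expect_equal(r$auc, auc_pairs(scores, labels), tolerance = 1e-12)
  expect_equal(r$auc, auc_trapezoid(r$sensitivity, r$specificity),
               tolerance = 1e-12)
  expect_true(all(r$sensitivity >= 0 & r$sensitivity <= 1))
  expect_true(all(r$specificity >= 0 & r$specificity <= 1))
  skip_if_not_installed("pROC")
  pr <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)

  expect_error(roc_analysis(1:5, rep(1, 5)), "both classes")
  expect_error(roc_analysis(1:4, c(0, 1, 2, 1)), "0/1")
})

test_that("null-association ROC converges to AUC one half", {
  set.seed(27)
  r <- roc_analysis(rnorm(10000), rbinom(10000, 1, 0.4))
  expect_equal(r$auc, 0.5, tolerance = 0.02)
})

test_that("dichotomization is boundary-inclusive and monotone in the cutoff", {
  expect_equal(dichotomize_residual(0.25), 0L)
  expect_equal(dichotomize_residual(0.50), 1L)
  mags <- c(0.1, 0.25, 0.4, 0.5, 0.5, 0.6, 0.75, 0.9, 1.2, 1.5)
  pos_rate <- vapply(c(0.25, 0.5, 0.75, 1), function(k)
    mean(dichotomize_residual(mags, k)), numeric(1))
  expect_true(all(diff(pos_rate) <= 0))
  expect_equal(dichotomize_residual(astig(-0.75, 10)), 1L)
  expect_error(dichotomize_residual(0.5, cutoff = 0), "positive")
})

test_that("Youden cutoff on a noise-free cohort matches exhaustive labeling", {
  # with noise off, residual = 2 C sin(theta); an eye is positive iff
  # theta >= asin(cutoff / (2 C)); check the ROC cutoff against a
  # brute-force sweep of every candidate threshold
  cfg <- cohort_config(n_eyes = 80, efficacy = 1, noise_sd_1m = 0,
                       noise_sd_3m = 0, quantize_step = 0, seed = 28)
  coh <- generate_cohort(cfg)
  labels <- dichotomize_residual(abs(coh$post3m_cyl_D), 0.5)
  r <- roc_analysis(coh$rotation_deg, labels)
  js <- vapply(r$thresholds, function(t) {
    sens <- mean(coh$rotation_deg[labels == 1] >= t)
    spec <- mean(coh$rotation_deg[labels == 0] < t)
    sens + spec - 1
  }, numeric(1))
  expect_equal(r$youden_max, max(js), tolerance = 1e-12)
  expect_equal(r$optimal_cutoff, r$thresholds[which.max(js)])
})
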