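test_that("threshold sweep reproduces the published category arithmetic", {
  co <- reconstruct_paper_cohort()
  af <- diagnostic_table(co, "af", 0:5)
  expect_equal(af$sensitivity[af$threshold_mm == 0], 8 / 21)
  expect_equal(af$sensitivity_2dp[af$threshold_mm == 0], 0.38)
  expect_equal(af$fpr[af$threshold_mm == 0], 5 / 152)
  expect_equal(af$fpr_2dp[af$threshold_mm == 0], 0.03)
  expect_equal(af$sensitivity_2dp[af$threshold_mm == 5], 1.00)

  sf <- diagnostic_table(co, "safir", 0:5)
  expect_equal(sf$sensitivity[sf$threshold_mm == 0], 15 / 21)
  expect_equal(sf$sensitivity_2dp[sf$threshold_mm == 0], 0.71)
  expect_equal(sf$fpr[sf$threshold_mm == 0], 0)
  expect_equal(sf$sensitivity_2dp[sf$threshold_mm == 5], 1.00)
  expect_equal(sf$fpr[sf$threshold_mm == 5], 73 / 152)
  expect_equal(sf$fpr_2dp[sf$threshold_mm == 5], 0.48)
})

test_that("threshold sweep saturates and is monotone", {
  co <- simulate_cohort(cohort_spec(n = 300, seed = 5))
  dt <- diagnostic_table(co, "af", 0:(max(co$mam_af_mm) + 1))
  last <- nrow(dt)
  expect_equal(dt$sensitivity[last], 1)
  expect_equal(dt$fpr[last], 1)
  expect_true(all(diff(dt$sensitivity) >= 0))
  expect_true(all(diff(dt$fpr) >= 0))

  all_neg <- co; all_neg$ltp <- 0L
  expect_error(diagnostic_table(all_neg, "af"), "non-LTP")
})

test_that("AUC is 1 for perfect separation and 0.5 under independence", {
  co <- data.frame(mam_af_mm = c(-1, 0, 1, 5, 6, 7, 8),
                   ltp = c(1, 1, 1, 0, 0, 0, 0),
                   time_months = 1:7)
  expect_equal(suppressWarnings(roc_auc(co, "af", boot_n = 50, seed = 1))$auc,
               1)

  null <- simulate_cohort(cohort_spec(n = 2000, hr_per_mm = 1, h0 = 0.01,
                                      seed = 77))
  auc0 <- roc_auc(null, "af", boot_n = 50, seed = 1)$auc
  expect_lt(abs(auc0 - 0.5), 0.05)
})

test_that("AUC equals the brute-force Mann-Whitney probability", {
  set.seed(60)
  for (i in 1:10) {
    n <- sample(30:200, 1)
    co <- data.frame(mam_af_mm = sample(-3:10, n, replace = TRUE),
                     ltp = rbinom(n, 1, 0.3), time_months = runif(n, 1, 40))
    if (sum(co$ltp) %in% c(0, n)) next
    r <- roc_auc(co, "af", boot_n = 10, seed = 1)
    expect_equal(r$auc, brute_auc(co$mam_af_mm, co$ltp), tolerance = 1e-12)
    expect_gte(r$auc, r$ci95["low"] - 1e-9)
    expect_lte(r$auc, r$ci95["high"] + 1e-9)
  }
})

test_that("Kaplan-Meier equals the empirical survival without censoring", {
  co <- data.frame(mam_af_mm = rep(2, 20), ltp = 1L,
                   time_months = 1:20)
  km <- suppressWarnings(km_logrank(co, "af"))
  ecdf_surv <- 1 - seq_len(20) / 20
  expect_equal(km$curves$surv, ecdf_surv, tolerance = 1e-12)
  # KM curve starts at 1 after time 0, is non-increasing
  expect_true(all(diff(km$curves$surv) <= 0))
})

test_that("log-rank is null for identical strata and KM medians are correct", {
  base <- data.frame(time_months = rep(c(3, 7, 12, 20, 30), 8),
                     ltp = rep(c(1, 1, 0, 1, 0), 8))
  two <- rbind(transform(base, mam_af_mm = 2),
               transform(base, mam_af_mm = 7))
  km <- suppressWarnings(km_logrank(two, "af"))
  expect_lt(km$chisq, 1e-9)
  expect_gt(km$p_value, 0.99)

  lambda <- 0.05
  set.seed(13)
  co <- data.frame(mam_af_mm = 2, ltp = 1L,
                   time_months = rexp(5000, lambda))
  fit <- suppressWarnings(km_logrank(co, "af"))$fit
  med <- summary(fit)$table["median"]
  expect_lt(abs(med - log(2) / lambda) / (log(2) / lambda), 0.05)
})

test_that("Cox coefficient matches a hand-maximized partial likelihood", {
  co <- data.frame(time_months = c(1, 2, 3), ltp = c(1L, 1L, 0L),
                   mam_af_mm = c(1, 0, 2))
  neg_log_pl <- function(b) {
    x <- co$mam_af_mm
    -(b * x[1] - log(exp(b * x[1]) + exp(b * x[2]) + exp(b * x[3])) +
        b * x[2] - log(exp(b * x[2]) + exp(b * x[3])))
  }
  hand <- stats::optimize(neg_log_pl, c(-10, 10), tol = 1e-10)$minimum
  fit <- suppressWarnings(cox_fit(co, "mam", "af", "univariable"))
  expect_equal(log(fit$hr), hand, tolerance = 1e-6)
})

test_that("Cox fit recovers a strong protective margin effect", {
  co <- simulate_cohort(cohort_spec(n = 1500, hr_per_mm = 0.5, seed = 17))
  fit <- cox_fit(co, "mam", "af", "univariable")
  expect_gt(fit$hr, 0.4)
  expect_lt(fit$hr, 0.6)
  expect_lt(fit$p_value, 1e-6)
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)

  multi <- cox_fit(co, c("mam", "size_cm", "subcapsular"), "af",
                   "multivariable")
  expect_equal(nrow(multi), 3)
  expect_true(all(multi$hr > 0))
})

test_that("ICC(A,1) and difference summaries behave per definition", {
  a <- c(3, 5, 7, 2, 8, 4)
  expect_equal(icc_agreement(a, a)$icc, 1.0)
  expect_equal(icc_agreement(a, a)$median_abs_difference, 0)

  # a constant offset hurts absolute agreement but not consistency
  b <- a + 3
  abs_icc <- icc_agreement(a, b)$icc
  n <- length(a); k <- 2
  x <- cbind(a, b)
  ms <- suppressWarnings(
    anova(stats::aov(val ~ subj + rater,
                     data = data.frame(val = as.vector(x),
                                       subj = factor(rep(1:n, k)),
                                       rater = factor(rep(1:k, each = n))))))
  MSR_o <- ms["subj", "Mean Sq"]; MSC_o <- ms["rater", "Mean Sq"]
  MSE_o <- ms["Residuals", "Mean Sq"]
  consistency <- (MSR_o - MSE_o) / (MSR_o + (k - 1) * MSE_o)
  expect_lt(abs_icc, consistency)

  # worked 3-pair example against the mean-squares formula
  got <- icc_agreement(c(3, 5, 7), c(4, 3, 7))
  expect_equal(got$median_difference, 0)
  expect_equal(got$median_abs_difference, 1)
  x2 <- cbind(c(3, 5, 7), c(4, 3, 7)); n2 <- 3
  ms2 <- anova(stats::aov(val ~ subj + rater,
                          data = data.frame(val = as.vector(x2),
                                            subj = factor(rep(1:n2, 2)),
                                            rater = factor(rep(1:2, each = n2)))))
  MSR2 <- ms2["subj", "Mean Sq"]; MSC2 <- ms2["rater", "Mean Sq"]
  MSE2 <- ms2["Residuals", "Mean Sq"]
  want <- (MSR2 - MSE2) /
    (MSR2 + MSE2 + 2 * (MSC2 - MSE2) / n2)
  expect_equal(got$icc, want, tolerance = 1e-12)
})

test_that("agreement pairs are restricted to the comparable 0-10 mm range", {
  a <- c(-1, 2, 5, 11, 7)
  b <- c(0, 3, 5, 9, 6)
  ag <- icc_agreement(a, b)
  expect_equal(ag$n_pairs, 3)
  expect_equal(ag$n_excluded, 2)
  expect_error(icc_agreement(c(5, 5, 5), c(5, 5, 5)), "zero variance")
})
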