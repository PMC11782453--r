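mam_column <- function(software = c("af", "safir")) {
  software <- match.arg(software)
  paste0("mam_", software, "_mm")
}

# Half-up rounding to `digits` decimals, for table reporting.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Sensitivity / false-positive-rate sweep over margin thresholds
#'
#' For each threshold t, a tumor tests positive when its MAM is strictly
#' below t. Sensitivity is the positive fraction among tumors with local
#' tumor progression (LTP); the false positive rate is the positive fraction
#' among tumors without. Residual-tumor cases enter as the -1 mm sentinel,
#' so the t = 0 row counts exactly the incomplete-coverage class.
#'
#' @param records cohort data.frame ([simulate_cohort()] schema).
#' @param software which software's margin column to use (`"af"` or
#'   `"safir"`).
#' @param thresholds integer thresholds in mm (default 0:10).
#' @return A data.frame of class `diagnostic_table` with columns
#'   `threshold_mm`, `tp`, `fn`, `fp`, `tn`, `sensitivity`, `fpr` (exact
#'   fractions) and `sensitivity_2dp`, `fpr_2dp` (half-up 2-decimal
#'   reporting).
#' @export
diagnostic_table <- function(records, software = c("af", "safir"),
                             thresholds = 0:10) {
  col <- mam_column(match.arg(software))
  mam <- records[[col]]
  ltp <- records$ltp == 1
  if (!any(ltp) || all(ltp))
    stop("need at least one LTP and one non-LTP case to form rates",
         call. = FALSE)
  n_pos <- sum(ltp); n_neg <- sum(!ltp)
  rows <- lapply(thresholds, function(t) {
    pos <- mam < t
    tp <- sum(pos & ltp); fp <- sum(pos & !ltp)
    data.frame(threshold_mm = t, tp = tp, fn = n_pos - tp, fp = fp,
               tn = n_neg - fp,
               sensitivity = tp / n_pos, fpr = fp / n_neg)
  })
  out <- do.call(rbind, rows)
  out$sensitivity_2dp <- round_half_up(out$sensitivity)
  out$fpr_2dp <- round_half_up(out$fpr)
  class(out) <- c("diagnostic_table", "data.frame")
  out
}

#' ROC curve and AUC of margin as an LTP discriminator
#'
#' Treats lower margins as higher risk (score = -MAM) and computes the
#' tie-aware AUC — the trapezoidal area, equal to the normalized
#' Mann-Whitney statistic — with a stratified-bootstrap 95% CI.
#'
#' @inheritParams diagnostic_table
#' @param boot_n bootstrap replicates for the CI (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @param ci_level confidence level (default 0.95).
#' @return A list of class `roc_result`: `auc`, `ci95` (low, high),
#'   `curve` (data.frame `fpr`, `sensitivity`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(records, software = c("af", "safir"), boot_n = 2000L,
                    seed = 20240802L, ci_level = 0.95) {
  col <- mam_column(match.arg(software))
  ltp <- records$ltp
  if (!any(ltp == 1) || all(ltp == 1))
    stop("need at least one LTP and one non-LTP case for ROC analysis",
         call. = FALSE)
  # controls (no LTP) are expected to have the larger margins
  roc <- pROC::roc(response = ltp, predictor = records[[col]],
                   levels = c(0, 1), direction = ">", quiet = TRUE)
  ci <- with_seed(seed,
    pROC::ci.auc(roc, conf.level = ci_level, method = "bootstrap",
                 boot.n = boot_n, boot.stratified = TRUE))
  curve <- data.frame(fpr = 1 - roc$specificities,
                      sensitivity = roc$sensitivities)
  curve <- curve[order(curve$fpr, curve$sensitivity), ]
  structure(list(auc = as.numeric(pROC::auc(roc)),
                 ci95 = c(low = as.numeric(ci[1]), high = as.numeric(ci[3])),
                 curve = curve, n_pos = sum(ltp == 1), n_neg = sum(ltp == 0)),
            class = "roc_result")
}

mam_strata <- function(mam) {
  cut(mam, breaks = c(-Inf, 0, 4.5, Inf),
      labels = c("<=0 mm", "1-4 mm", ">=5 mm"))
}

#' Kaplan-Meier curves and log-rank test across margin strata
#'
#' Stratifies tumors into the three margin classes (MAM <= 0, 1-4 mm,
#' >= 5 mm), estimates LTP-free survival per stratum with the product-limit
#' estimator, and compares strata with the log-rank test. Strata with no
#' tumors are dropped with a warning.
#'
#' @inheritParams diagnostic_table
#' @return A list of class `km_result`: `fit` (a
#'   [survival::survfit()] object), `strata_n`, `chisq`, `df`, `p_value`,
#'   and `curves` (data.frame `stratum`, `time`, `surv`, `n_risk`,
#'   `n_event`).
#' @export
km_logrank <- function(records, software = c("af", "safir")) {
  col <- mam_column(match.arg(software))
  stratum <- mam_strata(records[[col]])
  present <- levels(stratum)[table(stratum) > 0]
  if (length(present) < nlevels(stratum))
    warning("dropping empty margin stratum: ",
            paste(setdiff(levels(stratum), present), collapse = ", "),
            call. = FALSE)
  df <- data.frame(time = records$time_months, event = records$ltp,
                   stratum = factor(as.character(stratum), levels = present))
  fit <- survival::survfit(survival::Surv(time, event) ~ stratum, data = df)
  strata_sizes <- if (is.null(fit$strata)) {
    stats::setNames(length(fit$time), present[1])
  } else stats::setNames(fit$strata, sub("^stratum=", "", names(fit$strata)))
  curves <- data.frame(
    stratum = rep(names(strata_sizes), strata_sizes),
    time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
    n_event = fit$n.event)
  if (length(present) > 1L) {
    lr <- survival::survdiff(survival::Surv(time, event) ~ stratum, data = df)
    chisq <- lr$chisq; dfree <- length(lr$n) - 1L
    p <- stats::pchisq(chisq, dfree, lower.tail = FALSE)
  } else {
    chisq <- NA_real_; dfree <- NA_integer_; p <- NA_real_
  }
  structure(list(fit = fit, strata_n = as.vector(table(df$stratum)),
                 chisq = chisq, df = dfree, p_value = p, curves = curves),
            class = "km_result")
}

#' Cox proportional-hazards models of LTP-free survival
#'
#' Fits Cox models (Efron tie handling) of time to local tumor progression.
#' In univariable mode each covariate is fitted alone; in multivariable
#' mode all covariates enter one model. The margin column of the selected
#' software can be included by naming `"mam"` among the covariates.
#'
#' @inheritParams diagnostic_table
#' @param covariates character vector of cohort column names; the shorthand
#'   `"mam"` resolves to the selected software's margin column.
#' @param mode `"univariable"` or `"multivariable"`.
#' @return A data.frame of class `cox_fit` with one row per term: `term`,
#'   `hr`, `ci_low`, `ci_high`, `p_value`, `loglik`, `n_event`, `mode`.
#' @export
cox_fit <- function(records, covariates = "mam", software = c("af", "safir"),
                    mode = c("univariable", "multivariable")) {
  mode <- match.arg(mode)
  col <- mam_column(match.arg(software))
  covariates[covariates == "mam"] <- col
  missing <- setdiff(covariates, names(records))
  if (length(missing))
    stop("unknown covariate column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  n_event <- sum(records$ltp == 1)
  one_fit <- function(vars) {
    if (n_event < 5L * length(vars))
      warning(sprintf("only %d events for %d covariate(s): estimates may be unstable",
                      n_event, length(vars)), call. = FALSE)
    fml <- stats::as.formula(paste(
      "survival::Surv(time_months, ltp) ~", paste(vars, collapse = " + ")))
    fit <- withCallingHandlers(
      survival::coxph(fml, data = records, ties = "efron",
                      control = survival::coxph.control(iter.max = 100)),
      warning = function(w) {
        # separation ("coefficient may be infinite") is reported, not fatal;
        # a true failure to converge is
        if (grepl("Ran out of iterations", conditionMessage(w)))
          stop("Cox model did not converge for ",
               paste(vars, collapse = " + "), " after maximum iterations",
               call. = FALSE)
      })
    s <- summary(fit)
    data.frame(term = rownames(s$coefficients),
               hr = s$coefficients[, "exp(coef)"],
               ci_low = s$conf.int[, "lower .95"],
               ci_high = s$conf.int[, "upper .95"],
               p_value = s$coefficients[, "Pr(>|z|)"],
               loglik = fit$loglik[2],
               n_event = n_event, mode = mode, row.names = NULL)
  }
  out <- if (mode == "univariable")
    do.call(rbind, lapply(covariates, one_fit))
  else one_fit(covariates)
  class(out) <- c("cox_fit", "data.frame")
  out
}

#' Inter-software agreement: ICC(A,1) and margin differences
#'
#' Two-way random-effects, absolute-agreement, single-measurement
#' intraclass correlation (McGraw & Wong ICC(A,1)) between two software's
#' per-tumor margins, with the F-distribution 95% CI, plus the median
#' (signed) difference and median absolute difference with IQRs. Pairs are
#' restricted to tumors with both margins in the directly comparable 0-10 mm
#' range, since the coverage-style software does not report absolute values
#' outside it.
#'
#' @param a,b numeric margin vectors (mm), paired by tumor. Alternatively
#'   `a` may be a cohort data.frame, in which case the `mam_af_mm` /
#'   `mam_safir_mm` columns are used.
#' @param range length-2 inclusive comparability range (default `c(0, 10)`).
#' @param ci_level confidence level (default 0.95).
#' @return A list of class `agreement_stats`: `icc`, `icc_ci` (low, high),
#'   `median_difference` and `iqr_difference` (a - b), `median_abs_difference`
#'   and `iqr_abs_difference`, `n_pairs`, `n_excluded`.
#' @export
icc_agreement <- function(a, b = NULL, range = c(0, 10), ci_level = 0.95) {
  if (is.data.frame(a)) {
    b <- a$mam_safir_mm
    a <- a$mam_af_mm
  }
  stopifnot(length(a) == length(b))
  keep <- a >= range[1] & a <= range[2] & b >= range[1] & b <= range[2] &
    !is.na(a) & !is.na(b)
  n_excluded <- sum(!keep)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2L) stop("need at least 2 comparable pairs", call. = FALSE)
  k <- 2
  x <- cbind(a, b)
  gm <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  MSR <- k * sum((row_m - gm)^2) / (n - 1)
  MSC <- n * sum((col_m - gm)^2) / (k - 1)
  SSE <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + gm)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  if (denom < 1e-12)
    stop("zero variance across tumors: ICC undefined", call. = FALSE)
  icc <- (MSR - MSE) / denom
  alpha <- 1 - ci_level
  # McGraw & Wong F-based bounds for ICC(A,1)
  aa <- k * icc / (n * (1 - icc))
  bb <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (aa * MSC + bb * MSE)^2 /
    ((aa * MSC)^2 / (k - 1) + (bb * MSE)^2 / (n - 1))
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  hi <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  d <- a - b
  structure(list(icc = icc, icc_ci = c(low = lo, high = hi),
                 median_difference = stats::median(d),
                 iqr_difference = stats::quantile(d, c(.25, .75),
                                                  names = FALSE),
                 median_abs_difference = stats::median(abs(d)),
                 iqr_abs_difference = stats::quantile(abs(d), c(.25, .75),
                                                      names = FALSE),
                 n_pairs = n, n_excluded = n_excluded),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement_stats> n = %d pairs (%d outside 0-10 mm excluded)\n",
              x$n_pairs, x$n_excluded))
  cat(sprintf("  ICC(A,1): %.2f (95%% CI %.2f-%.2f)\n", x$icc,
              x$icc_ci[1], x$icc_ci[2]))
  cat(sprintf("  median difference: %g mm (IQR %g to %g)\n",
              x$median_difference, x$iqr_difference[1], x$iqr_difference[2]))
  cat(sprintf("  median absolute difference: %g mm (IQR %g to %g)\n",
              x$median_abs_difference, x$iqr_abs_difference[1],
              x$iqr_abs_difference[2]))
  invisible(x)
}
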