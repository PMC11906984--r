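## Model adequacy and reliability statistics: normalized quantile residuals
## and their moments, Filliben coefficient, worm plots, Nagelkerke R^2, and
## the two-way mixed-effects ICC for baseline weight reliability.

#' Normalized quantile residuals
#'
#' `r_i = qnorm(F(y_i; mu_i, sigma_i, nu_i, tau_i))` under the fit's family;
#' standard normal when the model is correctly specified. CDF values are
#' clipped to `[1e-12, 1 - 1e-12]` before inversion (a message reports any
#' clipping).
#'
#' @param fit a `gwg_fit`.
#' @param data observations to evaluate; defaults to the training data.
#' @return vector of residuals.
#' @export
quantile_residuals <- function(fit, data = NULL) {
  if (is.null(data)) {
    par <- fit$fitted
    y <- fit$data$gwg_kg + fit$shift_delta
  } else {
    par <- predict_params(fit, data)
    y <- data$gwg_kg + fit$shift_delta
  }
  u <- family_cdf(y, fit$family, par$mu, par$sigma, par$nu, par$tau)
  n_clip <- sum(u < 1e-12 | u > 1 - 1e-12)
  if (n_clip > 0)
    message("quantile_residuals: clipped ", n_clip, " extreme CDF value(s)")
  qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
}

## uniform order-statistic medians (Filliben's approximation)
order_stat_medians <- function(n) {
  i <- seq_len(n)
  m <- (i - 0.3175) / (n + 0.365)
  m[1] <- 1 - 0.5^(1 / n)
  m[n] <- 0.5^(1 / n)
  m
}

#' Moment and normality summary of quantile residuals
#'
#' Mean, variance, coefficient of skewness and coefficient of kurtosis
#' (moment divisor `n`; kurtosis is raw, normal reference 3), plus the
#' Filliben correlation coefficient: the correlation between the sorted
#' residuals and normal quantiles of the uniform order-statistic medians.
#'
#' @param residuals numeric vector, `n >= 8`.
#' @return list of class `residual_summary`.
#' @export
residual_summary <- function(residuals) {
  r <- residuals[is.finite(residuals)]
  n <- length(r)
  if (n < 8) stop_bad("need at least 8 residuals")
  m <- mean(r)
  m2 <- mean((r - m)^2)
  if (m2 == 0) stop_bad("residuals have zero variance")
  out <- list(
    mean = m,
    variance = m2,
    skewness = mean((r - m)^3) / m2^1.5,
    kurtosis = mean((r - m)^4) / m2^2,
    filliben = stats::cor(sort(r), qnorm(order_stat_medians(n))),
    n = n)
  class(out) <- "residual_summary"
  out
}

#' @export
print.residual_summary <- function(x, ...) {
  cat("Quantile-residual summary (n =", x$n, ")\n")
  cat(sprintf("  mean %8.4f   variance %6.4f\n", x$mean, x$variance))
  cat(sprintf("  skewness %6.4f   kurtosis %6.4f   Filliben %7.5f\n",
              x$skewness, x$kurtosis, x$filliben))
  invisible(x)
}

#' Worm plot coordinates
#'
#' Detrended normal Q-Q plot: `x` are the normal quantiles of the uniform
#' order-statistic medians, `y` the sorted residuals minus `x`, and the 95%
#' pointwise band is `+/- 1.96 sqrt(p(1-p)/n) / phi(x)`.
#'
#' @param residuals numeric vector, `n >= 20`.
#' @return data frame with `x`, `y`, `band`.
#' @export
worm_plot_data <- function(residuals) {
  r <- residuals[is.finite(residuals)]
  n <- length(r)
  if (n < 20) stop_bad("need at least 20 residuals for a worm plot")
  p <- order_stat_medians(n)
  x <- qnorm(p)
  data.frame(x = x,
             y = sort(r) - x,
             band = 1.96 * sqrt(p * (1 - p) / n) / dnorm(x))
}

#' Nagelkerke generalised R-squared
#'
#' `R^2 = 1 - exp((2/n) (l0 - l1))` with `l0`, `l1` the maximised
#' log-likelihoods of the intercept-only and fitted model.
#'
#' @param fit fitted `gwg_fit`.
#' @param null_fit intercept-only fit of the same family on the same data;
#'   any object with `logLik` and `n` entries.
#' @export
generalized_r2 <- function(fit, null_fit) {
  if (!isTRUE(all.equal(fit$n, null_fit$n)))
    stop_bad("fit and null_fit must share the same n")
  1 - exp((2 / fit$n) * (null_fit$logLik - fit$logLik))
}

#' Two-way mixed-effects intraclass correlation (single measure)
#'
#' From the two-way ANOVA decomposition of an n-subjects x 2-occasions
#' table: consistency `ICC(C,1) = (MSR - MSE) / (MSR + (k-1) MSE)` and
#' absolute agreement `ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE +
#' (k/n)(MSC - MSE))`, with 95% confidence intervals via the standard
#' F-based formulas (McGraw & Wong). Used here to compare self-reported
#' pre-pregnancy weight with the first measured antenatal weight.
#'
#' @param pairs two-column matrix or data frame, one row per subject.
#' @param conf_level confidence level for the intervals.
#' @return list of class `icc_result` with `icc_consistency`,
#'   `icc_absolute` and their confidence intervals.
#' @export
icc_two_way <- function(pairs, conf_level = 0.95) {
  x <- as.matrix(pairs)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  if (k != 2L) stop_bad("pairs must have exactly two measurement columns")
  if (n < 3L) stop_bad("need at least 3 complete pairs")
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  SSR <- k * sum((row_m - grand)^2)
  SSC <- n * sum((col_m - grand)^2)
  SST <- sum((x - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (MSR <= 0) stop_bad("zero between-subject variance")
  icc_c <- (MSR - MSE) / (MSR + (k - 1) * MSE)
  icc_a <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  alpha <- 1 - conf_level
  # consistency CI
  Fv <- MSR / MSE
  FL <- Fv / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
  FU <- Fv * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
  ci_c <- c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
  # absolute agreement CI (Satterthwaite df)
  a <- k * icc_a / (n * (1 - icc_a))
  b <- 1 + k * icc_a * (n - 1) / (n * (1 - icc_a))
  v <- (a * MSC + b * MSE)^2 /
       ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  Fs <- qf(1 - alpha / 2, n - 1, v)
  Fs2 <- qf(1 - alpha / 2, v, n - 1)
  lower_a <- n * (MSR - Fs * MSE) /
    (Fs * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper_a <- n * (Fs2 * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * Fs2 * MSR)
  out <- list(icc_consistency = icc_c, icc_absolute = icc_a,
              ci_consistency = ci_c, ci_absolute = c(lower_a, upper_a),
              ms = c(MSR = MSR, MSC = MSC, MSE = MSE),
              n = n, conf_level = conf_level)
  class(out) <- "icc_result"
  out
}

#' @export
print.icc_result <- function(x, ...) {
  cl <- round(100 * x$conf_level)
  cat(sprintf("ICC (two-way mixed, single measure), n = %d pairs\n", x$n))
  cat(sprintf("  absolute agreement: %.4f (%d%% CI %.4f to %.4f)\n",
              x$icc_absolute, cl, x$ci_absolute[1], x$ci_absolute[2]))
  cat(sprintf("  consistency:        %.4f (%d%% CI %.4f to %.4f)\n",
              x$icc_consistency, cl, x$ci_consistency[1], x$ci_consistency[2]))
  invisible(x)
}

#' Baseline weight reliability from visit data
#'
#' Pairs each woman's self-reported pre-pregnancy weight with her first
#' measured weight in the 4-10 week window and computes [icc_two_way()].
#'
#' @param visits,cohort the registry tables.
#' @param window gestational-age window for the first measurement.
#' @export
baseline_reliability <- function(visits, cohort, window = c(4, 10)) {
  v <- visits[visits$gest_age_weeks >= window[1] &
              visits$gest_age_weeks <= window[2], , drop = FALSE]
  v <- v[order(v$woman_id, v$gest_age_weeks), , drop = FALSE]
  v <- v[!duplicated(v$woman_id), , drop = FALSE]
  i <- match(v$woman_id, cohort$woman_id)
  icc_two_way(cbind(self_report = cohort$prepreg_weight_kg[i],
                    first_measured = v$weight_kg))
}
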