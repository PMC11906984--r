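# Diagnostics: quantile residuals, moment/normality summaries, worm plots,
# generalised R-squared and the two-way ICC.

test_that("quantile residuals of a NO intercept fit are standardised residuals", {
  set.seed(1)
  d <- data.frame(gwg_kg = rnorm(500, 4, 1.5), gest_age = runif(500, 4, 42))
  f <- suppressWarnings(fit_gamlss(d, model_spec(
    "NO", mu = param_terms(~1), sigma = param_terms(~1),
    control = engine_control(tol = 1e-10, max_outer = 300))))
  r <- quantile_residuals(f)
  yb <- mean(d$gwg_kg); s <- sqrt(mean((d$gwg_kg - yb)^2))
  expect_equal(r, (d$gwg_kg - yb) / s, tolerance = 1e-6)
  # an observation exactly at its fitted median has residual ~ 0
  d2 <- rbind(d, data.frame(gwg_kg = f$fitted$mu[1], gest_age = 20))
  expect_lt(abs(quantile_residuals(f, d2)[501]), 1e-10)
  # probability-integral-transform definition check
  u <- family_cdf(d$gwg_kg, "NO", f$fitted$mu, f$fitted$sigma)
  expect_equal(r, qnorm(u), tolerance = 1e-12)
})

test_that("residual summary matches a direct brute-force computation", {
  r <- c(-1.3, -0.7, -0.2, 0, 0.1, 0.4, 0.8, 1.1, 1.9, 2.5)
  s <- residual_summary(r)
  n <- 10; m <- sum(r) / n
  m2 <- sum((r - m)^2) / n
  expect_equal(s$mean, m)
  expect_equal(s$variance, m2)
  expect_equal(s$skewness, (sum((r - m)^3) / n) / m2^1.5)
  expect_equal(s$kurtosis, (sum((r - m)^4) / n) / m2^2)
  i <- 1:n
  mm <- (i - 0.3175) / (n + 0.365)
  mm[1] <- 1 - 0.5^(1 / n); mm[n] <- 0.5^(1 / n)
  expect_equal(s$filliben, cor(sort(r), qnorm(mm)))
  expect_error(residual_summary(r[1:5]), "at least 8")
  expect_error(residual_summary(rep(1, 10)), "zero variance")
})

test_that("Filliben is exactly 1 for residuals at the order-statistic medians", {
  n <- 50
  r <- qnorm(gwgtraj:::order_stat_medians(n))
  expect_equal(residual_summary(r)$filliben, 1, tolerance = 1e-12)
})

test_that("kurtosis of a standard normal sample is near 3", {
  set.seed(3)
  s <- residual_summary(rnorm(1e4))
  expect_gt(s$kurtosis, 2.8); expect_lt(s$kurtosis, 3.2)
  expect_equal(s$variance, 1, tolerance = 0.05)
})

test_that("worm plot coordinates and band behave as defined", {
  n <- 25
  p <- gwgtraj:::order_stat_medians(n)
  r <- qnorm(p)[sample(n)]          # exactly the medians, shuffled
  wp <- worm_plot_data(r)
  expect_lt(max(abs(wp$y)), 1e-12)
  expect_equal(wp$x, qnorm(p))
  expect_equal(wp$band, 1.96 * sqrt(p * (1 - p) / n) / dnorm(qnorm(p)))
  half <- floor(n / 2)
  expect_true(all(diff(wp$band[1:half]) < 0))           # shrinks to centre
  expect_true(all(diff(wp$band[(n - half + 1):n]) > 0)) # grows to the tail
  expect_error(worm_plot_data(rnorm(10)), "at least 20")
})

test_that("generalised R-squared follows the Nagelkerke formula", {
  fake <- function(ll, n) list(logLik = ll, n = n)
  expect_equal(generalized_r2(fake(-100, 100), fake(-150, 100)),
               1 - exp(-1), tolerance = 1e-6)
  expect_identical(generalized_r2(fake(-42, 50), fake(-42, 50)), 0)
  expect_error(generalized_r2(fake(-1, 10), fake(-1, 11)), "same n")
  # oracle on a real NO fit: likelihood ratio from lm logLik
  set.seed(4)
  d <- data.frame(gwg_kg = rnorm(200, 1, 1) + 0.2 * (1:200) / 50,
                  gest_age = (1:200) / 5 + 4)
  f <- fit_baseline(d, "linear", formula = ~gest_age)
  null <- gwgtraj:::fit_null(f)
  r2 <- generalized_r2(f, null)
  y <- d$gwg_kg
  ll1 <- sum(dnorm(y, fitted(lm(y ~ d$gest_age)),
                   sqrt(mean(resid(lm(y ~ d$gest_age))^2)), log = TRUE))
  ll0 <- sum(dnorm(y, mean(y), sqrt(mean((y - mean(y))^2)), log = TRUE))
  expect_equal(r2, 1 - exp((2 / 200) * (ll0 - ll1)), tolerance = 1e-8)
})

test_that("two-way ICC matches an aov-based mean-squares oracle", {
  set.seed(5)
  x <- matrix(rnorm(12, 70, 5), ncol = 2)
  x[, 2] <- x[, 1] + rnorm(6, 0.5, 1)
  res <- icc_two_way(x)
  long <- data.frame(y = c(x), subj = factor(rep(1:6, 2)),
                     occ = factor(rep(1:2, each = 6)))
  ms <- summary(aov(y ~ subj + occ, long))[[1]][["Mean Sq"]]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]; n <- 6; k <- 2
  expect_equal(res$icc_consistency, (MSR - MSE) / (MSR + MSE), tolerance = 1e-10)
  expect_equal(res$icc_absolute,
               (MSR - MSE) / (MSR + MSE + (k / n) * (MSC - MSE)),
               tolerance = 1e-10)
})

test_that("ICC definitional contrasts and invariances hold", {
  set.seed(6)
  a <- rnorm(30, 70, 6)
  same <- icc_two_way(cbind(a, a))
  expect_equal(same$icc_consistency, 1)
  expect_equal(same$icc_absolute, 1)
  off <- icc_two_way(cbind(a, a + 3))
  expect_equal(off$icc_consistency, 1)
  expect_lt(off$icc_absolute, 1)
  # common rescaling leaves both unchanged; shifting one column only
  # affects absolute agreement. A systematic occasion offset keeps
  # MSC >= MSE so consistency >= absolute holds (it can reverse by a hair
  # when the occasion mean square falls below the error mean square).
  noisy <- cbind(a, a + 0.8 + rnorm(30, 0, 1))
  r1 <- icc_two_way(noisy)
  r2 <- icc_two_way(noisy * 3.7)
  expect_equal(r1$icc_consistency, r2$icc_consistency, tolerance = 1e-12)
  expect_equal(r1$icc_absolute, r2$icc_absolute, tolerance = 1e-12)
  r3 <- icc_two_way(cbind(noisy[, 1], noisy[, 2] + 5))
  expect_equal(r3$icc_consistency, r1$icc_consistency, tolerance = 1e-12)
  expect_lt(r3$icc_absolute, r1$icc_absolute)
  expect_gte(r1$icc_consistency, r1$icc_absolute)
  expect_true(all(r1$ci_consistency <= 1) && all(r1$ci_absolute <= 1))
  expect_error(icc_two_way(cbind(rep(1, 5), rep(1, 5))), "between-subject")
  expect_error(icc_two_way(noisy[1:2, ]), "at least 3")
})

test_that("baseline reliability on synthetic data shows high agreement", {
  sim <- small_registry(n_women = 2000, seed = 9)
  res <- baseline_reliability(sim$visits, sim$cohort)
  # self-report error 0.7 kg against weight SD ~ 10 kg: ICC should be high
  expect_gt(res$icc_consistency, 0.95)
  expect_gt(res$icc_absolute, 0.9)
  expect_lt(res$ci_absolute[1], res$icc_absolute)
})

test_that("residuals of a correctly specified BCT fit pass KS across seeds", {
  pvals <- vapply(1:10, function(s) {
    d <- bct_sim(5000, seed = 100 + s)
    f <- suppressWarnings(fit_gamlss(d, recovery_spec(tol = 1e-3,
                                                      max_outer = 60)))
    suppressWarnings(ks.test(quantile_residuals(f), "pnorm"))$p.value
  }, 0)
  expect_true(all(pvals > 0.01))
})

test_that("misspecification is visible: NO fit on skewed BCT data", {
  d <- bct_sim(5000, seed = 44, sigma = 0.15)
  f <- suppressWarnings(fit_gamlss(d, model_spec(
    "NO", mu = param_terms(~1, smooth = smoother_spec("pspline")),
    sigma = param_terms(~1),
    control = engine_control(tol = 1e-3, max_outer = 60))))
  s <- residual_summary(quantile_residuals(f))
  expect_gt(abs(s$skewness), 0.15)
  expect_lt(s$filliben, 0.999)
})
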