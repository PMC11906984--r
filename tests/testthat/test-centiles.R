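# Centile construction, coverage reporting, batch charts and the pipeline
# front end.

fit_once <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- bct_sim(4000, seed = 55)
      cache <<- suppressWarnings(fit_gamlss(d, recovery_spec(tol = 1e-3,
                                                             max_outer = 60)))
    }
    cache
  }
})

test_that("default levels are the +/- 2, 1, 0 SD set and P50 is the median", {
  f <- fit_once()
  ct <- centile_curves(f, grid = seq(6, 40, 2))
  expect_identical(ct$levels, c(2.3, 16, 50, 84, 97.7))
  pr <- predict_params(f, data.frame(gest_age = seq(6, 40, 2)))
  med <- family_quantile(0.5, f$family, pr$mu, pr$sigma, pr$nu, pr$tau) -
    f$shift_delta
  expect_equal(unname(ct$values[, "P50"]), med, tolerance = 1e-12)
  # non-crossing across the grid
  expect_true(all(apply(ct$values, 1, function(r) all(diff(r) > 0))))
  expect_error(centile_curves(f, grid = numeric(0)), "empty")
  expect_error(centile_curves(f, levels = c(0, 50)), "levels")
})

test_that("back-shift is consistent with the CDF identity", {
  f <- fit_once()
  ct <- centile_curves(f, grid = c(20, 35), levels = c(10, 50, 90))
  pr <- predict_params(f, data.frame(gest_age = c(20, 35)))
  for (j in seq_along(ct$levels)) {
    u <- family_cdf(ct$values[, j] + f$shift_delta, f$family,
                    pr$mu, pr$sigma, pr$nu, pr$tau)
    expect_equal(u, rep(ct$levels[j] / 100, 2), tolerance = 1e-8)
  }
})

test_that("fitted centiles track the truth centiles on matched data", {
  f <- fit_once()
  grid <- seq(10, 40, 1)
  ct <- centile_curves(f, grid = grid)
  mc <- function(t) 0.0025 * t^2 + 0.18 * t
  truth <- sapply(c(2.3, 16, 50, 84, 97.7) / 100, function(p)
    family_quantile(p, "BCT", mu = mc(grid) + 30, sigma = 0.12,
                    nu = -1, tau = 8) - 30)
  expect_lt(mean(abs(ct$values - truth)), 0.5)
})

test_that("held-out coverage sits at the nominal levels", {
  f <- fit_once()
  heldout <- bct_sim(1e4, seed = 56)
  cov <- coverage_report(f, heldout)
  expect_true(all(diff(cov$empirical) > 0))
  for (i in seq_len(nrow(cov))) {
    expect_lt(abs(cov$empirical[i] - cov$level[i]), 3 * cov$se[i])
  }
  expect_lt(abs(cov$empirical[cov$level == 2.3] - 2.3), 0.45)
  expect_lt(abs(cov$empirical[cov$level == 50] - 50), 1.5)
  expect_error(coverage_report(f, heldout[0, ]), "empty")
})

test_that("coverage against the generating truth is nominal by construction", {
  set.seed(57)
  n <- 2e4
  t <- runif(n, 4, 42)
  mc <- function(tt) 0.0025 * tt^2 + 0.18 * tt
  u <- runif(n)
  y <- family_quantile(u, "BCT", mc(t) + 30, 0.12, -1, 8) - 30
  for (p in c(2.3, 50, 97.7)) {
    qs <- family_quantile(p / 100, "BCT", mc(t) + 30, 0.12, -1, 8) - 30
    expect_lt(abs(mean(y < qs) - p / 100), 3 * sqrt(p / 100 * (1 - p / 100) / n))
  }
})

test_that("centile tables round-trip through CSV exactly", {
  f <- fit_once()
  ct <- centile_curves(f, grid = seq(10, 40, 5))
  tmp <- tempfile(fileext = ".csv")
  write_centiles(ct, tmp)
  back <- read.csv(tmp, check.names = FALSE)
  expect_equal(as.data.frame(ct), back, tolerance = 1e-12)
  unlink(tmp)
})

# --- full-registry fit shared by the batch/pipeline tests ----------------

registry_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- small_registry(n_women = 1200, seed = 7)
      pp <- preprocess_gwg(sim$visits, sim$cohort, seed = 7)
      cache <<- suppressWarnings(fit_gamlss(pp$data, model_spec("BCT")))
    }
    cache
  }
})

test_that("batch charts emit four BMI-category tables per ethnicity, deterministically", {
  f <- registry_fit()
  out1 <- tempfile("charts1_"); out2 <- tempfile("charts2_")
  t1 <- batch_charts(f, ethnicities = "Australian/European", output_dir = out1,
                     grid = seq(6, 40, 2))
  files <- list.files(out1)
  expect_length(files, 4L)
  expect_setequal(sub("centiles_Australian_European_(.*)\\.csv", "\\1", files),
                  c("underweight", "normal", "overweight", "obese"))
  batch_charts(f, ethnicities = "Australian/European", output_dir = out2,
               grid = seq(6, 40, 2))
  for (fn in files)
    expect_identical(readLines(file.path(out1, fn)),
                     readLines(file.path(out2, fn)))
  # generator BMI effect is negative: higher BMI category, lower median curve
  meds <- vapply(t1, function(ct) mean(ct$values[, "P50"]), 0)
  expect_true(all(diff(meds[c("Australian_European_underweight",
                              "Australian_European_normal",
                              "Australian_European_overweight",
                              "Australian_European_obese")]) < 0))
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("unseen profile categories are rejected", {
  f <- registry_fit()
  expect_error(centile_curves(f, data.frame(
    age_years = 30, bmi = 22, ethnicity_region = "Atlantis",
    parity_class = "0")), "fitted coding")
})

test_that("the demo pipeline runs end to end with the documented ranking", {
  cfgfile <- system.file("extdata", "demo_config.json", package = "gwgtraj")
  out <- tempfile("run_")
  res <- run_pipeline(cfgfile, out_dir = out, verbose = FALSE)
  cmp <- res$comparison
  expect_setequal(cmp$label, c("linear", "cubic_polynomial",
                               "bct_cubic_spline", "bct_pspline"))
  bct_rows <- which(cmp$label %in% c("bct_pspline", "bct_cubic_spline"))
  lin_row <- which(cmp$label == "linear")
  expect_true(all(cmp$aic[bct_rows] < cmp$aic[lin_row]))
  expect_true(file.exists(file.path(out, "run_report.json")))
  expect_true(file.exists(file.path(out, "comparison.csv")))
  expect_true(file.exists(file.path(out, "centiles_profile01.csv")))
  # determinism: a second run differs only in timestamps
  out2 <- tempfile("run2_")
  res2 <- run_pipeline(cfgfile, out_dir = out2, verbose = FALSE)
  expect_equal(res$comparison, res2$comparison, tolerance = 1e-12)
  expect_identical(readLines(file.path(out, "comparison.csv")),
                   readLines(file.path(out2, "comparison.csv")))
  unlink(c(out, out2), recursive = TRUE)
})

test_that("the CLI reports usage errors with exit status 2", {
  expect_identical(gwg_cli(character(0), quit_on_exit = FALSE), 2L)
  expect_identical(suppressMessages(
    gwg_cli(c("frobnicate"), quit_on_exit = FALSE)), 2L)
  expect_identical(suppressMessages(
    gwg_cli(c("run", "--bogus"), quit_on_exit = FALSE)), 2L)
})

test_that("the CLI simulate subcommand writes the registry tables", {
  out <- tempfile("cli_")
  cfg <- tempfile(fileext = ".json")
  writeLines('{"n_women": 60, "seed": 3}', cfg)
  status <- gwg_cli(c("simulate", "--config", cfg, "--out", out),
                    quit_on_exit = FALSE)
  expect_identical(status, 0L)
  expect_true(file.exists(file.path(out, "cohort.csv")))
  expect_true(file.exists(file.path(out, "visits.csv")))
  expect_identical(nrow(read_cohort(file.path(out, "cohort.csv"))), 60L)
  unlink(out, recursive = TRUE); unlink(cfg)
})
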