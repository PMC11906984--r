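# Synthetic cohort generator: determinism, marginal fidelity, support and
# truth-centile coverage.

test_that("generation is deterministic under a fixed seed", {
  cfg <- cohort_config(n_women = 200, seed = 42)
  s1 <- simulate_registry(cfg)
  s2 <- simulate_registry(cfg)
  expect_identical(s1, s2)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_women = 0), "positive")
  expect_error(cohort_config(parity_probs = c(0.5, 0.5)), "three")
  expect_error(cohort_config(ethnicity_probs = c(bogus = 1)), "region labels")
  expect_error(cohort_config(visits_min = 5, visits_max = 2), "visits_min")
})

test_that("degenerate ethnicity probabilities put every woman in one region", {
  pr <- setNames(rep(0, 13), gwgtraj:::ETHNICITY_REGIONS)
  pr["Polynesian"] <- 1
  co <- generate_cohort(cohort_config(n_women = 50, seed = 1,
                                      ethnicity_probs = pr))
  expect_true(all(co$ethnicity_region == "Polynesian"))
})

test_that("marginals match their targets within 3 Monte-Carlo SEs at n = 1e5", {
  n <- 1e5
  cfg <- cohort_config(n_women = n, seed = 1)
  co <- generate_cohort(cfg)
  expect_lt(abs(mean(co$age_years) - 28.4), 0.05)          # printed example
  expect_lt(abs(mean(co$age_years) - 28.4), 3 * 4.86 / sqrt(n))
  expect_lt(abs(sd(co$age_years) - 4.86), 3 * 4.86 / sqrt(2 * n))
  expect_lt(abs(mean(co$delivery_gest_weeks) - 38.9), 3 * 1.71 / sqrt(n))
  pp <- prop.table(table(co$parity_class))
  for (k in names(cfg$parity_probs <- setNames(cfg$parity_probs,
                                               gwgtraj:::PARITY_CLASSES))) {
    p0 <- cfg$parity_probs[[k]]
    expect_lt(abs(pp[[k]] - p0), 3 * sqrt(p0 * (1 - p0) / n))
  }
  pe <- prop.table(table(co$ethnicity_region))
  for (k in names(cfg$ethnicity_probs)) {
    p0 <- cfg$ethnicity_probs[[k]]
    expect_lt(abs(pe[[k]] - p0), 3 * sqrt(p0 * (1 - p0) / n))
  }
  vi <- generate_visits(co, cfg)
  counts <- tabulate(vi$woman_id, nbins = n)
  expect_lt(abs(mean(counts) - 2.85), 0.05)
  expect_true(all(counts >= 1 & counts <= 21))
})

test_that("visit schedules respect support and ordering", {
  cfg <- cohort_config(n_women = 400, seed = 3)
  co <- generate_cohort(cfg)
  vi <- generate_visits(co, cfg)
  expect_true(all(vi$gest_age_weeks > 4))
  expect_true(all(vi$gest_age_weeks <=
                  co$delivery_gest_weeks[vi$woman_id] + 1e-12))
  expect_true(all(vi$gest_age_weeks <= 43))
  incr <- tapply(vi$gest_age_weeks, vi$woman_id, function(t) all(diff(t) > 0))
  expect_true(all(incr))
  cfg1 <- cohort_config(n_women = 100, seed = 3, visits_min = 1, visits_max = 1)
  vi1 <- generate_visits(generate_cohort(cfg1), cfg1)
  expect_identical(nrow(vi1), 100L)
})

test_that("weights match the analytic normal limit within 2% at n = 1e5", {
  n <- 1e5
  cfg <- cohort_config(n_women = n, seed = 5)
  co <- generate_cohort(cfg)
  # all visits at 40 weeks; symmetric light-tailed truth, no offsets
  vi <- data.frame(woman_id = co$woman_id, visit_no = 1L, gest_age_weeks = 40)
  tr <- truth_model(sigma_curve = function(t) rep(0.05, length(t)),
                    nu_const = 1, tau_const = 1e7,
                    age_slope = 0, bmi_slope = 0,
                    parity_offsets = c("0" = 0, "1-3" = 0, ">3" = 0),
                    ethnicity_offsets = setNames(rep(0, 13),
                                                 gwgtraj:::ETHNICITY_REGIONS))
  sim <- generate_weights(vi, co, tr, cfg, measurement_noise = FALSE)
  mu_shifted <- tr$median_curve(40) + tr$shift_delta
  expect_lt(abs(sd(sim$visits$true_gain_kg) / (mu_shifted * 0.05) - 1), 0.02)
  expect_lt(abs(median(sim$visits$true_gain_kg) - tr$median_curve(40)),
            3 * 1.2533 * sd(sim$visits$true_gain_kg) / sqrt(n))
  expect_true(all(sim$visits$weight_kg > 0))
})

test_that("gain is exactly zero at week 0 with noise off and degenerate scale", {
  cfg <- cohort_config(n_women = 20, seed = 6)
  co <- generate_cohort(cfg)
  vi <- data.frame(woman_id = co$woman_id, visit_no = 1L, gest_age_weeks = 0)
  tr <- truth_model(sigma_curve = function(t) rep(1e-9, length(t)),
                    age_slope = 0, bmi_slope = 0,
                    parity_offsets = c("0" = 0, "1-3" = 0, ">3" = 0),
                    ethnicity_offsets = setNames(rep(0, 13),
                                                 gwgtraj:::ETHNICITY_REGIONS))
  sim <- generate_weights(vi, co, tr, cfg, measurement_noise = FALSE)
  expect_lt(max(abs(sim$visits$true_gain_kg)), 1e-6)
})

ref_profile <- data.frame(age_years = 28.4, bmi = 25,
                          ethnicity_region = "Australian/European",
                          parity_class = "0")

test_that("truth centiles are exact quantiles of the generating law", {
  tr <- truth_model()
  ct <- truth_centiles(tr, ref_profile, grid = seq(4, 42, 2))
  expect_identical(ct$levels, c(2.3, 16, 50, 84, 97.7))
  # monotone across levels at every grid point
  expect_true(all(apply(ct$values, 1, function(r) all(diff(r) > 0))))
  # median curve at the reference profile (offsets zero)
  # identity up to the (tiny) kernel truncation mass at heavy tails
  expect_equal(unname(ct$values[, "P50"]),
               tr$median_curve(seq(4, 42, 2)), tolerance = 1e-5)
  # symmetric truth: outer centiles symmetric about the median
  trs <- truth_model(nu_const = 1, tau_const = 1e8)
  cs <- truth_centiles(trs, ref_profile, grid = c(20, 40),
                       levels = c(2.3, 50, 97.7))
  expect_lt(max(abs((cs$values[, 3] - cs$values[, 2]) -
                    (cs$values[, 2] - cs$values[, 1]))), 1e-6)
  expect_error(truth_centiles(tr, ref_profile, grid = numeric(0)), "empty")
  expect_error(truth_centiles(tr, ref_profile, levels = c(0, 50)), "levels")
})

test_that("empirical gains respect the truth centiles (coverage at n = 1e5)", {
  n <- 1e5
  cfg <- cohort_config(n_women = n, seed = 8, visits_min = 1, visits_max = 1)
  co <- generate_cohort(cfg)
  vi <- generate_visits(co, cfg)
  tr <- truth_model()
  sim <- generate_weights(vi, co, tr, cfg, measurement_noise = FALSE)
  off <- truth_offsets(tr, co)[match(sim$visits$woman_id, co$woman_id)]
  t <- sim$visits$gest_age_weeks
  u <- family_cdf(sim$visits$true_gain_kg + tr$shift_delta, tr$family,
                  mu = tr$median_curve(t) + off + tr$shift_delta,
                  sigma = tr$sigma_curve(t), nu = tr$nu_const,
                  tau = tr$tau_const)
  for (p in c(0.023, 0.16, 0.5, 0.84, 0.977))
    expect_lt(abs(mean(u < p) - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("cohort and visit tables round-trip through CSV", {
  sim <- small_registry(n_women = 40, seed = 2)
  tmp <- tempfile(fileext = ".csv")
  write_visits(sim$visits, tmp)
  back <- read_visits(tmp)
  expect_equal(back$gest_age_weeks, sim$visits$gest_age_weeks,
               tolerance = 1e-12)
  expect_identical(back$woman_id, sim$visits$woman_id)
  unlink(tmp)
})
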