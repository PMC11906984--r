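## Synthetic registry emulation: marginals follow the characteristics table
## of a large Australian antenatal registry (n = 39 846); the gain-generating
## truth is a configurable Box-Cox family so parameter recovery is testable.

ETHNICITY_REGIONS <- c(
  "Australian/European", "Polynesian", "Mainland Asian", "Maritime Asian",
  "Northeast Asian", "South central Asian", "African",
  "Indigenous/Torres Strait Island", "South America", "Southeast Europe",
  "Eastern Europe", "North Africa and the Middle East", "Other")

ETHNICITY_PCT <- c(41.4, 1.5, 7.4, 4.0, 4.9, 22.8, 3.3, 0.7, 0.5, 7.5, 3.0,
                   1.3, 1.7)

PARITY_CLASSES <- c("0", "1-3", ">3")

#' Configuration of the synthetic antenatal cohort
#'
#' Defaults reproduce the registry's published marginals: maternal age
#' mean 28.4 (SD 4.86) years, 13 country-of-birth regions with the printed
#' proportions, parity 40.3 / 56.0 / 3.8 per cent across 0, 1-3 and >3
#' previous births, delivery gestation mean 38.9 (SD 1.71) weeks, and a mean
#' of 2.85 weight measurements per woman (range 1-21). The self-report /
#' scale measurement error SD is 0.70 kg, so the week-0 gain-score variance
#' is 0.70^2 + 0.70^2 = 0.98 kg^2.
#'
#' @param n_women number of women.
#' @param seed integer seed; the cohort, visit and weight stages use seeds
#'   `seed`, `seed + 1`, `seed + 2` so each stage regenerates stably.
#' @param age_mean,age_sd maternal age distribution, years.
#' @param ethnicity_probs named probabilities over the 13 regions
#'   (renormalised to sum to 1).
#' @param parity_probs probabilities for parity 0 / 1-3 / >3 (renormalised).
#' @param gestation_mean,gestation_sd delivery gestation, weeks. Draws are
#'   truncated to (22, 43]; the latent mean is shifted so the realised mean
#'   equals `gestation_mean`.
#' @param visits_mean,visits_min,visits_max per-woman visit-count law:
#'   1 + Poisson(`visits_mean` - 1), truncated to `[visits_min, visits_max]`.
#' @param self_report_error_sd SD (kg) of both the scale measurement error
#'   and the pre-pregnancy self-report error.
#' @param height_mean,height_sd maternal height, metres.
#' @param bmi_meanlog,bmi_sdlog log-normal pre-pregnancy BMI law (kg/m^2).
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_women = 1000L, seed = 1L,
                          age_mean = 28.4, age_sd = 4.86,
                          ethnicity_probs = NULL,
                          parity_probs = c(0.403, 0.560, 0.038),
                          gestation_mean = 38.9, gestation_sd = 1.71,
                          visits_mean = 2.85, visits_min = 1L, visits_max = 21L,
                          self_report_error_sd = 0.70,
                          height_mean = 1.62, height_sd = 0.065,
                          bmi_meanlog = log(24), bmi_sdlog = 0.19) {
  if (n_women < 1) stop_bad("n_women must be a positive integer")
  if (is.null(ethnicity_probs)) {
    ethnicity_probs <- ETHNICITY_PCT
    names(ethnicity_probs) <- ETHNICITY_REGIONS
  }
  if (is.null(names(ethnicity_probs)) ||
      !all(names(ethnicity_probs) %in% ETHNICITY_REGIONS))
    stop_bad("ethnicity_probs must be named with the 13 region labels")
  if (any(ethnicity_probs < 0) || sum(ethnicity_probs) <= 0)
    stop_bad("malformed ethnicity probabilities")
  if (any(parity_probs < 0) || sum(parity_probs) <= 0 ||
      length(parity_probs) != 3L)
    stop_bad("parity_probs must be three non-negative values")
  if (visits_min > visits_max) stop_bad("visits_min must be <= visits_max")
  stopifnot(age_sd > 0, gestation_sd > 0, self_report_error_sd > 0)
  structure(list(
    n_women = as.integer(n_women), seed = as.integer(seed),
    age_mean = age_mean, age_sd = age_sd,
    ethnicity_probs = ethnicity_probs / sum(ethnicity_probs),
    parity_probs = parity_probs / sum(parity_probs),
    gestation_mean = gestation_mean, gestation_sd = gestation_sd,
    visits_mean = visits_mean, visits_min = as.integer(visits_min),
    visits_max = as.integer(visits_max),
    self_report_error_sd = self_report_error_sd,
    height_mean = height_mean, height_sd = height_sd,
    bmi_meanlog = bmi_meanlog, bmi_sdlog = bmi_sdlog),
    class = "cohort_config")
}

default_ethnicity_offsets <- function() {
  c("Australian/European" = 0, "Polynesian" = 0.254,
    "Mainland Asian" = -1.11, "Maritime Asian" = -0.788,
    "Northeast Asian" = -0.7, "South central Asian" = -0.859,
    "African" = -1.483, "Indigenous/Torres Strait Island" = -0.473,
    "South America" = -0.336, "Southeast Europe" = -0.677,
    "Eastern Europe" = 0.405, "North Africa and the Middle East" = -0.211,
    "Other" = -0.086)
}

#' Ground-truth gain-generating model for the synthetic cohort
#'
#' The true gain at gestational age `t` weeks for a woman with covariate
#' offset `o` is drawn on the shifted scale: `gain + shift_delta` follows the
#' configured Box-Cox family with location `median_curve(t) + o +
#' shift_delta`, scale `sigma_curve(t)`, and constant `nu`, `tau`. The
#' default median curve `0.0025 t^2 + 0.18 t` reaches about 11.2 kg at 40
#' weeks; the default scale grows linearly with gestation, giving the
#' increasing spread seen in the registry; `nu = -1` induces positive skew
#' and `tau = 8` moderately heavy tails.
#'
#' Covariate offsets default to the registry's linear-model coefficients:
#' -0.016 kg per year of age (centred at 28.4), -0.106 kg per BMI unit
#' (centred at 25), parity 1-3 / >3 effects -0.717 / -1.532 kg, and the
#' per-region effects with Australian/European as reference.
#'
#' @param median_curve function of gestational age (weeks) returning the
#'   median gain (kg); must be 0 at 0 and non-decreasing on [0, 43].
#' @param sigma_curve function of gestational age returning the scale
#'   (coefficient of variation on the shifted scale); must be positive.
#' @param nu_const,tau_const constant skewness / kurtosis parameters.
#' @param age_slope,age_ref,bmi_slope,bmi_ref linear covariate effects (kg
#'   per unit) and their centring values.
#' @param parity_offsets,ethnicity_offsets named additive offsets (kg).
#' @param shift_delta positive shift (kg) mapping gains to the positive
#'   support of the Box-Cox families.
#' @param family generating family, default `"BCT"`.
#' @return object of class `truth_model`.
#' @export
truth_model <- function(median_curve = function(t) 0.0025 * t^2 + 0.18 * t,
                        sigma_curve = function(t) 0.010 + 0.0028 * t,
                        nu_const = -1, tau_const = 8,
                        age_slope = -0.016, age_ref = 28.4,
                        bmi_slope = -0.106, bmi_ref = 25,
                        parity_offsets = c("0" = 0, "1-3" = -0.717, ">3" = -1.532),
                        ethnicity_offsets = default_ethnicity_offsets(),
                        shift_delta = 30, family = "BCT") {
  check_family(family)
  if (abs(median_curve(0)) > 1e-12) stop_bad("median_curve(0) must be 0")
  tt <- seq(0, 43, by = 0.5)
  if (any(diff(median_curve(tt)) < -1e-10))
    stop_bad("median_curve must be non-decreasing on [0, 43]")
  if (any(sigma_curve(tt) <= 0)) stop_bad("sigma_curve must be positive")
  if (tau_const <= 0 || shift_delta <= 0) stop_bad("tau_const and shift_delta must be > 0")
  structure(list(median_curve = median_curve, sigma_curve = sigma_curve,
                 nu_const = nu_const, tau_const = tau_const,
                 age_slope = age_slope, age_ref = age_ref,
                 bmi_slope = bmi_slope, bmi_ref = bmi_ref,
                 parity_offsets = parity_offsets,
                 ethnicity_offsets = ethnicity_offsets,
                 shift_delta = shift_delta, family = family),
            class = "truth_model")
}

#' Additive covariate offset (kg) under the truth model
#'
#' @param truth a [truth_model()].
#' @param data data frame with columns `age_years`, `bmi`,
#'   `ethnicity_region`, `parity_class`.
#' @export
truth_offsets <- function(truth, data) {
  truth$age_slope * (data$age_years - truth$age_ref) +
    truth$bmi_slope * (data$bmi - truth$bmi_ref) +
    unname(truth$parity_offsets[as.character(data$parity_class)]) +
    unname(truth$ethnicity_offsets[as.character(data$ethnicity_region)])
}

## mean of a (lo, hi]-truncated normal
truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

rtruncnorm <- function(n, mu, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mu, sd), pnorm(hi, mu, sd))
  qnorm(u, mu, sd)
}

#' Generate the per-woman cohort table
#'
#' One row per woman: age, country-of-birth region, parity class, height,
#' pre-pregnancy BMI and (true) pre-pregnancy weight, and delivery
#' gestation. Fully reproducible under the configured seed.
#'
#' @param config a [cohort_config()].
#' @return data frame with one row per woman.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(child_seed(config$seed, 0L))
  n <- config$n_women
  age <- rnorm(n, config$age_mean, config$age_sd)
  eth <- sample(names(config$ethnicity_probs), n, replace = TRUE,
                prob = config$ethnicity_probs)
  par <- sample(PARITY_CLASSES, n, replace = TRUE, prob = config$parity_probs)
  height <- pmin(pmax(rnorm(n, config$height_mean, config$height_sd), 1.35), 2.0)
  bmi <- exp(rnorm(n, config$bmi_meanlog, config$bmi_sdlog))
  # latent mean adjusted so the (22, 43]-truncated draw has the target mean
  mu_star <- uniroot(function(m)
    truncnorm_mean(m, config$gestation_sd, 22, 43) - config$gestation_mean,
    c(config$gestation_mean - 3, config$gestation_mean + 3))$root
  gest <- rtruncnorm(n, mu_star, config$gestation_sd, 22, 43)
  data.frame(
    woman_id = seq_len(n), age_years = age,
    ethnicity_region = eth, parity_class = par,
    height_m = height, bmi = bmi,
    prepreg_weight_true_kg = bmi * height^2,
    delivery_gest_weeks = gest,
    stringsAsFactors = FALSE)
}

#' Generate the per-woman visit schedule
#'
#' Visit counts follow 1 + Poisson(`visits_mean` - 1) truncated to
#' `[visits_min, visits_max]`; visit gestational ages are Beta(2, 1.2) draws
#' scaled to (4, delivery], sorted, so sampling is denser late in pregnancy.
#'
#' @param cohort output of [generate_cohort()].
#' @param config the same [cohort_config()].
#' @return data frame of visits: `woman_id`, `visit_no`, `gest_age_weeks`.
#' @export
generate_visits <- function(cohort, config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(child_seed(config$seed, 1L))
  n <- nrow(cohort)
  if (any(cohort$delivery_gest_weeks <= 4))
    stop_bad("delivery gestation must exceed the first-visit bound of 4 weeks")
  counts <- pmin(pmax(1L + rpois(n, max(config$visits_mean - 1, 0)),
                      config$visits_min), config$visits_max)
  total <- sum(counts)
  id <- rep(cohort$woman_id, counts)
  delivery <- rep(cohort$delivery_gest_weeks, counts)
  raw <- rbeta(total, 2, 1.2)
  t <- 4 + (delivery - 4) * raw
  ord <- order(id, t)
  id <- id[ord]; t <- t[ord]
  # enforce strict increase within woman (ties have probability zero but
  # guard against them anyway)
  dup <- c(FALSE, diff(t) <= 0 & diff(id) == 0)
  while (any(dup)) {
    t[dup] <- t[dup] + 1e-6
    ord2 <- order(id, t); id <- id[ord2]; t <- t[ord2]
    dup <- c(FALSE, diff(t) <= 0 & diff(id) == 0)
  }
  data.frame(woman_id = id,
             visit_no = sequence(counts),
             gest_age_weeks = t)
}

#' Attach measured weights to a visit schedule
#'
#' Measured weight = true pre-pregnancy weight + true gain + scale error,
#' where the true gain is a draw from the truth model's Box-Cox family at
#' the visit's gestational age plus the woman's covariate offset. Also adds
#' the self-reported pre-pregnancy weight (true weight + self-report error)
#' to the cohort table as `prepreg_weight_kg`.
#'
#' @param visits output of [generate_visits()].
#' @param cohort output of [generate_cohort()].
#' @param truth a [truth_model()].
#' @param config the same [cohort_config()].
#' @param measurement_noise logical; set `FALSE` to disable both error terms.
#' @return list with elements `visits` (now carrying `weight_kg` and
#'   `true_gain_kg`) and `cohort` (now carrying `prepreg_weight_kg`).
#' @export
generate_weights <- function(visits, cohort, truth, config,
                             measurement_noise = TRUE) {
  stopifnot(inherits(truth, "truth_model"), inherits(config, "cohort_config"))
  set.seed(child_seed(config$seed, 2L))
  i <- match(visits$woman_id, cohort$woman_id)
  off <- truth_offsets(truth, cohort)[i]
  t <- visits$gest_age_weeks
  delta <- truth$shift_delta
  mu <- truth$median_curve(t) + off + delta
  if (any(mu <= 0)) stop_bad("truth parameters leave the family support: ",
                             "median + offset + shift_delta must stay positive")
  gain <- family_sample(length(t), truth$family, mu = mu,
                        sigma = truth$sigma_curve(t),
                        nu = truth$nu_const, tau = truth$tau_const) - delta
  esd <- if (measurement_noise) config$self_report_error_sd else 0
  meas_err <- if (esd > 0) rnorm(length(t), 0, esd) else 0
  self_err <- if (esd > 0) rnorm(nrow(cohort), 0, esd) else 0
  visits$true_gain_kg <- gain
  visits$weight_kg <- cohort$prepreg_weight_true_kg[i] + gain + meas_err
  cohort$prepreg_weight_kg <- cohort$prepreg_weight_true_kg + self_err
  list(visits = visits, cohort = cohort)
}

#' Simulate a full synthetic registry
#'
#' Runs [generate_cohort()], [generate_visits()] and [generate_weights()]
#' in their documented substream order.
#'
#' @inheritParams generate_weights
#' @return list with `cohort` and `visits` data frames.
#' @export
simulate_registry <- function(config, truth = truth_model()) {
  cohort <- generate_cohort(config)
  visits <- generate_visits(cohort, config)
  generate_weights(visits, cohort, truth, config)
}

#' Exact centiles of the generating distribution
#'
#' Ground-truth quantile curves for a covariate profile on a gestational-age
#' grid; the oracle for parameter-recovery and coverage tests.
#'
#' @param truth a [truth_model()].
#' @param profile one-row data frame (or list) with `age_years`, `bmi`,
#'   `ethnicity_region`, `parity_class`.
#' @param grid gestational ages (weeks).
#' @param levels centile levels in (0, 100).
#' @return object of class `gwg_centiles`.
#' @export
truth_centiles <- function(truth, profile,
                           grid = seq(4, 42, by = 0.5),
                           levels = c(2.3, 16, 50, 84, 97.7)) {
  if (length(grid) == 0) stop_bad("empty gestational-age grid")
  if (any(levels <= 0 | levels >= 100)) stop_bad("levels must be in (0, 100)")
  off <- truth_offsets(truth, as.data.frame(profile))
  delta <- truth$shift_delta
  vals <- sapply(levels, function(p)
    family_quantile(p / 100, truth$family,
                    mu = truth$median_curve(grid) + off + delta,
                    sigma = truth$sigma_curve(grid),
                    nu = truth$nu_const, tau = truth$tau_const) - delta)
  vals <- matrix(vals, nrow = length(grid))
  colnames(vals) <- paste0("P", levels)
  structure(list(profile = as.data.frame(profile), grid = grid,
                 levels = levels, values = vals, source = "truth"),
            class = "gwg_centiles")
}

#' @export
print.gwg_centiles <- function(x, ...) {
  cat("GWG centile table (", x$source %||% "fit", "): ",
      length(x$grid), " grid points x ", length(x$levels), " levels\n", sep = "")
  show <- cbind(gest_age_weeks = x$grid, x$values)
  print(utils::head(round(as.data.frame(show), 3), 8))
  if (length(x$grid) > 8) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.gwg_centiles <- function(x, ...) {
  data.frame(gest_age_weeks = x$grid, x$values, check.names = FALSE)
}

#' Write / read the delimited cohort and visit tables
#'
#' CSV, UTF-8, header row; the documented exchange format of the pipeline.
#'
#' @param cohort,visits data frames as produced by [simulate_registry()].
#' @param path output file path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
write_visits <- function(visits, path) {
  utils::write.csv(visits, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path)
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")

#' @rdname write_cohort
#' @export
read_visits <- function(path)
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
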