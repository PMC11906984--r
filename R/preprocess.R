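## Raw visit tables -> modelling-ready gain scores: gain computation, week-0
## pseudo-observations, windowed 4-SD exclusion, ethnicity-specific BMI
## coding and the first-visit re-baselining sensitivity variant.

BMI_SCHEMES <- list(
  WHO   = c(18.5, 25.0, 30.0),
  China = c(18.5, 24.0, 28.0),
  Korea = c(18.5, 23.0, 25.0))

BMI_CATEGORIES <- c("underweight", "normal", "overweight", "obese")

#' BMI category under the WHO, Chinese or Korean scheme
#'
#' Categories are left-closed, right-open: WHO normal weight is
#' `[18.5, 25.0)`, Chinese `[18.5, 24.0)` with obese `>= 28`, Korean
#' `[18.5, 23.0)` with obese `>= 25`. Scheme selection by birth region:
#' only `"Mainland Asian"` triggers the Chinese scheme (and an explicit
#' `"Korea"` region the Korean one); all other regions use WHO.
#'
#' @param bmi positive BMI values, kg/m^2.
#' @param region optional country-of-birth region used to pick the scheme.
#' @param scheme explicit scheme label, one of `"WHO"`, `"China"`, `"Korea"`;
#'   overrides `region`.
#' @return factor with levels underweight / normal / overweight / obese.
#' @export
bmi_category <- function(bmi, region = NULL, scheme = NULL) {
  if (any(is.finite(bmi) & bmi <= 0) || any(is.nan(bmi)) || any(is.infinite(bmi)))
    stop_bad("bmi must be positive")
  if (is.null(scheme)) {
    scheme <- if (is.null(region)) rep("WHO", length(bmi))
              else bmi_scheme_for_region(region)
  }
  scheme <- rep_len(scheme, length(bmi))
  out <- character(length(bmi))
  for (s in unique(scheme)) {
    cuts <- BMI_SCHEMES[[s]]
    if (is.null(cuts)) stop_bad("unknown BMI scheme: ", s)
    i <- scheme == s
    out[i] <- BMI_CATEGORIES[findInterval(bmi[i], cuts) + 1L]
  }
  factor(out, levels = BMI_CATEGORIES)
}

#' @rdname bmi_category
#' @export
bmi_scheme_for_region <- function(region) {
  ifelse(region == "Mainland Asian", "China",
         ifelse(region == "Korea", "Korea", "WHO"))
}

join_covariates <- function(obs, cohort) {
  i <- match(obs$woman_id, cohort$woman_id)
  obs$age_years <- cohort$age_years[i]
  obs$ethnicity_region <- cohort$ethnicity_region[i]
  obs$parity_class <- cohort$parity_class[i]
  obs$bmi <- if ("bmi" %in% names(cohort)) cohort$bmi[i]
             else cohort$prepreg_weight_kg[i] / cohort$height_m[i]^2
  obs$bmi_category <- bmi_category(obs$bmi, region = obs$ethnicity_region)
  obs
}

#' Compute gain scores from visit weights
#'
#' Gestational weight gain is the measured weight minus the (self-reported)
#' pre-pregnancy weight; negative gains are preserved. Visits of women with
#' a missing pre-pregnancy weight or missing covariates are dropped and
#' counted in the `n_dropped` attribute.
#'
#' @param visits data frame with `woman_id`, `gest_age_weeks`, `weight_kg`.
#' @param cohort data frame with `woman_id`, `prepreg_weight_kg` and the
#'   covariates (`age_years`, `height_m` or `bmi`, `ethnicity_region`,
#'   `parity_class`).
#' @return data frame of gain observations with covariates joined and an
#'   `is_week0_pseudo = FALSE` flag; attribute `n_dropped` counts removals.
#' @export
compute_gwg <- function(visits, cohort) {
  i <- match(visits$woman_id, cohort$woman_id)
  pre <- cohort$prepreg_weight_kg[i]
  obs <- data.frame(woman_id = visits$woman_id,
                    gest_age = visits$gest_age_weeks,
                    gwg_kg = visits$weight_kg - pre,
                    is_week0_pseudo = FALSE)
  obs <- join_covariates(obs, cohort)
  keep <- stats::complete.cases(obs)
  dropped <- sum(!keep)
  if (dropped > 0)
    message("compute_gwg: dropped ", dropped,
            " visit(s) with missing baseline weight or covariates")
  out <- obs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  out
}

#' Week-0 pseudo-observations
#'
#' A zero gain at week 0 has no variation and stalls the fitting
#' iterations, so each woman instead receives a pseudo-gain drawn from a
#' Gaussian with mean 0 and variance `2 * error_sd^2` (the self-report and
#' scale errors combined: 0.70^2 + 0.70^2 = 0.98 kg^2 at the default).
#'
#' @param cohort per-woman table carrying the covariates.
#' @param error_sd single-measurement error SD in kg, default 0.70.
#' @param seed optional seed for a dedicated reproducible substream.
#' @return data frame of pseudo-observations flagged `is_week0_pseudo`.
#' @export
draw_week0 <- function(cohort, error_sd = 0.70, seed = NULL) {
  if (!is.finite(error_sd) || error_sd <= 0) stop_bad("error_sd must be > 0")
  if (!is.null(seed)) set.seed(child_seed(seed, 3L))
  obs <- data.frame(woman_id = cohort$woman_id,
                    gest_age = 0,
                    gwg_kg = rnorm(nrow(cohort), 0, sqrt(2) * error_sd),
                    is_week0_pseudo = TRUE)
  obs <- join_covariates(obs, cohort)
  obs[stats::complete.cases(obs), , drop = FALSE]
}

## windows: integer gestational weeks, merged left-to-right until each
## window holds >= min_n real observations (final short window merges back)
sd_windows <- function(gest_age, min_n = 30L) {
  bin <- floor(gest_age)
  ub <- sort(unique(bin))
  counts <- table(factor(bin, levels = ub))
  win <- integer(length(ub)); w <- 1L; acc <- 0L
  for (j in seq_along(ub)) {
    win[j] <- w
    acc <- acc + counts[j]
    if (acc >= min_n && j < length(ub)) { w <- w + 1L; acc <- 0L }
  }
  if (acc < min_n && acc > 0 && w > 1L) win[win == w] <- w - 1L
  win[match(bin, ub)]
}

#' Exclude gain scores outside 4 SD of their gestational window
#'
#' Gains are windowed by integer gestational week (windows merged until
#' each holds at least 30 real observations, falling back to a single
#' global window); within each window, observations further than 4 SD from
#' the window mean are removed. Week-0 pseudo-observations are never
#' excluded and never contribute to the window statistics. A window with
#' zero SD excludes nothing.
#'
#' @param obs gain observations from [compute_gwg()] (optionally with
#'   pseudo rows bound on).
#' @param k SD multiplier, default 4.
#' @param min_window minimum real observations per window, default 30.
#' @return list with `kept` (the retained rows) and `n_excluded`.
#' @export
exclude_4sd <- function(obs, k = 4, min_window = 30L) {
  real <- !obs$is_week0_pseudo
  if (sum(real) < 2L) stop_bad("need at least 2 real observations")
  win <- sd_windows(obs$gest_age[real], min_n = min_window)
  drop <- logical(nrow(obs))
  g <- obs$gwg_kg[real]
  for (w in unique(win)) {
    i <- win == w
    x <- g[i]; n <- length(x)
    if (n < 3L) next
    # leave-one-out mean/SD: guards against a single gross error masking
    # itself in a small window; indistinguishable from the plain rule at
    # registry scale
    S <- sum(x); Q <- sum(x^2)
    m_loo <- (S - x) / (n - 1)
    v_loo <- pmax((Q - x^2 - (S - x)^2 / (n - 1)) / (n - 2), 0)
    s_loo <- sqrt(v_loo)
    drop[real][i] <- s_loo > 0 & abs(x - m_loo) > k * s_loo
  }
  list(kept = obs[!drop, , drop = FALSE], n_excluded = sum(drop))
}

#' Re-baseline gains at the first measured visit
#'
#' Sensitivity-analysis variant: the self-reported pre-pregnancy weight is
#' discarded and each woman's earliest measured weight becomes her gain
#' origin; that earliest visit is retained as a zero-gain anchor. BMI is
#' recomputed from the baseline weight.
#'
#' @inheritParams compute_gwg
#' @return data frame of gain observations.
#' @export
rebaseline_first_visit <- function(visits, cohort) {
  ord <- order(visits$woman_id, visits$gest_age_weeks)
  v <- visits[ord, , drop = FALSE]
  first <- !duplicated(v$woman_id)
  base <- v$weight_kg[first]
  names(base) <- v$woman_id[first]
  obs <- data.frame(woman_id = v$woman_id,
                    gest_age = v$gest_age_weeks,
                    gwg_kg = v$weight_kg - base[as.character(v$woman_id)],
                    is_week0_pseudo = FALSE)
  cohort2 <- cohort
  cohort2$prepreg_weight_kg <- base[as.character(cohort$woman_id)]
  cohort2$bmi <- NULL
  obs <- join_covariates(obs, cohort2)
  out <- obs[stats::complete.cases(obs), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full preprocessing pipeline
#'
#' Gain computation (or first-visit re-baselining), week-0
#' pseudo-observations and the 4 SD exclusion, with a structured report of
#' counts in and out.
#'
#' @inheritParams compute_gwg
#' @param error_sd week-0 pseudo-draw error SD (kg).
#' @param seed seed for the week-0 substream.
#' @param week0 add week-0 pseudo-observations?
#' @param exclude apply the 4 SD rule?
#' @param first_visit_baseline use the re-baselined sensitivity variant?
#' @return list with `data` (modelling-ready observations) and `report`.
#' @export
preprocess_gwg <- function(visits, cohort, error_sd = 0.70, seed = 1L,
                           week0 = TRUE, exclude = TRUE,
                           first_visit_baseline = FALSE) {
  obs <- if (first_visit_baseline) rebaseline_first_visit(visits, cohort)
         else compute_gwg(visits, cohort)
  n_in <- nrow(visits)
  n_dropped <- attr(obs, "n_dropped") %||% 0L
  if (week0) obs <- rbind(obs, draw_week0(cohort, error_sd, seed = seed))
  n_excluded <- 0L
  if (exclude) {
    ex <- exclude_4sd(obs)
    obs <- ex$kept
    n_excluded <- ex$n_excluded
  }
  rownames(obs) <- NULL
  list(data = obs,
       report = list(n_visits_in = n_in, n_dropped_missing = n_dropped,
                     n_week0_pseudo = sum(obs$is_week0_pseudo),
                     n_excluded_4sd = n_excluded, n_out = nrow(obs),
                     baseline = if (first_visit_baseline) "first_visit"
                                else "pre_pregnancy"))
}
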