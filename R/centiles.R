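## Centile chart construction from a fitted model, coverage validation, and
## the batch per-BMI-category chart generator.

DEFAULT_LEVELS <- c(2.3, 16, 50, 84, 97.7)

#' Centile trajectory curves for a covariate profile
#'
#' Evaluates the fitted distribution parameters at the profile along a
#' gestational-age grid and applies the family quantile function at each
#' level, back-shifting by the model's `shift_delta` so the curves are on
#' the raw gain scale. Default levels are P2.3 / P16 / P50 / P84 / P97.7
#' (the -2, -1, 0, +1, +2 SD positions under normality).
#'
#' @param fit a `gwg_fit`.
#' @param profile one-row data frame (or list) of covariates matching the
#'   fitted coding, e.g. `age_years`, `bmi`, `ethnicity_region`,
#'   `parity_class`.
#' @param grid gestational ages in weeks (default 4 to 42 by 0.5).
#' @param levels centile levels in percent, inside (0, 100).
#' @return object of class `gwg_centiles`.
#' @export
centile_curves <- function(fit, profile = NULL,
                           grid = seq(4, 42, by = 0.5),
                           levels = DEFAULT_LEVELS) {
  if (length(grid) == 0) stop_bad("empty gestational-age grid")
  if (any(levels <= 0 | levels >= 100)) stop_bad("levels must be in (0, 100)")
  profile <- as.data.frame(profile %||% list())
  nd <- if (ncol(profile) > 0)
    cbind(profile, gest_age = grid, row.names = NULL)
  else data.frame(gest_age = grid)
  par <- tryCatch(predict_params(fit, nd), error = function(e)
    stop_bad("profile could not be evaluated under the fitted coding: ",
             conditionMessage(e)))
  vals <- sapply(levels, function(p)
    family_quantile(p / 100, fit$family, par$mu, par$sigma, par$nu, par$tau) -
      fit$shift_delta)
  vals <- matrix(vals, nrow = length(grid))
  colnames(vals) <- paste0("P", levels)
  if (any(apply(vals, 1, function(r) any(diff(r) <= 0))))
    warning("centile curves cross on part of the grid (ill-fitted model?)",
            call. = FALSE)
  structure(list(profile = profile, grid = grid, levels = levels,
                 values = vals, source = "fit"),
            class = "gwg_centiles")
}

#' Empirical coverage of fitted centile curves
#'
#' For each level `p`, the fraction of observations whose gain falls below
#' their own profile-specific centile value (equivalently, whose fitted CDF
#' value is below `p/100`), with binomial standard errors.
#'
#' @param fit a `gwg_fit`.
#' @param data observations to evaluate (held-out, or the training set).
#' @param levels centile levels in percent.
#' @return data frame of class `coverage_report`.
#' @export
coverage_report <- function(fit, data, levels = DEFAULT_LEVELS) {
  if (nrow(data) == 0) stop_bad("empty data")
  par <- predict_params(fit, data)
  u <- family_cdf(data$gwg_kg + fit$shift_delta, fit$family,
                  par$mu, par$sigma, par$nu, par$tau)
  n <- length(u)
  emp <- vapply(levels / 100, function(p) mean(u < p), 0)
  out <- data.frame(level = levels, empirical = 100 * emp,
                    se = 100 * sqrt((levels / 100) * (1 - levels / 100) / n),
                    n = n)
  class(out) <- c("coverage_report", "data.frame")
  out
}

BMI_MIDPOINTS <- c(underweight = 17.5, normal = 21.7, overweight = 27.5,
                   obese = 32.5)

#' Batch centile charts by BMI category and ethnicity
#'
#' One centile table (CSV) per BMI category and requested ethnicity, with
#' profile covariates set to group-representative values: BMI at the WHO
#' category midpoint (17.5 / 21.7 / 27.5 / 32.5), age at `age`, parity 0.
#' File naming is deterministic. Charts (base-graphics PDF) are only
#' rendered when `render = TRUE`, keeping the default path text-only.
#'
#' @param fit a `gwg_fit`.
#' @param ethnicities character vector of ethnicity regions.
#' @param output_dir writable output directory.
#' @param age profile age in years (default the registry mean, 28.4).
#' @param parity profile parity class.
#' @param grid,levels as in [centile_curves()].
#' @param render also write PDF charts?
#' @return invisible named list of `gwg_centiles` tables.
#' @export
batch_charts <- function(fit, ethnicities = "Australian/European",
                         output_dir = ".", age = 28.4, parity = "0",
                         grid = seq(4, 42, by = 0.5),
                         levels = DEFAULT_LEVELS, render = FALSE) {
  if (!dir.exists(output_dir) &&
      !dir.create(output_dir, recursive = TRUE, showWarnings = FALSE))
    stop_bad("cannot create output directory ", output_dir)
  out <- list()
  for (eth in ethnicities) {
    for (cat_i in names(BMI_MIDPOINTS)) {
      prof <- data.frame(age_years = age, bmi = BMI_MIDPOINTS[[cat_i]],
                         ethnicity_region = eth, parity_class = parity,
                         stringsAsFactors = FALSE)
      ct <- centile_curves(fit, prof, grid, levels)
      slug <- paste0(gsub("[^A-Za-z0-9]+", "_", eth), "_", cat_i)
      path <- file.path(output_dir, paste0("centiles_", slug, ".csv"))
      utils::write.csv(as.data.frame(ct), path, row.names = FALSE)
      if (render) {
        grDevices::pdf(file.path(output_dir, paste0("centiles_", slug, ".pdf")),
                       width = 7, height = 5)
        plot_centiles(ct, main = paste(eth, "-", cat_i))
        grDevices::dev.off()
      }
      out[[slug]] <- ct
    }
  }
  invisible(out)
}

#' Plot a centile table with base graphics
#'
#' @param x a `gwg_centiles` object.
#' @param main plot title.
#' @param ... passed to [graphics::matplot()].
#' @export
plot_centiles <- function(x, main = "GWG centiles", ...) {
  graphics::matplot(x$grid, x$values, type = "l", lty = 1,
                    col = grDevices::hcl.colors(ncol(x$values), "Zissou 1"),
                    xlab = "Gestational age (weeks)", ylab = "Weight gain (kg)",
                    main = main, ...)
  graphics::legend("topleft", legend = colnames(x$values), bty = "n",
                   col = grDevices::hcl.colors(ncol(x$values), "Zissou 1"),
                   lty = 1, cex = 0.8)
  invisible(x)
}

#' @rdname write_cohort
#' @param centiles a `gwg_centiles` object.
#' @export
write_centiles <- function(centiles, path) {
  utils::write.csv(as.data.frame(centiles), path, row.names = FALSE)
  invisible(path)
}
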