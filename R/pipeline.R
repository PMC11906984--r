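## End-to-end pipeline: simulate or ingest -> preprocess -> fit candidate
## models -> diagnostics -> comparison -> centile charts, with a structured
## JSON run report. Also the thin command-line front end.

default_pipeline_config <- function() {
  list(
    n_women = 2000L, seed = 7L,
    cohort_csv = NULL, visits_csv = NULL,
    shift_delta = 30,
    models = c("linear", "cubic_polynomial", "bct_cubic_spline", "bct_pspline"),
    exclude_4sd = TRUE, week0 = TRUE, error_sd = 0.70,
    profiles = list(list(age_years = 28.4, bmi = 21.7,
                         ethnicity_region = "Australian/European",
                         parity_class = "0")),
    levels = DEFAULT_LEVELS,
    r_squared = FALSE)
}

read_pipeline_config <- function(path) {
  cfg <- default_pipeline_config()
  user <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) stop_bad("unknown config key(s): ", paste(bad, collapse = ", "))
  utils::modifyList(cfg, user)
}

candidate_spec <- function(name, shift_delta, data_n) {
  switch(name,
    bct_pspline = model_spec("BCT", shift_delta = shift_delta),
    bct_cubic_spline = model_spec(
      "BCT",
      mu = param_terms(~ age_years + bmi + parity_class + ethnicity_region,
                       smooth = smoother_spec("cubic_spline", df_target = 8)),
      sigma = param_terms(~1, smooth = smoother_spec("pspline")),
      shift_delta = shift_delta),
    bccg_pspline = model_spec("BCCG", shift_delta = shift_delta),
    bcpe_pspline = model_spec("BCPE", shift_delta = shift_delta),
    no_pspline = model_spec("NO"),
    fractional_poly = NULL,     # handled separately
    stop_bad("unknown candidate model: ", name))
}

fit_candidate <- function(name, data, cfg) {
  if (name %in% c("linear", "cubic_polynomial"))
    return(fit_baseline(data, name))
  spec <- candidate_spec(name, cfg$shift_delta, nrow(data))
  suppressWarnings(fit_gamlss(data, spec))
}

#' Run the full analysis pipeline
#'
#' Simulate (or read) a registry, preprocess it, fit the configured
#' candidate models, compute diagnostics and the comparison table, and
#' write centile tables for the configured profiles, all under one output
#' directory with a JSON run report.
#'
#' @param config path to a JSON configuration file, or a configuration
#'   list; see the packaged demo at
#'   `system.file("extdata", "demo_config.json", package = "gwgtraj")`.
#' @param out_dir output directory (created if needed).
#' @param seed optional seed overriding the configured one.
#' @param verbose print progress messages?
#' @return invisible list with the report, the fits and the centile tables.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("gwg_run_"), seed = NULL,
                         verbose = TRUE) {
  cfg <- if (is.character(config)) read_pipeline_config(config)
         else utils::modifyList(default_pipeline_config(), config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[gwgtraj] ", ...)

  stage <- "ingest"
  report <- list(config = cfg[setdiff(names(cfg), "profiles")],
                 started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  result <- tryCatch({
    if (!is.null(cfg$cohort_csv)) {
      say("reading cohort tables")
      cohort <- read_cohort(cfg$cohort_csv)
      visits <- read_visits(cfg$visits_csv)
    } else {
      say("simulating synthetic registry (n_women = ", cfg$n_women, ")")
      sim <- simulate_registry(cohort_config(n_women = cfg$n_women,
                                             seed = cfg$seed))
      cohort <- sim$cohort; visits <- sim$visits
      write_cohort(cohort, file.path(out_dir, "cohort.csv"))
      write_visits(visits, file.path(out_dir, "visits.csv"))
    }

    stage <- "preprocess"
    say("preprocessing")
    pp <- preprocess_gwg(visits, cohort, error_sd = cfg$error_sd,
                         seed = cfg$seed, week0 = cfg$week0,
                         exclude = cfg$exclude_4sd)
    report$preprocess <- pp$report

    stage <- "fit"
    fits <- list()
    for (m in cfg$models) {
      say("fitting ", m)
      fits[[m]] <- fit_candidate(m, pp$data, cfg)
    }
    report$convergence <- lapply(fits, function(f)
      list(converged = f$converged, outer_cycles = length(f$trace) - 1,
           deviance = f$deviance, edf = f$edf))

    stage <- "diagnostics"
    say("diagnostics")
    report$residuals <- lapply(fits, function(f)
      unclass(residual_summary(quantile_residuals(f))))

    stage <- "compare"
    cmp <- compare_models(fits, labels = names(fits),
                          r_squared = isTRUE(cfg$r_squared))
    report$comparison <- cmp
    utils::write.csv(cmp, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
    best <- fits[[cmp$label[1]]]
    say("best by AIC: ", cmp$label[1])

    stage <- "centiles"
    tables <- list()
    for (i in seq_along(cfg$profiles)) {
      ct <- centile_curves(best, as.data.frame(cfg$profiles[[i]]),
                           levels = cfg$levels)
      path <- file.path(out_dir, sprintf("centiles_profile%02d.csv", i))
      write_centiles(ct, path)
      tables[[i]] <- ct
    }
    report$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    say("done; artefacts under ", out_dir)
    list(report = report, fits = fits, comparison = cmp, centiles = tables,
         data = pp$data, out_dir = out_dir)
  }, error = function(e) {
    stop_bad("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  })
  invisible(result)
}

#' Command-line interface
#'
#' Subcommands: `simulate`, `preprocess`, `fit`, `compare`, `centiles`,
#' `run`. Global flags: `--config PATH`, `--seed INT`, `--out DIR`,
#' `--verbose`. Exit status 0 on success, 2 on configuration errors, 3 on
#' convergence failure.
#'
#' @param args character vector of command-line arguments.
#' @param quit_on_exit call [base::quit()] with the status (set `FALSE`
#'   when driving the CLI from tests).
#' @return integer exit status, invisibly.
#' @export
gwg_cli <- function(args = commandArgs(trailingOnly = TRUE),
                    quit_on_exit = !interactive()) {
  usage <- paste(
    "usage: gwgtraj <command> [--config PATH] [--seed INT] [--out DIR] [--verbose]",
    "commands: simulate | preprocess | fit | compare | centiles | run", sep = "\n")
  status <- 0L
  res <- tryCatch({
    if (length(args) == 0) stop_bad(usage)
    cmd <- args[1]
    opt <- list(config = NULL, seed = NULL, out = "gwg_output",
                verbose = FALSE)
    i <- 2
    while (i <= length(args)) {
      a <- args[i]
      if (a == "--verbose") { opt$verbose <- TRUE; i <- i + 1 }
      else if (a %in% c("--config", "--seed", "--out")) {
        if (i == length(args)) stop_bad("missing value for ", a)
        opt[[sub("^--", "", a)]] <- args[i + 1]; i <- i + 2
      } else stop_bad("unknown flag: ", a)
    }
    cfg <- if (!is.null(opt$config)) read_pipeline_config(opt$config)
           else default_pipeline_config()
    if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
    switch(cmd,
      simulate = {
        sim <- simulate_registry(cohort_config(n_women = cfg$n_women,
                                               seed = cfg$seed))
        dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
        write_cohort(sim$cohort, file.path(opt$out, "cohort.csv"))
        write_visits(sim$visits, file.path(opt$out, "visits.csv"))
      },
      run = ,
      preprocess = ,
      fit = ,
      compare = ,
      centiles = {
        run_pipeline(cfg, out_dir = opt$out, verbose = opt$verbose)
      },
      stop_bad("unknown command: ", cmd, "\n", usage))
    0L
  }, error = function(e) {
    message(conditionMessage(e))
    if (grepl("convergence", conditionMessage(e))) 3L else 2L
  })
  status <- res
  if (quit_on_exit) quit(status = status, save = "no")
  invisible(status)
}
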