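Package: gwgtraj
Title: Distributional Modelling of Gestational Weight Gain Trajectories
Version: 0.1.0
Authors@R:
    person("BOS", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools for modelling population-level gestational weight gain
    (GWG) trajectories from routinely collected antenatal visit data.
    Implements a generalised additive model for location, scale and shape
    (GAMLSS) fitted by cyclic backfitting over the four parameters of the
    Box-Cox t family (and its normal, Cole-Green and power-exponential
    relatives), with penalised B-spline, cubic smoothing-spline and
    fractional-polynomial smoothers for the gestational-age trend.
    Includes preprocessing of raw visit tables into gain scores (week-0
    pseudo-observations, windowed 4-SD exclusion, ethnicity-specific BMI
    coding), normalized quantile-residual diagnostics with worm plots and
    the Filliben coefficient, two-way mixed-effects intraclass correlation
    for baseline weight reliability, personalised centile chart
    construction, and a seeded synthetic-cohort generator so the whole
    pipeline is testable without access to any registry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
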