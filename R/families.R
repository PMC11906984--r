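#' Response families for gestational weight gain modelling
#'
#' Four-parameter distribution machinery used by the fitting engine: the
#' Box-Cox t family (`BCT`), its Cole-Green (`BCCG`, normal kernel) and
#' power-exponential (`BCPE`) relatives, and the plain normal (`NO`).
#' The Box-Cox families have positive support; negative weight gains are
#' handled upstream by modelling `gwg + shift_delta` (see [model_spec()]).
#'
#' Parameterisation: `mu > 0` is the (approximate) median, `sigma > 0` an
#' approximate coefficient of variation, `nu` the Box-Cox transform power
#' controlling skewness (`nu = 1` is symmetric on the raw scale), and
#' `tau > 0` the kernel shape: t degrees of freedom for `BCT` (small `tau`
#' means heavy tails), power-exponential shape for `BCPE` (`tau = 2`
#' recovers `BCCG`). For `NO`, `mu` is unrestricted, `sigma` is the SD and
#' `nu`, `tau` are unused.
#'
#' @param y vector of positive responses (any real for `NO`).
#' @param p probabilities in (0, 1).
#' @param n number of draws.
#' @param mu,sigma,nu,tau distribution parameters, recycled against `y`/`p`.
#' @param family one of `"NO"`, `"BCCG"`, `"BCPE"`, `"BCT"`.
#' @param seed optional integer seed for [family_sample()].
#' @return `family_logpdf` the log density; `family_cdf` probabilities;
#'   `family_quantile` quantiles; `family_sample` random draws.
#' @examples
#' family_quantile(0.5, "BCT", mu = 40, sigma = 0.1, nu = -1, tau = 8)
#' @name gwg-families
NULL

GWG_FAMILIES <- c("NO", "BCCG", "BCPE", "BCT")

check_family <- function(family) {
  if (!is.character(family) || length(family) != 1L || !family %in% GWG_FAMILIES)
    stop_bad("family must be one of ", paste(GWG_FAMILIES, collapse = ", "))
  family
}

check_params <- function(family, mu, sigma, nu, tau, y = NULL) {
  if (any(!is.finite(mu)) || any(!is.finite(sigma)) || any(sigma <= 0))
    stop_bad("sigma must be finite and positive; mu finite")
  if (family != "NO") {
    if (any(mu <= 0)) stop_bad(family, " requires mu > 0")
    if (any(!is.finite(nu))) stop_bad("nu must be finite")
    if (!is.null(y) && any(y <= 0)) stop_bad(family, " has positive support")
  }
  if (family %in% c("BCPE", "BCT") && (any(!is.finite(tau)) || any(tau <= 0)))
    stop_bad("tau must be finite and positive for ", family)
  invisible(TRUE)
}

## --- power-exponential kernel, standardised to mean 0, variance 1 --------

pe_logc <- function(tau) 0.5 * (-(2 / tau) * log(2) + lgamma(1 / tau) - lgamma(3 / tau))

pe_logpdf0 <- function(z, tau) {
  lc <- pe_logc(tau)
  log(tau) - lc - 0.5 * abs(z / exp(lc))^tau - (1 + 1 / tau) * log(2) - lgamma(1 / tau)
}

pe_cdf0 <- function(q, tau) {
  cc <- exp(pe_logc(tau))
  s <- 0.5 * abs(q / cc)^tau
  0.5 * (1 + pgamma(s, shape = 1 / tau) * sign(q))
}

pe_quantile0 <- function(p, tau) {
  cc <- exp(pe_logc(tau))
  s <- qgamma(2 * abs(p - 0.5), shape = 1 / tau)
  sign(p - 0.5) * cc * (2 * s)^(1 / tau)
}

## kernel dispatch: density, cdf, quantile of the standardised kernel
kernel_logpdf <- function(z, family, tau) {
  switch(family,
    BCCG = dnorm(z, log = TRUE),
    BCPE = pe_logpdf0(z, tau),
    BCT  = dt(z, df = tau, log = TRUE)
  )
}

kernel_cdf <- function(q, family, tau) {
  switch(family,
    BCCG = pnorm(q),
    BCPE = pe_cdf0(q, tau),
    BCT  = pt(q, df = tau)
  )
}

kernel_quantile <- function(p, family, tau) {
  switch(family,
    BCCG = qnorm(p),
    BCPE = pe_quantile0(p, tau),
    BCT  = qt(p, df = tau)
  )
}

## Box-Cox transform z = ((y/mu)^nu - 1)/(nu sigma); expm1 keeps the nu -> 0
## limit exact to machine precision.
bc_z <- function(y, mu, sigma, nu) {
  k <- max(length(y), length(mu), length(sigma), length(nu))
  lr <- rep_len(log(y / mu), k)
  sigma <- rep_len(sigma, k); nu <- rep_len(nu, k)
  ifelse(abs(nu) < 1e-12, lr / sigma, expm1(nu * lr) / (nu * sigma))
}

#' @rdname gwg-families
#' @export
family_logpdf <- function(y, family, mu, sigma, nu = 1, tau = 10) {
  family <- check_family(family)
  if (family == "NO") {
    check_params(family, mu, sigma, nu, tau)
    return(dnorm(y, mean = mu, sd = sigma, log = TRUE))
  }
  check_params(family, mu, sigma, nu, tau, y = y)
  k <- max(length(y), length(mu), length(sigma), length(nu), length(tau))
  y <- rep_len(y, k); mu <- rep_len(mu, k); sigma <- rep_len(sigma, k)
  nu <- rep_len(nu, k); tau <- rep_len(tau, k)
  z <- bc_z(y, mu, sigma, nu)
  # truncation renormalises mass to the admissible z range; vanishes at nu = 0
  trunc <- ifelse(abs(nu) < 1e-12, 0,
                  log(kernel_cdf(1 / (sigma * abs(nu)), family, tau)))
  (nu - 1) * log(y) - nu * log(mu) - log(sigma) +
    kernel_logpdf(z, family, tau) - trunc
}

#' @rdname gwg-families
#' @export
family_cdf <- function(y, family, mu, sigma, nu = 1, tau = 10) {
  family <- check_family(family)
  if (family == "NO") {
    check_params(family, mu, sigma, nu, tau)
    return(pnorm(y, mean = mu, sd = sigma))
  }
  check_params(family, mu, sigma, nu, tau, y = y)
  k <- max(length(y), length(mu), length(sigma), length(nu), length(tau))
  y <- rep_len(y, k); mu <- rep_len(mu, k); sigma <- rep_len(sigma, k)
  nu <- rep_len(nu, k); tau <- rep_len(tau, k)
  z <- bc_z(y, mu, sigma, nu)
  Fz <- kernel_cdf(z, family, tau)
  lim <- 1 / (sigma * pmax(abs(nu), 1e-12))
  upper <- ifelse(abs(nu) < 1e-12, 1, kernel_cdf(lim, family, tau))
  lower <- ifelse(nu > 1e-12, kernel_cdf(-lim, family, tau), 0)
  pmin(pmax((Fz - lower) / upper, 0), 1)
}

#' @rdname gwg-families
#' @export
family_quantile <- function(p, family, mu, sigma, nu = 1, tau = 10) {
  family <- check_family(family)
  check_prob(p)
  if (family == "NO") {
    check_params(family, mu, sigma, nu, tau)
    return(qnorm(p, mean = mu, sd = sigma))
  }
  check_params(family, mu, sigma, nu, tau)
  k <- max(length(p), length(mu), length(sigma), length(nu), length(tau))
  p <- rep_len(p, k); mu <- rep_len(mu, k); sigma <- rep_len(sigma, k)
  nu <- rep_len(nu, k); tau <- rep_len(tau, k)
  lim <- 1 / (sigma * pmax(abs(nu), 1e-12))
  upper <- ifelse(abs(nu) < 1e-12, 1, kernel_cdf(lim, family, tau))
  lower <- ifelse(nu > 1e-12, kernel_cdf(-lim, family, tau), 0)
  z <- kernel_quantile(p * upper + lower, family, tau)
  ifelse(abs(nu) < 1e-12,
         mu * exp(sigma * z),
         mu * exp(log1p(nu * sigma * z) / nu))
}

#' @rdname gwg-families
#' @export
family_sample <- function(n, family, mu, sigma, nu = 1, tau = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  u <- runif(n)
  family_quantile(u, family, mu, sigma, nu, tau)
}

#' Box-Cox t density, distribution, quantile and sampling functions
#'
#' Convenience wrappers around the `"BCT"` case of the generic family API;
#' `dBCT` returns the density (or log density).
#'
#' @inheritParams gwg-families
#' @param x,q vector of positive quantiles.
#' @param log logical; return log density?
#' @export
dBCT <- function(x, mu = 1, sigma = 0.1, nu = 1, tau = 10, log = FALSE) {
  lp <- family_logpdf(x, "BCT", mu, sigma, nu, tau)
  if (log) lp else exp(lp)
}

#' @rdname dBCT
#' @export
pBCT <- function(q, mu = 1, sigma = 0.1, nu = 1, tau = 10)
  family_cdf(q, "BCT", mu, sigma, nu, tau)

#' @rdname dBCT
#' @export
qBCT <- function(p, mu = 1, sigma = 0.1, nu = 1, tau = 10)
  family_quantile(p, "BCT", mu, sigma, nu, tau)

#' @rdname dBCT
#' @export
rBCT <- function(n, mu = 1, sigma = 0.1, nu = 1, tau = 10, seed = NULL)
  family_sample(n, "BCT", mu, sigma, nu, tau, seed = seed)

## --- scores --------------------------------------------------------------

# Predictor scales used throughout the engine: mu identity (guarded positive
# for the Box-Cox families), sigma log, nu identity, tau log.
family_params <- function(family) {
  switch(family, NO = c("mu", "sigma"), BCCG = c("mu", "sigma", "nu"),
         BCPE = , BCT = c("mu", "sigma", "nu", "tau"))
}

eta_to_param <- function(eta, what) {
  switch(what,
    mu = eta, sigma = exp(eta), nu = eta,
    tau = pmin(pmax(exp(eta), 1e-2), 1e6))
}

param_to_eta <- function(value, what) {
  switch(what, mu = value, sigma = log(value), nu = value, tau = log(value))
}

#' Score functions on the predictor scale
#'
#' First derivatives of the per-observation log-likelihood with respect to
#' each parameter's additive predictor (`mu`: identity link, `sigma`: log,
#' `nu`: identity, `tau`: log). Analytic for the normal family and for the
#' `mu`/`sigma` scores of `BCCG`; central finite differences elsewhere.
#'
#' @inheritParams gwg-families
#' @param what which parameter's score, one of `"mu"`, `"sigma"`, `"nu"`, `"tau"`.
#' @return vector of derivatives, one per observation.
#' @export
param_scores <- function(y, family, mu, sigma, nu = 1, tau = 10,
                         what = c("mu", "sigma", "nu", "tau")) {
  family <- check_family(family)
  what <- match.arg(what)
  if (!what %in% family_params(family))
    stop_bad("parameter ", what, " is not part of family ", family)
  if (family == "NO") {
    if (what == "mu") return((y - mu) / sigma^2)
    return((y - mu)^2 / sigma^2 - 1)        # d l / d log(sigma)
  }
  if (family == "BCCG" && what %in% c("mu", "sigma")) {
    z <- bc_z(y, mu, sigma, nu)
    if (what == "mu") return((z / sigma + nu * (z^2 - 1)) / mu)
    a <- 1 / (sigma * pmax(abs(nu), 1e-12))
    # includes the truncation term's derivative on the log-sigma scale
    tr <- ifelse(abs(nu) < 1e-12, 0, a * dnorm(a) / pnorm(a))
    return(z^2 - 1 + tr)
  }
  # central difference on the predictor scale
  eta <- param_to_eta(switch(what, mu = mu, sigma = sigma, nu = nu, tau = tau), what)
  h <- 1e-5 * (1 + abs(eta))
  args <- list(mu = mu, sigma = sigma, nu = nu, tau = tau)
  args_hi <- args; args_hi[[what]] <- eta_to_param(eta + h, what)
  args_lo <- args; args_lo[[what]] <- eta_to_param(eta - h, what)
  lp_hi <- family_logpdf(y, family, args_hi$mu, args_hi$sigma, args_hi$nu, args_hi$tau)
  lp_lo <- family_logpdf(y, family, args_lo$mu, args_lo$sigma, args_lo$nu, args_lo$tau)
  (lp_hi - lp_lo) / (2 * h)
}
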