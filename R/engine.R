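#' Per-parameter term specification
#'
#' Additive predictor for one distribution parameter: a parametric formula
#' (intercept, linear and categorical terms) plus an optional smooth in
#' gestational age.
#'
#' @param formula right-hand-side formula of parametric terms, e.g.
#'   `~ age_years + bmi + parity_class + ethnicity_region`.
#' @param smooth optional [smoother_spec()] for the gestational-age trend
#'   (`"pspline"` or `"cubic_spline"` kinds are accepted by the engine).
#' @export
param_terms <- function(formula = ~1, smooth = NULL) {
  stopifnot(inherits(formula, "formula"))
  if (!is.null(smooth) && !inherits(smooth, "smoother_spec"))
    stop_bad("smooth must be a smoother_spec")
  structure(list(formula = formula, smooth = smooth), class = "param_terms")
}

#' Engine control parameters
#'
#' @param max_outer maximum outer backfitting cycles (default 50).
#' @param tol convergence tolerance on the change in global deviance.
#' @param step_halving_max maximum step-halvings per parameter update.
#' @param freeze_shape_iters outer cycles during which `nu` and `tau` are
#'   held at their initial values (stabilises the Box-Cox families).
#' @export
engine_control <- function(max_outer = 50L, tol = 1e-3, step_halving_max = 5L,
                           freeze_shape_iters = 2L) {
  list(max_outer = as.integer(max_outer), tol = tol,
       step_halving_max = as.integer(step_halving_max),
       freeze_shape_iters = as.integer(freeze_shape_iters))
}

#' Distributional regression model specification
#'
#' The default mirrors the chart-building model: covariates plus a
#' penalised B-spline in gestational age on the location, a gestational-age
#' smooth on the scale, and intercept-only skewness and kurtosis.
#'
#' @param family response family, see [family_logpdf()].
#' @param mu,sigma,nu,tau [param_terms()] for each distribution parameter.
#' @param shift_delta positive shift (kg) added to the gain scores before
#'   fitting a Box-Cox family (they have positive support; gains can be
#'   negative). Quantiles are shifted back on output. Ignored for `"NO"`.
#' @param control an [engine_control()] list.
#' @export
model_spec <- function(family = "BCT",
                       mu = param_terms(~ age_years + bmi + parity_class +
                                          ethnicity_region,
                                        smooth = smoother_spec("pspline")),
                       sigma = param_terms(~1, smooth = smoother_spec("pspline")),
                       nu = param_terms(~1),
                       tau = param_terms(~1),
                       shift_delta = 30,
                       control = engine_control()) {
  family <- check_family(family)
  if (shift_delta <= 0) stop_bad("shift_delta must be positive")
  structure(list(family = family,
                 terms = list(mu = mu, sigma = sigma, nu = nu, tau = tau),
                 shift_delta = shift_delta, control = control),
            class = "gwg_model_spec")
}

## --- design construction --------------------------------------------------

build_design <- function(pt, data, smooth_var = "gest_age") {
  tf <- stats::terms(pt$formula)
  mf <- stats::model.frame(tf, data, na.action = stats::na.fail)
  X <- stats::model.matrix(tf, mf)
  xlev <- stats::.getXlevels(tf, mf)
  des <- list(terms = tf, xlevels = xlev, X = X, smooth = NULL)
  if (!is.null(pt$smooth)) {
    if (!pt$smooth$kind %in% c("pspline", "cubic_spline"))
      stop_bad("the engine supports pspline and cubic_spline smooths")
    if (pt$smooth$kind == "cubic_spline") {
      if (!is.numeric(pt$smooth$df_target))
        stop_bad("a cubic_spline smooth needs a numeric df_target")
      des$smooth <- list(spec = pt$smooth, var = smooth_var, state = NULL)
      return(des)
    }
    x <- data[[smooth_var]]
    bas <- bspline_basis(x, pt$smooth)
    q <- ncol(bas$B)
    # sum-to-zero constraint on the coefficients removes the constant
    # direction that would be confounded with the intercept
    Z <- qr.Q(qr(matrix(1, q, 1)), complete = TRUE)[, -1, drop = FALSE]
    P <- diff_penalty(q, pt$smooth$penalty_order)
    des$smooth <- list(spec = pt$smooth, basis = bas, Z = Z,
                       B = bas$B %*% Z, var = smooth_var,
                       P = crossprod(Z, P %*% Z),
                       lambda = NULL)
  }
  des
}

design_matrix <- function(des, data) {
  A <- des$X
  if (!is.null(des$smooth)) A <- cbind(A, des$smooth$B)
  A
}

eval_design <- function(des, newdata) {
  tf <- stats::delete.response(des$terms)
  mf <- stats::model.frame(tf, newdata, xlev = des$xlevels,
                           na.action = stats::na.fail)
  X <- stats::model.matrix(tf, mf)
  if (is.null(des$smooth) || is.null(des$smooth$basis)) return(X)
  B <- eval_bspline(des$smooth$basis, newdata[[des$smooth$var]])
  cbind(X, B %*% des$smooth$Z)
}

## penalty matrix for the joint [X B] system
joint_penalty <- function(des, lambda) {
  p <- ncol(des$X)
  if (is.null(des$smooth)) return(matrix(0, p, p))
  q <- ncol(des$smooth$B)
  Pen <- matrix(0, p + q, p + q)
  Pen[(p + 1):(p + q), (p + 1):(p + q)] <- lambda * des$smooth$P
  Pen
}

## weighted penalised solve; rhs formed as A'(w*eta + u) so the working
## response never has to be materialised where the weight is tiny
solve_param <- function(A, Pen, w, eta, u) {
  AtW <- t(A * w)
  M <- AtW %*% A + Pen
  rhs <- crossprod(A, w * eta + u)
  ridge <- diag(1e-9 * (mean(diag(M)) + 1), nrow(M))
  coef <- tryCatch(solve(M, rhs), error = function(e) solve(M + ridge, rhs))
  edf <- sum(diag(tryCatch(solve(M, AtW %*% A), error = function(e)
    solve(M + ridge, AtW %*% A))))
  list(coef = drop(coef), eta = drop(A %*% coef), edf = edf)
}

## GAIC(2)-based lambda update on the current working problem
update_lambda <- function(A, des, w, eta, u, current) {
  n <- nrow(A)
  z_w <- w * eta + u            # = W z
  gaic <- function(lambda) {
    f <- solve_param(A, joint_penalty(des, lambda), w, eta, u)
    # weighted RSS of the working response: z'Wz - 2 c'A'Wz + c'A'WAc,
    # computed without forming z where w ~ 0
    r <- (w * eta + u) / pmax(w, 1e-10) - f$eta    # z - eta_hat
    rss <- sum(pmax(w, 1e-10) * r^2)
    n * log(max(rss, 1e-300) / n) + 2 * f$edf
  }
  grid <- if (is.null(current)) 10^seq(-3, 7, length.out = 11)
          else current * 10^seq(-1, 1, by = 0.5)
  grid[which.min(vapply(grid, gaic, 0))]
}

## one working-response update for a parameter's additive predictor.
## pspline smooths enter a joint penalised solve; cubic smoothing splines
## are backfitted against the parametric part.
fit_working <- function(d, data, w, eta, u) {
  if (is.null(d$smooth) || d$smooth$spec$kind == "pspline") {
    A <- if (is.null(d$smooth)) d$X else cbind(d$X, d$smooth$B)
    if (!is.null(d$smooth)) {
      if (identical(d$smooth$spec$df_target, "auto")) {
        d$smooth$lambda <- update_lambda(A, d, w, eta, u, d$smooth$lambda)
      } else if (is.null(d$smooth$lambda)) {
        d$smooth$lambda <- lambda_for_df(A, w, joint_penalty(d, 1),
                                         ncol(d$X) + d$smooth$spec$df_target)
      }
    }
    f <- solve_param(A, joint_penalty(d, d$smooth$lambda %||% 0), w, eta, u)
    return(list(eta = f$eta, coef = f$coef, edf = f$edf, d = d))
  }
  # cubic smoothing spline: classic backfitting on the working response
  wf <- pmax(w, 1e-10)
  z <- eta + u / wf
  x <- data[[d$smooth$var]]
  X <- d$X
  s <- if (is.null(d$smooth$state)) rep(0, length(z)) else d$smooth$state$fitted0
  beta <- NULL; st <- NULL
  for (cycle in 1:3) {
    ls <- stats::lm.wfit(X, z - s, wf)
    beta <- ls$coefficients
    st <- cubic_spline_fit(x, z - drop(X %*% beta), weights = wf,
                           df_target = d$smooth$spec$df_target,
                           all_knots = FALSE)
    sbar <- sum(wf * st$fitted) / sum(wf)
    s <- st$fitted - sbar
  }
  # absorb the smooth's level into the parametric part one last time
  ls <- stats::lm.wfit(X, z - s, wf)
  beta <- ls$coefficients
  base_pred <- st$predict
  shift <- sum(wf * st$fitted) / sum(wf)
  st$fitted0 <- s
  st$predict_centred <- function(newx) base_pred(newx) - shift
  d$smooth$state <- st
  list(eta = drop(X %*% beta) + s, coef = beta,
       edf = ncol(X) + st$edf - 1, d = d)
}

globaldev <- function(y, family, par) {
  -2 * sum(family_logpdf(y, family, par$mu, par$sigma, par$nu, par$tau))
}

clamp_eta <- function(eta, what, family) {
  if (what == "mu" && family != "NO") return(pmax(eta, 1e-2))
  if (what == "sigma") return(pmin(pmax(eta, log(1e-5)), log(5)))
  if (what == "nu") return(pmin(pmax(eta, -10), 10))
  if (what == "tau") return(pmin(pmax(eta, log(1e-2)), log(1e6)))
  eta
}

#' Fit a distributional regression model by cyclic backfitting
#'
#' For each distribution parameter in turn (mu, sigma, nu, tau), the
#' engine forms the score `u` of the log-likelihood with respect to that
#' parameter's predictor, quasi-Fisher weights `w = u^2` (floored at
#' 1e-10), and updates the predictor by a penalised weighted least-squares
#' fit of the working response `eta + u/w`. Updates that increase the
#' global deviance are step-halved; the outer loop stops when the deviance
#' changes by less than `control$tol`.
#'
#' @param data preprocessed gain observations (needs `gwg_kg`, `gest_age`
#'   and any covariates named in the spec).
#' @param spec a [model_spec()].
#' @param verbose print the deviance trace?
#' @return object of class `gwg_fit`.
#' @export
fit_gamlss <- function(data, spec = model_spec(), verbose = FALSE) {
  stopifnot(inherits(spec, "gwg_model_spec"))
  family <- spec$family
  delta <- if (family == "NO") 0 else spec$shift_delta
  y <- data$gwg_kg + delta
  if (family != "NO" && any(y <= 0))
    stop_bad("shift_delta too small: shifted response must be positive")
  n <- length(y)
  ctrl <- spec$control
  pars <- family_params(family)
  des <- lapply(spec$terms[pars], build_design, data = data)

  # initialisation: mu from a response-scale penalised LS fit on its own
  # design (so the starting predictor lies in the model span), constants
  # elsewhere
  eta <- list()
  init_fit <- fit_working(des$mu, data, rep(1, n), y, rep(0, n))
  des$mu <- init_fit$d
  eta$mu <- clamp_eta(init_fit$eta, "mu", family)
  s0 <- if (family == "NO") sd(y) else sd(y / pmax(eta$mu, 1e-2))
  eta$sigma <- rep(log(max(s0, 1e-4)), n)
  if ("nu" %in% pars) eta$nu <- rep(1, n)
  if ("tau" %in% pars) eta$tau <- rep(log(10), n)

  cur_par <- function() lapply(stats::setNames(pars, pars), function(k)
    eta_to_param(eta[[k]], k))
  par <- cur_par()
  par$nu <- par$nu %||% 1; par$tau <- par$tau %||% 10
  dev <- globaldev(y, family, par)
  if (!is.finite(dev)) stop_bad("non-finite likelihood at initialisation")
  trace <- dev
  coefs <- lapply(stats::setNames(pars, pars), function(k) {
    d <- des[[k]]
    p <- ncol(d$X) +
      if (is.null(d$smooth) || is.null(d$smooth$B)) 0L else ncol(d$smooth$B)
    cf <- numeric(p)
    cf[1] <- eta[[k]][1]        # designs carry an intercept first
    cf
  })
  coefs$mu <- init_fit$coef
  edfs <- stats::setNames(rep(NA_real_, length(pars)), pars)
  edfs["mu"] <- init_fit$edf
  converged <- FALSE

  for (iter in seq_len(ctrl$max_outer)) {
    dev_start <- dev
    for (k in pars) {
      if (k %in% c("nu", "tau") && family != "NO" &&
          iter <= ctrl$freeze_shape_iters) next
      u <- param_scores(y, family, par$mu, par$sigma, par$nu, par$tau, what = k)
      if (any(!is.finite(u))) u[!is.finite(u)] <- 0
      w <- pmax(u^2, 1e-10)
      fitk <- fit_working(des[[k]], data, w, eta[[k]], u)
      eta_new <- clamp_eta(fitk$eta, k, family)
      # step-halving on deviance increase
      eta_old <- eta[[k]]
      accepted <- FALSE
      for (h in 0:ctrl$step_halving_max) {
        eta_try <- eta_old + (eta_new - eta_old) / 2^h
        par_try <- par
        par_try[[k]] <- eta_to_param(eta_try, k)
        dev_try <- globaldev(y, family, par_try)
        if (is.finite(dev_try) && dev_try <= dev + 1e-8) {
          eta[[k]] <- eta_try; par <- par_try; dev <- dev_try
          accepted <- TRUE
          break
        }
      }
      if (accepted) {
        coefs[[k]] <- fitk$coef
        edfs[k] <- fitk$edf
        des[[k]] <- fitk$d
      }
    }
    trace <- c(trace, dev)
    if (verbose) message(sprintf("iter %2d deviance %.4f", iter, dev))
    if (abs(dev_start - dev) < ctrl$tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("fit_gamlss: outer iteration cap reached before convergence",
            call. = FALSE)
  # parameters without an accepted update keep their (constant) initial
  # value; count 1 edf for each fitted constant
  for (k in pars) if (is.na(edfs[k]))
    edfs[k] <- if (is.null(des[[k]]$smooth)) ncol(des[[k]]$X) else NA_real_
  total_edf <- sum(edfs, na.rm = TRUE)
  structure(list(
    family = family, spec = spec, shift_delta = delta,
    designs = des, coefs = coefs, eta = eta,
    fitted = par, deviance = dev, logLik = -dev / 2,
    edf = total_edf, edf_by_param = edfs, n = n,
    lambda = lapply(des, function(d) d$smooth$lambda),
    converged = converged, trace = trace,
    data = data),
    class = "gwg_fit")
}

#' @export
print.gwg_fit <- function(x, ...) {
  cat("GWG distributional fit —", x$family, "family\n")
  cat("  n =", x$n, " global deviance =", round(x$deviance, 2),
      " edf =", round(x$edf, 2), "\n")
  cat("  AIC =", round(x$deviance + 2 * x$edf, 2),
      " SBC =", round(x$deviance + log(x$n) * x$edf, 2), "\n")
  cat("  converged:", x$converged, "(", length(x$trace) - 1, "outer cycles )\n")
  invisible(x)
}

#' Evaluate the fitted distribution parameters for new observations
#'
#' @param fit a `gwg_fit`.
#' @param newdata data frame with the covariates and `gest_age`.
#' @return list of vectors `mu`, `sigma`, `nu`, `tau` (shifted scale).
#' @export
predict_params <- function(fit, newdata) {
  pars <- family_params(fit$family)
  out <- list()
  for (k in pars) {
    cf <- fit$coefs[[k]]
    d <- fit$designs[[k]]
    if (is.null(cf)) {            # constant parameter never updated
      out[[k]] <- rep(fit$fitted[[k]][1], nrow(newdata))
      next
    }
    eta <- if (!is.null(d$smooth) && d$smooth$spec$kind == "cubic_spline" &&
               !is.null(d$smooth$state)) {
      tf <- stats::delete.response(d$terms)
      mf <- stats::model.frame(tf, newdata, xlev = d$xlevels,
                               na.action = stats::na.fail)
      drop(stats::model.matrix(tf, mf) %*% cf) +
        d$smooth$state$predict_centred(newdata[[d$smooth$var]])
    } else {
      drop(eval_design(d, newdata) %*% cf)
    }
    out[[k]] <- eta_to_param(clamp_eta(eta, k, fit$family), k)
  }
  out$nu <- out$nu %||% rep(1, nrow(newdata))
  out$tau <- out$tau %||% rep(10, nrow(newdata))
  out
}

#' Baseline regression fits (linear and cubic polynomial)
#'
#' Normal-family least-squares fits returned in the same shape as
#' [fit_gamlss()] results so that diagnostics and model comparison apply
#' uniformly. The linear model regresses the gain on gestational age and
#' the covariates; the cubic adds squared and cubic gestational-age terms.
#'
#' @param data gain observations.
#' @param which `"linear"` or `"cubic_polynomial"`.
#' @param formula optional explicit right-hand-side formula; the default
#'   uses `gest_age` (plus its powers for the cubic) and whichever of
#'   `age_years`, `bmi`, `parity_class`, `ethnicity_region` are present.
#' @return object of class `gwg_fit` (family `"NO"`).
#' @export
fit_baseline <- function(data, which = c("linear", "cubic_polynomial"),
                         formula = NULL) {
  which <- match.arg(which)
  if (is.null(formula)) {
    covs <- intersect(c("age_years", "bmi", "parity_class", "ethnicity_region"),
                      names(data))
    covs <- covs[vapply(covs, function(v) length(unique(data[[v]])) > 1, TRUE)]
    rhs <- c("gest_age",
             if (which == "cubic_polynomial") c("I(gest_age^2)", "I(gest_age^3)"),
             covs)
    formula <- stats::reformulate(rhs)
  } else if (which == "cubic_polynomial" &&
             !any(grepl("gest_age\\^3", deparse(formula)))) {
    formula <- stats::update.formula(formula,
      ~ . + I(gest_age^2) + I(gest_age^3))
  }
  tf <- stats::terms(formula)
  mf <- stats::model.frame(tf, data)
  X <- stats::model.matrix(tf, mf)
  y <- data$gwg_kg
  ls <- stats::lm.fit(X, y)
  if (ls$rank < ncol(X)) stop_bad("rank-deficient baseline design")
  mu <- ls$fitted.values
  sigma <- sqrt(sum(ls$residuals^2) / length(y))   # MLE divisor n
  dev <- -2 * sum(dnorm(y, mu, sigma, log = TRUE))
  des <- list(mu = list(terms = tf, xlevels = stats::.getXlevels(tf, mf),
                        X = X, smooth = NULL))
  structure(list(
    family = "NO", spec = NULL, shift_delta = 0, which = which,
    designs = des,
    coefs = list(mu = ls$coefficients, sigma = log(sigma)),
    eta = list(mu = mu, sigma = rep(log(sigma), length(y))),
    fitted = list(mu = mu, sigma = rep(sigma, length(y)),
                  nu = 1, tau = 10),
    deviance = dev, logLik = -dev / 2,
    edf = ncol(X) + 1, edf_by_param = c(mu = ncol(X), sigma = 1),
    n = length(y), lambda = NULL, converged = TRUE, trace = dev,
    data = data),
    class = "gwg_fit")
}

## intercept-only fit of the same family, for the Nagelkerke R-squared
fit_null <- function(fit) {
  data <- fit$data
  if (fit$family == "NO") {
    y <- data$gwg_kg
    mu <- mean(y); s <- sqrt(mean((y - mu)^2))
    return(list(logLik = sum(dnorm(y, mu, s, log = TRUE)), n = length(y)))
  }
  spec0 <- model_spec(family = fit$family,
                      mu = param_terms(~1), sigma = param_terms(~1),
                      nu = param_terms(~1), tau = param_terms(~1),
                      shift_delta = fit$shift_delta,
                      control = engine_control(max_outer = 30L, tol = 1e-2))
  f0 <- suppressWarnings(fit_gamlss(data, spec0))
  list(logLik = f0$logLik, n = f0$n)
}

#' Rank fitted models by information criteria
#'
#' `AIC = deviance + 2 edf`, `SBC = deviance + log(n) edf`, plus the
#' Nagelkerke generalised R-squared against the intercept-only fit of each
#' model's own family. Sorted ascending by AIC; ties broken by SBC, then
#' label.
#'
#' @param fits list of `gwg_fit` objects on the identical observation set.
#' @param labels character labels, one per fit.
#' @param r_squared compute the generalised R-squared column? (Requires a
#'   null refit per Box-Cox family; disable for speed.)
#' @return data frame, one row per model.
#' @export
compare_models <- function(fits, labels = names(fits), r_squared = TRUE) {
  if (is.null(labels)) labels <- paste0("model", seq_along(fits))
  ns <- vapply(fits, function(f) f$n, 0)
  if (length(unique(ns)) != 1L)
    stop_bad("all fits must be on the identical observation set")
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    r2 <- if (r_squared) {
      nf <- fit_null(f)
      1 - exp((2 / f$n) * (nf$logLik - f$logLik))
    } else NA_real_
    data.frame(label = labels[i], family = f$family,
               deviance = f$deviance, edf = f$edf,
               aic = f$deviance + 2 * f$edf,
               sbc = f$deviance + log(f$n) * f$edf,
               r2 = r2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$aic, out$sbc, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}
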