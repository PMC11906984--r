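#' Smoother specification
#'
#' Describes an additive term for the gestational-age trend. `pspline` is a
#' degree-3 B-spline basis on equally spaced knots with a difference penalty
#' on adjacent coefficients; `cubic_spline` a natural cubic smoothing spline
#' targeted at a fixed effective df; `fractional_poly` a best-subset
#' fractional polynomial; `polynomial`/`linear` plain parametric trends.
#'
#' @param kind one of `"pspline"`, `"cubic_spline"`, `"fractional_poly"`,
#'   `"polynomial"`, `"linear"`.
#' @param knots number of interior knots for the P-spline basis (default 20).
#' @param degree B-spline degree (default 3, cubic).
#' @param penalty_order order of the difference penalty (default 2, so
#'   straight lines are unpenalised).
#' @param df_target effective degrees of freedom, or `"auto"` to choose the
#'   smoothing parameter by generalised AIC.
#' @param power_set candidate fractional-polynomial powers.
#' @param fp_degree fractional-polynomial degree, 1 or 2.
#' @param poly_degree degree for `kind = "polynomial"`.
#' @return an object of class `smoother_spec`.
#' @export
smoother_spec <- function(kind = c("pspline", "cubic_spline", "fractional_poly",
                                   "polynomial", "linear"),
                          knots = 20L, degree = 3L, penalty_order = 2L,
                          df_target = "auto",
                          power_set = c(-2, -1, -0.5, 0, 0.5, 1, 2, 3),
                          fp_degree = 1L, poly_degree = 3L) {
  kind <- match.arg(kind)
  if (knots < penalty_order + 1L) stop_bad("need knots >= penalty_order + 1")
  if (is.numeric(df_target) && df_target < 1) stop_bad("df_target must be >= 1")
  if (!fp_degree %in% 1:2) stop_bad("fp_degree must be 1 or 2")
  structure(list(kind = kind, knots = as.integer(knots),
                 degree = as.integer(degree),
                 penalty_order = as.integer(penalty_order),
                 df_target = df_target, power_set = sort(power_set),
                 fp_degree = as.integer(fp_degree),
                 poly_degree = as.integer(poly_degree)),
            class = "smoother_spec")
}

#' B-spline basis on equally spaced knots
#'
#' Builds the P-spline design matrix: `spec$knots` interior knots equally
#' spaced over `xrange`, extended by `degree` invisible boundary knots each
#' side, so each row sums to one. Values of `x` outside `xrange` are clamped
#' to the boundary (flat extrapolation of the basis).
#'
#' @param x evaluation points.
#' @param spec a [smoother_spec()].
#' @param xrange numeric length-2 range defining the knot span; defaults to
#'   `range(x)`.
#' @return list with the basis matrix `B`, the full knot vector, `degree`
#'   and `xrange`.
#' @export
bspline_basis <- function(x, spec = smoother_spec(), xrange = NULL) {
  xrange <- xrange %||% range(x)
  if (diff(xrange) <= 0) stop_bad("degenerate x range")
  nseg <- spec$knots + 1L
  if (length(unique(x)) < 2L && is.null(xrange))
    stop_bad("need at least two distinct x values")
  h <- diff(xrange) / nseg
  kn <- seq(xrange[1] - spec$degree * h, xrange[2] + spec$degree * h,
            length.out = nseg + 2L * spec$degree + 1L)
  # clamp inside the valid design range, robust to fp rounding of the knots
  lo <- kn[spec$degree + 1L]; hi <- kn[length(kn) - spec$degree]
  xc <- pmin(pmax(x, lo), hi)
  B <- splines::splineDesign(knots = kn, x = xc, ord = spec$degree + 1L)
  list(B = B, knots = kn, degree = spec$degree, xrange = xrange)
}

## evaluate a stored basis at new points (clamped to the knot span)
eval_bspline <- function(bas, newx) {
  kn <- bas$knots
  lo <- kn[bas$degree + 1L]; hi <- kn[length(kn) - bas$degree]
  splines::splineDesign(knots = kn, x = pmin(pmax(newx, lo), hi),
                        ord = bas$degree + 1L)
}

diff_penalty <- function(p, order) {
  D <- diff(diag(p), differences = order)
  crossprod(D)
}

## penalised weighted LS solve; ridge fallback for singular systems
pen_wls <- function(B, y, w, P, lambda) {
  BtW <- t(B * w)
  A <- BtW %*% B + lambda * P
  b <- BtW %*% y
  coef <- tryCatch(solve(A, b), error = function(e) {
    solve(A + diag(1e-8, nrow(A)), b)
  })
  H <- tryCatch(solve(A, BtW %*% B), error = function(e)
    solve(A + diag(1e-8, nrow(A)), BtW %*% B))
  list(coef = drop(coef), edf = sum(diag(H)))
}

#' Fit a penalised B-spline smoother
#'
#' Solves the penalised weighted least-squares problem
#' `min sum w (y - B a)^2 + lambda * ||D a||^2` with `D` the order-`d`
#' difference operator on adjacent basis coefficients.
#'
#' @param x,y data vectors.
#' @param weights positive observation weights (default 1).
#' @param spec a [smoother_spec()].
#' @param lambda smoothing parameter `>= 0`; if `NULL`, chosen by
#'   [select_lambda()] when `spec$df_target == "auto"`, otherwise solved to
#'   match `spec$df_target`.
#' @return a `smoother_state` list: coefficients, `lambda`, effective df,
#'   fitted values and a `predict(newx)` closure.
#' @export
pspline_fit <- function(x, y, weights = NULL, spec = smoother_spec(),
                        lambda = NULL) {
  w <- weights %||% rep(1, length(x))
  if (any(w <= 0)) stop_bad("weights must be positive")
  bas <- bspline_basis(x, spec)
  P <- diff_penalty(ncol(bas$B), spec$penalty_order)
  if (is.null(lambda)) {
    lambda <- if (identical(spec$df_target, "auto"))
      select_lambda(x, y, weights = w, spec = spec)
    else
      lambda_for_df(bas$B, w, P, spec$df_target)
  }
  if (lambda < 0) stop_bad("lambda must be >= 0")
  fit <- pen_wls(bas$B, y, w, P, lambda)
  state <- list(kind = "pspline", coef = fit$coef, lambda = lambda,
                edf = fit$edf, basis = bas,
                fitted = drop(bas$B %*% fit$coef))
  state$predict <- function(newx) {
    drop(eval_bspline(bas, newx) %*% fit$coef)
  }
  class(state) <- "smoother_state"
  state
}

edf_at_lambda <- function(B, w, P, lambda) {
  BtWB <- crossprod(B * sqrt(w))
  A <- BtWB + lambda * P
  ridge <- diag(1e-9 * (mean(diag(A)) + 1), nrow(A))
  H <- tryCatch(solve(A, BtWB), error = function(e) solve(A + ridge, BtWB))
  sum(diag(H))
}

## monotone search: edf decreases in lambda
lambda_for_df <- function(B, w, P, df_target, tol = 1e-3) {
  lo <- 1e-8; hi <- 1e12
  f <- function(ll) edf_at_lambda(B, w, P, exp(ll)) - df_target
  if (f(log(lo)) < 0) return(lo)
  if (f(log(hi)) > 0) return(hi)
  exp(uniroot(f, c(log(lo), log(hi)), tol = tol)$root)
}

#' Choose a P-spline smoothing parameter by generalised AIC
#'
#' Minimises `n * log(RSS_w / n) + 2 * edf` (the Gaussian profile deviance
#' plus twice the effective df) over a log-spaced `lambda` grid, refined by
#' golden-section search between the grid minimum's neighbours.
#' Deterministic.
#'
#' @inheritParams pspline_fit
#' @param grid log10-spaced candidate grid for `lambda`.
#' @return the selected `lambda`.
#' @export
select_lambda <- function(x, y, weights = NULL, spec = smoother_spec(),
                          grid = 10^seq(-4, 8, length.out = 25)) {
  w <- weights %||% rep(1, length(x))
  bas <- bspline_basis(x, spec)
  P <- diff_penalty(ncol(bas$B), spec$penalty_order)
  n <- length(y)
  gaic <- function(lambda) {
    fit <- pen_wls(bas$B, y, w, P, lambda)
    rss <- sum(w * (y - drop(bas$B %*% fit$coef))^2)
    n * log(max(rss, 1e-300) / n) + 2 * fit$edf
  }
  vals <- vapply(grid, gaic, 0)
  i <- which.min(vals)
  lo <- log(grid[max(1, i - 1)]); hi <- log(grid[min(length(grid), i + 1)])
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- gaic(exp(c1)); f2 <- gaic(exp(c2))
  for (it in 1:40) {
    if (f1 < f2) { b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- gaic(exp(c1))
    } else { a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- gaic(exp(c2)) }
    if (b - a < 1e-4) break
  }
  exp((a + b) / 2)
}

#' Natural cubic smoothing spline with a target effective df
#'
#' Thin wrapper around [stats::smooth.spline()] with the smoothing
#' parameter solved so that the trace of the smoother matrix matches
#' `df_target`. `df_target` equal to the number of distinct `x` values
#' returns the natural interpolating spline. Ties in `x` are collapsed by
#' weighted averaging.
#'
#' @inheritParams pspline_fit
#' @param df_target requested effective degrees of freedom, in
#'   `[2, number of distinct x]`.
#' @param all_knots logical; use every distinct `x` as a knot (exact natural
#'   spline). Defaults to `TRUE` for up to 200 distinct values.
#' @export
cubic_spline_fit <- function(x, y, weights = NULL, df_target,
                             all_knots = length(unique(x)) <= 200) {
  w <- weights %||% rep(1, length(x))
  nux <- length(unique(x))
  if (df_target < 2 || df_target > nux)
    stop_bad("df_target must lie in [2, number of distinct x]")
  if (df_target <= 2 + 1e-8) {
    # lambda -> Inf limit of the natural spline: weighted least-squares line
    fit <- stats::lm.wfit(cbind(1, x), y, w)
    cf <- fit$coefficients
    state <- list(kind = "cubic_spline", edf = 2, lambda = Inf,
                  fitted = fit$fitted.values,
                  predict = function(newx) cf[1] + cf[2] * newx)
    class(state) <- "smoother_state"
    return(state)
  }
  if (df_target >= nux - 1e-8) {
    agg <- collapse_ties(x, y, w)
    fn <- stats::splinefun(agg$x, agg$y, method = "natural")
    state <- list(kind = "cubic_spline", edf = nux, lambda = 0,
                  fitted = fn(x), predict = fn)
    class(state) <- "smoother_state"
    return(state)
  }
  fit <- stats::smooth.spline(x, y, w = w, df = df_target, cv = FALSE,
                              all.knots = all_knots,
                              control.spar = list(low = -3, high = 4, tol = 1e-6))
  state <- list(kind = "cubic_spline", edf = fit$df, lambda = fit$lambda,
                fitted = predict(fit, x)$y,
                predict = function(newx) predict(fit, newx)$y,
                sspline = fit)
  class(state) <- "smoother_state"
  state
}

collapse_ties <- function(x, y, w) {
  ux <- sort(unique(x))
  yy <- vapply(ux, function(v) {
    i <- x == v
    sum(w[i] * y[i]) / sum(w[i])
  }, 0)
  list(x = ux, y = yy)
}

## fractional polynomial basis under the Royston-Altman convention:
## power 0 is log x; repeated powers multiply by log x.
fp_basis <- function(x, powers) {
  out <- matrix(NA_real_, length(x), length(powers))
  prev_p <- NULL
  for (j in seq_along(powers)) {
    p <- powers[j]
    col <- if (p == 0) log(x) else x^p
    if (!is.null(prev_p) && identical(p, prev_p)) col <- out[, j - 1] * log(x)
    out[, j] <- col
    prev_p <- p
  }
  colnames(out) <- paste0("fp", seq_along(powers))
  out
}

#' Best-subset fractional polynomial fit
#'
#' Enumerates all power combinations of the configured degree from
#' `spec$power_set` (repeated powers use the `x^p`, `x^p log x` convention;
#' power 0 means `log x`), fits each by weighted least squares with an
#' intercept, and keeps the combination with the smallest weighted residual
#' sum of squares. `x` must be positive; non-positive values trigger a
#' logged location shift.
#'
#' @inheritParams pspline_fit
#' @export
fractional_poly_fit <- function(x, y, weights = NULL, spec = smoother_spec("fractional_poly")) {
  w <- weights %||% rep(1, length(x))
  shift <- 0
  if (min(x) <= 0) {
    ux <- sort(unique(x))
    inc <- if (length(ux) > 1) min(diff(ux)) else 1
    shift <- -min(x) + inc
    message("fractional_poly_fit: shifting x by ", signif(shift, 4),
            " to obtain positive support")
  }
  xs <- x + shift
  pw <- spec$power_set
  cands <- if (spec$fp_degree == 1L) lapply(pw, function(p) p)
  else {
    out <- list()
    for (i in seq_along(pw)) for (j in i:length(pw))
      out[[length(out) + 1L]] <- c(pw[i], pw[j])
    out
  }
  best <- NULL
  for (powers in cands) {
    X <- cbind(1, fp_basis(xs, powers))
    fit <- stats::lm.wfit(X, y, w)
    rss <- sum(w * fit$residuals^2)
    if (is.null(best) || rss < best$rss)
      best <- list(rss = rss, powers = powers, coef = fit$coefficients,
                   fitted = fit$fitted.values)
  }
  state <- list(kind = "fractional_poly", powers = best$powers,
                coef = best$coef, shift = shift, rss = best$rss,
                edf = length(best$coef), lambda = 0,
                fitted = best$fitted, n_candidates = length(cands))
  state$predict <- function(newx)
    drop(cbind(1, fp_basis(newx + shift, best$powers)) %*% best$coef)
  class(state) <- "smoother_state"
  state
}
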