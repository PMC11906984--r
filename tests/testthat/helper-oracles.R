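# Independent oracles and small fixture builders shared across the suite.

# de Boor recursion for a single B-spline basis function (textbook form,
# independent of splines::splineDesign)
deboor_basis <- function(x, knots, i, degree) {
  if (degree == 0)
    return(as.numeric(knots[i] <= x & x < knots[i + 1]))
  d1 <- knots[i + degree] - knots[i]
  d2 <- knots[i + degree + 1] - knots[i + 1]
  a <- if (d1 > 0) (x - knots[i]) / d1 * deboor_basis(x, knots, i, degree - 1) else 0
  b <- if (d2 > 0) (knots[i + degree + 1] - x) / d2 *
         deboor_basis(x, knots, i + 1, degree - 1) else 0
  a + b
}

# dense penalised WLS by augmented least squares through qr (independent of
# the package's normal-equations solve)
pspline_dense_oracle <- function(B, y, w, D, lambda) {
  aug_X <- rbind(B * sqrt(w), sqrt(lambda) * D)
  aug_y <- c(sqrt(w) * y, rep(0, nrow(D)))
  qr.coef(qr(aug_X), aug_y)
}

# difference operator used by the oracle
diff_matrix <- function(p, order) diff(diag(p), differences = order)

# direct simulation from a BCT truth with a known median curve; the
# "correctly specified" world for recovery, residual and coverage tests
bct_sim <- function(n, seed, sigma = 0.12, nu = -1, tau = 8, delta = 30,
                    median_curve = function(t) 0.0025 * t^2 + 0.18 * t) {
  set.seed(seed)
  t <- runif(n, 4, 42)
  u <- runif(n)
  y <- family_quantile(u, "BCT", mu = median_curve(t) + delta,
                       sigma = sigma, nu = nu, tau = tau) - delta
  data.frame(gwg_kg = y, gest_age = t)
}

recovery_spec <- function(tol = 1e-4, max_outer = 200) {
  model_spec("BCT",
             mu = param_terms(~1, smooth = smoother_spec("pspline")),
             sigma = param_terms(~1), nu = param_terms(~1),
             tau = param_terms(~1),
             control = engine_control(tol = tol, max_outer = max_outer))
}

# small registry simulation used by several files
small_registry <- function(n_women = 600, seed = 7) {
  simulate_registry(cohort_config(n_women = n_women, seed = seed))
}
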