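---
title: "Modelling gestational weight gain trajectories: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gestational weight gain trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gwgtraj)
```

## The problem

Gestational weight gain (GWG) — the weight measured at gestational age
$t$ minus the pre-pregnancy weight — is nonlinear in $t$, increasingly
variable as pregnancy progresses, positively skewed, and heavy-tailed.
Centile charts, the output clinicians want, are statements about the whole
conditional distribution of gain given gestational age and maternal
covariates, not just its mean. `gwgtraj` therefore centres on
distributional regression: every parameter of the response distribution
gets its own additive predictor.

## The model

On the shifted scale $y' = \mathrm{gwg} + \delta$ (see below), the
response follows a Box-Cox $t$ (BCT) distribution with parameters
$(\mu, \sigma, \nu, \tau)$. Writing $z = ((y'/\mu)^\nu - 1)/(\nu\sigma)$
(and $z = \log(y'/\mu)/\sigma$ at $\nu = 0$), the log-density is

$$\log f(y') = (\nu - 1)\log y' - \nu \log \mu - \log\sigma
  + \log f_T(z;\tau) - \log F_T\!\big(1/(\sigma|\nu|);\tau\big),$$

where $f_T, F_T$ are the Student-$t$ density and CDF with $\tau$ degrees
of freedom; the last term renormalises for the truncation implied by the
transform. $\mu$ is the (near-exact) median, $\sigma$ a coefficient of
variation, $\nu$ controls skewness ($\nu = 1$: symmetric on the raw
scale; $\nu < 1$: positive skew), $\tau$ the tails. Replacing the $t$
kernel by the standard normal gives the Cole-Green family (BCCG); by the
power exponential with shape $\tau$, BCPE (so BCPE with $\tau = 2$ *is*
BCCG — one of the identities the test suite pins). The plain normal (NO)
on the unshifted scale completes the set and carries the linear and
cubic-polynomial baselines.

Each parameter has a predictor: by default covariates (age, BMI, parity
class, birth-region) plus a penalised B-spline in gestational age on
$\mu$; a gestational-age smooth on $\log\sigma$; intercepts for $\nu$ and
$\log\tau$. All of this is configuration (`model_spec()`), not
hard-coding. Links: identity for $\mu$ (guarded positive), log for
$\sigma$ and $\tau$, identity for $\nu$.

### The shift $\delta$

Box-Cox families have positive support, but gains can be negative (early
pregnancy, and all week-0 pseudo-draws). We model $y' = \mathrm{gwg} +
\delta$ with $\delta = 30$ kg by default — far below any physiologically
possible gestational weight loss — and back-shift all quantiles on
output. The shift is measure-preserving, so deviances and information
criteria remain comparable with the unshifted normal fits. How the
original analyses reconciled the support constraint is not documented
anywhere we could follow; the explicit shift is this package's own,
configurable, resolution.

## Preprocessing rules

* **Gain scores** are exact differences; negative gains are kept.
* **Week-0 pseudo-observations**: one per woman, drawn from
  $N(0, 0.70^2 + 0.70^2 = 0.98)$ — the self-report and scale errors of a
  0.70 kg single-measurement error combined. A degenerate zero at week 0
  has no variation and stalls the iterations; the draw is "a nudge" whose
  influence fades within a few weeks.
* **4 SD exclusion**: observations are windowed by integer gestational
  week, windows merged left-to-right until each holds ≥ 30 real
  observations (single global window as fallback), because gain variance
  grows several-fold across gestation and a global SD would trim almost
  nothing early and too much late. Within a window we use the
  *leave-one-out* mean and SD: with the candidate point included, a
  single gross error (say 50 kg among values near 0) inflates the SD
  enough to mask itself at any realistic window size. At registry scale
  the two rules are numerically identical; in small windows only the
  leave-one-out version excludes what a human would. Week-0 pseudo-rows
  are never excluded and never enter window statistics; a zero-SD window
  excludes nothing.
* **BMI coding** is left-closed, right-open: WHO normal weight is
  $[18.5, 25.0)$, the Chinese scheme reads "24–28" as $[24, 28)$ with
  obese $\ge 28$, the Korean scheme $[23, 25)$ with obese $\ge 25$. Only
  the "Mainland Asian" birth region triggers the Chinese scheme (and an
  explicit "Korea" region the Korean one); all other regions, including
  Japanese and Taiwanese ancestries, use WHO. Missing values are never
  imputed; incomplete rows are dropped and counted.

## Fitting algorithm

`fit_gamlss()` runs cyclic backfitting over the parameters in the order
$\mu \to \sigma \to \nu \to \tau$. For the current parameter with
predictor $\eta$:

1. score $u_i = \partial \ell_i / \partial \eta_i$ (analytic for NO and
   for BCCG's $\mu, \sigma$, central finite differences otherwise);
2. quasi-Fisher weights $w_i = \max(u_i^2, 10^{-10})$ — the squared-score
   approximation to the information, which is robust for heavy-tailed
   families where the observed second derivative can go negative;
3. penalised weighted least squares of the working response
   $\eta + u/w$ on the parameter's design. The right-hand side is
   assembled as $A^\top(w\eta + u)$, so the working response is never
   materialised where $w$ is tiny;
4. step-halving toward the previous predictor whenever the update would
   increase the global deviance (up to 5 halvings, else the update is
   rejected), which makes the accepted deviance trace monotone;
5. stop when the outer-cycle deviance change falls below `tol`
   (default $10^{-3}$; the closed-form equivalence tests tighten it).

$\nu$ and $\tau$ are frozen for the first two outer cycles — the Box-Cox
families are poorly identified until $\mu$ and $\sigma$ are roughly
right. Initialisation: $\mu$ from a penalised least-squares fit of $y'$
on its own design (initialising inside the model span matters: a freer
init can have lower deviance than anything the model can represent, and
every subsequent update would be rejected); $\sigma$ from a global
coefficient of variation; $\nu = 1$; $\tau = 10$. $\tau$ is clamped to
$[10^{-2}, 10^6]$ — outside that range the family is indistinguishable
from its limits in double precision.

### Smooth terms

The P-spline is a cubic B-spline basis on 20 equally spaced interior
knots with a second-order difference penalty; the basis enters the joint
penalised solve with a QR-absorbed sum-to-zero constraint on its
coefficients (the constant direction is otherwise exactly confounded with
the intercept *and* annihilated by the penalty — a genuinely singular
system). $\lambda$ is chosen by generalised AIC, $n\log(\mathrm{RSS}_w/n)
+ 2\,\mathrm{edf}$, on a log-spaced grid with golden-section refinement
(`select_lambda()`), re-localised each outer cycle; a numeric `df_target`
instead solves $\lambda$ by monotone search on the effective df. A
`cubic_spline` smooth is honoured as a genuine natural cubic smoothing
spline (backed by `stats::smooth.spline`, df-matched; `df_target = 2`
and `df_target = n` are special-cased to the exact limits its internal
search cannot reach) and is backfitted against the parametric terms —
so the P-spline and cubic-spline model variants really are different
estimators, not one estimator with two labels. Fractional polynomials
(powers from $\{-2,-1,-0.5,0,0.5,1,2,3\}$, with the $x^p, x^p\log x$
repeated-power convention) are provided as a baseline smoother and
selected by residual sum of squares over the full enumeration.

## Diagnostics

Normalized quantile residuals $r_i = \Phi^{-1}(F(y_i'))$ are standard
normal under a correct model; we summarise mean, variance, skewness and
kurtosis with moment divisor $n$ (kurtosis raw, normal reference 3) and
the Filliben correlation against normal quantiles of the uniform
order-statistic medians. Worm plots are detrended Q-Q plots with the
$\pm 1.96\sqrt{p(1-p)/n}/\phi(x)$ band. Model ranking uses AIC
($\mathrm{deviance} + 2\,\mathrm{edf}$), SBC ($+\log(n)\,\mathrm{edf}$)
and Nagelkerke's $R^2 = 1 - \exp\{(2/n)(\ell_0 - \ell_1)\}$. Baseline
weight reliability uses the two-way mixed-effects single-measure ICC in
both the absolute-agreement and consistency definitions with F-based
confidence intervals; the two definitions differ exactly when one
measurement is systematically offset, which is the clinically relevant
failure mode for self-reported weight. (Consistency ≥ absolute agreement
holds whenever the occasion mean square exceeds the error mean square; on
data with no systematic offset the inequality can reverse by a sliver —
the tests encode that nuance rather than a false theorem.)

## The synthetic registry: a stated world

`cohort_config()` defaults encode the published marginal structure of the
motivating registry: age $\sim N(28.4, 4.86^2)$; 13 birth regions with
the published proportions; parity 40.3 / 56.0 / 3.8 %; delivery
gestation mean 38.9, SD 1.71 weeks; visit counts $1 +
\mathrm{Poisson}(1.85)$ truncated to $[1, 21]$ (mean 2.85); measurement
and self-report error SD 0.70 kg. Choices the source leaves open, fixed
once here:

* **Visit times**: Beta(2, 1.2) scaled to (4 weeks, delivery] — sampling
  densifies late in pregnancy, as antenatal schedules do.
* **Delivery gestation support**: draws are truncated to (22, 43] so all
  gestational ages stay in the modelled range; the latent mean is solved
  (about 38.94) so the *realised* mean is exactly 38.9 — a plain
  truncation would bias the mean by ~0.04 weeks, outside the generator's
  own 3-Monte-Carlo-SE fidelity contract at $n = 10^5$.
* **Height and BMI**: height $\sim N(1.62, 0.065^2)$ m; pre-pregnancy
  BMI log-normal with median 24 and log-SD 0.19 (≈ 12 % obese, ≈ 8 %
  underweight — plausible for a diverse antenatal population).
* **Truth model**: median gain $m(t) = 0.0025t^2 + 0.18t$ (≈ 11.2 kg at
  40 weeks, matching the ~10 kg rise in median weight across the
  registry's gestation intervals); scale $\sigma(t) = 0.010 + 0.0028t$
  on the shifted scale (gain SD ≈ 6 kg at term); $\nu = -1$ (clear
  positive skew), $\tau = 8$ (moderately heavy tails). Covariate offsets
  are the registry's published linear-model coefficients: −0.016 kg per
  year of age, −0.106 kg per BMI unit, parity 1–3 / >3 at −0.717 /
  −1.532 kg, and the per-region effects with Australian/European as
  reference. With $\nu = -1$ the upper tail of the gain distribution is
  a power law ($\sim y^{-2}$): rare implausibly large gains occur by
  construction and are exactly what the 4 SD rule is for.
* **Substreams**: cohort, visits and weights use seeds `seed`,
  `seed + 1`, `seed + 2`, so regenerating one stage never perturbs
  another.

**What a green test establishes — and what it does not.** The generator
treats gains as independent across a woman's visits given her covariates,
because the modelling framework itself conditions on covariates and
treats observations as independent; no within-woman serial correlation is
simulated, so the tests cannot detect mis-calibrated standard errors that
real repeated measures would induce. Measurement noise is another honest
gap: observed gain = true gain + scale error − self-report error, i.e.
the observable is a BCT *convolved with* ≈ N(0, 0.98) noise. A BCT fit to
the full noisy pipeline is therefore (mildly, deliberately) misspecified
— it recovers the truth's median curve to a few tenths of a kg, not
exactly. The parameter-recovery and coverage acceptance criteria are
accordingly evaluated on data simulated directly from the model family
(the "correctly specified" world), while the model-ranking and
sensitivity-analysis criteria use the full noisy registry, where being
exactly right is impossible but being *better than the linear baseline*
is the reproducible claim.

## Sensitivity analysis (re-baselining)

`rebaseline_first_visit()` discards the self-report and anchors each
woman's gains at her first measured weight (kept as a zero-gain
observation). Mirroring the motivating analysis, the acceptance test
restricts this to women first measured at ≤ 10 weeks. The re-baselined
gain omits whatever was gained before the first visit — under the default
truth, a median of ≈ 1.5 kg for first visits at ≤ 10 weeks — so the two
median trajectories cannot agree more closely than that residual offset.
The stated tolerance for "the trajectories converge beyond 25 weeks" is
therefore a maximum absolute gap of 2.0 kg over weeks 25–42: the derived
offset bound plus fitting noise, fixed before the test was first run.

## Numerical choices and degenerate inputs

* Box-Cox transform computed via `expm1`, making the $\nu \to 0$ limit
  exact to machine precision (tested at $\nu = 10^{-9}$).
* CDF values are clipped to $[10^{-12}, 1 - 10^{-12}]$ before normal
  inversion in the residuals (clipping is reported).
* Singular penalised systems fall back to a relative ridge
  ($10^{-9}\times$ the mean diagonal); rank-deficient baseline designs
  are an error, not a silent drop.
* Ties in the smoothing-spline abscissa are collapsed by weighted means;
  model comparison refuses fits on different observation sets; AIC ties
  break by SBC, then label, so orderings are deterministic.

## Known limitations

* No within-woman correlation structure, in the generator or the
  likelihood (see above).
* Standard errors and confidence bands for smooth terms are deliberately
  not produced: with additive smooth terms present, per-term intervals
  invite over-interpretation.
* The per-BMI-category batch charts condition the *full* fitted model at
  a representative profile (WHO category midpoints 17.5 / 21.7 / 27.5 /
  32.5 kg/m²; cohort-mean age; parity 0) rather than refitting per
  stratum — cheaper, and it keeps the charts mutually consistent, but it
  assumes the covariate effects are correctly shared across strata.
* The neural-network comparator explored alongside the original analysis
  is out of scope here, as are maternal-complication outcomes.
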