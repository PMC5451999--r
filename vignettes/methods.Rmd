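---
title: "Ensemble spatiotemporal estimation of PM2.5: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble spatiotemporal estimation of PM2.5: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

Daily fine-particulate (PM2.5) exposure fields must often be reconstructed
from a sparse provincial monitoring network — on the order of a hundred
stations covering a region of several hundred kilometres — together with
covariates observed everywhere (meteorology, satellite aerosol optical
thickness and vegetation indices, traffic and land-use descriptors, and
sometimes co-located PM10). `pm25ens` implements a three-stage estimator for
this setting:

1. **Non-linear additive mean model.** Daily log concentrations are modelled
   as

   $$y(s,t) = \mu(s,t) + \varepsilon(s,t), \qquad
     \mu(s,t) = f_1(t) + f_2(t) + \sum_i s(x_i(s,t)) + \sum_k s(p_k(s)),$$

   where $f_1, f_2$ are smoothed temporal basis functions shared by all
   stations, $x_i(s,t)$ are spatiotemporal covariates, $p_k(s)$ are
   station-level spatial covariates, and $s(\cdot)$ are penalized cubic
   smooths with capped effective degrees of freedom (default 10 per term).
   The log scale is used because daily concentrations are strongly
   right-skewed; predictions are back-transformed by plain exponentiation
   with no lognormal bias correction, so the estimator targets the median
   rather than the mean of the conditional distribution.

2. **Bootstrap aggregation with performance weighting.** B bootstrap
   resamples (size n, with replacement; B = 1000 in production, smaller in
   tests) each train one additive model. A resample contains on average
   $1-(1-1/n)^n \approx 63.2\%$ of the distinct rows; each member is scored
   by $R^2_i$ on its own out-of-bag (~36.8%) rows, and members are combined
   with weights

   $$w_i = \frac{(R^2_i)^2}{\sum_j (R^2_j)^2},$$

   so stronger members dominate superlinearly. The ensemble reports the
   weighted mean $\mu_f = \sum_i w_i \mu_i$ and the weighted standard
   deviation

   $$\sigma_f = \sqrt{\frac{\sum_i w_i (\mu_i - \mu_f)^2}
                           {\frac{M-1}{M} \sum_i w_i}}$$

   with $M$ the number of nonzero weights, as an uncertainty measure
   ($\sigma_f$ reduces to the ordinary sample SD under equal weights, and is
   defined as 0 when $M = 1$).

3. **Daily ordinary kriging of residuals.** The ensemble's station residuals
   retain spatial autocorrelation. For each day independently, an
   exponential variogram
   $\gamma(d,t) = c_0(t) + c(t)\,(1 - e^{-d/a_0(t)})$ (with spherical,
   circular, Gaussian and linear families as alternatives selectable by
   leave-one-station-out cross-validation) is fitted to that day's residuals
   and used in ordinary kriging with the unbiasedness constraint
   $\sum_i \lambda_i = 1$. The kriged residual is added to the ensemble mean
   on the log scale before back-transform. Regional means are obtained by
   block averaging of point predictions over a polygon.

## Temporal basis functions

The basis functions are the first two right singular vectors of the
station-by-day log-concentration matrix after each station's own mean has
been removed. Per-station centring is what isolates the *shared* temporal
shape: subtracting each day's cross-station mean instead would remove
exactly the common seasonal signal and leave the basis describing
station-level anomalies (we verified this empirically — the first component's
cosine similarity with a planted seasonal curve collapses from >0.99 to
~0.03 under day-mean centring). Missing entries are first completed by
iterative truncated-SVD imputation (fill with day means, factorise, refill
missing entries from the rank-r reconstruction, iterate to a relative
tolerance of 1e-6; rank 2 by default, matching the number of retained basis
functions). Signs are fixed so each basis vector is positive in mid-winter
(day 15), making "high in winter" the positive direction, and the vectors
are smoothed by cubic smoothing splines (`all.knots`, default 12 equivalent
df over a year) before entering the mean model.

## Covariate screening and selection

Candidates are screened for multicollinearity by variance inflation factors
(VIF$_j = 1/(1-R^2_j)$ from regressing column j on the rest; iterative
removal above a conventional threshold of 10), then reduced by
backward-stepwise AIC using the same penalized additive fitter as the
ensemble, with mgcv's double-penalty shrinkage enabled so an uninformative
smooth can be penalized to zero. Because shrinkage makes a noise term's AIC
contribution hover around zero (and conditional AIC can credit noise with up
to ~1–2 units), the removal rule follows the familiar delta-AIC equivalence
convention: a variable is retained only if it improves AIC by more than
`aic_tol = 2`. A strict "every removal must lower AIC" rule demonstrably
keeps pure-noise covariates. A correlation-screen utility is provided for
exploratory pruning without a fixed significance rule.

## Variogram fitting: numerical choices

- **Empirical variogram.** 12 equal-width lag bins to a maximum lag of half
  the largest inter-station distance, minimum 5 pairs per retained bin;
  per-bin semivariance is half the mean squared residual difference.
- **WLS fit.** Pair-count-weighted least squares (Cressie weights
  optional), multi-start L-BFGS-B over a deterministic grid of range
  starts, with parameters bounded to the resolvable region
  ($c_0 \le 2\max\hat\gamma$, $c \le 3\max\hat\gamma$, $a_0 \le$ max lag).
  Unbounded fits walk onto a degenerate ridge where an enormous range and
  sill mimic a line through drifting large-lag bins.
- **Parsimony guard.** Structured families contain a second ridge: a
  vanishing range mimics a pure nugget, so on spatially independent
  residuals an unguarded fit reports spurious structure almost always
  (94/100 simulated fields). A structured WLS fit is therefore kept only
  when it beats the pure-nugget fit by an F-style criterion at level 0.95;
  the ML fitter uses the analogous likelihood-ratio test.
- **Maximum-likelihood refinement.** Daily residual variograms are fitted by
  profile-mean Gaussian ML (Nelder-Mead on log parameters, seeded by the
  WLS fit). Binned WLS is noticeably inefficient for the range parameter:
  on simulated 96-station exponential fields its median relative error in
  $a_0$ was ~0.45–0.56 across binning and weighting settings, versus ~0.25
  for ML on identical fields. WLS remains the fitter when only a bare
  empirical variogram is available, and for the linear family (which has no
  valid stationary covariance).
- **Family selection.** Leave-one-station-out kriging RMSE per candidate
  family; the exponential family is displaced only when a competitor's
  improvement is significant by a one-sided paired t-test (level 0.05) on
  station-wise squared errors. Raw LOOCV scores of bounded families differ
  by far less than their sampling noise, so an unguarded argmin is decided
  by noise.
- **Kriging system.** The variogram-form augmented system is solved with a
  global neighbourhood (all stations; the network is small). Stations at
  identical coordinates are averaged first. Kriging variance is clamped at
  zero against roundoff. "Range" is reported both as $a_0$ and as the
  effective range $3a_0$ for the exponential family; the range of a
  pure-nugget day is reported as NA.

## Validation design

Six scenarios cross the engine (single additive model vs bagged ensemble),
the use of log PM10 as a predictor, and residual kriging. Single-model
scenarios are scored by repeated k-fold cross-validation (10 x 10-fold by
default, record-level folds; a leave-stations-out mode is available for
spatial validation but is not the default). Bagging scenarios are scored
out-of-bag: a row is predicted only by members that did not resample it,
with weights renormalized over those members. With residual kriging, each
station-day's residual is estimated by leave-one-station-out kriging within
its day — never using the station's own residual, which would be trivially
exact whenever the nugget is zero. All metrics (R2 = 1 - SSE/SST and RMSE)
are computed on back-transformed concentrations in ug/m3.

## What the synthetic generator emulates

The generator plants exactly the structure the estimator assumes, with every
truth stored for recovery tests:

- a clustered network (default 96 stations in ~17 urban clusters over a
  ~420 km square, mirroring a provincial monitoring layout);
- a winter-high seasonal signal on the log scale (annual amplitude 0.60,
  semi-annual 0.12) — chosen together with the residual-field schedule so
  that the first temporal SVD component carries a majority (~0.57) of total
  variance and the spatial field a substantial share (~0.44), the regime the
  method is designed for;
- smooth covariate effects, including a deliberately non-monotone
  temperature response, so the additive fitter's advantage over a linear
  model is testable;
- daily Gaussian random fields drawn by Cholesky factorization from an
  exponential variogram whose range, partial sill and nugget interpolate
  between mid-winter (a0 = 60 km, c = 0.12, c0 = 0.008) and mid-summer
  (30 km, 0.06, 0.004) on an annual cosine — a 2:1 winter:summer range
  contrast;
- a PM2.5/PM10 ratio with mean 0.57 and total SD 0.10, drawn per *day*
  (seasonal, winter-high) plus a small per-record perturbation and truncated
  to (0.2, 0.95). The day-common component reflects how observed daily
  ratios track a dominant trend with minor station-level variation; it also
  means PM10-based models leave a spatially coherent daily residual that
  kriging can legitimately recover;
- 4% missingness, completely at random, independently in each panel;
- iid log-scale noise (SD 0.05).

What it does *not* emulate: real covariate textures (reanalysis meteorology,
satellite AOT), spatially structured missingness, instrument changes, or
non-stationary anisotropic residual fields. Passing the planted-recovery
tests therefore demonstrates internal consistency of the estimator under its
own assumptions, not performance on real monitoring data.

## Problem sizes and defaults used in tests

The shipped test-suite and acceptance script run the full pipeline at the
generator's default size (96 stations x 365 days = 35,040 station-days) with
B = 25 ensemble members, and the geostatistical recovery studies over 50
simulated days; unit tests use smaller panels. B is a first-class knob —
production runs use B = 1000; the OOB-weighted ensemble mean is already
stable at a few dozen members, which is what the scenario comparisons need.

## Other design choices and limitations

- **Coordinates.** Inputs are WGS84 degrees; distances are computed on a
  local equirectangular projection centred on the data's bounding box,
  adequate at provincial extents (a few hundred km). Kriging across
  continental extents would need a proper projection library.
- **Negative member R2.** An out-of-bag $R^2_i < 0$ (a member worse than
  the mean) is clamped to zero before weighting, removing the member.
- **Scale of kriged residuals.** Residuals are computed and kriged on the
  log scale, where the additive model defines them, and added before
  back-transform; a concentration-scale variant would target a different
  (mean-type) functional.
- **Transfer across years.** Daily residual surfaces can be looked up by
  day-of-year for other years under a limited-change assumption; results
  are explicitly flagged as extrapolations.
- **Thin days.** Days with fewer than 10 reporting stations get no kriging
  (residual term 0) and a prominent warning.
- **Uncertainty.** $\sigma_f$ measures between-member spread only; it does
  not include variogram-parameter uncertainty or kriging variance, which
  are reported separately.
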