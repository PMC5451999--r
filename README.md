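# pm25ens

Ensemble spatiotemporal estimation of daily PM2.5 concentrations from sparse
monitoring networks, for exposure assessment in environmental epidemiology.

Monitoring of fine particulate matter (PM2.5) is recent and spatially thin:
a typical provincial network has on the order of a hundred stations. Health
studies nevertheless need daily concentration estimates at arbitrary
locations, including periods and places without monitors. `pm25ens`
implements a three-stage estimator for this problem:

1. **Non-linear additive mean model** on log concentrations,

   y(s,t) = mu(s,t) + eps(s,t),
   mu(s,t) = f1(t) + f2(t) + sum_i s(x_i(s,t)) + sum_k s(p_k(s)),

   where f1, f2 are SVD-derived temporal basis functions (shared seasonal
   trends, smoothed by cubic splines), x_i are spatiotemporal covariates
   (meteorology, satellite products, optionally co-located PM10), p_k are
   spatial covariates (traffic, land use), and s(.) are penalized smooths
   with capped degrees of freedom (mgcv under the hood).

2. **Bagging with performance weighting.** B bootstrap resamples each train
   one additive model; each member is scored by R2 on its out-of-bag rows
   (a size-n resample keeps ~63.2% of distinct rows) and members are
   combined with weights w_i = (R2_i)^2 / sum_j (R2_j)^2. The ensemble
   reports a weighted mean and a weighted standard deviation as an
   uncertainty measure.

3. **Daily ordinary kriging of residuals.** Residual spatial autocorrelation
   is modelled per day by an exponential variogram
   gamma(d) = c0 + c (1 - exp(-d/a0)) (four alternative families selectable
   by leave-one-station-out cross-validation), and kriged residuals are
   added on the log scale before back-transform. Block averages over region
   polygons give regional means.

A synthetic-data module generates full monitoring years with known planted
structure (seasonal signal, smooth covariate effects, daily Gaussian
residual fields with a winter:summer variogram schedule, PM2.5/PM10 ratio
near 0.57, 4% missingness) so the whole pipeline is testable end to end
without any external data. Six model scenarios (single model vs bagging, with
and without PM10, with and without residual kriging) and 10 x 10-fold /
out-of-bag validation support model comparison.

## Worked example

```r
library(pm25ens)

# a synthetic monitoring year: 96 stations x 365 days
cfg <- sim_config(seed = 7)
dat <- generate_panel(cfg)

# impute, extract seasonal basis, assemble the modelling table
imp   <- svd_impute(log_transform(dat$pm25))
basis <- smooth_basis(extract_basis(imp))
long  <- panel_to_long(dat$pm25, dat$covariates, basis, dat$pm10)

terms <- c("f1", "f2", "temp", "humid", "road", "elev")

# bagging without (3) and with (4) daily residual kriging
r3 <- run_scenario(scenario_config(3), long, terms, B = 25, seed = 11)
r4 <- run_scenario(scenario_config(4), long, terms, B = 25, seed = 11)
r3
#> <pm_metric_report> scenario 3 (bagging): R2 = 0.478, RMSE = 27.76 ug/m3 (n = 33557)
r4
#> <pm_metric_report> scenario 4 (bagging): R2 = 0.804, RMSE = 17.00 ug/m3 (n = 33557)
```

Scenario 3 is the bagged additive model alone: out-of-bag R2 of 0.48 means
the covariates and seasonal basis explain about half the variance of daily
concentrations. Scenario 4 adds leave-one-station-out kriging of the daily
residuals, lifting out-of-bag R2 to 0.80 — the spatially structured residual
field accounts for the ~0.33 difference, and RMSE (in ug/m3, on the
concentration scale) drops accordingly. `r4$vgm_params` holds the fitted
per-day variogram parameters (nugget, partial sill, range), whose
winter-high seasonal pattern mirrors the planted schedule.

For predictions at new locations:

```r
pipe <- fit_pipeline(dat$pm25, dat$pm10, dat$covariates,
                     covariate_terms = c("temp", "humid", "road", "elev"),
                     B = 25, seed = 1)
pred <- predict_locations(pipe, targets)   # x, y, day + covariates
# columns: mean_log, sd_log, residual_log, concentration = exp(mean_log + residual_log)
```

A thin command-line front-end (`inst/cli/pm25ens.R`) exposes the pipeline as
`simulate / fit / predict / validate / basis / variogram` subcommands driven
by a YAML config.

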