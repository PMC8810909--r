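# urbancline

Tools for estimating **urban–rural clines in melanism** — the dark
coat-color morph of the eastern gray squirrel (*Sciurus
carolinensis*) — from crowdsourced occurrence records across many
cities, and for verifying every stage of that analysis on synthetic
data with known truth.

Community-science projects produce large numbers of georeferenced
squirrel photographs whose coat color is classified by volunteer
votes. Turning those votes into an inference about how melanism
changes along urbanization gradients requires a chain of steps, each
of which this package implements and tests:

1. **Consensus classification** — per-image votes on the number of
   squirrels and each squirrel's color are aggregated under a minimum
   agreement rule (default 80% with at least 10 votes); images that
   fail agreement, show no squirrel, lack a location, or fall outside
   the native range are dropped, with a per-stage count report.
2. **Study regions** — each city footprint is buffered by 25% of the
   mean distance from its centroid to its cardinal-direction extents;
   cities need at least 100 records, and overlapping regions keep the
   one with the larger sample (spatial spread breaks near-ties).
3. **Spatial thinning** — records are thinned to a minimum separation
   (default 10 m) to reduce sampling bias; small conflict clusters
   are solved to a provably maximum retained set, large ones
   greedily.
4. **Covariates** — percent impervious cover within 1 km of each
   record (exact cell-intersection raster extraction), and per-region
   forest cover, winter temperature, and log city area.
5. **The model** — a binomial GLMM on the melanic indicator

   logit P(melanic_ij) = β₀ + β₁·imperv_ij + β₂·temp_j + β₃·forest_j
   + β₄·logsize_j + β₅·imperv·temp + β₆·imperv·forest
   + β₇·imperv·logsize + u_j,  u_j ~ N(0, σ²_city)

   with impervious cover min–max rescaled within each city to [0, 1]
   and all predictors standardized (mean 0, SD 1). Fitting uses a
   Laplace-approximated marginal likelihood (penalized IRLS inner
   loop, one-dimensional profile over log σ), with two-sided Wald
   tests and binned-residual diagnostics.
6. **Spatial correction** — a residual autocovariate (inverse-distance
   weighted mean of neighboring residuals within a radius equal to
   the greatest nearest-neighbor distance) is standardized and added
   as a predictor, and Moran's I correlograms in 1-km distance rings
   verify the reduction of residual spatial autocorrelation.

A synthetic-data generator (`simulate_study()`, `simulate_frame()`)
draws cities, landscapes, effort-biased observation locations, vote
records, and melanism outcomes from exactly this model, so parameter
recovery, consensus behavior, thinning optimality, and the spatial
correction are all testable without any data download.

## Worked example

Simulate a study at the default conditions (43 cities, per-city
counts with median 254 in 101–4731, published effect sizes as truth)
and fit the global model:

```r
library(urbancline)

cfg   <- sim_config(seed = 42)
frame <- simulate_frame(cfg)      # 29,594 observations, 43 cities
fit   <- fit_melanism_model(frame)
summary(fit)
```

```
Binomial GLMM (Laplace): 29594 obs, 43 clusters, logLik -8606.72
Random-intercept SD: 0.6284

               term estimate      se       z        p
        (Intercept)  -2.8466 0.12264 -23.211  < 2e-16
           x_imperv   0.1952 0.04298   4.542 5.56e-06
             x_temp  -1.9674 0.14777 -13.314  < 2e-16
           x_forest   0.2490 0.14375   1.732   0.0832
          x_logsize   0.5038 0.11688   4.310 1.63e-05
    x_imperv:x_temp  -0.1572 0.05202  -3.023   0.0025
  x_imperv:x_forest   0.1133 0.02110   5.368 7.96e-08
 x_imperv:x_logsize   0.1544 0.02535   6.090 1.13e-09
```

The generative truth for this run was β = (−3.0, 0.17, −2.14, 0.30,
0.58, −0.15, 0.15, 0.13) with σ_city = 0.8: every estimate lands
within sampling error of its target, the urbanization slope
(`x_imperv`) is positive and significant, winter temperature is
strongly negative (melanism is rarer where winters are warm), and
the impervious × city-size and impervious × forest interactions show
clines steepening in large, well-forested cities.

Predicted cline for a large (350,000 ha), well-forested (45%) cold
city (−5 °C), population level:

```r
predict_cline(fit, imperv = c(0, 0.5, 1), winter_temp = -5,
              forest_pct = 45, city_area_ha = 350000)
#   imperv  prob
#      0.0 0.089
#      0.5 0.190
#      1.0 0.361
```

The probability of melanism roughly quadruples from the rural edge to
the urban core. `rac_refit(frame, fit)` adds the residual
autocovariate and returns before/after Moran correlograms;
`run_pipeline(simulate_study(cfg), pipeline_config())` executes the
whole chain from raw votes to the corrected fit, and
`sensitivity_analysis()` refits over the 10/50/100 m thinning and
500 m/1 km/10 km extraction-radius grids.

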