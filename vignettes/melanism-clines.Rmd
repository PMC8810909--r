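---
title: "Methods: urban-rural melanism clines from crowdsourced records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: urban-rural melanism clines from crowdsourced records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`urbancline` estimates how the prevalence of melanism in gray
squirrels changes along urbanization gradients, replicated across
many cities. The response is a per-record binary indicator (1 =
melanic; gray and rare other morphs = 0). For record $i$ in city $j$:

$$\mathrm{logit}\,P(y_{ij}=1) = \beta_0 + \beta_1 x^{imp}_{ij}
 + \beta_2 x^{temp}_j + \beta_3 x^{forest}_j + \beta_4 x^{size}_j
 + \beta_5 x^{imp}x^{temp} + \beta_6 x^{imp}x^{forest}
 + \beta_7 x^{imp}x^{size} + u_j, \qquad u_j \sim N(0,\sigma^2_{city}).$$

Impervious cover (the urbanization metric) is measured as the mean
percent impervious surface within a 1-km disc around each record,
then min–max rescaled within each city to $[0,1]$ so the slope
$\beta_1$ has the same "rural edge to urban core" interpretation in
every city regardless of how much absolute impervious cover the city
spans. City-level covariates — mean winter (coldest-quarter)
temperature in °C, percent forest cover, and log footprint area in
hectares — are constant within a city. All predictors (including the
rescaled impervious variable) are standardized to mean 0, SD 1 over
the analysis frame, so coefficients are comparable effect sizes; the
standardization statistics are stored with the fit and reused at
prediction time. Interactions are elementwise products of the
standardized main effects.

Assumptions worth stating: records are conditionally independent
Bernoulli draws given the linear predictor and the city intercept;
the city effect is a single Gaussian intercept (no random slopes);
and sampling effort may vary over space but does not differentially
favor one morph along the gradient.

## Estimation

`fit_glmm()` maximizes a Laplace-approximated marginal likelihood.
For a candidate $\sigma$, the inner loop maximizes the joint
penalized log-likelihood over $(\beta, u)$ by penalized IRLS; because
the random effect is a single intercept, the mixed-model normal
equations are solved exactly per iteration with a Schur complement on
the (diagonal) cluster block, at $O(np^2)$ per iteration. Each IRLS
proposal is accepted only if it does not decrease the penalized
log-likelihood; otherwise the step is halved (down to $2^{-26}$ of
the proposal). This guards against divergence under quasi-separation,
which occurs regularly at these prevalences: cities with cold winters
and strong clines can have near-empty outcome cells. The Laplace
objective is the penalized log-likelihood at the mode minus
$\tfrac12\sum_j \log(1+\sigma^2 s_j)$ with $s_j$ the cluster sum of
IRLS weights. The outer loop is a one-dimensional optimization over
$\log\sigma$ on $[\log 10^{-4}, \log 10]$; an estimate at the lower
boundary is reported as $\hat\sigma = 0$ with a `sigma_collapsed`
flag. Convergence tolerance is $10^{-8}$ relative change in the
objective.

Because $\beta$ is profiled inside the penalized step, its optimum
ignores the dependence of the Laplace log-determinant term on
$\beta$; the test suite shows agreement with an independent
implementation that optimizes the full objective to within a few
percent of a standard error, and exact agreement ($10^{-6}$) with
IRLS logistic regression when $\sigma = 0$. Standard errors for
$\beta$ come from the inverse Schur-complement information at the
optimum, conditional on $\hat\sigma$ — the convention of standard
mixed-model software. Wald tests are two-sided normal tests of
$\hat\beta/\mathrm{SE}$.

`binned_residuals()` sorts records by fitted probability (stable
sort, ties broken by row index), cuts them into $\lceil\sqrt n\rceil$
equal-count bins by default, and reports per-bin mean response
residuals with a $2\,\mathrm{sd}/\sqrt{n_{bin}}$ band.

## The spatial correction

Residual spatial autocorrelation (squirrels near each other are more
alike than the model predicts, e.g. through local founder effects) is
handled with a residual autocovariate: response-scale residuals
$y - \hat p$ from the initial fit are averaged over each record's
neighbors with symmetric inverse-distance weights $w_{ij} = 1/d_{ij}$
("B"-style, no row standardization) within a radius set by default to
the greatest nearest-neighbor distance of the thinned records; the
autocovariate is standardized like every other predictor and the
model refit with it. Moran's I is computed in 1-km distance rings
from 0 to the radius, with binary within-ring weights, before and
after the refit.

Numerical choices: coincident points (possible after projection even
with 10-m thinning) get a distance floor of half the smallest nonzero
pairwise distance so $1/d$ stays finite; isolated points get
autocovariate 0; a radius that captures no pair at all leaves the
model unchanged rather than refitting with a constant column. The
choice of response-scale residuals (rather than Pearson) follows the
residual-autocovariate literature; a `residual_type` switch exposes
the alternative. Weights are built globally across cities (the
radius is defined on the full thinned dataset); with cities far
apart, cross-city pairs simply never enter.

# Geometry and extraction

All metric work happens in planar meters. Geographic footprints are
projected per city with a spherical azimuthal equidistant projection
centered on the footprint, which preserves exactly the distances the
buffering step needs; synthetic data is generated directly in planar
coordinates. Cardinal-extent distances are measured from the
footprint centroid to the bounding-box edges (the paper-style
"maximum extent in each cardinal direction" is ambiguous between
bounding box and farthest vertex; the bounding-box reading is used).
The buffer is 25% of the mean of the four distances, applied as a
Minkowski dilation; buffered polygons are built for convex
footprints (the synthetic generator produces convex hulls), while
point-membership tests use exact distance-to-polygon predicates that
hold for any simple polygon.

Raster extraction uses exact cell-intersection weights, not
cell-center membership: the 1-km disc is represented as a 64-gon
(area deficit 0.16%, well below the extraction noise), each boundary
cell is clipped with a vectorized Sutherland–Hodgman pass, and
interior cells take full weight. Missing cells drop out of numerator
and denominator. Region-level covariates are the same weighted mean
over the buffered polygon.

Spatial thinning retains a maximal set of records no two of which are
closer than the minimum distance. The conflict graph is split into
connected components; components of at most 25 points are solved to a
provably maximum independent set by branch and bound, larger
components by greedy highest-degree removal with seeded random
tie-breaks over replicates (keeping the best replicate). The exact
small-component path exists because greedy removal is provably
suboptimal on some configurations no matter how ties are broken —
test fixtures found such cases — while real thinning conflicts at
10–100 m almost always form tiny components where exactness is
cheap.

City selection assigns each thinned record to every buffered region
containing it, drops regions below the minimum count (default 100),
and resolves overlapping retained regions by sample size, breaking
near-ties (within 5%) by the convex-hull area of the assigned
records. Records contained in two retained, non-overlapping regions
go to the nearer centroid; unique assignment is required by the
random-intercept structure.

A degenerate city whose records all share one impervious value would
make min–max rescaling 0/0; it is set to 0 with a warning, since such
a city contributes no within-city cline information but still informs
the city-level effects.

An open choice: whether the rescaled $[0,1]$ impervious variable is
itself standardized before entering the design. The default is
rescale-then-standardize, consistent with "all predictors
standardized" and with effect-size comparability;
`build_model_frame(standardize_imperv = FALSE)` keeps the raw
$[0,1]$ scale.

# Consensus classification

Votes arrive per image: a count question (zero / one / two-or-more)
and per-squirrel color questions (gray / melanic / other / unclear).
A question resolves to its modal label when the mode's share of all
votes is at least the threshold (default 0.8) and at least the
minimum number of votes were cast (default 10); "unclear" votes count
in the denominator but never become an observation, and ties at the
mode are unresolved (with a threshold above 0.5 a tie can never
reach it; this is asserted defensively). An image is retained when
its count resolves to a nonzero value and at least one squirrel's
color resolves; images with two resolved morphs yield one observation
per morph. Color votes for multi-squirrel images are paired by slot
index — the simplest reproducible rule, since vote platforms do not
document slot alignment. Location and native-range filters follow,
with every stage tallied in a `ConsensusReport`-style count list.

# The synthetic generator

The generator exists so that every downstream stage can be validated
by parameter recovery, and its defaults are the study conditions the
analysis targets:

* 43 cities, footprint areas log-uniform on 25,000–350,000 ha
  (the range spanned by the prediction scenarios), convex polygon
  footprints scaled exactly to the drawn area;
* per-city record counts log-normal with median 254, truncated to
  101–4731 — matching the reported median, range, and (through the
  log-scale SD of 1.3) the reported total of about 27,000 records;
* impervious cover declining logistically with distance from the
  city centroid (midpoint at 0.8–1.0 of the effective radius,
  baseline 0–5%, core amplitude 60–95%), clipped to [0, 100];
* city-level winter temperature uniform on −12 to 8 °C and forest
  cover uniform on 10–60%, spanning the prediction scenarios
  (−5/5 °C, 15/45%);
* observation locations sampled with density proportional to
  $1 + k\cdot\mathrm{imperv}/100$ ($k = 2$), mimicking
  community-science effort concentrating in cities while keeping
  rural mass — $k$ is a free knob, not an estimate, since observer
  bias is not quantified;
* melanism drawn from the model above with
  $\beta = (-3.0, 0.17, -2.14, 0.30, 0.58, -0.15, 0.15, 0.13)$ and
  $\sigma_{city} = 0.8$. The five slopes with published point
  estimates are used verbatim; the intercept, forest main effect and
  impervious × temperature values are plausible choices consistent
  with melanism being uncommon overall and clines weakening in warm
  cities, fixed once and not revisited;
* votes with a 2% error rate from 10 voters per question, wrong
  votes uniform over the wrong labels;
* optionally, a spatially autocorrelated logit-scale Gaussian field
  with exponential covariance, simulated on a coarse per-city grid
  (spacing half the range, node count capped at 40 × 40) and
  bilinearly interpolated to the records.

`rac_sim_config()` freezes the conditions for the spatial-correction
study: 8 cities, ~350 records each, noise range 5 km with SD 1.5 —
the SD calibrated once so the uncorrected model's first-bin (0–1 km)
residual Moran's I sits near 0.11, the regime the correction is meant
to handle.

What the generator does **not** emulate: real impervious surfaces
are not radially monotone; forest and temperature vary within
regions; observers revisit landmarks (true point patterns are far
more clustered); vote error is not uniform across morphs or voters;
and cities are placed far apart, so cross-city spatial structure is
absent. Passing recovery tests therefore demonstrates correctness of
the estimation machinery under the assumed model, not robustness of
the scientific conclusions to violations of it.

# Problem sizes and determinism

All randomness flows from integer seeds; every generator function
draws from named substreams of the config seed, so identical configs
give byte-identical outputs and the RNG state of the caller is left
untouched. The test suite runs parameter recovery on 50 replicates
at the full study scale (43 cities, ~27k records; the model fit
takes well under a second per replicate), the spatial-correction
study on 50 replicates at the reduced `rac_sim_config()` scale
(~3,000 records each, chosen to keep dense within-city pair
enumeration cheap), and the end-to-end pipeline on a 6-city smoke
study with rasters (6 cities is the practical minimum: with fewer,
the impervious main effect plus its three interactions saturate the
per-city slopes and the design degenerates). Exhaustive-search
oracles (independent sets, dense weight matrices, permutation nulls)
run at n ≤ 200.

# Known limitations

* The Laplace approximation is least accurate for small cities at
  extreme prevalences; no adaptive quadrature is offered.
* $\hat\sigma_{city}$ carries the usual downward Laplace bias
  (visible but mild at 43 clusters) and collapses to the boundary on
  small studies; the flag should be checked before interpreting it.
* Buffered polygons are constructed for convex footprints only;
  strongly concave city footprints would need a full polygon-offset
  routine (membership tests, areas, and centroids are exact for any
  simple polygon).
* Confidence intervals for $\sigma_{city}$ and profile/bootstrap
  alternatives to Wald tests are out of scope.
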