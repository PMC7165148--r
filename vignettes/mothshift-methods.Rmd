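---
title: "Methods: season metrics, hierarchical elevation trends, and community ordination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: season metrics, hierarchical elevation trends, and community ordination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mothshift)
```

# The scientific problem

Boreal nocturnal moths live on a knife edge of seasonal time: an individual
must reach a diapause-capable stage before the first autumn frosts, so the
number of days warm enough for growth (the *season length*) is a direct
constraint on fitness. A fixed transect of eleven light traps on a
sub-arctic fell slope (340–470 m a.s.l., four vegetation zones from spruce
ravine to treeless summit), operated nightly from mid-May to mid-October
for 35 years, together with a weather station on the same slope, allows
four linked questions to be asked:

1. Has the favorable season lengthened?
2. Does the previous season's length predict moth abundance?
3. Have species' elevational centres of gravity (COG) moved uphill, and do
   life-history traits explain which species moved?
4. Has the assemblage structure of the community changed in space and time?

`mothshift` implements the full chain of analyses as reusable,
pipe-friendly functions, together with a synthetic-data generator whose
ground truth is known exactly, so that every stage can be validated by
parameter recovery rather than by eye.

# Season metrics from daily temperatures

Each year's daily mean temperatures are smoothed with a penalized cubic
regression spline (basis dimension 20, penalty by generalized cross
validation; `fit_daily_smoother()`). Three threshold rules on the smoothed
curve define the metrics (`season_metrics()`):

* **season length** — days with temperature at or above 10 °C, the point
  below which larval growth effectively ceases;
* **season start** — first crossing of 8 °C;
* **season end** — last crossing of 3 °C.

"At or above" is applied uniformly, crossings are evaluated on the integer
Julian-day grid, and multiple crossings of a noisy curve collapse to the
outermost pair. Two season-length modes are provided because the day-count
definition and the smoothed-crossing procedure are both defensible:
`smoothed-span` (the default; last minus first 10 °C crossing of the
smooth curve, plus one) and `raw-count` (count of observed days at or
above 10 °C). On noiseless unimodal curves they agree exactly, and the
package asserts this as a test invariant. Temporal trends are ordinary
least squares on calendar year with a two-sided t test, reported with the
Durbin–Watson statistic and the lag-1 residual autocorrelation
(`trend_regression()`); values of |rho| below about 0.35 are taken as
compatible with independent residuals.

# The Gibbs sampler for Gaussian mixed models

All four models are Gaussian linear mixed models fitted by a purpose-built
blocked Gibbs sampler (`gibbs_lmm()`, C++ core):

* fixed effects drawn jointly from their multivariate normal full
  conditional under a near-flat normal prior (variance $10^8$);
* random effects drawn per grouping level — either scalar intercepts or
  correlated (intercept, slope) pairs;
* scalar variances from inverse-Gamma conditionals with prior
  $\mathrm{IG}(\nu/2,\ \nu V/2)$, defaults $V = 1$, $\nu = 0.002$;
* 2×2 covariance blocks from inverse-Wishart conditionals with scale
  $\nu V$ and degrees of freedom $\nu$ (default $V = I$, $\nu = 1.002$),
  a parameterization whose prior expectation of the covariance is
  $\nu V/(\nu - d - 1)$ when defined. Conventions differ between software
  packages, so this one is stated explicitly.

Posterior summaries follow one convention everywhere
(`posterior_summary()`, `tidy()`): the posterior mean, the 95% highest
posterior density interval (shortest window over the sorted draws,
earliest window on ties), and the effective sample size by the
initial-positive-sequence estimator, $n/(1 + 2\sum_k \hat\rho_k)$ with
autocorrelations accumulated until the first non-positive consecutive
pair. Prior sensitivity (`prior_sensitivity()`) refits with the observed
response variance divided evenly across the $k$ random components plus the
residual ($V = \widehat{\mathrm{var}}(y)/(k+1)$, $\nu = k + 1$) and
reports each posterior-mean shift in units of the primary posterior SD.

**Run lengths.** The published long-run settings (2.5 million iterations,
50,000 burn-in, thinning 100) remain available via
`mcmc_config(paper_scale = TRUE)`. The package default is a desk-scale run
of 60,000 iterations (10,000 burn-in, thinning 10, 5,000 retained draws),
which in the parameter-recovery studies below reproduces interval coverage
indistinguishable from longer runs for these model sizes; all reported
examples and tests use the desk scale.

**Weighted sufficient statistics.** Individual observations that share all
covariates (e.g. every moth of one species caught in one year, whose
"observation" is the elevation of its trap) are collapsed to a weighted
cell (weight, cell mean, pooled within-cell sum of squares). The collapsed
likelihood is identical, the chain is identical draw for draw, and the fit
is an order of magnitude faster; a test asserts exact equality of the two
chains.

# Elevational centre-of-gravity trends

Each captured individual contributes one observation whose value is the
elevation of its trap. The primary estimator (`species_slopes()`) is the
model with a fixed intercept only and a per-species correlated
(intercept, year) random block; a species' slope (m/yr) is its random
year-slope, and the year covariate is centred at the series midpoint for
identifiability (slopes are unaffected). A Gaussian likelihood on a
support of eleven trap elevations is an approximation — it is adopted
deliberately, and a two-stage check (annual COG, then per-species OLS on
year) is always reported alongside; on abundant species the two agree to
within ~0.1 m/yr in the recovery studies. Species are classified by the
HPD-sign rule: *increased* when the 95% HPD lower limit exceeds zero,
*decreased* when the upper limit is below zero, otherwise *stable*.
`classify_trends()` is a pure function of those signs, and re-applying it
to the bundled published 57-species slope table reproduces the printed
39/15/3 classification exactly.

The trait model (`trait_model()`) explains slope variation (displayed
×100) by the standardized historical COG (first five years, pooled counts;
sample-SD standardization) with first- and second-order terms,
over-wintering stage, life cycle, host type and host specificity
(reference levels: adult / annual / dwarf shrubs / polyphagy), with nested
taxonomic random intercepts (genus, family, superfamily) standing in for
phylogeny. Taxonomic signal is screened with Moran's I under binary
share-a-group weights, whose permutation expectation is $-1/(n-1)$.

# Abundance and flight-period models

`abundance_climate_model()` regresses log10(n + 1) annual catch per
species and trap on vegetation zone, the previous year's season length and
end, and zone × climate interactions, with trap and year random intercepts
and a species-level correlated (intercept, elevation) block, elevation
continuous on the 0–130 m scale. Climate covariates are standardized
internally for mixing and the reported coefficients are back-transformed
draw by draw to the per-day scale.

`flight_period_duration()` smooths the log10(n + 1) across-trap mean daily
catch and counts days above 0.2 (a mean catch of about 1.6 individuals).
The across-trap mean treats the transect as one population sample; a
per-trap-sum convention is a documented alternative via the `n_traps`
argument. The spline basis is 12 — chosen because at 10 the smoother
audibly smears the edges of narrow flight curves in the oracle tests,
while 12 recovers the analytic width of noiseless Gaussian and step curves
to within two days. The threshold back-transform $10^{0.2} \approx 1.585$
matches "1.6 individuals" only on the $n + 1$ scale; the package applies
the threshold on the transformed scale throughout, so the ambiguity has no
computational consequence. Weather covariates (mean and CV of daily
temperature) are computed over the threshold-exceedance hull; windows with
mean below 5 °C are flagged because a CV over near-zero means is
ill-behaved. `flight_period_model()` adds year, log10 abundance and the
temperature × CV interaction as fixed effects with species random
intercepts.

# Community ordination from first principles

Catches are pooled into trap × period assemblages (nine 4-year periods,
the last clipped to three years; 99 assemblages under the default layout),
log10(n + 1)-transformed, and compared by Bray–Curtis dissimilarity.
`nmds()` minimizes Kruskal's stress-1 by alternating isotonic regression
(pool-adjacent-violators with the primary treatment of ties — tied
dissimilarities unconstrained among themselves) with Guttman-transform
steps under a halving line search that accepts only stress-decreasing
moves, so stress is monotone within a run by construction. The best of a
metric-scaling start plus random restarts is returned centred, rotated to
principal axes and scaled to unit RMS distance. On the standard synthetic
fixture the stress agrees with the community-ecology reference
implementation to four decimals, and planar configurations self-embed with
stress below 0.01 and Procrustes correlation above 0.99.

`envfit_ord()` fits environmental variables post hoc: continuous
variables (and ordered factors, encoded as integer ranks — the "time
period" axis is an ordered nine-level factor but is reported with axis
loadings like a vector, so the rank encoding is the operative
interpretation) by regression on the axes, with unit direction cosines and
$r^2$; unordered factors by level centroids with the among-centroid share
of the configuration sum of squares. Significance is by permutation,
$p = (1 + \#\{r^2_{perm} \ge r^2\})/(n_{perm} + 1)$. The
"minimum season length within a time period" covariate is literally the
minimum of the per-year season lengths in the period. Zone-wise turnover
is summarized by `assemblage_dispersion()` (mean distance to the zone
centroid in ordination space). Thin-plate-spline ordination surfaces are
deliberately out of scope; the dispersion and envfit statistics carry the
quantitative claims.

# The synthetic-data generator

`simulate_weather()` builds each year from a Gaussian-bump seasonal curve
(peak +13 °C around day 200 over a −8 °C baseline, width 50 days) plus
three stochastic layers: a smooth within-season anomaly (natural cubic
spline through iid knot values every 15 days, SD 2 °C — weather regimes,
which keep season length and season end only weakly correlated, matching
the observed near-independence of the two), iid daily noise (SD 1.5 °C),
and a linear warming trend split between the ascending limb
(0.0434 °C/yr) and the descending limb (0.077 °C/yr). The limb rates were
calibrated once, analytically, so the noiseless-curve trends equal the
reported study conditions — season length +0.55 d/yr (5 days/decade) and
season end +0.33 d/yr (3 days/decade), with a weak negative season-start
trend — and the anomaly SD reproduces the reported interannual range of
season lengths (roughly 40–108 days) and a slope SE near 0.2. The
generator's own ground truth (noiseless-curve crossings per year) rides
along as an attribute.

`generate_catches()` draws daily counts per species × trap × day from a
Poisson (optionally negative-binomial) process whose expectation
factorizes exactly: annual abundance (log10-linear in the previous year's
true season length) × Gaussian flight-curve day weight × Gaussian
elevation-preference trap weight normalized to sum to one over the
transect. Catches are generated only within the mid-May–mid-October
trapping window, and only for years whose preceding season is available.
Two design points deserve emphasis:

* **Drift is defined on the realized COG scale.** Because the transect
  truncates the preference distribution, moving the preference mean
  linearly would move the realized COG nonlinearly. The generator instead
  moves the *realized* expected COG linearly at `elevation_drift` m/yr and
  solves for the preference mean by numerical inversion. Ground truth and
  estimand then coincide, which is what makes HPD-coverage statements
  about the drift parameter meaningful.
* **Zone-specific climate response is separate from drift truth.** A
  species-level `climate_response` scale lets fell-top specialists ignore
  season length, and a trap-level `zone_response` option applies the
  climate benefit zone by zone *after* weight normalization. The latter
  necessarily distorts realized COGs (the ledger records the distorted
  expectation as `cog_expected` next to the drift target `cog_true`), so
  the standard drift-recovery fixture keeps `zone_response` uniform and
  the abundance-model recovery fixture uses it with drift switched off.

The standard community (`standard_species_set()`) holds 20 species —
five drifting uphill at +1 m/yr, two retreating at −0.5 m/yr, thirteen
stationary including two fell-top specialists with `climate_response = 0`
and two rare species designed to fail the selection filters — with
expected totals near 150,000 individuals over 35 years. Lognormal noise
at the year (SD 0.15 log10 units, shared across species) and species-year
(SD 0.2) levels supplies realistic overdispersion; optional zone-year
noise (used with a large tundra value in the dispersion studies) emulates
the environmental stochasticity of the treeless summit. The ground-truth
ledger (species parameters, per-year true COG and flight window, realized
totals) is written as JSON by `write_ledger_json()`; tests read it, the
pipeline never does.

What the generator does *not* emulate: spatial autocorrelation between
traps beyond elevation preference, outbreak population cycles,
detection-efficiency drift, bimodal flight curves (the study region is
strictly univoltine), or the real species list. Passing recovery tests
therefore demonstrate that the estimators are correct for the assumed
statistical structure — not that the structure captures every feature of
real light-trap data.

# Study sizes and numerical choices

Parameter-recovery studies use the standard fixture at 37 weather years ×
11 traps × 20 species with desk-scale MCMC; the drift-recovery suite runs
50 seeded replicates and requires 95% HPD coverage of the true drift in at
least 85% of species × replicate pairs, and "stable" classification of
null species at the same rate. Smaller module tests use a
15-catch-year, 8-species fixture. Other numerical choices: threshold
crossings use ≥ on integer days; the smoother fits observed days only and
evaluates crossings on the observed span; empty seasons yield length 0
(not an error) while start/end are still reported when their own
thresholds are met; all-zero assemblage pairs get Bray–Curtis 0 with a
warning; non-positive-definite inverse-Wishart scale matrices are jittered
and counted (`glance()$jitter_count`); NMDS non-convergence returns the
best configuration found with `converged = FALSE`.

# Known limitations

* The Gaussian engine has no non-Gaussian links, Metropolis steps, or
  model-comparison criteria (DIC/WAIC) — every response in scope is
  (transformed to) Gaussian.
* The individual-elevation likelihood is Gaussian on an 11-point support;
  the two-stage estimator is the built-in sanity check.
* The slope scale of the published per-species table is not asserted to be
  m/yr; the package reports m/yr and offers the ×100 display scale for the
  trait model so magnitudes are comparable.
* Migrant/resident classification is expert knowledge and out of scope;
  the selection filters assume a resident roster.
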