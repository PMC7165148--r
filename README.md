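# mothshift

Climate-driven elevational change in boreal nocturnal moths, as a tested,
reusable R pipeline.

A fixed transect of 11 light traps (340–470 m a.s.l., four vegetation
zones from spruce ravine to treeless fell summit) sampled nocturnal moths
nightly from mid-May to mid-October for 35 years, with a weather station
on the same slope. `mothshift` implements the complete analysis chain for
such a survey:

* **Season metrics** — per-year season start, length and end from daily
  mean temperatures, via a penalized regression spline and threshold
  crossings (10 °C for the growing season, 8 °C for start, 3 °C for end),
  with OLS temporal trends and Durbin–Watson diagnostics.
* **A Gibbs sampler for Gaussian mixed models** (`gibbs_lmm()`, C++ core)
  with correlated random intercept–slope blocks, inverse-Gamma /
  inverse-Wishart variance priors, 95% HPD intervals, effective sample
  sizes and prior-sensitivity refits — the engine behind all four models.
* **Elevational trends** — each captured individual is an observation
  whose value is its trap's elevation; a fixed-intercept model with
  per-species correlated (intercept, year) random effects yields each
  species' centre-of-gravity slope (m/yr), classified *increased /
  stable / decreased* by the sign of its 95% HPD interval, plus a trait
  model (over-wintering stage, life cycle, host type, host specificity,
  historical range, taxonomic random effects) and taxonomic Moran's I.
* **Abundance vs climate** — log10(n+1) annual catches against the
  previous season's length and end, zone interactions, and trap / year /
  species-by-elevation random effects.
* **Flight periods** — annual flight-period duration as days on which the
  smoothed log10(n+1) mean daily catch exceeds 0.2, modeled against year,
  abundance and within-flight weather.
* **Community ordination** — trap × 4-year-period assemblages,
  Bray–Curtis dissimilarity, nonmetric multidimensional scaling
  (stress-1, isotonic regression, Guttman steps — implemented from first
  principles and agreeing with `vegan::metaMDS` to four decimals on the
  standard fixture), environmental vector/centroid fitting with
  permutation tests, and per-zone dispersion.
* **A synthetic-data generator** with an exact ground-truth ledger
  (drift per species, true season metrics, flight windows), so every
  estimator is validated by parameter recovery.

## Worked example

```r
library(mothshift)

# 37 years of synthetic sub-arctic weather (1977-2013 conditions)
w <- simulate_weather(weather_config(seed = 1))
m <- season_metrics(w)
trend_regression(m, "length_days")
#> # A tibble: 1 x 7
#>   slope    se t_stat  p_value dw_statistic     rho     n
#>   <dbl> <dbl>  <dbl>    <dbl>        <dbl>   <dbl> <int>
#> 1 0.689 0.176   3.92 0.000392         2.02 -0.0515    37
```

The season lengthens by ~0.69 days per year in this realization (the
generating trend is 0.55 d/yr, i.e. 5 days per decade), with no residual
autocorrelation of concern (|rho| < 0.35).

```r
# catches for the standard 20-species community, then per-species slopes
sim <- generate_catches(w, seed = 2)
sl  <- species_slopes(sim$catches, mcmc = mcmc_config(seed = 3))
classify_trends(sl)
#> # A tibble: 1 x 3
#>   increased stable decreased
#>       <int>  <int>     <int>
#> 1         5     13         2
```

The five species generated with +1 m/yr uphill drift are classified
*increased*, the two retreating species *decreased*, and the thirteen
stationary species *stable*. `autoplot(sl)` draws the caterpillar plot;
`tidy()` / `glance()` work on every fitted model. The bundled published
57-species slope table reclassifies as 39 increased / 15 stable /
3 decreased:

```r
classify_trends(published_slope_table())
#> # A tibble: 1 x 3
#>   increased stable decreased
#>       <int>  <int>     <int>
#> 1        39     15         3
```

`run_pipeline()` chains all stages (seasons → selection → abundance,
elevation, traits, phenology, community) and writes per-stage CSVs plus a
JSON manifest with checksums.

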