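# warsawlh

Life-history analysis tools for a long-lived, data-poor deepwater grouper:
otolith-based ageing precision, bomb-radiocarbon age validation, juvenile
habitat inference from seawater DIC Δ¹⁴C, and Bayesian growth/mortality
estimation from length–age composition data. The motivating application is
Warsaw grouper (*Hyporthodus nigritus*) in the northern Gulf of Mexico — a
species with validated ages to 61 y, no formal stock assessment, and
fishery-dependent data whose size-selectivity breaks naive growth fitting.

## What it computes

**Ageing precision.** Beamish–Fournier average percent error
APE = (100/R) Σᵢ |xᵢⱼ − x̄ⱼ| / x̄ⱼ averaged over fish, Chang's CV
(CV = √2·APE for two readers), and percent agreement within 0, 1, 2 years.

**Bomb-radiocarbon validation.** The 1950s–60s nuclear-testing pulse put a
dated Δ¹⁴C mark in the ocean's mixed layer. An otolith core records the
birth-year signature, so cores plotted at `collection year − age` against a
loess-fitted (degree 2, span 0.20, tricube) coral/known-age-otolith
reference series test the accuracy of the ages: residual tests
(Shapiro–Wilk, Levene, mean-zero t) and a sum-of-squared-residual profile
under purposeful ±1–3 y age shifts, minimised at zero shift when ageing is
unbiased. Confidence bands are Bonferroni-corrected for the number of cores
compared.

**DIC depth regression.** OLS of Δ¹⁴C on depth in the 200–600 m band; a
slope near −0.3 ‰/m (≈ −29 ‰ per 100 m) separates the ¹⁴C-enriched mixed
layer from depleted slope water, so core values matching surface water
place juveniles on the shelf (< 200 m).

**Growth and mortality.** An equilibrium catch-composition model:
von Bertalanffy growth L(a) = L∞(1 − e^(−k(a−t₀))) across 21 persistent
growth-type groups, logistic selectivity V(l) = 1/(1+e^(−(l−l₅₀)/γ)),
survivorship decaying at M + F·V(l), observations multinomial on an
age × length-bin grid. All 8 parameters are estimated on the log scale by
adaptive Metropolis–Hastings (multistart mode search, Roberts–Rosenthal
mixture proposal, 4 chains) with log-normal priors — weak on growth and
selectivity, informative on M from the Hewitt–Hoenig longevity estimator
M = 4.22/t_max. Convergence via Gelman–Rubin, Geweke and
Heidelberger–Welch (coda). A plain least-squares VBGF is included to
demonstrate the failure mode the Bayesian model fixes.

Synthetic-data generators (`generate_reference_series()`,
`generate_population_sample()`, `generate_double_reads()`,
`generate_dic_profile()`) emulate every input, so the whole pipeline runs
offline; `run_pipeline()` orchestrates the stages and writes per-stage
CSVs plus a deterministic `report.json`.

## Worked example

```r
library(warsawlh)

## 1. ageing precision on a double-read synthetic sample (n = 485)
pop <- generate_population_sample(
  growth_params(1533, 0.14, 1.82, 0.17, 812, 78.8, 0.066, 0.34),
  485, seed = 7)
reads <- generate_double_reads(pop$age_years, reader_error_model(seed = 8))
precision_summary(reads)
#>   ape_pct   cv_pct agree0_pct agree1_pct agree2_pct   n
#> 1 4.42554 6.258659   38.96907   80.82474    95.6701 485
```

APE 4.4% with CV 6.3% (= √2 × APE); readers agree exactly on 39% of fish,
within ±1 y on 81% and ±2 y on 96%.

```r
## 2. audit the published otolith-core table: years of formation are
##    recomputed as collection year minus age; typos are flagged, not fixed
cores <- read_core_samples(system.file("extdata", "warsaw_core_d14c.csv",
                                       package = "warsawlh"))
cores[cores$year_mismatch,
      c("sample_id", "sample_date", "age_years", "printed_year",
        "year_of_formation")]
#>    sample_id sample_date age_years printed_year year_of_formation
#> 7      WRG-7  10/18/2009         5         2002              2004
#> 8   WRG-0022  12/22/2005         1         2008              2004
#> 10  WRG-1465  12/12/2013        41         1964              1972
```

```r
## 3. validate ages against a reference curve (synthetic here)
cfg <- bomb_curve_config(seed = 1)
fit <- fit_loess(generate_reference_series(cfg))
syn <- generate_core_samples(cfg, 14, seed = 3)
residual_test(fit, syn)
#> Radiocarbon residual test (n = 14 comparable samples)
#>   mean residual: -1.65 permil
#>   Shapiro-Wilk p = 0.735, Levene p = 0.208, mean-zero t p = 0.331
#>   consistent with reference at alpha = 0.05 : TRUE
ssr_bias_profile(fit, syn)[, c("shift", "ssr_d14c")]
#>   shift  ssr_d14c
#> 1    -3 11280....
#> 4     0   523....   <- minimum at zero shift: ageing unbiased
#> 7     3  6212....
```

```r
## 4. DIC depth regression (synthetic profile at the observed slope)
fit_depth_regression(generate_dic_profile(dic_profile_config(seed = 2)))
#> DIC depth regression, 200-600 m (n = 11):
#>   slope -0.3011 permil/m (SE 0.0151), R^2 = 0.978, p = 9.53e-09
#>   = -30.1 permil per 100 m of depth
```

```r
## 5. mortality bookkeeping
hewitt_hoenig_m(61)          # 0.069  (longevity-based M, 1/y)
mortality_summary(0.34, 0.066)$z       # 0.406  (Z = F + M, 1/y)
```

A full Bayesian fit at production scale looks like

```r
obs <- simulate_catch(growth_params(1533, 0.14, 1.82, 0.17,
                                    812, 78.8, 0.066, 0.34),
                      1338, seed = 640)
fit <- run_mcmc(obs, priors = growth_priors(),
                config = mcmc_config(n_chains = 4, burn_in = 5000,
                                     n_samples = 20000, seed = 641))
fit$posterior                # natural-scale means + log-space SDs
convergence_diagnostics(fit) # PSRF / Geweke / Heidelberger-Welch
```

and recovers the generating parameters (L∞ within a few percent, k and F
within their posterior spread) while leaving the informative M prior
essentially un-updated — composition data identify total mortality only.

See `vignettes/warsaw-grouper-methods.Rmd` for the model construction,
numerical choices, and the limits of what the synthetic studies show.

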