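---
title: "Methods: bomb-radiocarbon age validation and Bayesian growth estimation for a deepwater grouper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bomb-radiocarbon age validation and Bayesian growth estimation for a deepwater grouper}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(warsawlh)
```

## The scientific problem

Warsaw grouper (*Hyporthodus nigritus*) is a long-lived, deepwater serranid
whose stock status in the northern Gulf of Mexico is unknown. Everything a
stock assessment needs — growth, longevity, mortality — rests on otolith age
estimates, and deepwater otoliths are hard to read. This package implements
the full analysis chain for such a data-poor species:

1. **Ageing precision** between two otolith readers (APE, CV, percent
   agreement).
2. **Age validation** with the bomb-radiocarbon chronometer: the rapid rise
   in marine Δ¹⁴C caused by 1950s–60s atmospheric weapons testing is a dated
   chemical mark; an otolith core (first months of life) carries the Δ¹⁴C of
   the water in the birth year, so plotting core values at
   `collection year − age` against a coral/known-age-otolith reference curve
   tests whether the ages are right.
3. **Juvenile habitat** inference from the depth profile of seawater
   dissolved inorganic carbon (DIC) Δ¹⁴C.
4. **Growth and mortality** from length–age composition data with a
   Bayesian equilibrium model that accounts for gear selectivity and
   size-selective mortality — the reason a naive least-squares von
   Bertalanffy fit fails on fishery-dependent data.

Because the raw fish records behind such studies are rarely deposited, the
package ships synthetic-data generators with the statistical structure each
stage assumes, so the entire pipeline is testable offline.

## Reader precision

For fish $j$ read by $R$ readers with reads $x_{ij}$ and mean
$\bar{x}_j$, the Beamish–Fournier average percent error is
$\mathrm{APE} = \frac{1}{J}\sum_j \frac{100}{R} \sum_i |x_{ij}-\bar{x}_j| / \bar{x}_j$,
and Chang's CV uses the sample ($n-1$) standard deviation,
$\mathrm{CV} = \frac{1}{J}\sum_j 100\, s_j/\bar{x}_j$. For two readers
$\mathrm{CV} = \sqrt{2}\,\mathrm{APE}$ fish by fish, which the tests use as
an algebraic cross-check. Fish missing a read from either reader are
excluded from all three statistics, matching the usual "subsample read by
both readers" design.

## The reference curve and its confidence band

The reference series (coral plus known-age otolith Δ¹⁴C versus year of
formation) is fit with classical loess: local quadratic regression, tricube
weights, span = 0.20 as a fraction of points, no robustness iterations,
computed exactly (`surface = "direct"`). These settings matter because
loess dialects differ; this one is the default behaviour of the standard R
implementation, and the test suite pins it against a brute-force local
weighted least-squares oracle to $10^{-8}$.

Confidence intervals around the curve are Bonferroni-corrected: with $m$
otolith cores being compared, each pointwise t-interval is built at level
$\alpha/m$, giving simultaneous familywise coverage $\ge 1-\alpha$ *for the
smooth itself*. A coverage simulation in the tests shows the multiplicity
correction is conservative (97% simultaneous coverage of the estimator's
expected value at 14 query years), but coverage of the *true* generator
mean is slightly below nominal (about 93–94%) because local quadratic
smoothing is biased where the curve bends hard (the rise into the peak).
That bias, about 1–2 ‰ at span 0.20 with the default synthetic curve, is an
inherent smoothing property, not a defect of the band.

## Residual test and the SSR bias profile

Residuals are observed core Δ¹⁴C minus the fitted curve at the estimated
birth year. Cores whose birth year predates the reference range cannot be
validated and are reported separately, never silently dropped. The report
carries Shapiro–Wilk (normality) and Levene (variance homogeneity between
early and late birth years, split at the median) checks, and the verdict is
a one-sample t-test of mean zero at $\alpha = 0.05$ — the paper trail for
"no significant difference" claims. Degenerate all-zero residuals are
declared consistent directly, since the t statistic is undefined there.

Ageing bias is profiled by purposely shifting ages by −3 … +3 years. A
positive shift makes fish older, i.e. moves the birth year *earlier*; the
d14c-mode SSR is $\sum_i (\Delta^{14}C_i - \hat f(b_i - s))^2$ where $b_i$
is the unshifted birth year. Unbiased ageing shows a minimum at $s = 0$.
A second mode inverts the fitted curve on its monotone rise segment and
sums squared birth-year differences; cores whose Δ¹⁴C lies below the
pre-bomb plateau have no inverse and are assigned the rise-start year and
flagged. Both modes are reported; the Δ¹⁴C mode is primary because the
residual is measured in the quantity actually observed.

Published tables of core samples sometimes carry internal inconsistencies;
`read_core_samples()` therefore always recomputes `collection year − age`
and flags rows whose printed year of formation disagrees, without guessing
which field is wrong.

## DIC depth regression

Ordinary least squares of DIC Δ¹⁴C on depth, restricted to the closed
200–600 m window (both ends inclusive — the source range is stated without
specifying openness, and inclusive ends are the conservative reading). The
slope has a two-sided t-test p-value, and `slope_per_100m()` re-expresses
it in ‰ per 100 m, the form used when comparing otolith-core values to
water-column values.

## The growth/selectivity/mortality model

### Construction

Ages are integers $1 \dots A$ (default $A=65$); lengths fall in bins of
width $w = 50$ mm spanning 0–2,500 mm. The population is $G = 21$
equal-weight growth-type groups with persistent relative deviations
$\delta_g = \Phi^{-1}\!\big((g-\tfrac12)/G\big)\,\mathrm{cv}_{len}$, so a
fish that is 10% above the mean curve at age 5 is still 10% above it at age
40. Group length at age is $l_{ga} = \mu_a (1+\delta_g)$, floored at 1 mm,
with $\mu_a = L_\infty(1-e^{-k(a-t_0)})$. Selectivity is logistic,
$V(l) = (1+e^{-(l-l_{50})/\gamma})^{-1}$ with spread $\gamma$ in mm.
Survivorship is $S_{g,1}=1$,
$S_{g,a+1} = S_{g,a}\, e^{-(M + F\,V(l_{ga}))}$: fast-growing groups become
vulnerable sooner and are fished down harder — the mechanism that biases
naive growth fits. Catch mass $S_{ga} V(l_{ga})/G$ accumulates on the grid,
and observations are multinomial draws of grid cells.

With $G = 21$ and $\mathrm{cv}_{len} = 0.17$ the deviations span about
±34%, so simulated size-at-age for old fish spans roughly
$L_\infty \pm 500$ mm — the spread real length–age scatter shows for this
species.

### Numerical choices

*Bin sharing.* Each group's catch mass is shared linearly between the two
bins whose centres bracket $l_{ga}$ (with clamping at the grid edges),
rather than dumped into the single containing bin. The point-mass
alternative makes every cell probability piecewise constant in the
parameters: the log-likelihood of ~1,300 observations becomes a comb of
plateaus and hundred-log-unit cliffs on which gradient methods stall far
from the optimum and Markov chains wedge. Linear sharing makes the surface
continuous while preserving the two closed forms the model is checked
against: the age marginal is exactly geometric in $Z$ when selectivity is
saturated, and mean length at age reproduces $\mu_a$ to $\sim 10^{-8}$
relative error when $F = 0$ (bin-centre coordinates preserve first
moments). A smoothing constant $\varepsilon = 10^{-10}$ per cell keeps the
likelihood finite for stray observations.

*Ages at the floor.* Below $t_0$ the mean length floors at 1 mm, and such
lengths are represented by the first bin; age-1 cells are therefore
coarse, which is immaterial because selectivity at those lengths is
essentially zero.

### Priors and likelihood

All eight parameters are sampled on the log scale with log-normal priors
(median + log-SD per parameter). The default prior set places weak priors
(log-SD 2–5) on growth, length-CV and selectivity, an informative prior on
$M$ (median 0.069 / y from the longevity estimator, log-SD 0.1), and a weak
prior on $F$. Working in log space forces $t_0 > 0$; that is a modelling
choice, documented rather than patched, and it is how a positive posterior
age-intercept arises. The log-likelihood is
$\sum_i \log P(a_i, \mathrm{bin}(l_i))$.

### Sampling

The posterior is estimated by random-walk Metropolis–Hastings on the 8
log-parameters, four chains by default.

* **Initialisation.** Starting chains at the prior medians can land on a
  likelihood plateau (every observation in an $\varepsilon$-cell, zero
  gradient), so the sampler first builds crude data-driven estimates — a
  catch-curve $Z$ from the descending age frequencies, a least-squares
  VBGF for the growth parameters, length quantiles for $L_\infty$ and
  $l_{50}$ — and polishes the posterior mode with alternating BFGS and
  Nelder–Mead cycles. Because the surface has multiple basins differing
  mainly in $L_\infty$, the polish is launched from a deterministic
  profile of seven $L_\infty$ values spanning 0.95–1.40 × the 99th length
  percentile (with $k$ and $t_0$ re-fit at each so the curve stays aligned
  with the data), plus randomly jittered starts and two re-polishes of the
  incumbent. Purely random multistarts are not reliable here: single
  starts stall in local basins 100+ log units below the global one, and
  profile-structured starts are what makes the mode search reproducible
  across prior settings.
* **Proposal.** A Roberts–Rosenthal mixture: with probability 0.95 a
  multivariate normal shaped by the chain's running covariance estimate
  and scaled by a Robbins–Monro recursion targeting ~30% acceptance; with
  probability 0.05 a fixed diagonal kick (SD 0.05 in log space).
  Adaptation diminishes as $1/i$ and continues through sampling.
  The fixed component exists because covariance adaptation alone can
  collapse inside a micro-mode and freeze a chain there; the kick lets it
  escape. Continued diminishing adaptation (rather than a hard freeze at
  the end of burn-in) keeps late chains well-tuned and preserves
  ergodicity.
* **Seeds.** Chain $c$ uses `seed + c`; every generator takes an explicit
  seed and restores the caller's RNG state.

Convergence is checked with the Gelman–Rubin PSRF across chains, the
Geweke first-10%-vs-last-50% comparison, and the Heidelberger–Welch
stationarity test, with an overall pass requiring PSRF < 1.1, |z| < 2 and
stationarity passes. One caveat learned from constructed pathologies: the
Heidelberger–Welch stationarity verdict has little power against smooth
trends (the trend inflates its spectral-density estimate), so trending
chains are in practice caught by Geweke and split chains by the PSRF.

### What the simulation studies show — and what they do not

On synthetic catches ($n = 1{,}338$) drawn from the model at the estimated
parameter values for this stock, four chains of 20,000 retained draws
recover $L_\infty$ within ~5%, $k$ within ~20% and $F$ within ~30%; the
posterior log-SD of $M$ stays within 20% of its informative prior (0.1),
i.e. composition data do not update natural mortality — only total
mortality is estimable, so $F$ inherits the $M$ prior's uncertainty. The
$L_\infty$ posterior is insensitive to moving its weak prior median between
1,618, 1,687 and 1,850 mm. These checks validate the estimation machinery
against the model's own data-generating process; they cannot validate the
model against a real population, where ageing error, time-varying
recruitment and dome-shaped selectivity — all absent from the generator —
would widen the honest uncertainty.

The equilibrium age marginal at the estimated parameters has a median age
of 9 y and is strongly right-skewed, though less extreme than raw landed-age
distributions for this species (where >90% of fish are under 10 y): a
landings sample reflects effort concentration as well as equilibrium
composition, and the generator emulates only the latter.

### Problem sizes used in the checks

The routine test suite uses populations of 300–1,338 fish, chains of
800–20,000 retained draws, 200–1,000 replicate simulations for the
calibration studies, and 500 replicates for the coverage study. The
production-scale default (4 × 200,000 draws) is exposed through
`mcmc_config()` but deliberately not exercised by the tests; posterior
summaries at the test scale are already stable to well within the
tolerances quoted above.

## Mortality arithmetic

The longevity-based estimator is $M = 4.22/t_{max}$ (reported to three
decimals), $Z = F + M$, and the overfishing indicator is $F\!:\!M$
(reported to one decimal). Note that ratios of *rounded* posterior means
can differ in the last digit from the ratio of unrounded draws: with
$F = 0.34$ and $M = 0.066$ the exact ratio is 5.15.

## Pipeline

`run_pipeline()` wires the stages together: synthetic inputs are generated
for anything not supplied as a CSV, per-stage CSV outputs and a
consolidated `report.json` are written, and a `run.log` captures versions,
seeds and timings. The report is a pure function of configuration and
seed — running the same configuration twice yields byte-identical reports —
while wall-clock details live only in the log. A failed stage is logged
and recorded in the report without destroying the outputs of completed
stages.

## Known limitations

* The generator's bomb curve is a smoothstep through three anchors; real
  reference series have year-to-year structure and regionally varying
  amplitudes.
* Reader error is Gaussian with SD proportional to age; real reader error
  is likely age-dependent in shape, and no published error structure
  exists for this species.
* The composition model assumes equilibrium: stable recruitment, $M$, $F$
  and selectivity over the decades spanned by the ages. Violations load
  onto $F$ and $\mathrm{cv}_{len}$ in ways the simulations do not probe.
* Sex-specific growth is out of scope (insufficient sex data in this
  fishery), as are spatial sampling structure and decay/fractionation
  corrections, which happen upstream at the AMS laboratory.
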