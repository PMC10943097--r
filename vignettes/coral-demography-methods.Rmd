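---
title: "Methods: size-structured coral demography with thermal-stress climatologies and Bayesian GLMs"
author: "coraldemog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: size-structured coral demography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

`coraldemog` implements a decadal analysis workflow for size-structured
coral populations on subtropical reefs. The unit of observation is the
individual coral colony: one row per colony carrying its site, shelf
position (inshore/offshore), survey year and month, transect, genus,
planar area in cm², and binary flags for bleaching, partial mortality and
partial capture in the survey photograph. Environmental context comes from
daily sea surface temperature (SST) and chlorophyll-a series per site.

Because colony-level monitoring data of this kind are typically available
only on request, the package ships a first-class synthetic-data generator
whose parameters are *planted* and therefore recoverable: every downstream
estimator can be validated against known truth. The generator is not a
test fixture; it is part of the package surface.

# Colony preprocessing conventions

* **Lower size cut-off 0.8 cm²** (~1 cm diameter): smaller colonies cannot
  be captured consistently across photographic surveys and are excluded.
* **Survey periods**: years 2010/2012 map to P1 (pre-bleaching state),
  April and October 2016 to P2 (bleaching event and immediate aftermath),
  2018/2019 to P3 (early recovery). Years outside the mapping are an
  error, not silently dropped.
* **Partially captured colonies** (colonies extending beyond the photo
  frame; their recorded planar area is an underestimate) are retained by
  default because they still carry abundance information; the sensitivity
  mode `include_partially_captured = FALSE` drops them.
* All log transforms are the **natural log**. The base affects neither KS
  statistics, quintile membership nor skewness — only the reported scale
  of the log-area summaries.

A documented assumption: the mean colony size is reported on the raw cm²
scale, while the coefficient of variation (sigma/mu) and the adjusted
Fisher–Pearson skewness are computed on log-area. Published summary values
of the kind the generator is asked to plant (CVs of 0.3–0.5 with raw means
of tens to hundreds of cm²) are only mutually consistent under this
log-scale reading, so the package adopts it throughout.

# The synthetic generator

## Size distributions

Colony areas are generated as `exp(X)` with `X` skew-normal on log-area.
A lognormal (normal on the log scale) cannot plant nonzero log-scale
skewness, which real size-frequency distributions show (laminar taxa
dominated by large colonies are left-skewed on the log scale); the
skew-normal is the minimal extension with closed-form moments. For
targets (raw-scale mean area, log-scale CV, log-scale skewness),
`solve_size_params()`:

1. inverts the closed-form skewness formula for the shape parameter
   (feasible for |skewness| < 0.9953; an infeasible target is an explicit
   error, never a silent clamp);
2. solves one monotone scalar equation for the scale parameter, using the
   skew-normal moment generating function `E[e^X] = 2 exp(xi + omega^2/2)
   Phi(omega * delta)` for the raw-scale mean (root bracketing plus
   `uniroot` at tolerance 1e-12).

The zero-CV limit degenerates to a point mass and is only defined for a
zero skewness target.

## Condition flags and partial capture

Bleaching and partial mortality are size-dependent Bernoulli draws on the
logit scale (`intercept + slope * logArea`, plus an additive logit boost
of bleached status on partial mortality). Partial capture is modelled as
multiplicative truncation: a flagged colony's recorded area is its true
area times a uniform fraction in [0.3, 1), mimicking a colony extending
beyond the frame. The default partial-capture rate is 10.7%. Colony
counts per stratum are fixed (not Poisson) so planted totals are exact;
`count_mode = "poisson"` restores count noise when wanted.

## Environmental series

Daily SST is baseline + seasonal sinusoid (peaking mid February, the
Austral summer maximum) + rectangular anomaly pulses + Gaussian noise;
chlorophyll-a is generated analogously in opposite phase (winter-peaking,
as on shelf waters under seasonal mixing) with configurable missing-data
windows. Offshore sites in the default pipeline run 1 °C warmer with 30%
lower chlorophyll, reflecting stronger western-boundary-current influence
offshore. What the generator does *not* emulate: spatial autocorrelation
of colonies within transects (colonies are exchangeable within strata),
autocorrelated SST noise, cloud-driven seasonal clustering of
chlorophyll gaps, and colony growth/mortality as a process through time —
period contrasts are planted marginally, not mechanistically. Passing
tests therefore demonstrate correctness of the estimators under the
stated sampling models, not robustness to every feature of field data.

# Thermal stress metrics

The climatology is computed per site: the monthly mean for calendar month
m is the average over baseline years of that year's month-m daily mean
(equal weight per year; leap days go to February). MMM is the maximum of
the 12 values (heat-stress baseline), mMM the minimum (cold-stress
baseline). The baseline defaults to the full available record; an
externally supplied MMM/mMM can be passed through a `coral_climatology`
object when reproducing values computed against a fixed satellite-era
baseline.

Degree heating weeks with a 0 °C threshold:

    DHW_0C(t) = sum_{d = t-83..t} max(0, SST(d) - MMM) / 7

an 84-day (12-week) trailing window *inclusive* of the current day, in
°C-weeks. With the 0 °C threshold every positive anomaly accumulates, so
values exceed the conventional satellite product that only accumulates
anomalies ≥ 1 °C above MMM. Degree cooling weeks accumulate deficits
below `mMM + offset` (offset 0 → DCW_0C, offset 1 → DCW_1C); they are
stored negative (more negative = more cold stress) and reported as
magnitudes. Because the threshold `mMM + 1` is higher, `|DCW_1C| >=
|DCW_0C|` pointwise — a property the tests verify on random series along
with exact equivalence of the rolling implementation (cumulative sums)
to the brute-force 84-term definition.

The first 83 days of any stress series are burn-in and reported as
missing, not as partial sums. Annual summaries take calendar-year means
of SST and gap-filled chlorophyll and within-year maxima of the stress
metrics; the per-year heat/cold stress predictor is the annual maximum of
the rolling metric (not its value on survey dates) — the quantity that
summarises the worst stress a cohort experienced in that year.
Chlorophyll gaps are filled by linear interpolation in time; leading and
trailing gaps are left missing because extrapolation has no support.

# Size structure

Quintile size classes use boundaries at the 20/40/60/80th percentiles of
log-area pooled across **all years** within a genus × habitat stratum,
with the linear-interpolation quantile convention (type 7, the default in
mainstream statistical software; the test oracles use the same
convention). The same boundaries apply to every year, so temporal shifts
are measured against a fixed reference. Q1 is "small" (the population
replenishment proxy), Q2–Q4 "medium", Q5 "large" (reproductive output
proxy). Bins are left-closed/right-open: a colony exactly on a boundary
goes to the upper bin; if all pooled values are identical the scheme is
degenerate (warned) and everything lands in Q5 by that rule.

Distributional comparisons use the two-sample Kolmogorov–Smirnov test
(two-sided D, asymptotic p), pooling transects — the D statistic is
invariant to strictly monotone transforms, so the log base is immaterial.

# Change estimation

Percentage change is `100 * (after - before) / before`; a zero baseline
is returned as missing with a warning. Uncertainty comes from a
stratified nonparametric bootstrap: colonies are resampled with
replacement within site × period cells, size-class counts and metrics are
recomputed per replicate with the *fixed* pooled scheme, and the
replicate distribution of percentage changes is summarised by its median
and 66%/95% highest posterior density intervals (the shortest contiguous
interval containing the requested mass of sorted replicate values —
shorter than equal-tailed intervals for skewed replicate distributions).
The resampling unit is the colony, because size-class counts are
colony-level statistics; transect-block resampling is available as a
sensitivity mode (`unit = "transect"`). An alternative reading of this
kind of uncertainty display — resampling from model posteriors rather
than from the data — is accommodated by summarising externally supplied
draws with the same `hpd()` function.

# Bayesian GLMs

`bglm()` fits three families through JAGS: gaussian (identity link) for
mean size, Bernoulli (logit) for bleaching/partial-mortality incidence,
and negative binomial (log link) for counts, parameterised as a
Poisson-gamma mixture (`y ~ Pois(mu * g)`, `g ~ Gamma(r, r)`), whose
marginal is exactly negative binomial with dispersion r. The JAGS `glm`
module is loaded at package load for block-updating samplers, which mix
far better on logistic models than one-at-a-time updates.

Defaults, all exposed:

* **MCMC**: 3 chains × 4000 iterations, warmup 200 (used as the JAGS
  adaptation phase), thinning 5 → 760 retained draws per chain, 2280
  total. Chain RNGs are seeded deterministically from the settings seed.
* **Priors** ("weakly informative, conservative"): Normal(0, 2.5²) on
  coefficients of standardized predictors, Normal(0, 5²) on the
  intercept, half-Cauchy(0, 5) on the gaussian residual SD and the
  negative-binomial dispersion.
* **Standardization**: continuous predictors (columns with > 2 distinct
  values) are centred and scaled internally; coefficients are reported on
  the standardized scale and `predict()` undoes the scaling. Recovery
  tests that assert natural-scale coefficients set `standardize = FALSE`.
* **Convergence**: Gelman–Rubin R-hat per parameter with a 1.05 flag
  threshold; flagged fits are refused by `compare_models()` unless
  forced.

Reported diagnostics per fit: posterior medians, 95% HPD intervals,
R-hat, Bayes R² (per-draw explained variance: `var(mu) / (var(mu) +
expected residual variance)`, with family-specific residual variance),
a posterior-predictive check on the replicated mean and SD, and LOOIC.
LOOIC is computed from the pointwise log-likelihood by importance-sampled
leave-one-out with weight truncation at `sqrt(S)` times the mean weight
(Ionides 2008), a stabilised variant of IS-LOO implemented in the
package; model weights are pseudo-BMA, `w_i ∝ exp(-ΔLOOIC_i / 2)`,
normalised — the relative likelihood of each model in the set.

For small-coral abundance, counts are pooled across transects per
site-year (constant survey area of 108 m² per site means no exposure
offset is needed). Candidate models are all additive subsets of the
screened environmental predictors {SST_mean, Chla_mean, DHW0, DCW1} (16
models including intercept-only). The collinearity screen drops one
member of every pair with |Pearson r| > 0.8, keeping the
higher-priority predictor; the default priority retains DCW_1C over
DCW_0C, the two being near-collinear by construction since both
accumulate from the same SST record.

# Numerical and design choices

* **Quantile convention** type 7 everywhere (boundaries, percentile
  summaries, oracles), so quintile boundaries on {1..5} are exactly
  (1.8, 2.6, 3.4, 4.2).
* **HPD** from sorted samples: the shortest window containing
  `ceiling(mass * n)` values; a point mass yields a zero-width interval;
  `n_boot = 1` collapses intervals onto the single replicate.
* **Degenerate inputs**: empty colony tables keep their schema; strata
  with an empty period yield flagged-missing change estimates rather
  than errors; skewness is reported missing below n = 3.
* **Determinism**: one master seed drives generator, bootstrap and MCMC
  via fixed derivation; reruns produce byte-identical CSVs and digests.

# Problem sizes used in the validation suite

Chosen to make Monte-Carlo error small relative to the tolerances while
keeping the suite interactive: 4×10⁵–10⁶ draws for moment recovery
(3 analytic SEs), 10⁵ colonies for rate and quintile-balance checks,
1000 random series for the rolling-window equivalence (tolerance 1e-9),
200 synthetic datasets for bootstrap coverage and 50 replicates per
family for GLM interval coverage (both at the ≥ 90% nominal-coverage
bar, which leaves Monte-Carlo slack below the 95% nominal level). The
coverage replicates run shortened chains — the property under test is
interval coverage, not mixing depth — except the negative-binomial
replicates, which need longer chains for the latent-mixture dispersion to
converge; the package defaults remain the full 3 × 4000 settings.

# Known limitations

* The negative-binomial latent-mixture parameterisation slows JAGS
  mixing for the dispersion parameter at small n; the R-hat flag
  catches this, and longer chains resolve it.
* IS-LOO with truncation is less robust than Pareto-smoothed importance
  sampling for highly influential observations; LOOIC differences much
  smaller than their SEs should not be over-read.
* The generator plants marginal patterns; it cannot validate inferences
  that depend on within-transect spatial structure or temporal colony
  identity, which the colony-level analyses here do not use.
* External satellite-product reproduction (fixed-baseline MMM values)
  requires supplying the product's own climatology; recomputing a
  fixed-era baseline from a short record is deliberately not attempted.
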