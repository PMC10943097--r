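# coraldemog

Decadal, size-structured demography of subtropical coral populations:
thermal-stress climatologies from daily SST, quintile size-class analyses,
bootstrap change estimation with highest-posterior-density (HPD) intervals,
and Bayesian GLMs linking bleaching, partial mortality and juvenile
abundance to colony size, taxon, survey period and environment.

The package is written for reef ecologists and biostatisticians analysing
colony-level photographic survey data (one row per coral colony: site,
shelf position, survey date, transect, genus, planar area in cm², and
binary bleaching / partial-mortality / partial-capture flags) together
with satellite SST and chlorophyll-a series. Because such datasets are
often request-only, a synthetic generator with *planted, recoverable*
parameters is part of the package, so the entire pipeline can be validated
end to end against known truth.

## What it computes

**Thermal stress.** Per-site monthly-mean climatology with MMM (maximum of
monthly means) and mMM (minimum); degree heating weeks with a 0 °C anomaly
threshold,

    DHW_0C(t) = Σ_{d=t−83..t} max(0, SST(d) − MMM) / 7   [°C-weeks]

over a trailing 84-day window inclusive of the current day, and the
analogous degree cooling weeks DCW_0C / DCW_1C accumulating deficits below
mMM and mMM + 1 °C (negative internally, reported as magnitudes). Annual
site summaries: mean SST, mean gap-filled chlorophyll-a, and within-year
stress maxima.

**Size structure.** Preprocessing (0.8 cm² lower cut-off, period grouping,
optional exclusion of partially captured colonies), quintile size classes
with boundaries at the pooled 20/40/60/80th percentiles of log-area per
genus × habitat (fixed across years; Q1 = small, Q2–Q4 = medium, Q5 =
large), per-stratum summaries (raw-scale mean area; log-scale CV = σ⁄μ,
adjusted Fisher–Pearson skewness, 20th/80th percentiles), and two-sample
Kolmogorov–Smirnov comparisons of size-frequency distributions.

**Change estimation.** Percentage changes 100·(after − before)/before in
class abundances and size metrics between periods, with a stratified
nonparametric bootstrap (colonies resampled within site × period; n = 1000
replicates by default) summarised by the replicate median and 66%/95% HPD
intervals.

**Bayesian GLMs.** One fitting function, `bglm(formula, data, family)`,
for gaussian, Bernoulli-logit and negative-binomial (log link) models,
sampled with JAGS (3 chains × 4000 iterations, warmup 200, thin 5 by
default; weakly informative priors). Each fit reports posterior medians,
95% HPD intervals, Gelman–Rubin R-hat, Bayes R², a posterior predictive
check and LOOIC; `compare_models()` turns LOOIC differences into
pseudo-BMA weights w_i ∝ exp(−Δ_i/2). A collinearity screen (|r| > 0.8)
and an all-subsets candidate set support the small-coral abundance
analysis. The usual methods work: `print`, `summary`, `coef`, `predict`,
`simulate`, `residuals`, `plot`.

## Worked example

Plant a Pocillopora-like population (raw-scale mean area 66.42 cm²,
log-scale CV 0.51, log-scale skewness −0.03 offshore; larger inshore),
survey it over three periods, and analyse:

```r
library(coraldemog)

sizes <- list(
  solve_size_params(66.42, 0.51, -0.03, taxon = "Pocillopora",
                    habitat = "offshore", n_per_stratum = 80L),
  solve_size_params(86, 0.51, -0.03, taxon = "Pocillopora",
                    habitat = "inshore", n_per_stratum = 80L))
cond <- condition_model(bleach_intercept = qlogis(0.5), bleach_slope = 0.4,
                        pm_intercept = qlogis(0.03), pm_bleached_boost = 1.1)
colonies <- generate_colony_table(sizes, cond, survey_design(), seed = 42)
proc <- preprocess_colonies(colonies)
summarize_sizes(proc)[1:2, ]
#>         genus    shelf period   n mean_area        cv  skewness      q20      q80
#> 1 Pocillopora  inshore     P1 934  84.84652 0.4745226 0.1855825 1.861734 4.571102
#> 2 Pocillopora offshore     P1 943  64.34907 0.5005038 0.1610876 1.680643 4.261569
```

Per-stratum means and CVs sit near their planted values (the small
positive shift in skewness relative to the planted −0.03 is real: the
0.8 cm² cut-off and the shrunken areas of partially captured colonies
both act on the observed distribution, not the latent one).

```r
quintile_scheme(proc, "Pocillopora", "offshore")
#> Quintile size-class scheme: Pocillopora / offshore (n = 2822 pooled)
#> log-area boundaries: 1.742, 2.640, 3.423, 4.322

ch <- bootstrap_changes(proc, n_boot = 1000, seed = 42,
                        period_pairs = list(c("P1", "P3")))
subset(as.data.frame(ch), quantity == "small" & habitat == "offshore",
       select = c(quantity, period_pair, point_pct, median_pct,
                  hpd95_lo, hpd95_hi))
#>   quantity period_pair point_pct median_pct  hpd95_lo hpd95_hi
#> 8    small       P1-P3 -8.866995  -9.068068 -22.52252       10
```

The small-colony abundance offshore changed by −8.9% between P1 and P3
(bootstrap median −9.1%); the 95% HPD interval spans zero, so no change is
distinguishable — as expected, since none was planted.

```r
fit <- bglm(bleached ~ log_area, proc, family = "bernoulli",
            settings = mcmc_settings(seed = 42))
summary(fit)
#> Bayesian GLM (bernoulli): bleached ~ log_area
#>
#>             median hpd95_lo hpd95_hi  rhat
#> (Intercept)  1.261    1.199    1.326 1.000
#> log_area     0.534    0.470    0.601 1.003
#>
#> Bayes R2 = 0.046; LOOIC = 5871.3 (SE 77.5); converged: TRUE
#> PPC tail probabilities: mean 0.51, sd 0.52
```

Larger colonies bleach more: the planted logit slope of 0.4 per unit
log-area corresponds to 0.4 × SD(log-area) ≈ 0.53 on the standardized
scale `bglm` reports, which is exactly where the posterior lands.

The whole pipeline (generation → stress metrics → size structure →
bootstrap changes → condition GLMs, with CSV outputs and a JSON manifest)
runs as one call: `run_pipeline(default_config(seed = 1))`.

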