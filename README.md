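# chronovar

Statistical pipeline for pilot **human chronobiome** studies: small cohorts
(≈6 subjects) deeply phenotyped over repeated 48-hour sessions, with
continuous remote sensing (actigraphy, ambulatory blood pressure, heart
rate, light, communication, mobility, nutrient intake) and sparse
12-hourly omics sampling (plasma/saliva metabolome, serum proteome, oral
microbiome) at 0/12/24/36/48 h — three morning and two evening collections
per session.

The central question such pilots ask is whether a *time-of-day signal* is
detectable at all above the "noise" of inter-individual behavioral
differences. `chronovar` implements the four statistical tools that answer
it, plus a synthetic-data generator so every stage is testable without
access to a cohort:

- **Time-versus-subject variance partition.** Per feature, a two-way
  main-effects ANOVA decomposes total variance into time-of-day, subject
  and residual shares: `pct_time = 100·SS_time/SS_total`, etc. Features
  with `pct_time ≥ 5%` are flagged time-varying, and panel summaries report
  the flagged percentage (e.g. 9 of 166 features → 5.4%).
- **Exhaustive morning/evening permutation test.** Dataset-level statistic
  `T = Σ_features (morning mean − evening mean)²` on unit-variance-scaled
  features, referenced against *every* distinct reassignment of epoch
  labels to within-session timepoints (the relabeling applies to all
  subjects at once, preserving within-subject pairing). The two-session
  reference design has `choose(5,3)² = 100` arrangements, so the smallest
  achievable p is 0.01.
- **Cosinor rhythmometry.** Fixed-period fit
  `y(t) = M + A·cos(2π(t − φ)/τ)`, τ = 24 h, via the linear
  reparameterization `y = M + β·cos(ωt) + γ·sin(ωt)` with
  `A = √(β² + γ²)`, `φ = atan2(γ, β)/ω`; zero-amplitude F-test; circadian
  amplitudes correlated across channels by squared Pearson R² and
  acrophases by a circular–circular correlation, Bonferroni-corrected.
- **Wake/sleep summaries and variance-correlation matrices.** Nocturnal
  dipping (wake mean − sleep mean) from diary-scored bins; pairwise
  simple-regression R² across all sensor channels with
  Bonferroni-corrected goodness-of-fit p-values.

## Worked example

Generate a synthetic cohort at the reference design and test one omics
panel:

```r
library(chronovar)
library(dplyr)

cfg <- generator_config(seed = 1)          # 6 subjects, 2 x 48 h sessions

# Nocturnal blood-pressure dipping from the sensor block
sens <- generate_sensor_streams(cfg)
b <- bin_stream(filter(sens$streams, channel == "map"), 30)
filter(wake_sleep_panel(b, sens$diary, width = 30), mode == "per_subject")
#> # A tibble: 1 × 6
#>   channel mode        wake_mean sleep_mean   dip dip_sd
#>   <chr>   <chr>           <dbl>      <dbl> <dbl>  <dbl>
#> 1 map     per_subject      87.8       70.1  17.7  0.361

# Morning/evening structure in the metabolome
om <- generate_omics(cfg, "metabolome")    # 166 features, 5.4% rhythmic
exhaustive_permutation_test(om)
#> # A tibble: 1 × 8
#>   scope   statistic n_permutations n_at_least_as_extreme p_value
#>   <chr>       <dbl>          <int>                 <int>   <dbl>
#> 1 dataset       18.1            100                     1    0.01
#> # i 3 more variables: min_achievable_p <dbl>, mode <chr>,
#> #   n_features_used <int>

flag_summary(classify_time_varying(partition_variance(om)), "metabolome")
#> # A tibble: 1 × 4
#>   dataset    n_features n_flagged pct_flagged
#>   <chr>           <int>     <int>       <dbl>
#> 1 metabolome        166        10           6
```

The generator plants a 19.4 mmHg mean-arterial-pressure dip during
self-reported sleep; the wake/sleep summary recovers it (17.7 here — the
midpoint rule for scoring bins against jittered sleep boundaries
attenuates the dip slightly, a property shared by any interval-scored
dipping estimate).
The permutation test sits at the scheme's floor (p = 0.01 of 100
arrangements) because 5.4% of features carry a genuine morning/evening
shift, and the 5% variance cutoff flags those features (plus the
occasional noise feature — with 6 subjects the subject sum of squares has
only 5 degrees of freedom, so the time share of a null feature has a
heavy upper tail).

## The analysis workflow

Numbered drivers under `analysis/` run the whole study on synthetic data
and write every table under `results/`:

```sh
Rscript analysis/01_simulate.R             # cohort: sensors, sleep, 4 omics panels
Rscript analysis/02_sensor_summaries.R     # wake/sleep means, nocturnal dipping
Rscript analysis/03_cosinor.R              # cosinor fits, amplitude/phase coupling
Rscript analysis/04_variance_partition.R   # per-feature time vs subject shares
Rscript analysis/05_permutation.R          # exhaustive morning/evening tests
Rscript analysis/06_variance_correlation.R # cross-channel R2 matrices
```

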