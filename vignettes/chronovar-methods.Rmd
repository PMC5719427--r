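---
title: "Detecting time-of-day signals in a pilot chronobiome cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting time-of-day signals in a pilot chronobiome cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronovar)
library(dplyr)
```

## The problem

A chronobiome pilot asks whether time-of-day signals survive the noise of
free-living behavior when only a handful of subjects can be deeply
phenotyped. The design `chronovar` targets is 6 subjects studied over two
48-hour sessions: continuous sensing (triaxial actigraphy, ambulatory
blood pressure and heart rate, wrist light, phone communication, GPS
mobility, photographed meals) and biospecimens at 0, 12, 24, 36 and 48 h.
The 12-hourly grid means any 24-h rhythm in the omics is aliased to a
two-level **morning/evening** contrast: hours 0, 24 and 48 are morning,
12 and 36 evening. All four statistical stages are built around that
constraint.

## Variance partition and the 5% cutoff

For each feature we fit a main-effects two-way ANOVA on the crossed
subject × time design and report each factor's share of the total sum of
squares. Choices worth stating:

- **Decomposition.** The subject-by-time interaction is absorbed into the
  residual. With one observation per (subject, session, timepoint) cell
  there are no interaction replicates; main-effects shares plus a
  remainder are the finest decomposition the design supports.
- **Time factor.** Default is the 5-level within-session timepoint, with
  sessions pooled as replicates of the same level; a 2-level
  morning/evening option mirrors the permutation contrast. In the
  balanced (or proportional-frequency) design the two main effects are
  orthogonal, so the shares are order-invariant; genuinely unbalanced
  data trigger a sequential-SS warning carried into the output.
- **Scale.** Metabolome/proteome features are log10-transformed first
  (the shares are invariant to affine rescaling, so natural vs base-10
  log is immaterial, but the log itself matters); microbiome proportions
  are analyzed untransformed.
- **Classification.** A feature is "time-varying" when its time share
  reaches 5% of total variance. The complementary rule
  `pct_time > pct_subject` is emitted alongside, but headline counts use
  the cutoff. With 6 subjects the subject SS has 5 degrees of freedom,
  so a null feature's time share has a heavy upper tail (its expectation
  is a ratio, and small subject draws inflate it); flagged sets at this
  scale therefore include occasional noise features. That is a property
  of the design, not of the implementation — the calibration tests
  compare replicate-averaged sums of squares, which are unbiased, to the
  closed-form expectations.

## The exhaustive permutation test

The dataset-level statistic is
`T = Σ_features (morning mean − evening mean)²` after scaling every
feature to unit variance; zero-variance features are excluded and
reported. The null reference enumerates **all distinct reassignments of
epoch labels to within-session timepoints**, applying each relabeling to
all subjects simultaneously (the timepoint column is the permutation
unit, preserving within-subject pairing) and keeping the 3-morning /
2-evening counts per session. Since T depends only on the epoch
partition, arrangements equivalent under within-epoch exchange are
enumerated once: `choose(5,3) = 10` per session, 100 jointly for two
sessions. The p-value is the proportion of arrangements, identity
included, with `T ≥ T_observed`, so `p ≥ 1/100 = 0.01` and the p-grid is
`{k/100}`. A design with more than 10⁶ arrangements falls back to
Monte-Carlo sampling of the same arrangement space with a stated seed.
We deliberately report `min_achievable_p` with every result: with sparse
designs the floor, not the signal, often determines the printed p-value,
and three omics panels landing on exactly the same p is the signature of
a floored test. Ties are counted with a 10⁻¹² absolute tolerance so that
exact ties (e.g. a constant matrix, where every arrangement gives T = 0
and p = 1) are handled deterministically.

## Cosinor rhythmometry

`fit_cosinor()` fits `y(t) = M + A·cos(2π(t − φ)/τ)` by the standard
linear reparameterization; the acrophase comes from
`atan2(γ, β)/ω mod τ`, so `A ≥ 0` and `φ ∈ [0, τ)` by construction. The
period is **fixed at 24 h**: a 48-h recording cannot meaningfully
resolve period, so free-period fitting is out of scope. The
zero-amplitude test is the F-test of the two harmonic coefficients
jointly zero. Degenerate designs — timestamps congruent modulo τ/2,
which collapse the harmonic columns to rank 1 — are detected by singular
values and rejected; this is exactly why the 12-hourly omics grid gets a
permutation test rather than a cosinor.

Amplitude/phase coupling across channels uses one fit per subject per
24-h window, giving paired vectors across (subject, window) units.
Amplitudes are compared by squared Pearson correlation (reported as %,
as R²); phases live on a circle, so they are compared with the
Jammalamadaka–SenGupta circular–circular correlation coefficient and its
asymptotic normal test, implemented directly from the sine-moment
formulas. The mean circular offset between two channels' acrophases is
reported in hours. Bonferroni correction multiplies by the number of
channel pairs actually tested (pairs skipped for zero variance or too
few observations are excluded from the multiplier and flagged).

## Sensor summaries

Streams are binned on half-open intervals anchored at midnight (default
60 min — hourly matches the BP monitor cadence and smooths event
channels; the dipping analyses use the monitor's native 30 min). Means
for continuous channels, sums for event channels (totals are conserved);
empty bins are missing, never zero-filled. A bin is scored sleep when
its **midpoint** falls inside a self-reported sleep interval — boundary
bins are assigned whole to one side, which avoids double counting but
attenuates dip estimates slightly when sleep boundaries fall mid-bin.
Wake/sleep summaries are emitted both per-subject-then-averaged and
pooled across subjects, labelled, because the two averaging orders
differ in unbalanced recordings. Variance-correlation matrices regress
every channel pair over shared bins (square-root transform for
count/event channels, matching display conventions), report R² = squared
Pearson correlation once per unordered pair, Bonferroni-correct by the
number of pairs tested, and carry `log10(p)` alongside raw p-values
because month-long recordings drive them below double-precision
underflow. Per-subject matrices are always available: between-subject
differences in these couplings are themselves a finding.

## What the generator emulates

`generator_config()` defaults are the study conditions:

- **Design:** 6 subjects, two 48-h sessions two weeks apart, biospecimens
  at 0/12/24/36/48 h.
- **Sensors:** each channel is
  `M + A·cos(2π(t − φ)/24) + subject offset + N(0, σ)` at its own
  cadence (1 min actigraphy/light, 30 min BP/HR), clipped at zero for
  count channels. BP/HR channels carry their diurnality through a
  planted **sleep dip** subtracted during self-reported sleep
  (23:00–07:00 with per-subject jitter): MAP 19.4 mmHg, HR 16.5 bpm,
  typical nocturnal dipping in healthy young adults. Communication,
  mobility and meals emit events only during wake (18.7 events/h and 1.6
  miles/h wake rates; three meals/day). Accelerometer axes 2–3 derive
  from axis 1 plus noise, and the vector magnitude is their Euclidean
  norm, so inter-axis couplings are strong as they are for a physical
  device. Per-subject log-normal amplitude factors and shared acrophase
  jitter make amplitudes and phases correlate across channels within a
  subject.
- **Omics:** log-abundances are feature baseline + subject random
  intercept `N(0, σ_s²)` + epoch shift (±β/2 for a `⌈ρ·n⌉` rhythmic
  subset) + residual `N(0, σ_e²)`, exponentiated. Panel sizes mirror the
  reference platforms (166 plasma metabolites, 1141 serum proteins).
  σ_s = 1.0 > σ_e = 0.3 so inter-subject differences dominate, the
  defining feature of omics variance at this scale. The metabolome
  defaults (ρ = 0.054, β = 1.5) make the morning/evening signal
  detectable; the proteome defaults (ρ = 0.005, β = 0.3) keep it
  subject-dominated and usually off the permutation floor, matching the
  qualitative ordering in which the proteome is the one panel where
  time-of-day fails to reach significance. An epoch shift rather than a
  continuous cosinor is planted because the 12-h grid aliases any 24-h
  cosine to exactly that two-level contrast.
- **Microbiome:** 12 oral genera with a realistic abundance-ranked
  baseline; each sample is Dirichlet(κ·p) with κ = 200, where `log p`
  adds a per-subject composition offset (sd 0.8) and per-genus epoch
  log-fold effects (3 of 12 genera planted, echoing the streptococcal /
  veillonella / actinomyces finding at genus level). The subject offset
  is needed because compositional closure otherwise spreads the epoch
  effect across all genera and every genus ends up "time-varying";
  with it, the flagged set is the planted minority.
- **Determinism:** one root seed spawns per-module child seeds, so
  stages regenerate independently and identical (config, seed) gives
  byte-identical output. Ground truth (rhythmic feature identities,
  planted dips and cosinor parameters) is emitted alongside the data.

What the generator does **not** emulate: behavioral autocorrelation
beyond the diurnal cycle, missing wear-time, measurement drift,
feature–feature correlation within omics panels, session effects, and
compositional count depth (the Dirichlet is a continuous idealization of
relative abundances). Passing recovery tests therefore show the
estimators are correct under the planted model, not that real cohorts
are this clean.

## Numerical choices and problem sizes

Tolerances: microbiome compositions renormalize within 10⁻⁶ of 1
(sequencing-style rounding) and validate to 10⁻⁹ after; permutation tie
detection at 10⁻¹²; round-trip I/O is lossless to 10⁻¹²; log10 display
transforms use a configurable offset, default half the smallest positive
value. The test suite and the analysis scripts run the full design at
reduced sampling (10–30 min sensor cadence, panels of 8–200 features,
200–500 replicate calibrations), sizes chosen so the whole suite
completes in about a minute while keeping every Monte-Carlo comparison
inside its stated error bounds. The calibration checks compare
replicate-averaged sums of squares against the closed-form expectations
`E[SS_subject] = (n_s−1)(σ_e² + n_t r σ_s²)`,
`E[SS_time] = (n_t−1)σ_e² + n_s r Σ_t(μ_t−μ̄)²` (with
`Σ_t(μ_t−μ̄)² = (6/5)β²` for the 3/2 epoch split) and
`E[SS_resid] = (N−n_s−n_t+1)σ_e²`.

## Known limitations

- The 100-arrangement space cannot produce p-values below 0.01; finer
  claims need more timepoints or more sessions, not more features.
- The variance partition is a fixed-effects SS decomposition, not a
  mixed-model (REML) variance-component estimate; the two agree in
  expectation here but diverge for unbalanced designs. The decomposition
  sits behind `partition_variance()` and can be swapped.
- Amplitude/phase correlations pool sessions by default (each 24-h
  window is a unit); per-session analysis is a matter of filtering the
  fits table before correlating.
- Dipping estimates from midpoint-scored bins attenuate toward zero by
  up to ~5% when sleep boundaries fall mid-bin; use the monitor's native
  cadence for dipping work.
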