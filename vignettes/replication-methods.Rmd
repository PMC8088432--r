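---
title: "Methods: validating a frozen amygdala-connectivity predictor of CBT response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating a frozen amygdala-connectivity predictor of CBT response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amygconn)
```

## The model under test

The package validates a fixed-coefficient linear model predicting
pre-to-post-treatment change in social anxiety severity (ΔLSAS,
baseline − post, positive = improvement) from two terms:

\[
\widehat{\Delta\text{LSAS}} = 0.6194\,\text{LSAS}_\text{baseline}
  + 8.6290\,z(\operatorname{atanh}(\bar r)) - 9.9763,
\]

where \(\bar r\) is the composite amygdala connectivity: the seed's Pearson
correlation with one positively weighted cluster averaged with its three
negative-cluster correlations, Fisher-transformed, then z-scored across the
cohort. The coefficients are *frozen*: nothing on the fixed pathway is
re-estimated in new data. `fit_ols()` provides the separate, clearly
labeled flexible pathway that re-estimates the same terms.

Two conventions needed pinning down:

* **Sign handling.** A plain average of the four correlations would let
  *stronger* negative-cluster connectivity *lower* the composite, which
  contradicts the biomarker's reported direction (greater positive-cluster
  and reduced negative-cluster connectivity both predict response, and the
  composite carries a positive coefficient). The default
  `sign_convention = "flip_negative"` therefore averages
  \((r_{pos}, -r_{neg1}, -r_{neg2}, -r_{neg3})\); the raw average is
  available and logged wherever it is used. Because the exact arithmetic of
  the composite is not fully documented publicly, the 1-vs-3 weighting is
  also configurable (`two_group = TRUE` averages \(r_{pos}\) with the mean
  of the flipped negative correlations).
* **Averaging before transforming.** The composite is averaged on the
  correlation scale and then Fisher-transformed. Transforming each
  correlation first is statistically more standard and is available as
  `fisher_first = TRUE` for sensitivity analysis, but the default follows
  the composite's definition.

For external validation the package defaults to the *centered* variant:
the intercept is dropped and baseline, outcome and (by construction of the
z-score) the connectivity term are cohort mean-centered. Intercepts absorb
study-level shifts in symptom change that no connectivity biomarker should
be credited for or charged with. The outcome is centered as well so that
full- and compact-model residuals remain comparable; centered predictions
equal the demeaned uncentered predictions whenever the connectivity term is
mean-zero, which the test suite verifies to \(10^{-10}\).

## Scoring: two R²'s and a permutation null

The full model is scored **against the compact baseline-only model**, not
against zero:

* **Prediction R²** \(= 1 - \mathrm{MSE}_{full}/\mathrm{MSE}_{compact}\):
  an absolute, scale-respecting measure of error reduction. It can be
  negative — a frozen model with a miscalibrated connectivity coefficient
  can predict *worse* than the compact benchmark.
* **Model-based R²**: squared Pearson correlations between observations
  and each model's predictions, and their difference. Scale-free, hence
  more forgiving of coefficient miscalibration, and informative for that
  reason.

Significance uses a permutation null: only the connectivity term is
shuffled across subjects, keeping the baseline–outcome pairing (and thus
the compact model) fixed; the full model's predictions and the metric are
recomputed per shuffle. Shuffling already-z-scored values is equivalent to
re-z-scoring after each shuffle, since the z-score is permutation
invariant. Both the add-one p-value \((1+b)/(1+B)\) and the null's 95th
percentile are reported; `n_perms = 10000` by default. If a permutation
renders a metric undefined (degenerate variance), that draw is redrawn and
counted in `n_redrawn`; with a continuous connectivity term this is a
measure-zero event.

The Anderson–Darling composite-normality test (`nortest::ad.test`) checks
that the three model terms are approximately Gaussian; it is a diagnostic,
not a gate.

## Power and precision analytics

`correlation_power()` implements the two-tailed Fisher-z power
\(\Phi(\lambda - z_{1-\alpha/2}) + \Phi(-\lambda - z_{1-\alpha/2})\) with
\(\lambda = \operatorname{atanh}(\rho)\sqrt{n-3}\): at \(\rho = 0.3\),
\(n = 40\), power is 0.469 — cohorts of this size are underpowered for
medium effects. `r2_confidence_interval()` converts a Fisher-z interval for
\(r\) into percent variance explained; at \(r = 0.46\) (i.e.
\(\sqrt{0.21}\) rounded to two decimals, the rounding under which the
interval endpoints are reproducible) and \(N = 38\) the 95% interval runs
from 2.7% to 46.2% — an effect "known" to one significant figure at best.
If the \(r\)-interval straddles zero the lower bound on variance explained
is clamped to 0.

## The synthetic cohort generator

No patient data for this biomarker are deposited anywhere, so the package
ships a generator whose defaults emulate the targeted clinical cohort:
42 analyzed subjects (25 treated immediately, 17 post-waitlist), baseline
LSAS mean 82.0 (SD 17.9), post-treatment mean 51.3 (SD 24.2), baseline
explaining 20% of change-score variance, and a configurable incremental
connectivity fraction (2% by default, the replication-scale effect; 21%
reproduces the original-report effect).

Internals worth knowing:

* The change score is built as
  \(\Delta = \bar\Delta + a\,(b - \bar b) + c\,z_{conn} + \varepsilon\)
  with \(a, c\) set from the requested variance fractions. The change-score
  SD is not free: it is derived so the implied post-treatment SD matches
  the requested 24.2, giving SD(Δ) ≈ 26.2 and a baseline slope of ≈ 0.65 —
  reassuringly close to the slopes actually reported for such cohorts.
* **The instrument floor.** LSAS cannot go below 0, and with SD(Δ) ≈ 26 a
  Gaussian post score dips below zero for roughly 2% of subjects. By
  default (`floor_scores = TRUE`) post scores are clipped to [0, 144],
  which biases the realized baseline variance fraction upward by about
  0.01 at the default settings; `floor_scores = FALSE` gives the exact
  latent-scale planting. The suite tests exact (±0.01) recovery on the
  latent scale and ±0.02 recovery under the floor.
* The latent composite connectivity is Gaussian with SD 0.15, clipped to
  (−0.9, 0.9). The biomarker's real distribution is not published; the SD
  is exposed as `conn_sd` and its value matters only through the planted
  variance fraction, which standardizes it away.
* Interim LSAS measures interpolate linearly between baseline and the
  realized post score plus noise (SD 4 points); only the LOCF endpoint
  matters downstream. Dropouts get a truncated series *and* fewer than 12
  sessions, so they exit at the eligibility filter, mirroring how the
  analyzed-cohort counts arose.

## The scan simulator

`simulate_scan()` produces voxel × time matrices for the five neural ROIs,
WM and CSF, a 6-column motion table, and a global-signal trace. The five
neural regions follow a single-factor correlation structure: seed–cluster
correlations \((c, -c, -c, -c)\) (flip-negative convention) and
cluster–cluster correlations \(\rho_i\rho_j\), realized through a symmetric
matrix square root with an eigenvalue-clipping repair if a requested target
is indefinite (the single-factor structure itself is positive-definite for
\(|c| < 1\)). On clean long scans the empirical composite converges to the
planted value; with the default 9 voxels/ROI and voxel noise SD 0.5 the
attenuation from voxel-level noise is below 1% of the composite.

Nuisance is planted in three layers: slow sinusoids + linear trend shared
across compartments (WM/CSF load heavily; neural regions load with a
consistent positive sign, as scanner drift and slow physiology do — a
zero-mean loading would make the confound cancel on a large fraction of
scans and leave nothing for the denoiser to remove); motion spikes that
exceed the 0.5 mm flagging threshold; and a broadband common deflection at
spiked volumes, the scrubbing target. Intensity outliers are planted in
the global signal at the same rate. `drift_amplitude = 0, spike_rate = 0`
yields a nuisance-free scan.

What the simulator does **not** emulate: spatial structure (no voxel
grids, smoothing, or registration error), physiological cardiac/respiratory
cycles, scanner-specific autocorrelation, or distance-dependent motion
artifacts. Passing tests show the pipeline recovers planted structure under
these idealized conditions, not that it removes every artifact class in
real data.

## Denoising: numerical choices

* **FD** is the Power-style sum of absolute backward differences, rotations
  converted at a 50 mm radius (configurable); the first volume is 0 by
  convention and summaries run over volumes 2..T.
* **Spike flagging** is per-parameter by default (any translation, or any
  radius-converted rotation, jumping ≥ 0.5 mm flags the volume), the
  conservative artifact-detection reading; a composite-displacement variant
  is selectable. Intensity flagging uses the two-sided |z| ≥ 3 rule with
  the sample SD (ddof = 1).
* **Tissue components** are per-compartment (3 WM + 3 CSF) by default —
  "three components of WM and CSF" is ambiguous between per-compartment and
  pooled, so the pooled variant is a flag.
* **The filter is an ideal DFT band-pass** (bins outside (0.01, 0.10) Hz
  zeroed, no padding): exact frequency response, testable to machine
  precision, and an orthogonal projection, at the price of edge ringing
  that a practitioner would weigh against IIR alternatives.
* **Order and idempotence.** The pipeline regresses first and filters
  second, as the residual-then-filter description of the original analysis
  requires. By default the nuisance regressors are themselves band-limited
  before regression (`filter_design = TRUE`); filtering and projection then
  commute, the whole clean-up is a projection (running it twice changes
  nothing, which the suite verifies at \(10^{-6}\) relative norm), and
  frequencies the filter removed cannot be reintroduced by the regression —
  the standard argument for band-limiting confound regressors. With the
  flag off, plain regress-then-filter is applied.

## Problem sizes and determinism

Simulation-based checks use sizes chosen to make Monte-Carlo error small
relative to the tolerances they assert: variance-fraction recovery at
n = 10⁵ subjects (±0.01 latent, ±0.02 floored); composite planting over
60–100 scans of 4,000–10,000 volumes (±0.02 on the mean); permutation size
over 500 null cohorts × 999 permutations (rejection in [0.03, 0.07]);
effect recovery over 200 cohorts × 499 permutations (mean incremental
model-based R² within ±0.05 of the planted 0.21 — the frozen, deliberately
non-refit connectivity coefficient keeps the recovered mean a little below
the plant, ≈ 0.18, well inside that band); the exhaustive-permutation
oracle at n = 6 and 7. Every stochastic path takes an explicit integer
seed, and equal seeds give bit-identical results, including through the
CLI.

## Known limitations

* The frozen coefficients are accepted as given; the package cannot check
  them against the original fitting data.
* ROI time series are the unit of analysis; image-space preprocessing
  (realignment, normalization, smoothing) is out of scope, and motion
  parameters are consumed as provided.
* The generator plants linear-Gaussian effects; floor effects aside, it
  will not expose estimator behavior under heavy tails, outcome skew, or
  nonlinear baseline dependence.
* The permutation test inherits the frozen-model premise: it tests whether
  the *given* linear combination predicts better than chance pairings, not
  whether any connectivity model could.
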