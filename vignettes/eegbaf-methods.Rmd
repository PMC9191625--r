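---
title: "Single-channel EEG brain-activity features: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-channel EEG brain-activity features: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package computes

`eegbaf` analyses a single frontal EEG channel (Fp1–Fp2 difference, 500 Hz)
recorded while a participant performs an auditory detection battery with
three load levels: resting state (RS), a single-instrument detection level
(D1), and a selective detection level among three instruments (D2). The
analysis has four stages:

1. **Wavelet-packet feature extraction.** Each 2048-sample window (advanced
   by 500 samples, i.e. one second, so consecutive windows overlap by about
   75%) is decomposed over the full wavelet-packet binary tree generated by
   a quadrature-mirror filter pair $(h, g)$: node $(\ell, f)$ maps to
   children $(\ell{+}1, 2f)$ through $h$ and $(\ell{+}1, 2f{+}1)$ through
   $g$, by convolution–decimation with circular boundaries. With orthonormal
   filters every level conserves energy exactly, and reconstruction from any
   disjoint node cover is exact to floating-point precision. A fixed library
   of 121 "brain activity features" (BAFs) is frozen beforehand from a
   baseline corpus: per-window best bases (Coifman–Wickerhauser bottom-up
   dynamic program under an additive cost, Shannon entropy by default) are
   pooled, every candidate node is scored by selection frequency times mean
   retained energy after hard-threshold denoising, and the 121 top-scoring
   nodes are kept (ties broken toward lower level, then lower frequency
   index). A BAF activation is a node-level energy — summed over all
   translations inside the node — which makes the per-second activation
   insensitive to where a transient falls within the window.
2. **Band powers.** A Hann-tapered one-sided periodogram per window, scaled
   so the bin sum equals the taper-corrected variance, summed over half-open
   bands (Delta 0.5–4, Theta 4–7, Alpha 8–15, Beta 16–31, lower Gamma
   32–45 Hz) and expressed as $10\log_{10}$ dB with a $-300$ dB floor.
3. **Linear features.** Higher-level features are linear functionals
   $V(w, x) = \Psi(\sum_i w_i x_i)$ over the 121 activations, with $\Psi$
   the identity (default) or a logistic. Two are Fisher discriminants
   (ridge-regularized pooled within-class covariance, unit-norm weights,
   class 1 scoring higher): a load feature trained on D1-vs-D2 windows
   ("VC9-like") and a rest-vs-task feature ("A0-like"). One is a principal
   component of an independent n-back-style training corpus ("ST4-like");
   see *The principal-component feature* below. Each applied series is
   scaled per recording to 0–100 by a robust min–max (1st percentile to 0,
   99th to 100, clipped; constants map to 50).
4. **Statistics.** Pearson and age-partialled correlations with Fisher-z
   intervals, Meng-style z-tests for overlapping dependent correlations, BCa
   bootstrap tests of (partial − unadjusted) correlation, Welch t-tests,
   linear mixed models with random task slopes selected by a
   likelihood-ratio ladder, and Tukey / Bonferroni / Benjamini–Hochberg
   post-hoc machinery, assembled into eight table-shaped outputs by
   `run_assessment_pipeline()`.

# Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `fs` | 500 | Hz | device sampling rate |
| `n_win` | 2048 | samples | power of 2 spanning the nominal 4-s window at 500 Hz (4.096 s) |
| `hop` | 500 | samples | 1-s feature cadence; 75% nominal overlap |
| `filter` | `db4` | — | 4-tap Daubechies; Haar available for hand-checkable tests |
| `depth` | 7 | levels | 254 candidate nodes ≥ 121 atoms |
| `n_atoms` | 121 | — | library size |
| `cost` | Shannon entropy | — | classical additive best-basis cost |
| `threshold_rule` (features) | `fixed`, τ = 0 | — | see *Denoising vs the feature layer* |
| `artifact_k` | 8 | MADs | robust flag threshold; ~5σ-equivalent under Gaussian noise |
| `hf_cutoff_hz` | 45 | Hz | atoms peaking above this count as muscle-band |
| `alpha` | 0.05 | — | study-wide significance level |
| `k_boot` | 1000 | replicates | BCa bootstrap sample count |

# The synthetic cohort generator

No recordings are distributed with the package; every downstream stage is
exercised on a generator that emulates the study population and the
*directions* of its reported effects. The cohort is 17/16/17 seniors in
MMSE groups split at the 24/27 cutoffs (ages 79.26 (8.57), 75.42 (7.36),
74.77 (8.05) years) plus 22 young controls (24.09 (2.79)); MMSE scores are
uniform integers within each group's range.

A recording is 1/f background noise (exponent 1, 10 µV SD) plus
amplitude-modulated Delta/Theta/Alpha oscillators and three planted
band-limited tracks aligned with designated library atoms:

* **Load effects, young profile only.** Theta (and, at half strength,
  Delta) oscillator amplitudes and the "VC9-like" track scale by
  +30% per task level for young profiles; the senior load gain is 0. The
  "A0-like" track has a flat task-on response (equal in D1 and D2) so that
  only the Theta/VC9 bands separate the two detection levels.
* **MMSE-linked patterns as burst duty cycles.** The "ST4-like" and
  "A0-like" tracks also occur as ~3-s bursts whose duty cycle grows
  linearly with MMSE (5%→30% across MMSE 17–30) and with 30 − MMSE
  respectively, independent of the task. Because the 0–100 scaling is
  per-recording min–max, a constant between-participant amplitude offset
  would be normalized away; a duty cycle moves the scaled *mean* without
  moving the scaled *range*, so the MMSE association survives scaling while
  planting no senior task effect — which is exactly the study's pattern
  (task modulation confined to the young group).
* **Behavior.** Per target, a hit occurs with probability decreasing in
  (30 − MMSE); RTs are log-normal with median increasing linearly in
  (30 − MMSE) and participant-level dispersion calibrated once so the
  cohort correlation between mean RT and MMSE is ≈ −0.55. Young profiles
  count as MMSE 30.
* **Artifacts.** 1-s EMG bursts (80–120 Hz band noise at 100 µV) at 0.5
  bursts/minute.

Effect magnitudes are free parameters fixed once so that the statistical
stages reach roughly 0.8 power at the study's group sizes; they are not
estimates of physiological amplitudes. What passing tests show is that the
*pipeline recovers what was planted* — they cannot certify behavior on real
EEG, which has nonstationarities, alpha-peak individuality, volume
conduction, and artifact structure the generator does not attempt.

# Design choices

**Window length.** The window is 2048 samples (4.096 s), taking the
power-of-2 requirement literally and treating "4 s" as nominal; the
overlap is likewise nominally 75% (exactly 1 − 500/2048 = 75.6%).

**Denoising vs the feature layer.** Universal hard thresholding
(τ = σ̂·√(2 ln N), σ̂ = MAD/0.6745 from the finest-scale high-pass block)
is implemented and exposed, and drives the library ranking. For the
*feature path*, however, the default is τ = 0: at realistic SNR the
universal threshold zeroes most node coefficients, making activations
nearly binary (zero vs. just-above-threshold), which destroys the
covariance structure the linear feature layer relies on. Continuous
energies keep the layer well conditioned; thresholded extraction remains
one config switch away.

**dB-scaled activations.** The feature layer sees activations as
$10\log_{10}(E + 1)$ rather than raw energies. Raw node energies are
heavy-tailed (approximately scaled chi-square), and both LDA (through its
pooled covariance) and PCA are unstable under such tails; the log transform
makes multiplicative gain factors additive and near-Gaussian. The `+1`
(µV²) offset pins an empty node at 0 dB.

**The principal-component feature.** In the study, the difficulty-
separating component of the training dataset happened to be the fourth.
Which index that component occupies depends on the variance ranking of the
training corpus's nuisance factors, which is not stable across random
corpora at feasible training sizes. The pipeline therefore *identifies* the
difficulty component among the leading eight by correlating component
scores with the training block labels (`identify_difficulty_component()`),
mirroring how such a component is found in practice;
`train_pca_feature()` itself keeps the fixed-index interface (default 4)
and is validated against a spectral oracle with known eigenvectors.

**Model-selection ladder.** Four fits — additive and interaction fixed
effects, each with random intercept or correlated random intercept + task
slope — all by maximum likelihood so deviance differences between fixed
structures are valid likelihood-ratio tests. The comparison table reports
each row against the previous one, as such tables are conventionally
printed, although the intercept-interaction → slope-additive rows are not
nested (no test is reported there). The slope is accepted if it improves
the additive model; the interaction decision is then re-taken on the slope
models. Fixed-effect t-tests use Satterthwaite degrees of freedom
(`lmerTest`), consistent with fractional dfs in this literature.

**Battery timing.** D1 is exactly three 90-s trials; melodies are placed
sequentially after a 5-s lead-in with inter-melody silences drawn uniformly
(10–18 s in D1, 8–14 s in D2), with rejection sampling to keep a trial
inside its slot. D2 trials are appended until the battery reaches at least
17 minutes, keeping the total at 18 ± 1 min by construction. The resting
block is modeled as one 120-s block placed first; the response window is
the melody duration + 2 s (silence minima of 8 s make this unambiguous);
on double clicks the first counts and the rest are ignored.

**EDF I/O.** Recordings are stored as minimal single-channel EDF (16-bit,
one record per second, physical range ±25 mV), written and read by the
package itself; quantization is ~0.76 µV per step, negligible against the
10 µV noise floor.

**Dependent-correlation test.** The overlapping-correlations z (both
correlations share the MMSE variable) on Fisher-transformed values, with
the median correlation between the non-shared variables entering the
dependence correction; the CI of the difference uses the paired-z
construction on the Fisher scale, mapped back by `tanh`.

**BCa details.** Case resampling with per-seed determinism; bias
correction ẑ₀ from the fraction of replicates below the point estimate
(clamped to (1/2k, 1 − 1/2k)); jackknife acceleration; a replicate with a
constant resampled column is redrawn, capped at 10 redraws. Partial
correlations inside the bootstrap use the three-correlation identity
rather than repeated regressions, for speed.

# Numerical conventions and degenerate inputs

* Time is 0-based seconds from the first sample; intervals are half-open,
  so band edges and event boundaries are counted exactly once (4 Hz belongs
  to Theta).
* Energy conservation is asserted to 1e-10, atom orthonormality to 1e-8,
  reconstruction to 1e-9 relative.
* Zero-power bands floor at −300 dB; constant feature series scale to 50;
  correlations at |r| = 1 are clamped before `atanh`.
* Constant inputs to correlation routines, single-class LDA input,
  rank-deficient PCA requests, recordings shorter than one window, and
  schedules without targets all raise immediate errors rather than
  propagating NaNs.
* Singular or non-convergent mixed-model fits are flagged on the fit object
  and warned about, never silently dropped.

# Problem sizes used by the test suite

The suite validates the transform algebra on 16–2048-sample frames (the
exhaustive best-basis oracle enumerates all 26 prunings of depth-3 trees),
parameter recovery on 500–2000-row feature matrices, bootstrap size on 200
null datasets of n = 60 with k = 200 replicates, mixed-model coverage on
100 replicates of 60 participants × 3 tasks × 5 repeats, and the full
synthetic study at the study's own sizes (72 participants, 18-minute
batteries). Library construction for unit tests uses a 3-minute baseline
corpus; the study-scale default is 12 minutes.

# Known limitations

* The library ranking rule (frequency × retained energy) is a documented
  stand-in; the original device's exact pruning statistics are not public.
* Whether published activations are energies, magnitudes, or signed
  projections is not stated; energies are the default here, with signed
  single-coefficient projections available behind the config.
* The generator plants effect *directions* with convenient magnitudes; it
  is not a biophysical EEG model, and absolute dB levels or effect sizes
  should not be compared against clinical recordings.
* Age-group confounding is emulated only through group membership; the
  partial-correlation stage therefore mostly demonstrates invariance, as in
  the study's own reported results.
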