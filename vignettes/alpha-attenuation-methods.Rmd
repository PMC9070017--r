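---
title: "Methods: target-related alpha attenuation in RSVP calibrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: target-related alpha attenuation in RSVP calibrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

RSVP (rapid serial visual presentation) spellers flash letters at
fixation while a user silently watches for a cued target; the decoder
must tell target from non-target epochs from the EEG alone.  Besides the
classic N200/P300 evoked complex, detecting a target transiently
suppresses the posterior alpha rhythm (8–13 Hz) — event-related
desynchronization (ERD) — roughly 300–800 ms after stimulus onset.  This
package implements the full analysis chain that quantifies that alpha
attenuation in calibration data and asks whether it can support
classification, and it pairs the chain with a synthetic EEG generator so
every stage is testable without human recordings.

A calibration block is 100 trials of 10-letter sequences at a 1 Hz or
4 Hz presentation rate (1 s target prompt, 500 ms fixation cross,
10 stimuli, 750 ms blank gap), giving exactly 100 target and 900
non-target stimulus epochs — a fixed 9:1 class imbalance.  Seven dry
electrodes (FCz, F7, Pz, P4, PO7, PO8, Oz) are sampled at 300 Hz.

## The measurement chain

1. **Filtering** — zero-phase Butterworth band-pass 1–45 Hz realized as
   cascaded order-8 high- and low-pass biquad sections (48 dB/octave
   design slope per edge) plus a 60 Hz notch (Q = 30).  The order-8
   edges are applied as second-order sections because a direct
   transfer-function realization of an order-8 edge at 1 Hz/300 Hz is
   numerically fragile.  Filters apply to the continuous record only, so
   filtering and epoching commute by construction.
2. **Downsampling** 300 → 150 Hz by decimation (safe after the 45 Hz
   low-pass); event indices are rescaled and rounded to the nearest
   sample.
3. **Pooling** — a virtual `POOL` channel, the samplewise mean of Pz,
   Oz, PO7, PO8; analyses run in parallel on `POOL` and Pz.
4. **Epoching** — 2.5 s epochs (−1250..+1250 ms) for time-frequency
   work, −200..+800 ms for ERPs.  All sample windows in the package are
   half-open `[start, end)` with stimulus onset at the t = 0 sample;
   this is the single time convention used everywhere.
5. **Spectrum and IAF** — per-epoch FFT amplitudes with a Tukey taper
   covering 20% of the epoch (10% per edge), variance-loss compensation
   (division by the taper RMS), epoch-averaged, and normalized so the
   4–20 Hz amplitudes sum to one (a max-to-one variant is selectable).
   The individual alpha frequency (IAF) is the most prominent local
   maximum in 7.5–12.5 Hz after masking ±0.25 Hz around the first three
   SSVEP harmonics of the presentation rate, with a prominence threshold
   of 5% of peak height, rounded to the nearest 0.5 Hz; when nothing
   qualifies the estimate falls back to 10 Hz.  The mask radius and the
   prominence rule are this package's deterministic replacement for
   manual peak review; at the full calibration size (1000 epochs) the
   averaged noise floor is smooth enough that a 1/f spectrum without
   alpha reliably triggers the fallback.
6. **Scaleogram** — complex Morlet CWT (parameter c = 5, i.e. spectral
   bandwidth f/5) at 48 log-spaced center frequencies spanning 4–16 Hz
   (`f_k = 4·4^((k−1)/47)`), wavelets truncated at ±4σ and normalized to
   unit energy.  The magnitude output is additionally calibrated per
   layer so a unit-amplitude tone at the layer's center frequency yields
   magnitude 1.  This units convention matters: raw unit-energy
   responses scale with √σ, which systematically tips the cross-layer
   argmax one layer low on a dense log grid; with the voltage
   calibration the peak layer identifies a tone's frequency exactly (a
   property the test suite checks for all 48 layers).  Z-scoring and
   envelope ratios are invariant to per-layer scaling, so downstream
   attenuation measures are unaffected by the choice.  Complex output is
   reduced to magnitude by default ("real part" is selectable).
7. **Z-transform** — every (epoch, channel, layer) series is
   standardized by the mean and SD of its own −600..−100 ms baseline;
   epochs with zero baseline SD are excluded as degenerate and logged.
   Baselines are per-epoch, not pooled, so each epoch's response is read
   against its own immediate history.
8. **Alpha activity and attenuation** — per-epoch mean Z in 300–800 ms
   at the single layer nearest the IAF (ties toward the lower
   frequency); class medians; the attenuation effect is the target
   median minus the non-target median (negative = target-related
   desynchronization), tested by a two-sided Mann-Whitney U.
9. **ERPs** — baseline-corrected (−200..0 ms) class averages; N200 =
   voltage minimum in 200–350 ms and P300 = maximum in 300–450 ms on the
   target average (ties to the earliest latency; fully automatic, no
   manual adjustment path); amplitudes are the 9-sample (~53 ms) mean
   around the target-derived latencies for both classes; target effect =
   target − non-target.
10. **Artifact rules** — gradients > 50 uV/ms, range > 125 uV within
    50 ms, |V| > 75 uV, or range < 0.5 uV sustained ≥ 100 ms; any
    channel, any rule flags the epoch.  Windows slide one sample and are
    rounded to whole samples.  Rejection is off by default, mirroring
    the primary analyses, and is enabled by a flag.
11. **Statistics** — Wilcoxon signed rank (paired medians; exact p up to
    25 untied nonzero differences, normal approximation with continuity
    correction otherwise), Mann-Whitney U (midranks, tie-corrected
    variance), Spearman rho (t approximation), Shapiro-Wilk.  These wrap
    the standard R implementations; no multiplicity correction is
    applied, matching the reporting convention of the analysis this
    package follows, and raw p values are reported.

## Classifiers

Alpha features keep the IAF-layer Z time series (not its window mean)
over the response window, concatenated across the four occipitoparietal
channels (500 ms at 150 Hz → 4 × 75 = 300 features).  Models:

* `logreg_l2` — ridge logistic regression (glmnet, λ = 1/n_train,
  equivalent to a unit-C L2 objective), class-weighted.
* `svc` — RBF support vector classifier, cost 1, class-weighted,
  per-feature standardization (without commensurate feature scales the
  RBF kernel collapses to the majority class).
* `tangent_space` — per-epoch 4×4 channel covariances over the response
  window, mapped to the tangent space at their affine-invariant
  geometric mean (upper-triangle vectorization, off-diagonals ×√2), then
  class-weighted ridge logistic regression.  Near-singular covariances
  receive automatic identity shrinkage, logged.
* `uniform_random` — seeded coin flip ignoring the features; the chance
  control.
* `rda_kde` — the ERP reference: 0..+500 ms epochs (2–45 Hz filtered,
  all 7 channels) → PCA retaining 95% variance → regularized
  discriminant analysis (class covariances shrunk toward the pooled
  covariance, λ = 0.9, then toward scaled identity, γ = 0.1) → Gaussian
  KDE (Silverman bandwidth) of the class-conditional discriminant
  scores, classified by log-density ratio at 0.

Everything is scored by balanced accuracy, the mean of per-class
recalls, over repeated stratified 80/20 train/test splits (10
repetitions by default; the split protocol is a package choice, as the
source analysis does not state one).  Window tuning varies the 500 ms
baseline start over −1050..−600 ms and the response start over
+150..+550 ms (50 ms grid by default, 10 × 9 points), re-deriving
Z-scores and features per grid point and scoring the logistic-regression
criterion model; ties resolve to the default pair (−600, +300).
`tune_windows()` scores whatever epochs it is given: pass training data
only for leakage-free (nested) tuning — the recommended use — or all
epochs to reproduce the literal non-nested procedure.

## The synthetic generator

`synthesize_recording()` renders a schedule into 7-channel voltage with:
1/f background noise (RMS 4 uV, exponent 1); an alpha oscillation at the
configured IAF (10 Hz, 10 uV) with a smooth random envelope (fractional
modulation 0.3) and posterior-dominant channel gains, whose envelope is
multiplied by (1 − d) inside 300–800 ms after each target with 50 ms
raised-cosine ramps (reference depth d = 0.5); Gaussian N200 (−5 uV,
250 ms, posterior) and P300 (+8 uV, 375 ms, Pz-dominant) templates with
σ = 25 ms on targets only (the centers of the detection windows);
SSVEP at the presentation rate plus 2nd/3rd harmonics (3 uV, relative
0.6/0.4), phase-locked to stimulus onsets and active only during letter
sequences; and optional 400 ms biphasic frontal blink transients
(150 uV).  Everything is deterministic given the seed.  Blinks are off
in the reference scenario so artifact content is controlled explicitly
(via `blink_rate` or `inject_artifacts()`, which also returns the
ground-truth list of contaminated epochs).

What the generator does and does not emulate: it reproduces the spectral
skeleton (alpha peak, SSVEP lines, 1/f floor), the latency structure of
the ERD and ERP effects, and the exact task bookkeeping; it does not
reproduce the non-stationarity, alpha bursting, or cross-trial
variability of real EEG, so synthetic effect sizes are larger and
cleaner than empirical ones (z-scored attenuation magnitudes of several
units rather than tenths, and near-ceiling ERP classification at the
reference noise level).  Passing tests therefore demonstrate
correctness of the measurement chain and qualitative orderings —
attenuation present and negative, weaker at 4 Hz than at 1 Hz (where
the baseline of each epoch sits inside the flickering sequence and
SSVEP harmonics sit beside the alpha layer), ERP classifier at or above
the alpha models above chance — not empirical effect sizes.

## Numerical choices and degenerate inputs

* Epoch windows half-open; window lengths rounded to whole samples.
* Band edges must satisfy 0 < low < high < fs/2; resampling only
  downward; pooling requires all subset channels present.
* Z-transform: zero baseline SD ⇒ epoch excluded (logged), never NaN.
* IAF: grid must cover 7.5–12.5 Hz; fallback is 10 Hz exactly.
* Layer selection ties break toward the lower frequency.
* Geometric mean of SPD matrices: fixed-point iteration, Frobenius
  tolerance 1e-8, max 50 iterations.
* RDA/KDE: zero-variance input or fewer than two informative principal
  components is an error; KDE densities are floored at 1e-300 before
  logs.
* The 250 ms ends of each 2.5 s epoch serve as wavelet edge buffers and
  are never measured by any default window.

## Problem sizes in the test suite

The suite exercises the full 100-trial bookkeeping exactly but runs the
simulation-heavy property checks at reduced calibration lengths chosen
once for desk-scale runtimes: 20–40 trials per simulated calibration
(200–400 epochs), 20 seeded runs for the d = 0.5 power check, 40 runs
for the d = 0 false-positive check, and 1000-epoch label structures
wherever the 9:1 imbalance itself is under test.  At these sizes the
reference effect is overwhelming (Mann-Whitney p ≈ 1e-8 at 30 trials),
so the reduced lengths do not weaken the checks.  The acceptance script
runs full 100-trial calibrations.

## Known limitations

* The alpha rhythm is a single amplitude-modulated oscillator per
  recording, coherent across channels up to gain; real posterior alpha
  has richer spatial structure, so pooled-vs-Pz contrasts are milder
  here than in real data.
* The classifier-side wavelet parameterization used by the original
  Python pipeline (bandwidth 1.5 Hz, center frequency 1.0, unnormalized
  scales) differs from the c = 5 convention; which numerics the original
  produced cannot be resolved from the text, so this package uses the
  c = 5 scaleogram for features and treats the alternative as out of
  scope.
* Participant-level empirical effect sizes cannot be reproduced without
  real recordings; the package targets task bookkeeping, signal physics,
  and qualitative orderings instead.
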