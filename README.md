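# rsvpalpha

Quantifying target-related posterior **alpha attenuation** in RSVP
(rapid serial visual presentation) brain-computer-interface
calibrations — and testing whether it can classify targets — on fully
synthetic, seedable EEG.

## Who this is for

BCI researchers who want a tested, reproducible implementation of the
alpha-ERD calibration analysis: stimulus scheduling, synthetic
multichannel EEG with controllable physiology and artifacts, the
filtering/epoching chain, individual alpha frequency (IAF) estimation,
Morlet scaleograms with baseline Z-scoring, N200/P300 target effects,
threshold-based artifact flagging, a nonparametric test battery, and
balanced-accuracy classifier comparisons under the paradigm's fixed 9:1
class imbalance.

## The core quantities

A calibration presents 100 ten-letter sequences at 1 or 4 Hz; each
sequence contains exactly one cued target (100 target / 900 non-target
epochs).  For each stimulus epoch the pipeline computes the mean
Z-scored magnitude of the wavelet layer nearest the participant's IAF
within a response window:

* **alpha activity** `z̄ = mean{ z(t) : t ∈ [300, 800) ms }` at the IAF
  layer, with `z(t) = (|W x|(t) − μ_b)/σ_b` standardized by the epoch's
  own −600..−100 ms baseline;
* **alpha attenuation effect** `Δ = median(z̄ | target) −
  median(z̄ | non-target)` — negative values mean target-related
  desynchronization — tested by a two-sided Mann-Whitney U;
* **balanced accuracy** `acc_bal = (acc_target + acc_non-target)/2` for
  classifiers trained on the IAF-layer time series (logistic ridge,
  RBF-SVC, Riemannian tangent space, a uniform-random control) and for
  the RDA/KDE ERP reference pipeline.

## Worked example

```r
library(rsvpalpha)

cfg <- default_config(
  schedule = list(rate_hz = 1, n_trials = 30, seq_len = 10),
  classify = list(run = TRUE, models = c("logreg_l2", "uniform_random"),
                  rda_kde = TRUE, cv = list(n_reps = 5, test_frac = 0.2),
                  tune = FALSE, grid_step_ms = 50))
report <- run_pipeline(cfg)
#> simulating 30 trials at 1 Hz
#> filtering 1-45 Hz + 60 Hz notch, resampling to 150 Hz
#> IAF: 10.0 Hz (detected)
#> POOL attenuation -5.902 (p = 6.8e-09)
#> Pz attenuation -4.037 (p = 3.64e-08)
#> logreg_l2: 0.906
#> uniform_random: 0.428
#> rda_kde: 1.000
```

Reading the output: the simulated participant's alpha peak is recovered
at 10.0 Hz; target epochs show strongly negative Z-scored alpha in the
300–800 ms response window relative to non-targets (the attenuation
effect, here −5.9 on the pooled occipitoparietal signal — synthetic
effects are cleaner than empirical ones), and the Mann-Whitney test
rejects equality.  The ridge classifier separates targets from
non-targets well above the chance-level control, and the ERP-based
RDA/KDE reference performs best — the expected ordering.
`run_pipeline(cfg, out_dir = "results/run1")` additionally writes the
spectrum, IAF, per-epoch alpha, attenuation, ERP summary, classifier
results and a run manifest as CSV/JSON.

The numbered scripts under `analysis/` walk the full study flow on a
12-participant synthetic cohort: `01_simulate.R` (reference EDF +
events), `02_spectra_iaf.R`, `03_alpha_attenuation.R` (within- and
across-participant tests), `04_erp.R` (target effects and alpha-ERP
correlations), `05_artifact.R`, `06_classify.R` (model comparison and
window tuning).  Run them from the repository root, in order:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_spectra_iaf.R
# ...
```

Tables land under `results/`, bulky raw EDFs under `scratch/`.

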