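---
title: "Methods: EOG gaze estimation, validation, and the surrogate null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EOG gaze estimation, validation, and the surrogate null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 3.5)
library(gazeog)
```

## The measurement problem

Electro-oculography (EOG) estimates gaze direction from the standing
corneo-retinal potential, picked up by skin electrodes around the
eyes. Unlike camera-based eye tracking it works with the eyes closed
and in darkness, but the raw signal is contaminated by electrode
drift, broadband noise, and blink artifacts, and it carries no
absolute calibration.

The paradigm this package models calibrates gaze proprioceptively:
the participant fixates, in a fixed order, a set of physical markers
they have explored by touch, without any visual target being needed.
Each trial is an instructed piecewise-constant gaze trajectory — an
initial center fixation followed by a sequence of marker fixations of
equal duration. Validation is two-fold:

1. **Convergent validity** (eyes open): the conditioned EOG signal is
   compared against a simultaneously recorded camera eye tracker via
   cosine similarity of grand averages, an equivalence test battery,
   and cross-correlation lag analysis.
2. **Absolute validity** (eyes closed, where no camera works): the
   conditioned EOG signal is compared against the *instructed*
   trajectory, with chance level estimated by a surrogate null in
   which the order of the fixation targets is randomly shuffled.

## The instructed trajectory

`default_pattern()` defines ten markers on the normalized
$[-1, 1]^2$ plane — the eight perimeter points of a 3×3 grid, the
center, and one interior point — visited in an 11-fixation sequence
(the upper-left marker opens and closes the sequence). With 2 s
fixations and a 2 s initial center phase, a trial lasts 24 s; at the
30 Hz analysis rate that is 720 samples per axis.

```{r trajectory}
p <- default_pattern()
p
tr <- build_trajectory(p, 30)
tr
autoplot(tr)
```

Segments use half-open sample intervals, so no sample belongs to two
fixations, and the sample count is exact at every rate
(`round(duration * fs)`).

## The synthetic cohort generator

Real recordings are not distributed with the package; instead a
generator produces trials whose artifact structure matches what the
conditioning chain is designed to remove. Defaults reproduce the
study design: 11 participants in a 2×2 within-subjects design
(lighting on/off × eyes open/closed), 10 trials per cell, with one
participant completing only the lights-off condition — leaving 210
eyes-open trials in the grand-average pool.

Per channel the model is: first-order-smoothed instructed trajectory
(saccadic step response, time constant 20 ms), plus random-walk
electrode drift and white noise; the vertical EOG channel
additionally receives biphasic blink transients at Poisson times, and
the eye-tracker channels receive sparse single-sample spike outliers
and a fixed modality lag (50 ms horizontal, 200 ms vertical; the EOG
leads). Eyes-closed trials have no tracker channels and inflated
noise.

```{r generator}
spec <- cohort_spec()
coh <- simulate_cohort(cohort_spec(n_participants = 2,
                                   trials_per_cell = 1,
                                   incomplete = list(),
                                   fs_eog_hz = 64, fs_et_hz = 64))
coh
```

Every trial draws from its own child seed derived from the master
seed, so any single trial can be regenerated without replaying the
whole cohort.

Two generator defaults deserve a note:

* **Blink duration 0.4 s.** The conditioning chain runs a 200 ms
  median filter *before* blink detection. A 200 ms biphasic transient
  has 100 ms lobes and is almost annihilated by that filter, which
  would make any detector operating downstream untestable; 0.4 s is
  within the physiological range of eyelid artifacts and survives the
  filter with its shape intact.
* **Eye-tracker rate 200 Hz** (a common gaze-sample rate for wearable
  trackers). The Hampel filter below uses a 100 ms window; the
  false-alarm probability of its 3-sigma rule is the tail of a
  t distribution with (window − 2) degrees of freedom, which at
  100 Hz (11-sample window) is 1.5% and only drops below the 1%
  design point for windows of about 15 samples or more. Analyses are
  still performed at the 30 Hz comparison rate.

## The conditioning chains

EOG, per channel (`preprocess_eog_signal()`):

| stage | parameter defaults | purpose |
|---|---|---|
| linear detrend | — | remove electrode drift trend |
| median filter | 200 ms window | suppress impulsive noise, keep edges |
| blink removal (vertical only) | Haar scale 20 @ 512 Hz, peak gap 0.5 s, pad 5 | excise blink transients |
| z-score | — | remove gain/offset (EOG is uncalibrated) |

Eye tracker, per channel (`preprocess_et_signal()`):

| stage | parameter defaults | purpose |
|---|---|---|
| Hampel filter | 100 ms window, 3 sigma | replace tracking-loss spikes |
| median filter | 100 ms window | residual impulse noise |
| z-score | — | common units with EOG |

Implementation conventions worth knowing:

* **Haar wavelet.** `haar_cwt()` correlates with a negative-then-
  positive Haar of total width `2 * scale` samples, normalized by
  `scale^(-1/2)`, zero-padded at the borders. A rising edge gives a
  positive coefficient peak; a positive biphasic blink therefore
  yields the signature positive-then-negative peak pair.
* **Blink detection threshold.** Peaks must exceed mean ± SD of the
  whole-trial coefficient sequence. One SD is deliberately permissive
  and presumes the coefficient statistics are dominated by saccades
  and blinks, as in a real trial; on a featureless noise-only signal
  some peaks always exceed one SD, so specificity claims are only
  meaningful in the trajectory-present regime.
* **Interpolation span.** The positive/negative coefficient peak pair
  marks a biphasic artifact's leading edge and central transition;
  the artifact extends about one inter-peak interval further. The
  span interpolated by `remove_blinks()` therefore runs from the
  positive peak to one inter-peak interval past the negative peak
  (plus `pad` samples each side). This also swallows the trailing
  recovery edge, whose own positive peak would otherwise pair
  spuriously with a later saccade.
* **Hampel dispersion.** The dispersion is the SD of the window
  *around the window median with the center sample excluded*. An
  included center sample masks its own detection: a lone spike of 100
  in a flat window inflates the SD enough that `|x - median|` never
  exceeds three of them. With leave-one-out SD the textbook example
  (lone spike, 7-sample window, 3 sigma) is caught. A scaled-MAD
  option is available.
* **Detrend asymmetry.** Only the EOG chain detrends. The instructed
  trajectory has a nonzero net slope, so even noiseless
  cross-modality cosines saturate near 0.97–0.99 rather than at 1,
  and a noise-free paired MAE against the un-detrended instructed
  target is ~0.1–0.2 z-units rather than 0. Tests and expectations
  account for this.

```{r chain}
trial <- simulate_eog_trial(build_trajectory(p, 512), noise_model(),
                            seed = 5)
v <- median_filter(linear_detrend(trial$v), 200)
detect_blinks(v, scale = 20)
```

## Similarity, lag, equivalence

For every participant the eyes-open trials are grand-averaged per
modality, resampled to 30 Hz, and compared:

* `modality_similarity_table()` — cosine similarity per lighting
  condition and axis.
* `modality_lag_table()` — full normalized cross-correlation, pooled
  over lighting. The coefficient curve is min-max rescaled to
  $[0, 1]$ and the lag axis mapped affinely to $[0, 1]$, so a peak at
  0.5 means temporal alignment; `peak_lag_s` is positive when the
  first signal (EOG) leads.
* `modality_equivalence_table()` — a Shapiro-gated paired test
  (paired t when the differences pass normality, Wilcoxon signed-rank
  otherwise) with Bonferroni correction, next to a TOST equivalence
  test whose smallest effect size of interest is standardized:
  `bound = sesoi_d * sd(diff)` with `sesoi_d = 0.1`, and a 90%
  confidence interval (`conf = 0.95` per one-sided test).

Post hoc power for the paired design comes from the noncentral
t distribution:

```{r power}
posthoc_power_paired(c(4.58, 1.85), n = 11, alpha = 0.05)
```

## The surrogate null

Eyes-closed trials have no reference tracker, so accuracy is scored
as MAE between the z-scored EOG and the z-scored instructed
trajectory at 30 Hz — and compared against the same score computed
for trajectories whose *visit sequence* has been shuffled
(`shuffle_visit_sequence()`; the initial center phase is never
shuffled).

The key property making this an exact null: shuffling permutes whole
fixation segments, so the multiset of instructed positions — and
hence the z-scored value multiset of the target — is preserved. Any
MAE difference between the paired and shuffled conditions is
attributable to temporal arrangement alone; for an EOG signal that
carries no trajectory information the expected MAE is identical under
both conditions.

```{r surrogate}
m <- noise_model()
closed <- simulate_cohort(cohort_spec(n_participants = 3,
                                      trials_per_cell = 2,
                                      incomplete = list(),
                                      fs_eog_hz = 64, fs_et_hz = 64,
                                      model = m))
closed <- preprocess_cohort(closed[closed$eye_state == "closed", ])
res <- surrogate_mae_test(closed, n_shuffles = 50, seed = 1)
res
autoplot(res)
```

Per axis, each trial's mean MAE over the shuffles enters a
Shapiro-gated paired test against its paired MAE (one value per
trial, full shuffle distribution retained in `res$shuffled_mae`).

## Reproducibility and the pipeline

All randomness flows from named seeds: `withr::with_seed()` gives
every simulated trial and every shuffle stream a local RNG, so
results are independent of evaluation order and the global RNG state
is never touched. The five stage functions `run_simulate()`,
`run_preprocess()`, `run_analyze()`, `run_surrogate()` and
`run_report()` are pure functions of (config, directories); written
outputs are delimited text with a provenance header (package version,
config hash, master seed), and a rerun with the same config is
byte-identical. A thin command-line wrapper over the same stages
ships in `system.file("scripts", "gazeog.R", package = "gazeog")`.

## Verification strategy and test problem sizes

The test suite checks the numerical kernels against brute-force
oracles (sliding median, windowed SD, Haar inner products, full
cross-correlation, MAE — exact or at 1e−9), the detector and the
statistics against generator ground truth, and the pipeline against
its own determinism contract. Monte-Carlo batteries use sizes chosen
to keep the suite fast while leaving the conclusions unambiguous;
they are package choices, not protocol constants:

* blink recovery: 20 trials with blinks + 20 without, at the full
  512 Hz EOG rate;
* post hoc power: cross-checked against a 100 000-replicate simulated
  t-test oracle (agreement within 0.005);
* surrogate direction of effect: an 11-participant, 2-trials-per-cell
  eyes-closed cohort at 128 Hz EOG; null calibration: 100 pure-noise
  (zero-gain) cohorts of 3 participants at 64 Hz, rejection rate
  required to sit in [0.01, 0.10] at nominal alpha 0.05;
* TOST consistency: 100 seeds of matched noisy copies (noise SD 0.01
  before z-scoring, placing the 90% CI half-width well below the
  SESOI bound) and of 10-SD-offset pairs.
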