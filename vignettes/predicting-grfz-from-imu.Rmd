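---
title: "Predicting vertical ground reaction forces from body-mounted IMU signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting vertical ground reaction forces from body-mounted IMU signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(equigrf)
```

## The problem

The vertical component of the ground reaction force (GRFz) is the reference
quantity for weight-bearing lameness assessment in horses, but measuring it
requires a force-instrumented treadmill or force plates — laboratory
equipment that is rarely available in clinical practice. Body-mounted
inertial measurement units (IMUs), in contrast, are cheap, portable and
already widely used for kinematic gait analysis. `equigrf` implements a
pipeline that learns the mapping from raw, calibrated IMU channels to the
per-limb GRFz of walking and trotting horses: a recurrent sequence model is
trained on strides for which both IMU signals and treadmill reference forces
are available, and then predicts full GRFz curves (and, separately, peak
forces) from IMU data alone.

Because the original treadmill recordings are not publicly deposited, the
package ships a physics-grounded synthetic gait generator that reproduces
the statistical and mechanical structure the analysis relies on. Every stage
of the pipeline — sensor conditioning, segmentation, dataset construction,
training, evaluation — is developed and tested against that generator.

## The synthetic gait generator

`simulate_trial()` produces one horse x gait x speed trial consisting of a
10 s standstill (for sensor calibration), a short transition, and steady
locomotion with mildly jittered stride periods (sd 1.5% of the stride).
Its mechanical core:

* **Stance waveforms.** Walk stances (duty factor 0.62) are a tilted sine
  hump minus a raised-cosine mid-stance dip, which yields the characteristic
  double peak — second peak higher for front limbs, first higher for hind
  limbs — and collapses to a single hump when the dip term vanishes. The dip
  deepens with speed (`dip_depth = 0.9 (v - 1.1)`, clamped to [0, 0.8]), so
  it disappears at low walking speeds. Trot stances (duty factor 0.44) are a
  single raised cosine. Footfalls follow the lateral walk sequence
  LH-LF-RH-RF at quarter-stride phases, and synchronous diagonal pairs
  (LH,RF)/(RH,LF) at trot.
* **Force balance.** Waveform amplitudes are rescaled per limb pair so that,
  averaged over interior strides, the front pair carries 57% and the hind
  pair 43% of body weight and the total equals g = 9.81 N/kg exactly.
  Left/right asymmetry ratios scale one side's amplitude so the Robinson
  symmetry index of the truth peaks follows its closed form.
* **Upper-body channels.** A body-mounted node senses a weighted share of
  the summed limb forces, `a_z = w_f (LF + RF) + w_h (LH + RH) - g`, with
  withers weights tilted toward the front pair, sacrum toward the hind pair,
  and the head adding a low-frequency bob. The weights satisfy the static
  mass-share convention so a standing horse reads zero acceleration (1 g on
  the sensor axis).
* **Limb channels.** Sagittal angular rate is near zero in stance with one
  biphasic wave per swing (300 dps walk, 450 dps trot); each hoof-on adds a
  short Gaussian acceleration transient (~20 g, sd 4 g) that deliberately
  exceeds the 16 g limb low-g range for most impacts.
* **Sensor corruption.** Per node: gyro bias ~ Uniform(-2, 2) dps per axis,
  accelerometer scale error ~ Uniform(-2%, 2%), white noise (0.05 g low-g,
  0.2 g high-g, 1 dps gyro), range clipping (low-g +-8 g upper body /
  +-16 g limbs; high-g +-100/+-200 g; gyro +-2000 dps), 200 Hz IMU rate.
  The force plate samples at 512 Hz on a clock offset by 0.1 s from the IMU
  clock, with 0.01 N/kg noise rectified at zero; a motion-capture surrogate
  (the withers angular-velocity magnitude on the force-plate clock) carries
  the synchronization information, mirroring a hardware-synced optical
  system. Noise-free truth channels are stored alongside so that every
  recovery test compares against truth, never against another estimate.

Population defaults (mass ~ Normal(526, 32) kg, walk 1.7/1.8 m/s, trot
3.3/4.0/4.5/5.0 m/s, >= 15 strides per trial) mirror the treadmill protocol
the pipeline targets. Stride durations and duty factors are not reported for
that protocol; the defaults (walk 1.10 s at 1.7 m/s, trot 0.72 s at
3.3 m/s, weakly speed-scaled) are literature-typical values chosen once to
satisfy the support-pattern constraints (walk always keeps at least two
hooves loaded; trot alternates diagonal support and suspension).

What the generator does *not* emulate: soft-tissue artifact, orientation
drift, hoof-specific impact spectra, inter-stride amplitude variability
beyond timing jitter, and any lameness-specific gait adaptation. Passing
tests therefore demonstrate that the pipeline's machinery is correct and
that the model can recover kinetics from kinematics under the stated
assumptions — not that the accuracy figures transfer to real horses.

## Sensor conditioning

The processing chain deliberately contains no filtering:

1. **Dual-range merge** (`merge_low_high_g()`): per axis and sample, the
   low-g reading is used where its absolute value is below 8 g and the
   high-g reading otherwise. The threshold is applied per axis because
   saturation is a per-channel hardware property.
2. **Standstill calibration**: the gyro bias is the per-axis mean over the
   10 s standstill and is subtracted everywhere; the accelerometer scale is
   the reciprocal of the magnitude of the standstill-mean acceleration
   vector, so the calibrated gravity reading is exactly 1 g. Averaging the
   vector before taking the magnitude avoids the upward noise-rectification
   bias (~0.24% at default noise) of averaging per-sample magnitudes; the
   orientation is constant at standstill, so both estimators target the
   same quantity.
3. **Synchronization** (`synchronize_streams()`): the clock offset is the
   lag maximizing the normalized cross-correlation of angular-velocity
   magnitudes on a common 200 Hz grid (search +-0.5 s, rejection below
   correlation 0.5); the force stream is then shifted and linearly
   resampled onto the IMU time base. The standstill-to-locomotion onset
   makes the correlation peak unique despite the periodicity of gait.

## Segmentation and dataset construction

Hoof events come either from the simulator truth or from a stand-in
detector (hoof-on: peak of the merged acceleration magnitude above 4 g;
hoof-off: first sagittal gyro upcross of 50 dps after the stance settles),
which recovers events to a median error well under 15 ms at default noise.

Windows contain one full stance and one full swing per limb. At trot this
is one stride, LH hoof-off to the next LH hoof-off, and consecutive windows
tile the trial. At walk, a window runs from an LH hoof-off to the earliest
subsequent RF hoof-off such that every limb has a complete swing followed
by its complete stance inside the window (about 1.75 strides under the
canonical phasing — the first RF hoof-off after the start cannot satisfy
completeness). The latest complete stance of each limb is recorded as its
*stance of interest*; windows failing completeness are dropped, not
repaired.

Each window becomes a fixed-size sample: per node, the 3 merged calibrated
acceleration channels and 3 bias-compensated gyro channels are linearly
resampled to 200 points and stacked in the frozen node order (head,
withers, sacrum, LF, RF, LH, RH), giving a (6 x N nodes) x 200 input; the
per-limb GRFz forms a 4 x 200 curve target (limb order LF, RF, LH, RH) and
the per-limb peak a 4 x 1 target. At walk the peak is the *second* of the
two principal stance peaks. Peak extraction is restricted to the limb's
stance of interest (padded by 2% of the window) because walk windows longer
than one stride contain a second complete stance of the boundary limbs;
the restriction uses only event times, which are available from the IMU
alone in deployment. Splits are horse-wise (no horse in two subsets),
normalization is per-channel min-max with bounds from the training subset
only, and metrics are always computed on denormalized values (N/kg).

## The sequence model

The predictor is a bilayer bidirectional LSTM (200 hidden units per layer
and direction at study scale; 64 in the scaled profile) with a dropout
layer of probability 0.40 between the recurrent layers and a fully
connected regression head — per time step for curves, from the final hidden
states for peaks. Training minimizes MSE on normalized targets with Adam
(initial learning rate 0.002, batch 64, at most 40 epochs), and the
returned weights are those of the epoch with minimum validation loss; the
selection rule is a design choice, as is Adam itself (only the initial
learning rate is prescribed). The forward pass and backpropagation through
time are implemented in RcppArmadillo and verified against numerical
gradients in the test suite; a closed-form parameter count is also checked.
Training is deterministic for a fixed seed (initialization, shuffling and
dropout masks all derive from it).

The experiment-level protocol repeats training with re-drawn horse splits
("10 different input datasets" at study scale) and reports mean and
standard deviation of each metric across repeats. Re-splitting (rather than
re-shuffling a fixed split) is the interpretation implemented, since it is
the only reading that changes the input datasets.

## Evaluation

* `stride_rmse()`: RMSE over the full 200-sample stride, stance and swing
  (a stance-only restriction is available but non-default).
* `stride_rho()`: correlation between predicted and reference curves.
  **Pearson is the default.** The reference GRFz is identically zero
  throughout the swing phase, so 38% (walk) to 56% (trot) of each stride's
  samples are rank ties; average-rank Spearman correlation then has an
  analytic ceiling of roughly 0.97 (walk) and 0.91 (trot) *even for a
  perfect stance prediction*, because the predicted swing samples order the
  tied reference samples arbitrarily. A rank correlation therefore cannot
  reflect stance accuracy on these curves, and reported medians above 0.99
  are only attainable as Pearson. Spearman remains available via
  `method = "spearman"` for sensitivity analysis, and a test documents the
  tie ceiling.
* `extract_pgrfz()`: trot, the global maximum; walk, local maxima with a
  prominence of at least 5% of the curve maximum inside the largest-area
  supra-threshold region, returning the later of the two principal peaks —
  or the single peak, flagged, when the dip has vanished. The 5% prominence
  value is a design choice; no numeric rule is prescribed.
* `robinson_si()`: `2 (L - R) / (L + R) x 100`, positive when the left peak
  is higher.
* `bland_altman()`: differences are `estimate - reference` (the direction is
  a documented convention), bias = mean, STD = sd, limits of agreement
  `bias +- 1.96 STD`.
* `compare_node_sets()` assembles, per node set (All, UB, Limbs, Sac, Wth),
  the curve RMSE/rho distributions, peak agreement via both routes
  (extracted from predicted curves vs directly predicted) and SI agreement
  for both limb pairs.

RMSE and rho are computed per stride and then aggregated by medians, the
reading consistent with boxplot-style summaries; pooled variants would mix
stride counts across horses.

## Scaled experiment sizes

The package's own experiments run at desk scale: 6 simulated horses split
4-1-1, about 230 (walk) and 260 (trot, thinned from ~870) strides per gait,
64 hidden units, the full 40-epoch budget. These sizes were chosen once as
the smallest configuration at which the headline accuracies stabilize; the
node-set ordering property uses an even smaller profile (32 hidden units,
12 epochs, 120 strides, 3 paired-seed repeats) because only the ordering,
not the absolute accuracy, is at stake there. All deviations from the
study-scale profile are listed in the run manifest written by
`run_pipeline()`.

## Numerical choices and degenerate inputs

Linear interpolation is used for all resampling (no method is prescribed);
window boundaries are half-open `[start, end)` with boundary events
belonging to the window that starts there; normalization channels with
`max = min` map to zero with a warning; constant traces make correlation
undefined and return NA with a warning; an all-zero curve has no peak and
is rejected; training aborts with a diagnostic if the loss becomes
non-finite. Predictions are reported raw: swing-phase values are neither
zeroed nor clipped, and values outside the training bounds are kept.

## Known limitations

The simulator's stereotypy makes the regression task easier than real data:
inter-stride variability is limited to timing jitter, sensor noise and
speed effects, and upper-body channels are exact (noisy) linear functionals
of the targets. Accuracy figures obtained here are ceilings, not estimates,
for real horses. The pipeline predicts GRFz only (the reference system
measures no horizontal forces), assumes treadmill-like steady locomotion,
and the trained models do not transfer to overground, ridden or lame
horses without new reference data.
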