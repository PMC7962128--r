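---
title: "Recognizing stroke gaits from shank angular velocity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing stroke gaits from shank angular velocity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokegait)
```

## The problem

Hemiplegic stroke leaves many survivors with abnormal walking patterns —
drop foot, circumduction, hip hiking, knee hyperextension ("back knee") —
that call for different rehabilitation strategies. Diagnosis is usually a
clinical judgement. This package implements an objective pipeline built on
a single signal: the angular velocity of the shank about the mediolateral
axis (the sagittal-plane rotation rate, in deg/s), measured by a wearable
gyroscope at 128 Hz.

The pipeline has three stages:

1. **Segmentation.** Each stride produces one tall positive peak in the
   shank angular velocity at mid-swing. Cycles are cut mid-swing to
   mid-swing and resampled to 100 points, so cycles from slow and fast
   walkers become comparable vectors. Only time is normalized; amplitudes
   are diagnostic and are left untouched.
2. **Recognition.** A two-part fully connected network maps the 100-point
   cycle to (a) a two-neuron detection output (normal gait vs. stroke
   gait) and (b) a five-neuron multi-label classification output (stroke
   gait plus the four abnormality flags). All hidden layers use
   `ReLU(z) = max(0, z)`; both outputs use the logistic sigmoid
   `sigma(z) = 1/(1 + exp(-z))` with a 0.5 decision threshold, because the
   labels are not mutually exclusive. Training minimizes binary
   cross-entropy with Adam.
3. **Evaluation.** Stratified 4-fold cross-validation; per-output
   confusion matrices; accuracy and F1 with the macro/micro conventions
   described below.

## Gait events

Three events are defined on the angular-velocity trace:

- **mid-swing** — the in-cycle maximum of the angular velocity;
- **heel strike** — the first negative trough after mid-swing (the first
  local minimum with a negative value);
- **toe off** — has no sharp signature in this single channel. The
  package implements a stated convention (most negative local minimum
  between a heel strike and the following mid-swing, i.e. the pre-swing
  trough) purely for completeness; nothing downstream consumes it.

Cycles are delimited at mid-swing rather than heel strike because the
global maximum is the easiest event to locate reliably. The boundary
convention is half-open, `[mid-swing k, mid-swing k+1)`, so consecutive
cycles partition the signal exactly and `n` events give `n - 1` cycles.

Peak picking uses two thresholds that are deliberately conservative for
comfortable-pace walking: a minimum peak height of 50 deg/s (well under
the 150–400 deg/s mid-swing peaks seen at self-selected speed, well above
stance-phase activity) and a minimum peak separation of 0.4 s (about half
the shortest plausible stride period). When two candidates are closer
than the separation, the taller wins; equal heights resolve to the
earlier sample, as does the first sample of a flat crest. No filter is
applied before peak detection by default; a zero-phase Butterworth
low-pass hook (`lowpass_hz`) exists for noisier hardware.

Time normalization is plain linear interpolation — the minimal assumption
— onto the grid `t_j = (j - 1) L / 100` over a cycle of `L` samples. The
first output point is exactly the mid-swing sample and the grid never
touches the next cycle. For cycles shorter than 100 samples the last grid
positions clamp to the final sample; at 128 Hz a walking cycle is ~128
samples, so the clamp is rarely exercised. On a 100-sample cycle the grid
is the identity, which makes normalization exactly idempotent.

## The network

The **detection trunk** is `100 -> [100 x 6 hidden, ReLU] -> 2 sigmoid`.
The **classification branch** consumes the trunk's last hidden
representation and continues `-> [100 x 10 hidden, ReLU] -> 5 sigmoid`.
The published architecture does not state what the classification part
takes as input; the trunk representation is the default here (matching
the sequential description of detection followed by classification of
detected stroke gaits), and `branch_input = "input"` switches to an
independent branch reading the raw cycle. Both wirings train stably on
the synthetic cohort.

Training follows the published protocol: batch size 500, 60 epochs,
dropout rate 0.2 applied to the ten classification hidden layers only.
Dropout is implemented in the inverted convention (surviving activations
scaled by `1/keep`), so inference needs no rescaling. Adam runs with its
published defaults (`alpha = 1e-3`, `beta1 = 0.9`, `beta2 = 0.999`,
`epsilon = 1e-8`); a step size of 3e-3 was tried and trains worse.

Numerical choices worth knowing about:

- **Loss.** Per sample, the loss is the mean binary cross-entropy over
  the 2 detection neurons plus the mean over the 5 classification
  neurons; batches average over samples. Predictions are clipped at
  1e-12 inside the logarithm, so a saturated perfect fit has loss
  ~1e-12 rather than 0 and a saturated error stays finite.
- **Classification loss on normal gaits.** By default the classification
  term is restricted to stroke-gait samples (`cls_loss_mode =
  "sg_only"`). The alternative — training the classification head on
  every sample with all-zero targets for normal gaits — is selectable
  (`"all"`), but in repeated runs those all-zero targets back-propagate
  through the shared trunk against the detection objective and
  destabilize detection (fold accuracies scattered over 0.76–0.99 versus
  0.98–1.00 under the default). Since only detected stroke gaits are
  ever routed to the classification part at inference, the restricted
  loss is also the semantically consistent choice.
- **Initialization.** Hidden layers draw He-style scaled uniform weights
  (`U(+-sqrt(6/fan_in))`, matched to ReLU); both sigmoid output layers
  start at exactly zero, so the untrained network outputs 0.5 everywhere
  and the first epochs are not spent escaping clipped-log saturation.
- **Determinism.** Every stochastic element — initialization, epoch
  shuffling, dropout masks — draws from one seeded stream per training
  run; identical (dataset, split, config, seed) reproduce identical
  weights bit for bit.
- **Gradients.** Backpropagation is exact for the composite loss
  (verified against central differences at ~1e-7 relative error,
  including through dropout masks and the shared trunk).

Prediction is **gated**: the detection label is the argmax of the two
detection probabilities (a tie goes to normal gait); the four abnormality
flags are read off the classification neurons at 0.5 only when detection
says stroke, and are forced to zero otherwise. Evaluation of the
classification head therefore happens on the samples the detection head
routes to it, mirroring the published confusion-matrix layout in which
the classification blocks total the number of gaits predicted as stroke.

## Summary-metric conventions

The published per-model summary table is reproducible exactly from the
published per-class confusion matrices only under one specific pair of
conventions, which this package adopts:

- **Detection** (two class blocks, normal and stroke each treated as the
  positive class): accuracy and F1 are the *macro* means of the two
  blocks' accuracy and F1. For these symmetric two-class blocks the macro
  and micro values agree to four decimals.
- **Classification** (five label blocks): accuracy is the mean over
  labels of per-label accuracy — equal to pooled accuracy whenever all
  blocks share one total, which holds for every published model — and F1
  is *micro*-averaged: TP/FP/FN pooled over the five labels before
  applying the F1 formula.

Metrics with zero denominators (e.g. precision with no positive
predictions) return `NA` with a warning and are excluded from averages.
Report printing rounds half-up to 4 decimals; computations never round.

Two transcription notes on the packaged fixtures. First, one printed cell
(model 4, circumduction, TN = 489) makes its block sum to 600 while every
other block of that model sums to the fold size 500, and contradicts the
model's published summary accuracy of 0.9728; the loader applies the
documented correction 489 -> 389 by default and `corrected = FALSE`
returns the verbatim transcription. Second, model 2's published
classification accuracy (0.9717) is not implied by its printed counts
(which give 0.9713); this discrepancy is reported as-is and not
reconciled.

## The synthetic cohort generator

No public stroke-gait dataset ships with the package, so the generator
provides labelled ground truth for testing every stage. One cycle is a
stance plateau plus three Gaussian bumps — mid-swing peak (+250 deg/s
nominal at phase 0.15), heel-strike trough (-100 at 0.30), pre-swing
trough (-80 at 0.88) — which realizes exactly the three event
definitions. Per-cycle duration jitter (5% s.d.) exercises the 100-point
normalization; per-cycle and per-leg amplitude factors scale the whole
waveform, emulating walking vigor.

The stroke-generic signature is **tremor**: band-limited noise
(Gaussian-kernel-filtered white noise, energy concentrated below roughly
15 Hz) with a default standard deviation of 15 deg/s, emulating the
visible trembling of paretic-side traces. Band-limited noise is both
physically truer than white noise — pathological shank oscillation lives
well below the 64 Hz Nyquist frequency — and survives the 100-point
resampling, so the learning task does not hinge on aliasing artifacts.
Held-out detection accuracy is flat (0.998–0.999) for tremor between 10
and 20 deg/s, so the default is not a sensitive tuning.

Each abnormality flag applies one deterministic waveform perturbation,
chosen so the flags have independent, learnable signatures rather than to
model stroke biomechanics:

- *drop foot*: mid-swing peak attenuated by 50% (a severe drop foot;
  because amplitude variation scales the whole waveform, attenuating only
  the peak changes the peak-to-trough ratio and stays identifiable);
- *circumduction*: swing peak broadened by 60%;
- *hip hiking*: +45 deg/s Gaussian bump at phase 0.45 (early mid-stance);
- *back knee*: +40 deg/s late-stance reversal bump at phase 0.80.

The two stance-phase bumps sit inside the minimum-separation exclusion
zones of the neighboring mid-swing peaks, so tremor excursions riding on
them do not register as spurious mid-swing events; end-to-end
segmentation at default tremor recovers planted cycle counts within one
cycle per hundred, and exactly at zero tremor.

The default cohort layout mirrors a published clinical study: eight
stroke subjects × two legs with fixed per-leg flag combinations (2037
stroke gaits, including one leg with all four abnormalities and legs with
a single one) and seven healthy subjects contributing 1000 normal gaits
per side. The generator plants `n + 1` mid-swing events per leg so that
mid-swing-to-mid-swing splitting yields exactly the configured `n`
cycles.

**What passing tests on this cohort do and do not show.** The generator
produces smooth template cycles plus parametric perturbations and
band-limited noise; it does not imitate real patients' spectra,
inter-stride correlations, sensor artifacts, or the mixed severity of
real abnormalities. Synthetic results demonstrate that the pipeline's
machinery — event detection, normalization, backpropagation, the
cross-validation protocol, the metric conventions — is correct and that
the network can learn multi-label structure from cycle shape; they do not
certify clinical accuracy on real gait data.

## Cross-validation design

Folds are stratified on the full six-flag label combination (falling back
to the detection label, with a warning, if some combination has fewer
members than folds) and are exact partitions; each of the four models
holds out a different fixed fold. Stratification operates on individual
gait cycles, as in the published protocol. That choice leaks subject
identity across folds — cycles of one patient appear in both training and
validation — so per-fold accuracies are optimistic relative to a
subject-level split. A subject-level mode is future work; the caveat
applies equally to the published numbers this package reproduces.

On one CPU the default synthetic run (cohort synthesis plus four trained
models at 4037 cycles, 60 epochs each) completes in a few minutes; the
reported acceptance run uses exactly these sizes.

## Known limitations

- Single-channel design: accelerometer and magnetometer channels are
  ignored by construction.
- Toe-off is a convention, not a validated event.
- The fold protocol is cycle-stratified (see above).
- Undefined-metric sentinels (`NA`) appear when a fold predicts no
  positives for some output; the packaged fixtures never hit this case.
- The published 99.35% detection accuracy on clinical data is
  reproducible here only as the deterministic reconstruction from the
  published confusion matrices; live retraining on the clinical
  recordings would require the original dataset.
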