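---
title: "Cuffless blood-pressure estimation from single-channel ECG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cuffless blood-pressure estimation from single-channel ECG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Continuous blood-pressure (BP) monitoring normally requires either an
invasive arterial line or a cuff that interrupts the subject every few
minutes. A cuffless alternative is to learn a mapping from the
electrocardiogram (ECG) — which can be recorded continuously and
unobtrusively — to systolic and diastolic pressure (SBP/DBP). The premise
is physiological: cardiac rhythm and waveform morphology co-vary with
vascular state, so a regressor that reads a short ECG window can track
pressure without any pressure sensor at inference time. Training such a
model requires paired data: ECG recorded simultaneously with an arterial
blood pressure (ABP) waveform whose per-cycle maxima and minima define the
SBP/DBP reference.

`ecg2bp` implements this pipeline end to end: waveform I/O, signal
conditioning, fixed-length segmentation, ABP-derived labeling, a compact
1D convolutional network, and device-validation style evaluation (AAMI
mean-error/SD check, BHS cumulative-percentage grading, Bland–Altman
agreement). A coupled ECG/ABP simulator with known ground truth makes
every stage testable without any data download.

## The synthetic data generator

`synth_config()` / `simulate_record()` emulate the kind of paired
recordings the pipeline is designed for: two channels sharing beat times,
sampled at a common rate (125 Hz by default — the rate of the ICU waveform
archives this kind of model is usually trained on).

**ECG.** Each beat contributes five Gaussian waves (P, Q, R, S, T) with
fixed amplitudes, offsets and widths relative to the R peak (R amplitude
1 mV). Beat times follow a heart-rate process: per-beat HR drawn as
`N(hr_bpm, hr_sd)` around an optionally ramping target. On top of the
clean signal the generator adds white broadband noise (`noise_sd`, mV), a
power-line sinusoid (`powerline_hz`, default 60 Hz), and a low-frequency
baseline-wander sinusoid (`wander_hz`, default 0.2 Hz — the respiratory
band).

**ABP.** Each cardiac cycle is a raised-cosine systolic upstroke (30 % of
the cycle) followed by an exponential diastolic decay (time constant 25 %
of the cycle), delayed 0.15 s after the R peak to mimic pulse arrival.
After rendering, every cycle is affinely rescaled so that its discrete
maximum equals that beat's SBP and its minimum equals its DBP *exactly*:
the waveform itself carries the ground truth, which is what makes the
label-extraction oracle tests exact rather than approximate.

**Coupling.** For BP to be recoverable from ECG alone, the generator
injects an explicit statistical link between rhythm and pressure:

> SBP_i = a + b · HR_i + ε_i,  ε_i ~ N(0, `coupling_eps_sd`)
> DBP_i = SBP_i − PP + η_i,  η_i ~ N(0, `dbp_noise_sd`)

with instantaneous heart rate HR_i = 60/RR_i, slope `b` = 0.5 mmHg/bpm,
per-beat noise 2 mmHg, and pulse pressure PP = `sbp_mmHg − dbp_mmHg`
(default 40 mmHg) by default. The intercept `a` is derived so the mean
pressure at the mean heart rate equals `sbp_mmHg`. `simulate_dataset()`
then jitters the HR baseline (SD 10 bpm) and the coupling intercept (SD
5 mmHg) across records, emulating between-subject variation; within a
record, beat-to-beat HR variability (SD 2 bpm) propagates into label
variation through the same law.

The intercept jitter deserves a caution: it models between-subject
pressure differences that are *not* mediated by heart rate, and is
therefore unrecoverable from ECG by construction — with the default SD of
5 mmHg it accounts for roughly two thirds of the pooled label variance.
That is realistic (real populations have exactly such offsets) but it
bounds any ECG-only estimator's accuracy. The package's
parameter-recovery experiment, whose point is to verify that the pipeline
recovers everything that is recoverable down to the injected per-beat
noise floor, therefore sets `bp_jitter_sd = 0` so the only label noise is
the 2 mmHg per-beat term the experiment's error budget is stated in.

**What this does and does not emulate.** The simulator reproduces the
*structure* of the learning problem — beat-synchronous two-channel data, a
BP signal carried by rhythm, realistic contaminants — but not the
physiology of real ECG–BP association: there are no arrhythmias, no
respiratory modulation, no motion artifacts, no morphology changes with
autonomic state, and the HR→BP law is linear by construction. A model
passing the recovery test here is therefore evidence that the *pipeline*
(filtering, labeling, optimization, evaluation) works, not evidence of
clinical accuracy on real patients.

## Signal conditioning

Two operations, in this order (the order is configurable; low-pass first
is the default because the wavelet stage then operates on a band-limited
signal):

1. **Low-pass filter** (`lowpass_filter()`): 4th-order Butterworth with a
   50 Hz cut-off, applied forward–backward (`signal::filtfilt`). The
   bidirectional pass squares the magnitude response and cancels the
   phase, so R-peak timing is preserved — the package asserts a ≤ 1 sample
   shift on clean fixtures. At 125 Hz sampling the design achieves < 1 %
   passband ripple at 10 Hz and > 99 % rejection at 58 Hz.
2. **Wavelet baseline removal** (`remove_baseline_wavelet()`): multilevel
   Daubechies-4 decomposition (periodised; the signal is symmetrically
   padded to a multiple of 2^levels), with the approximation band zeroed
   before reconstruction. The depth is rate-aware: the smallest number of
   levels whose approximation band lies below 0.5 Hz — 7 levels at 125 Hz,
   putting the band edge at 0.49 Hz. A 0.2 Hz wander sinusoid is
   suppressed to < 10 % residual RMS while a clean ECG passes with
   correlation > 0.99. The DWT is implemented in the package (no wavelet
   dependency) and is verified by an exact perfect-reconstruction test.

The ABP channel deliberately passes through **unfiltered**: its extrema
are the labels, and any smoothing would bias SBP downward and DBP upward.
A `filter_abp` flag exists for users who want symmetric treatment.

**Segmentation** (`segment_pair()`): non-overlapping windows of 128
samples (~1.02 s at 125 Hz). The trailing remainder is discarded — with
no overlap and a fixed length, partial frames have no defined place. At a
heart rate of 47–117 bpm a frame contains one or two complete cycles.

## Label extraction

`find_abp_extrema()` locates systolic peaks and diastolic troughs as
strict local extrema screened by (i) a prominence floor, 10 % of the
frame's dynamic range; (ii) a refractory separation of 0.3 s between
same-kind extrema (below any plausible cycle length); and (iii) forced
alternation. `label_frame()` averages peak and trough amplitudes in each
frame; a frame is excluded from training when it has no peak, no trough,
SBP ≤ DBP, SBP > 250 mmHg or DBP < 20 mmHg (all configurable bounds). On
noise-free synthetic ABP the extracted labels equal the generator's
per-beat pressures to floating-point accuracy — the central correctness
oracle of the package.

Frames without a detectable full cycle do occur at low heart rates (a
128-sample frame is shorter than a cycle below ~59 bpm), which is why
labeled datasets report a `valid` flag rather than failing.

## QRS detection and rhythm analysis

`detect_qrs()` follows the classic energy-transform design: a 5–15 Hz
Butterworth bandpass concentrates QRS energy and rejects P/T waves and
broadband noise; differentiation and squaring emphasize slope; a 150 ms
moving-window integral forms the detection function; an adaptive
signal/noise threshold (running signal- and noise-peak estimates, 0.25 s
refractory period) selects integration peaks; finally each detection is
refined to the local ECG maximum so indices land on R peaks. A trailing
energy screen removes residual detections far below the record's median
QRS energy. On the standard noisy fixture (10 s, 60 bpm, broadband noise
at 10 % of the R amplitude) sensitivity and positive predictivity are 1.0
across seeds. `rhythm_summary()` turns an annotation into RR intervals
and instantaneous heart rate (60/RR).

## The regressor

A compact 1D CNN maps one normalized 128-sample ECG frame to (SBP, DBP):
four convolution–ReLU–max-pool blocks with 32, 64, 128 and 256 filters
(kernel 5, stride 1, same padding; pool 2, so 128 → 64 → 32 → 16 → 8),
then a 128-unit dense feature layer, fully connected layers of 32 and 16
ReLU units, and a linear 2-output head.

One architectural choice deserves explanation. After the fourth pool the
feature map is 8 positions × 256 channels; a flatten would hand the dense
stack 2,048 features, whereas the design calls for a 128-unit feature
layer. The default resolves this with global average pooling over time
(256 features) feeding the 128-unit dense layer — the mildest reading of
the printed layer sizes. Time-averaging makes the features
translation-invariant, which at first sight should hurt: with kernel 5 a
deep unit's receptive field is ~0.49 s, shorter than a cardiac cycle, so
no single feature ever sees two R peaks and beat spacing is not directly
measurable. In practice the network senses rate through occupancy
statistics — the fraction of windows occupied by quiet baseline between T
and the next P scales with the RR interval, and averaged "quiet detector"
channels encode exactly that. In the package's recovery experiments the
pooled variant matches the flattened one (held-out SBP MAE ~2 mmHg, r
~0.9 under the standard conditions for both), so the default stays
`feature_pool = "gap"`, with `"flatten"` available for comparison.

**Input normalization.** Each frame is z-scored before entering the
network (`input_norm`, default on). Electrode gain is a nuisance variable
in practice; normalization removes it while leaving timing intact.

**Targets.** SBP/DBP are z-scored using training-split statistics
(`target_scaling`), and predictions are mapped back to mmHg. Squared
error on raw mmHg values would implicitly weight SBP errors above DBP
errors by their variance ratio.

**Optimization.** Minibatch Adam, batch 32, learning rate 0.01, MSE loss
— with four stabilizers, because 0.01 is roughly ten times the
conventional Adam step for a network of this size and Adam moves every
parameter by about the full step from the first update onward:

* *gradient-norm clipping* (`clip_norm`, default 1.0) bounds each
  update's global gradient norm;
* *linear warm-up* (`warmup_epochs`, default 3) ramps the step size from
  zero, so the early, misaligned updates are small;
* *failure-to-launch rescue* (`rescue_after` = 5, `max_restarts` = 3):
  the decisive failure mode at this rate is the 16-unit fully connected
  bottleneck dying — all units permanently negative, output constant,
  gradients zero — which no further training at any rate can undo. If
  after five epochs the best validation loss is still no better than the
  constant mean predictor, training restarts from the initial weights at
  a quarter of the rate, up to three times, and each restart is recorded
  in the returned history. Runs that learn normally at 0.01 are
  untouched; runs whose seed draws an unlucky trajectory retrain at the
  largest stable rate instead of silently returning a degenerate model;
* *reduce-on-plateau* (`lr_reductions`, default 2): when the
  early-stopping patience expires, the learning rate is halved and
  training resumes from the best checkpoint before the run is allowed to
  end — at an aggressive initial rate, the first plateau usually reflects
  step size, not convergence.

The 80/20
train/validation split is frame-level by default; a record-level mode
(`split_by = "record"`) assigns whole records to one side and is the
recommended setting when frames from one recording should not leak across
the split — frame-level splits overstate generalization for data with
per-record state. Early stopping monitors validation loss (patience 20 by
default) and the returned model is the best-epoch checkpoint
(`restore_best`).

## Evaluation

`evaluate_model()` (or `evaluate_pairs()` for precomputed estimates)
reports, per channel: Pearson correlation (a zero-variance estimator is
flagged degenerate rather than scored), signed mean error, sample-SD of
errors, MAE, an AAMI-style pass flag (|ME| ≤ 5 mmHg and SD ≤ 8 mmHg,
inclusive boundaries, thresholds configurable), a BHS-style letter grade
from the cumulative percentages of absolute errors within 5/10/15 mmHg
(A = 60/85/95, B = 50/75/90, C = 40/65/85, else D), and Bland–Altman bias
with 1.96-SD limits of agreement. The thresholds and band tables are
configuration values, not constants: the standards themselves evolve, and
the package should not hard-code a particular revision.

## Numerical choices and degenerate inputs

* The DWT uses periodised filtering with symmetric padding to a multiple
  of 2^levels; reconstruction without modification is exact to ~1e-15.
* `filtfilt` needs warm-up; signals shorter than 3×(2·order+1) samples
  are rejected with a parameter error rather than silently mis-filtered.
* Flat signals: ABP extrema detection returns a degenerate flag; QRS
  detection returns an empty annotation with a warning.
* Ties in pooling (`a == b`) resolve to the earlier sample; exact ties
  have probability zero for continuous inputs and a fixed resolution
  keeps training bit-reproducible.
* All sample indices are 0-based and all time intervals half-open, so
  segmentation, slicing and annotation indices compose without off-by-one
  corrections.
* Every stochastic component (generator, splits, initialization, batch
  order) derives from explicit seeds; the full pipeline is
  byte-reproducible given a config and master seed, and training runs
  serially so no parallel reduction order can perturb results.

## Problem sizes used in the shipped checks

The package's own test suite exercises the full system at deliberately
moderated scales: the parameter-recovery experiment trains on 2,000
frames (27 synthetic records of 120 s) for up to 30 epochs and evaluates
on 500 held-out frames; the capacity check memorizes 16 frames for 500
epochs; determinism is demonstrated on a 2-record pipeline run executed
twice. These sizes were chosen so that the whole suite documents the
system's behavior in minutes on a single CPU while still being large
enough for the statistical claims they support (a 500-frame hold-out
bounds the MAE estimate's standard error well below the tolerance being
asserted).

## Known limitations

* The learnable ECG→BP association in the synthetic data flows through
  heart rate alone; real waveforms carry morphology-mediated information
  the simulator does not model, and conversely real confounders
  (medication, posture, sensor placement) are absent.
* The WFDB reader/writer covers the minimal header + 16-bit signal subset
  needed for two-channel records, not the full format family.
* A 128-sample frame at 125 Hz cannot contain a full cycle below
  ~59 bpm; severe bradycardia yields mostly invalid frames at this frame
  length.
* The evaluation implements AAMI/BHS-style criteria as configurable
  summaries; it is not a certified implementation of any standard's full
  protocol (sample-size and subject-composition requirements are out of
  scope).
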