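---
title: "emgdx: methods and design notes"
author: "emgdx authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{emgdx: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Needle electromyography (nEMG) records motor unit action potentials
(MUAPs) from within a muscle during voluntary contraction. The waveform
statistics are diagnostic: neuropathic muscle shows MUAPs with large
amplitudes, long durations and *reduced* recruitment (few units firing,
even at strong effort), while myopathic muscle shows small, short MUAPs
with *early* recruitment (many low-threshold units active at weak
effort). Normal muscle sits between the two. `emgdx` implements a
diagnosis-aiding pipeline over such signals: a compact 1-D residual
convolutional network classifies fixed 0.4-s segments into
myopathy (M) / neuropathy (N) / normal (NL), and a divide-and-vote
scheme aggregates segment decisions into signal- and finally
patient-level diagnoses, which are then evaluated against a simulated
physician rater panel under nested cross-validation.

Because clinical nEMG databases are not shareable, the package is
driven end-to-end by its own synthetic cohort generator. The generator
is first-class, tested code: its class-conditional physiology defines
the study conditions under which every downstream claim is verified.

## The synthetic cohort generator

Each signal gets a *motor unit pool* drawn from its class physiology:

| parameter | M (myopathy) | NL (normal) | N (neuropathy) | unit |
|---|---|---|---|---|
| MUAP amplitude (peak-to-peak) | 100–400 | 300–800 | 800–3000 | µV |
| MUAP duration | 3–7 | 6–12 | 10–20 | ms |
| pool size (units) | 15–25 | 8–15 | 4–8 | – |
| recruitment threshold | U(0, 0.30) | U(0, 0.65) | U(0, 0.95) | fraction of maximal drive |
| firing rate at full drive | 10–25 | 8–20 | 12–30 | Hz |
| ISI coefficient of variation | 0.15 | 0.15 | 0.15 | – |
| noise RMS | 10 | 10 | 10 | µV |

The numeric ranges are the package's own defaults; their only contract
is the classic electrodiagnostic *ordering* — amplitude and duration
M < NL < N, recruitment-threshold spread M < NL < N (early versus
reduced recruitment) — which the test suite verifies with Monte-Carlo
confidence intervals over 200 pools per class. Every value is
config-overridable through `classPhysiology()`.

Mechanically, a MUAP template is a sum of `nPhases` alternating-sign
Gaussian lobes over its support, edge-tapered, baseline-corrected to
integrate to zero (charge balance) and rescaled to its exact
peak-to-peak amplitude. Units whose recruitment threshold does not
exceed the per-signal voluntary drive fire as independent renewal
processes with gamma-distributed inter-spike intervals (mean rate
scaled by drive); templates are summed at spike onsets, and Gaussian
noise band-limited to the 20 Hz – 10 kHz recording filter is added at
the stated RMS. Signals are synthesized at the 48 kHz acquisition rate.

Cohort shape mirrors the study design the pipeline targets: 19
patients per class (57 in total), 5–7 signals per patient, signal
durations uniform on 1.2–3.4 s (bracketing the reported per-class mean
signal lengths of roughly 2.2–2.9 s), and per-signal drive uniform on
0.3–1.0 to mimic minimal-to-maximal contraction. Seeding is
counter-based (`childSeed()`): each patient, signal and rater has a
private stream derived from the master seed, so enlarging a cohort
never reshuffles previously generated items and every `simulate*`
call is bit-reproducible.

The simulated 6-physician rater panel draws each label independently
from a per-rater confusion matrix: the shared default rows

```
        M     N     NL
 M    0.50  0.30  0.20
 N    0.08  0.77  0.15
 NL   0.25  0.55  0.20
```

perturbed by a mean-preserving Dirichlet jitter (concentration 300).
The NL row deliberately encodes the strong normal-to-neuropathy bias
reported for human raters on this task; the M and N rows echo the
reported pattern that neuropathy is recognised best and myopathy is
under-called. Signal and patient labels are sampled independently —
one plausible reading of how raters produce patient labels; a coupled
mode (patient label copied from the rater's own signal majority) would
be a natural extension.

What the generator does *not* emulate: resting-state and insertional
activity, fibrillations and positive sharp waves, needle-movement
artifacts, electrode geometry, multi-channel recordings, and the
long-tailed heterogeneity of real disease subtypes. Passing tests
therefore demonstrate that the pipeline recovers class structure of
the stated kind at the stated sizes — not clinical performance.

## Preprocessing

Signals are resampled 48 kHz → 10 kHz before segmentation, fixing the
window at 4000 samples. `signal::resample()`'s anti-aliasing proved
insufficient for the stop-band requirement (measured ≈ −6 dB at 6 kHz),
so the package applies its own rational resampler: a Kaiser-windowed
(β = 8, 1201 taps) linear-phase FIR low-pass designed with
`signal::fir1()` at the upsampled rate, applied through a polyphase
kernel with the group delay compensated. Measured behaviour: a 1 kHz
tone passes within 1 % amplitude; a 6 kHz tone (above the 5 kHz target
Nyquist) is attenuated by more than 60 dB.

Segmentation cuts non-overlapping 0.4-s windows from sample 1 and
discards the trailing remainder; a signal shorter than one window
yields no segments and is excluded (the same minimum-window rule that
excludes such recordings from model evaluation in practice).
Non-overlap is the simplest scheme consistent with one-segment-one-vote
counting. No per-segment amplitude normalisation is applied — absolute
amplitude *is* the diagnostic signal here — but a single global scale
constant (default 1/1000, µV → mV) conditions the network input.

## The segment classifier

The classifier is a compact 1-D residual network over raw segments:
a stem convolution, two residual blocks (two same-padding convolutions
plus an identity or 1×1-projected skip), average pooling between
stages, global average pooling and a linear 3-way softmax head. The
default configuration uses kernel 9 and channels 16 → 32
(19,331 parameters). The forward and backward passes are implemented
in the package (RcppArmadillo kernels for convolution and pooling;
gradients verified against finite differences in the test suite),
since no automatic-differentiation framework is available to R here —
and the contract is behavioural anyway: simplex outputs, desk-scale
trainability, input gradients for feature visualization.

Training minimises cross-entropy with class weights inversely
proportional to the per-class training segment counts (normalised to
mean 1), using Adam at learning rate 1e-3 and batch size 32.
Validation accuracy is evaluated every 30 gradient updates ("updates",
not epochs); training stops after 100 consecutive evaluations without
improvement and restores the best-validation checkpoint. Two
refinements are the package's own choices: a hard `maxUpdates` cap
(default 20,000) so training always terminates, and a tie rule that
keeps the *most trained* among equally accurate checkpoints while ties
still count toward patience. Validation accuracy is segment-level
(the simplest reading; a signal-level variant would be easy to add).
The optimizer is not dictated by the training schedule itself; Adam is
the package's choice and is configurable.

## Divide-and-vote aggregation

Each segment casts one argmax vote for its signal; the majority label
wins. Each signal then casts one vote for its patient, so signals
weigh equally regardless of duration or segment count — patients with
long recordings do not dominate their own diagnosis. Ties (possible
with even counts) are broken in favour of the tied class with the
larger summed probability mass, which is deterministic and respects
the classifier's confidence; ties surviving even that (exactly equal
mass) fall back to class order. A pooled mode
(`patientPooled = TRUE`), in which all of a patient's segments vote
directly, is provided for comparison. The majority scheme provably
boosts per-signal accuracy q > 1/2 at the patient level for
independent signal decisions; the suite verifies the boost by
simulation at q = 0.6 over 1, 3 and 5 signals per patient.

## Evaluation

Cross-validation is nested and *always split by patient* — never by
signal or segment, which would leak a patient's idiosyncrasies across
the train/test boundary. Five class-stratified outer folds serve as
test sets; the remaining patients are split into three inner folds
that rotate as validation sets; three model seeds are trained per
(outer, inner) pair. A (seed, inner-fold) pair defines one prediction
run spanning all outer folds, so every test patient and signal
receives exactly 9 predictions. Stratification keeps per-class fold
counts within ±1; remainder patients are placed greedily to balance
total fold sizes (11–12 patients per outer fold at 57 patients).

Metrics are accuracy plus macro-averaged one-vs-rest precision,
recall, specificity and F1 computed from the 3×3 confusion matrix,
with 0/0 ratios defined as 0. The same scoring code path evaluates
model runs and rater panels, so the two are directly comparable by
construction. Score sets are compared with a two-sided Mann–Whitney U
test, exact whenever the scores are tie-free and each side has fewer
than 50 observations, and a normal approximation with continuity
correction otherwise; medians with quartiles are reported alongside.
ROC and precision–recall points are exported per class by exhaustive
threshold sweeps (PR curves start at (0, 1) by the usual
no-positive-predictions convention), but no area under the ROC curve
is reported as a headline metric — threshold-free ranking quality is
not what a fixed-threshold diagnosis pipeline is asked to deliver.

## Interpretation tools

*Consensus / failure analysis.* An item is "highly consistent" when at
least 8 of the 9 model runs, or 5 of the 6 raters, assign the same
label; tied modal counts never yield a consensus. Cross-failure tables
count dual-consensus items that one source classifies correctly and
the other does not, broken down by the wrong label. Because the 9
model runs share training data while raters err independently, the
model ensemble is systematically more self-consistent — the suite
checks exactly that qualitative property on the default synthetic
panel.

*Feature visualization.* Class prototypes are synthesized by gradient
ascent on the pre-softmax class score from a small-noise start,
regularized by a squared-first-difference smoothness penalty (nEMG
prototypes should remain band-limited-plausible). Steps are
improvement-gated — a candidate that lowers the objective is rejected
and the step size halved (accepted steps grow it by 10 %) — so the
objective trace is non-decreasing by construction. On models trained
on the default physiology, the neuropathy prototype's peak-to-peak
amplitude exceeds the myopathy prototype's: the network demonstrably
learns the amplitude ordering rather than an artifact.

## Numerical choices and degenerate inputs

* Probability rows are simplex within 1e-6; log-loss clamps
  probabilities at 1e-12.
* WAV persistence uses 32-bit IEEE float mono; waveforms are quantised
  once at write time and round-trip exactly at that precision
  thereafter. Microvolt units live in the manifest (WAV is unitless).
* Empty segment lists, single-class training sets, non-stochastic
  confusion rows, all-zero confusion matrices, mixed-patient vote
  sets and upsampling requests are rejected with specific errors;
  a zero-drive, zero-noise render is exactly zero; a signal shorter
  than 0.4 s contributes zero segments rather than an error.
* Degenerate (constant-output) models make feature visualization warn
  rather than fail, returning the prototype for inspection.

## Problem sizes used by the tests and the acceptance script

The shipped evaluation uses the full default cohort (57 patients,
~340 signals, ~1800 segments) but a compact network — channels 6 → 12
with an 8× input decimation before the stem — and a capped schedule
(validation every 25 updates, patience 3, at most 180 updates), chosen
as the smallest configuration that cleanly saturates on the default
physiology; the 45 nested-CV trainings then complete in minutes on one
core. Unit tests run on a 9-patient miniature of the same generator.
The negative control repeats the full evaluation with all three class
physiologies collapsed to the normal one, and must fall to chance
(1/3 ± 0.15) — this guards the fold plan against label leakage.

## Known limitations

* The synthetic classes are far more separable than clinical nEMG;
  absolute accuracies here say nothing about hospital data.
* The rater model is a per-item confusion draw — no fatigue, learning,
  case-difficulty correlation, or signal–patient label coupling.
* The network is a deliberately small stand-in in the same family as
  published nEMG classifiers (residual 1-D convolutions over raw
  0.4-s segments); channel widths and depths are not tuned for, or
  claimed to match, any clinical benchmark.
* Exact Mann–Whitney p-values are unavailable under ties (the normal
  approximation is used), which matters for the small score sets
  typical here; tie-free score sets are exact.
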