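---
title: "Detecting atrial fibrillation from PPG under premature atrial complexes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting atrial fibrillation from PPG under premature atrial complexes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgaf)
```

## The problem

Photoplethysmography (PPG) — the optical pulse signal measured by a
fingertip oximeter or a wrist wearable — is an attractive screening channel
for atrial fibrillation (AF) because it can be recorded continuously and
cheaply. AF produces an *irregularly irregular* pulse, so classical
detectors summarise the inter-beat (RR) interval series with irregularity
features — the root-mean-square of successive differences (RMSSD), the
Shannon entropy (ShE) of the interval histogram, the signal
autocorrelation — and feed them to a linear-kernel support vector machine
(SVM).

The clinically hard case is sinus rhythm (SR) *with premature atrial
complexes* (PACs): an ectopic beat arrives early, produces a short RR
interval followed by a compensatory pause, and thereby mimics AF in every
interval-based feature. Patients who have just been electrically
cardioverted out of AF — exactly the population one wants to monitor for
recurrence — exhibit frequent PACs. `ppgaf` implements an end-to-end
pipeline for this setting: compact deep classifiers (a six-layer 1-D CNN
and a single-layer GRU) that read the raw 30-second PPG waveform, the
interval-based baselines they are compared against, the PAC indicator that
quantifies ectopy, two cross-validation scenarios, and a synthetic cohort
generator that stands in for clinical recordings.

## Synthetic cohort generator

No public dataset pairs pre-/post-cardioversion PPG with PAC annotations,
so the package ships a generator whose defaults define the frozen study
conditions used throughout the tests: 75 patients, one 15-minute AF
recording and one 15-minute SR recording each, at 100 Hz.

**RR model.** AF intervals are i.i.d. draws from a lognormal truncated to
[0.4, 2.2] times the mean RR — the simplest model that reproduces an
irregularly irregular rhythm with a configurable coefficient of variation
(patients draw CV in 0.18–0.30) and *no* serial correlation (checked by a
lag-1 autocorrelation test). SR intervals follow the mean RR modulated by a
respiratory sinusoid (0.25 Hz, depth 2–6%) plus small Gaussian jitter
(SD 15–40 ms). All intervals are floored at 0.26 s.

**PAC model.** PACs are inserted into the SR train at Poisson-distributed
positions (non-adjacent anchors). The ectopic beat follows its anchor after
a coupling interval drawn uniformly in [0.55, 0.80] of the local mean RR,
and the next sinus beat is delayed to a compensatory pause of 1.3 local-mean
RRs (window-scale local mean, so any 30-s analysis window containing the
PAC keeps a mean RR high enough for the rule to fire with margin); the train is then trimmed so total duration is preserved. Because
every coupling fraction is below 0.85, each inserted PAC violates the 85%
rule by construction, which pins the indicator's recall at 100% on
noise-free renders — a deliberate property that makes indicator failures
attributable to beat detection, not to the rule.

**Per-patient PAC burden.** A patient is PAC-positive with probability
0.48; positive patients draw a rate from a heavy-tailed lognormal
(median 2.8/min, log-SD 1.3, capped at 25/min). The heavy tail is what
populates the high-burden (≥ 20%) windows that the stratified-specificity
analysis needs. The mixture weight was calibrated once, by direct
measurement on the frozen cohort (seed 1), so that ~30% of
post-cardioversion 30-s windows contain at least one PAC (28.5% realised);
only that single prevalence figure was targeted — the full burden
histogram is whatever the mixture implies.

**Waveform model.** Each beat contributes a two-Gaussian pulse: a systolic
peak centred on the beat time (width 0.10 of the beat interval) and a
dicrotic bump at 0.35 of the interval (width 0.16, amplitude 0.35 of the
systolic peak). Pulse amplitude scales with the preceding interval
(slope 0.5, floored at 0.3), emulating reduced ventricular filling after a
short interval — so a PAC is visible in the waveform as a small, early
pulse. Gaussian noise (SD 3–8% of nominal pulse amplitude) is added.
Annotated beat times refer to the systolic peak.

**What the generator does *not* emulate**: motion artifacts (the emulated
protocol is supine rest), baseline wander from perfusion changes,
waveform-morphology pathology, other arrhythmias (ventricular ectopy,
atrial tachycardia), and sensor quantisation. Tests passing on this cohort
demonstrate the pipeline's internal correctness and the qualitative
orderings between methods; they do not certify clinical accuracy on real
recordings, where noise and artifact structure are far richer.

## Conditioning pipeline

Each recording is processed as: bias removal → 0.2–18 Hz band-pass →
segmentation into 30-s windows every 10 s (20-s overlap) → per-window
z-scoring. The filter is a 4th-order Butterworth applied forward and
backward (zero phase, so beat timing is preserved for the PAC indicator),
with odd-reflection padding to suppress the long transient of the 0.2 Hz
corner. Filtering precedes segmentation to avoid per-window edge
transients; normalisation is per window (population-SD z-score) so that
windows are amplitude-scale invariant, which the classifiers require. A
900-s recording yields `floor((900 - 30)/10) + 1 = 88` windows.

## Beat detection and the PAC indicator

Beats are local maxima of the conditioned signal above an adaptive
threshold — 0.45 of the typical systolic height (median of the 20 tallest
candidate peaks), which cleanly separates systolic peaks from dicrotic
bumps — accepted greedily by amplitude under a 0.25-s refractory period.
Two guards refuse degenerate windows: fewer than three beats, and a
local-maxima density above 12 per second (a band-limited pulse train is
smooth; that density signals broadband noise). Such windows are excluded
from interval-based analyses. The detector is validated against the
generator's ground truth (matching tolerance 150 ms) rather than trusted:
on the default-noise cohort its beat sensitivity and precision exceed
0.95.

The PAC indicator flags a beat when its preceding interval is strictly
below 0.85 of the mean interval of the window. "The average interval" is
read as the arithmetic mean of all intervals in the 30-s window, premature
ones included — the simplest reading for a per-window indicator; the
strict inequality takes "less than 85%" literally. The first beat of a
window has no preceding interval and can never be flagged. PAC burden is
the flagged fraction of beats. The indicator is only scored on SR windows:
applied to AF it fires on the rhythm's own irregularity, which is not
ectopy.

## Baseline detectors

Three previously published detector families are reimplemented as linear
SVMs (cost 1, features standardised by training-fold statistics):
RMSSD + ShE; the autocorrelation vector; and their concatenation (the
ensemble). ShE uses 16 equal-width bins over the window's own interval
range; the autocorrelation vector holds 30 equally spaced lags up to 3 s.
The exact feature recipes of the cited detectors are not published in
detail, so these are declared package defaults, all configurable. Features
are computed from *detected* beats, not ground truth, mirroring
deployment. Windows whose beat detection failed get training-median
features.

## Deep classifiers

Both classifiers map a 30-s window, resampled to 40 Hz (the conditioned
signal is band-limited to 18 Hz, so nothing is lost), to a two-class
softmax.

* **1D-CNN** — exactly six convolution blocks (kernel 7; strides
  4,2,2,2,2,2; channels 8,16,16,16,16,16; ReLU), global average pooling
  over the remaining time axis, and a 2-unit softmax head: ~8,600
  parameters.
* **RNN** — a single GRU layer reading the window as twenty 1.5-s frames
  (hidden size 32), its final hidden state feeding the softmax head:
  ~12,000 parameters. A single recurrent layer plus the softmax head was
  chosen where the architecture description was ambiguous about depth;
  depth is configurable.

Training minimises softmax cross-entropy with Adam (CNN: 1e-3; RNN: 3e-3;
3 epochs, batch 256). These schedules were chosen as
the smallest at which training converges on cohort-scale data (13,200
windows) — the synthetic separation problem is easy, and the loss plateaus
within the first epochs. The engine is written directly on BLAS matrix
products (convolutions evaluated via im2col gathers; the GRU by batched
recurrence with full backpropagation through time) and its gradients are
verified against numeric differentiation in the test suite. Training is
single-threaded-deterministic: identical seed, data and configuration
reproduce identical weights bit for bit.

**Confidence level.** For a two-class softmax output \((p_{AF}, p_{SR})\)
the confidence level is \(CL = 100 \cdot \max(p_{AF}, p_{SR})\), ranging
from 50% (uninformative) to 100% (fully decided) and symmetric in the
pair. This is the unique two-class definition consistent with that range.
Diagnoses with CL ≥ 95% are treated as confident; for a calibrated
classifier the misdiagnosis probability at CL \(x\) is approximately
\(100 - x\), which the confidence-level analysis tabulates per CL bin.

## Evaluation machinery

Two cross-validation scenarios mirror the two clinical questions:

* **Scenario A (patient-wise)**: patients are partitioned into 5 groups;
  no patient appears on both sides of a fold — performance on *new
  patients*.
* **Scenario B (sample-wise)**: windows are partitioned into 5 folds
  regardless of patient (stratified by label to keep the near-1:1 class
  balance; paired recordings make reweighting unnecessary) — performance
  when the training distribution matches the test distribution.

Each scenario is repeated (folds and initialisations redrawn) and the five
rates (accuracy, sensitivity, specificity, PPV, NPV; AF positive) are
averaged over all k × repeats validations, with per-fold values persisted
so the averages are auditable. The AUC is computed per repeat on the
pooled scores (each window scored exactly once per repeat) and averaged
over repeats; pooling-then-averaging was chosen where the aggregation
across validations was ambiguous, and both the pooled scores and per-repeat
AUCs are kept. All models within an experiment share identical fold
assignments, so pooled scores are paired and the DeLong test for
correlated ROC curves applies; the AUC itself is the midrank Mann–Whitney
estimator (identical to the trapezoidal area, which the tests verify by
dual computation). AUC confidence intervals use the DeLong standard error
throughout, for internal consistency with the comparison test.

Specificity is additionally stratified by PAC burden (bins 0–5, 5–10,
10–15, 15–20, ≥ 20%; the bin edges mirror the granularity at which such
results are usually displayed — empty bins are reported as undefined with
their counts). Statistical comparison of specificities between algorithms
uses a paired t-test over the validation replicates.

## Numerical choices and degenerate inputs

* Zero-phase filtering uses odd-reflection padding of `3/lo` seconds; edge
  effects at record boundaries are accepted.
* The z-score uses the population SD; constant windows are a degenerate
  input error.
* The 85% rule uses strict inequality; an interval at exactly the
  threshold is not premature.
* Beat matching for validation is greedy one-to-one in increasing time
  difference, tolerance 150 ms.
* Undefined rates (empty denominators) are `NA`, never 0.
* DeLong with identical AUCs and zero variance returns z = 0, p = 1.
* Non-finite training loss aborts with a diagnostic rather than continuing.

## Problem sizes used in the shipped tests

The frozen cohort (seed 1) is the full study scale: 75 patients ×
2 × 900 s = 13,200 windows. The end-to-end experiment in the test suite
runs both scenarios at k = 5 with 2 repeats — 40 deep-classifier fits —
which keeps the whole suite within a desktop coffee break while leaving
every qualitative claim testable: Scenario-B AUC of both deep models,
Scenario-B ≥ Scenario-A specificity, deep-vs-SVM specificity in the ≥ 20%
burden bin, and higher confidence on correct than on incorrect diagnoses.

## Known limitations

* The generator's two-Gaussian pulse and additive white noise are far
  simpler than real PPG; absolute performance numbers on synthetic data
  overstate what any method achieves clinically.
* The beat detector assumes the conditioned, z-scored single-channel
  signal and refuses very noisy windows rather than attempting artifact
  correction.
* PACs are the only modelled ectopy; ventricular premature beats and
  atrial tachycardia are out of scope.
* The confidence level is a softmax-derived score, not a calibrated
  posterior; on real data it should be recalibrated before clinical
  interpretation.
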