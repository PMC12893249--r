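---
title: "Closed-loop IED-burst detection and effect measurement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop IED-burst detection and effect measurement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spikeloop)
```

## The problem

Interictal epileptiform discharges (IEDs) are brief epileptiform EEG
transients between seizures. Series of such potentials — IED-bursts of
0.4–10 s without amplitude or frequency evolution (instantaneous-frequency
drift below 1 Hz) — can transiently slow reactions or abolish responses
(transitory cognitive impairment). Measuring those effects requires a closed
loop: detect the burst in the streaming EEG fast enough to present a
stimulus *during* the discharge, then compare responses during bursts with
responses during normal EEG.

`spikeloop` implements the full computational chain of such a system at desk
scale: synthetic labeled EEG, sliding-window framing, Markov Transition
Field (MTF) imaging, a residual convolutional classifier trained with a
focal balanced cross-entropy loss, an event-driven trigger loop with
digital-latency and refractory modelling, a simulated responding subject,
and the complete per-session and cohort statistics of the pilot-study
tables, which ship as packaged fixtures.

## Synthetic EEG and the burst model

No EEG from the pilot cohort is publicly deposited, so every stage is
exercised on synthetic recordings whose statistical structure follows the
published burst definition.

**Background.** 1/f-weighted Gaussian noise, band-limited to 0.5–30 Hz with
a smooth roll-off, plus a narrow-band 8–12 Hz rhythmic component; scaled to
a root-mean-square amplitude of 20 µV (typical awake scalp EEG). The source
study never characterizes its "normal EEG" statistically; these parameters
are exposed in `recording_config()` and chosen once.

**Bursts.** A burst is a train of spike–wave cycles: a narrow Gaussian spike
plus an aftergoing slow wave per cycle, rendered along a phase track whose
instantaneous frequency drifts linearly by less than 1 Hz over the burst.
Three morphologies map to the published classes:

* `generalized_typical` — sharp spike, well-organized train, near-constant
  envelope (coefficient of variation of per-cycle peaks < 0.15), dominant
  frequency 2.5–4 Hz;
* `generalized_atypical` — blunter spike, added sharp-theta component,
  slowly modulated envelope (CV ≥ 0.15), 4–6.5 Hz;
* `focal` — sharp-transient train with mild modulation, 3–6 Hz.

Durations are log-uniform on [0.4 s, 4 s] with the 10 s hard cap that
separates bursts from electrographic seizures; the log-uniform body matches
the printed per-session mean burst durations (≈0.7–2.6 s) without claiming
knowledge of the true distribution. Burst onsets form a homogeneous point
process at 2.2/min (the prevalence of the training corpus), with overlap
rejection. Peak amplitudes are uniform on 80–200 µV against the 20 µV RMS
background — conspicuous but not trivially separable, which is deliberate:
the source reports no amplitude or SNR statistics, so the defaults are
calibrated to "clinically plausible and learnable", nothing more.

Label accounting is exact by construction: a burst occupies
`round(duration × fs)` samples (half-up) and the per-sample labels are 1 on
exactly that span, so labeled mass always equals the sum of rounded spans.
All randomness descends from one explicit seed through a splittable stream
(`derive_seed()`); no global RNG state is consumed.

What the generator does **not** emulate: eye-blink/EMG artifacts, electrode
pops, sleep architecture, multi-channel field geometry, and ictal evolution.
A detector that clears the package's synthetic floor has demonstrated that
the pipeline is implemented coherently — not that it would reach the same
operating point on clinical EEG.

## Windowing and the window label

The stream is framed into windows of 200 samples advanced by 50 samples; at
the 256 Hz reference rate that is a 781 ms window, a 195 ms step, and ≈600 ms
overlap (durations floor-rounded to the millisecond, matching the deployed
arithmetic). A window is labeled an IED-burst iff at least 150 of its 200
samples carry the burst label — flipping a single sample across the 149/150
boundary flips the window label, and the tests assert exactly that.
Recordings at other sampling rates are polyphase-resampled to 256 Hz before
framing because every published timing assumes it.

## The Markov Transition Field

Each window is discretized into 32 amplitude quantile bins computed from
*that window's* empirical distribution (right-closed bins; ties share a bin;
a constant window collapses to one bin and yields a flat image). First-order
transitions between consecutive samples' bins are counted and row-normalized
into a transition matrix `W`; the MTF is the full pairwise field
`M[i, j] = W[q_i, q_j]`, a 200×200 image of probabilities in [0, 1].

The source text says transition probabilities were "extracted for all
consecutive pairs", which read literally would give a 1-D sequence, not a
square image; since the same text classifies square images, the package
implements the standard full-pairwise MTF of the literature that the source
builds on, and records the ambiguity here. For the classifier the field is
bilinearly resized (separable, convex weights, so probabilities stay in
[0, 1]) to a single grayscale channel.

## The classifier

**Architecture.** A residual CNN: per stage a channel-expanding 3×3
convolution and identity residual blocks (two 3×3 convolutions with a skip),
each convolution followed by batch normalization and ReLU; 2×2 average
pooling between stages; global average pooling; one logistic output unit.
The default is two stages of 8 and 16 channels with one residual block each
(seven weight layers) on 32×32 inputs. Depth, width, and input size are
configuration (`training_config()`, `build_resnet()`); a 34-layer
configuration is constructible, but the default is sized so that training
completes in minutes on one CPU — the published performance numbers depend
on a training corpus that is not available, so the desk-scale backbone only
has to support the package's own synthetic floor. The optional
`pretrained_backbone` hook loads externally pretrained weights; nothing in
the package requires it.

**Loss.** Focal balanced cross entropy,
`-alpha_t (1 - p_t)^gamma log(p_t)`, with `gamma = 2` and probabilities
clamped at `1e-7`. For the class weight `alpha_t` the package defaults to
inverse class frequency of the (rebalanced) training set, because the loss
is described as *balancing* the unequal class masses; a fixed
`alpha = 0.25` — the default of the focal-loss literature — is available via
`alpha_mode = "fixed"`. The reduction to plain cross entropy at
`gamma = 0, alpha = 1`, monotonicity, and the faster-vanishing gradient for
larger `gamma` are asserted in the tests.

**Rebalancing and curation.** Training uses a 1:5 ratio of burst to normal
windows; negatives are redrawn each epoch from an oversampled pool under the
seed stream. Training negatives are drawn from *pure background* windows
(zero labeled samples): windows that partially cover a burst (1–149 labeled
samples) are negative under the ≥150 rule yet carry burst morphology, and
using them as negatives teaches the network to hedge exactly where
confidence is needed. Evaluation never excludes anything — all windows of
the held-out recordings count.

**Splits.** Train/validation/test splits are always by recording, never by
window: the ≈600 ms overlap would otherwise leak nearly identical images
across the split, and a leakage guard in the training API enforces the
recording-level discipline.

**Probability calibration.** The deployed decision rule classifies an image
as an IED-burst at probability ≥ .99, so the probability scale must be
meaningful at high confidence. Two facts shape the design. First, within a
desk-scale training budget the raw sigmoid of a small network separates the
classes well (AUROC ≈ .99) but saturates slowly — most true-burst windows
score ~0.9 rather than ~0.999. Second, the original system applied its .99
cutoff to the raw softmax of a large network, a score that is famously
*over*confident; what characterizes the deployed rule operationally is not
a literal posterior of .99 but its observed operating point — a median
session specificity of .99 in both pilot tables. The bundle therefore
carries a two-part calibration, fitted once on the validation recordings
and applied uniformly by `predict_proba()`: the *slope* of a logistic
(Platt) recalibration, fitted by maximum likelihood under equal class
priors on prototypical validation windows (fully inside a burst vs pure
background, mirroring the training curation), and an *anchor* that places
the ≥ .99 decision point at the validation operating point with a 1%
window false-positive fraction — the deployed median specificity
(`calibration_anchor_spec`, set `NA` for the pure maximum-likelihood
placement). The decision threshold itself is never tuned and stays at .99,
and reported detection metrics come from test recordings disjoint from both
training and calibration.

**Optimization.** Adam (`lr = 3e-3` in the package's experiments), batch 64,
best-epoch selection by validation F1. Two runs from the same seed are
bit-reproducible because every random draw flows from the seed stream.

## The closed loop

The simulation is event-driven (no wall-clock sleeping). A window's
classification becomes available at `window end + packet delay (100 ms) +
processing delay (100 ms)`; a positive decision emits a trigger unless one
fired within the preceding refractory interval (default 1.0 s, tied to the
1 s response deadline; the source never states its retrigger rule but shows
two triggers inside one ≈2.5 s discharge, which the default reproduces).
A trigger is tagged true- or false-positive with the label of the window
that fired it — the same ≥150 rule used for evaluation.

The trigger-to-stimulus *digital latency* is log-normal with median 68 ms
and `sdlog = 0.35`, chosen so the published per-trigger examples
(44.3, 63.0, 73.2 ms) fall inside the central 80% of the distribution; the
source states only the median. Reaction-time measurement starts at stimulus
onset, emulating the photo-sensor correction of the hardware loop.

The virtual subject draws baseline reaction times from a Gaussian
(default 550 ± 100 ms), adds `delta_rt_ms` during true bursts, and crashes
when the response exceeds the 1 s deadline; for the cognitive probes it
draws correct/incorrect/missed with per-state probabilities, with an
optional hook that raises the miss probability with burst duration. The
model-latency figure of the deployed system (≈99 ms median per window) is
documentation only and never asserted — it is a property of the original
hardware, not of this simulation.

## Effect statistics

All formulas operate at session level and mirror the published table notes:

* ΔRT = mean RT during bursts − mean RT during normal EEG, the baseline
  coming from responses to false-positive triggers (each patient is their
  own control); missed trials are excluded from RT means.
* IED-associated crash probability = crashes during bursts / bursts × 100;
  normal-EEG crash probability = crashes during normal EEG / false-positive
  triggers × 100; crash probability *due to* bursts is their difference and
  may be negative (the fixtures contain a −2.9% session; values are never
  clipped).
* Cognitive-probe percentages follow the same per-state/adjusted pattern.
* The cumulative crash risk is a logistic curve in ΔRT calibrated in closed
  form to the two published anchors — 20% at 100 ms and 50% at 150 ms. The
  original nonlinear equation lives in an unavailable appendix; the logistic
  family was chosen as the simplest strictly increasing curve through both
  anchors with risk → 0 as ΔRT → 0, and the anchors are replaceable
  (`risk_curve()`).
* Window-level sensitivity/specificity (and event-level sensitivity: the
  fraction of bursts with ≥1 trigger) are reported side by side; the source
  does not state which level its tables use.
* Cohort summaries report mean, sample SD (n−1), count of non-missing
  values (pairwise deletion, mirroring the printed Count row), the median
  (midpoint of the central pair for even n), and a conservative
  distribution-free 95% CI for the median from order statistics — the
  largest `l` with `pbinom(l-1, n, 1/2) ≤ .025` giving `(x_(l), x_(n-l+1))`.
  This construction reproduces every printed CI in both tables exactly.
* The paired Wilcoxon test drops zero differences and uses the exact
  signed-rank distribution for n ≤ 25 untied differences.

**Fixture reproduction.** `table_reproduction_report()` recomputes every
summary cell of the packaged tables and compares at printed precision with
half-up rounding. The cells that do not reproduce are whitelisted
explicitly and fall into three families: printed SDs whose convention is
internally inconsistent (several columns reproduce only with a population
denominator or with unrounded session values, others only with the sample
convention — the package reports sample SD throughout); the baseline-RT
column of the car-test table, whose printed summary is consistent only with
one printed session value being excluded; and three count cells that
disagree with the printed per-patient entries. Medians, means (one
excepted), and all printed CIs reproduce.

## Numerical choices and degenerate inputs

* Burst sample spans round half-up; presentation rounding is half-up too
  (R's `round()` is half-to-even and would disagree with the printed
  tables).
* Quantile ties share the bin of their largest rank; constant windows are
  legal and produce flat images.
* Empty transition-matrix rows stay all-zero rather than being imputed.
* Zero denominators (sessions without bursts or without false positives)
  yield missing values, never zeros; a session with no bursts leaves every
  burst-effect column missing.
* Sensitivity with no true positives in the truth is reported missing, not 0.
* The focal loss clamps probabilities at `1e-7`; the calibration logit
  transform clamps at the same bound.
* The 95% median CI does not exist for n < 6 at the conservative level and
  is reported missing.

## Problem sizes

The package's standing experiments, as run by the test suite and the
acceptance script: synthesis and detection on 20 recordings of 10 min at
2.2 bursts/min (13 training, 3 validation, 4 test recordings), the detector
trained for 12 epochs at batch 64 with 16/32-channel stages; reaction-time
recovery with injected prolongations of 20/60/100 ms at 100 trials per
state over 20 seeds; latency calibration over 10 000 draws. These sizes
were chosen so a full run completes on a single CPU core in well under half
an hour while keeping roughly 2 000 burst windows in training — enough for
the floor the package sets itself.

Under exactly these conditions the held-out window-level sensitivity of the
default detector at the ≥ .99 rule sits in the high .70s with specificity
≈ .99 (the acceptance script prints the exact values for its seed), and the
event-level sensitivity — the fraction of bursts receiving at least one
trigger — exceeds .9. The window-level misses concentrate in the weakest
bursts (80–110 µV against the 20 µV RMS background) and in windows that
only partially cover a burst; the package's own window-level floor of .85
is not reached by the default desk-scale model, which the test suite
reports as a failing check rather than hiding. The corresponding clinical
quantity in the emulated cohort spanned .57–1.00 per session with a median
of .90.

## Known limitations

* Single channel only, as in the pilot deployment; no spatial field model.
* The synthetic background contains no artifacts, so false-positive rates on
  synthetic data are far below the 2–3/min of clinical sessions.
* The desk-scale network plus calibration is not the deployed 34-layer
  system; published clinical performance figures are out of reach by design
  and are not asserted anywhere.
* The risk curve interpolates two published anchor points; outside
  roughly 0–200 ms of ΔRT it extrapolates.
* EDF support covers the package's own single-signal files, not arbitrary
  multi-signal EDF+.
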