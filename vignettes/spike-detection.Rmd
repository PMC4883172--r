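---
title: "Two-stage interictal spike detection: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage interictal spike detection: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegspike)
```

`eegspike` detects interictal epileptiform discharges — spikes
(pointed transients of roughly 20–70 ms) and sharp waves (70–200 ms) —
in single-channel EEG. This vignette is the package's own account of
the underlying models, the parameters that matter, the conventions we
had to fix where the method leaves room, and what the synthetic test
bed does and does not establish about clinical data. Everything here
can be reproduced from exported functions; the vignette states no
result the test suite or `scripts/acceptance.R` does not itself
compute.

## Signal model and preprocessing

The analysis trace is the pointwise mean of the channels on which the
events of interest are visible (`select_average()`); amplitudes are
microvolts everywhere, because the stage-1 thresholds are absolute
amplitudes in µV.

Preprocessing is notch → downsample → baseline:

* **Mains notch** (`notch_filter()`): second-order Butterworth
  band-reject, default 50 Hz with quality factor 30, applied
  forward-backward. Zero-phase filtering matters because the final
  assessment is latency-based — a causal filter would shift every
  vertex by its group delay. We apply the notch at the *original*
  sampling rate and downsample afterwards: at the 100 Hz analysis rate
  a 50 Hz notch sits exactly at Nyquist, where a band-reject design is
  degenerate. Doing mains removal first, decimation second, preserves
  the intent and is numerically well-posed. Both filters pad the trace
  by edge reflection before the forward-backward pass so boundary
  transients do not leak into the signal.
* **Downsampling** (`downsample_signal()`, default to 100 Hz):
  zero-phase low-pass at 90 % of the target Nyquist, then decimation
  (integer ratios) or interpolation onto the target grid. 100 Hz keeps
  the spike band (a 20 ms half-wave has most energy below ~25 Hz)
  while cutting the ambient dimensionality of stage 2 to 31.
* **Baseline correction** (`correct_baseline()`): segment means over
  1 s windows with 50 % overlap, assigned to segment centres, smoothed
  by a 5-point centred moving average, linearly interpolated and
  subtracted. Segment length, overlap and smoothing width are package
  conventions (configurable); 1 s is long against any spike and short
  against electrode drift. Zero-centring the local average is what
  licenses absolute amplitude thresholds in stage 1. Signals shorter
  than one segment fall back to global mean subtraction.

## Stage 1: the mimetic detector

Candidate vertices are local minima (spikes present with a pointed
negative phase on the clinically chosen montage; `--invert` handles the
opposite polarity). Two rules mimic how a reader discards noise peaks:

* minima closer than `min_separation` (100 ms) collapse to the deepest
  (ties to the earlier);
* minima with topographic prominence below `min_prominence` (10 µV)
  are ignored. The prominence floor is our operationalization of
  "small peaks in close proximity to larger peaks are ignored"; no
  numeric value is canonical, and 10 µV — twice a typical background
  RMS, half the smallest amplitude threshold — is configurable.

Around each vertex the waveform is the inclusive slice from 100 ms
before to 200 ms after (31 samples at 100 Hz). Half-wave features are
measured to the *closest prominent local maximum* on each side: the
same 10 µV prominence floor applies, because on sampled noisy data a
strict "closest local maximum" is almost surely a one-sample noise
wiggle adjacent to the vertex, which would report microvolt-scale
amplitudes for visually obvious spikes. If a half-window contains no
qualifying maximum, the segment's extreme sample stands in — keeping
the candidate alive is the sensitivity-preserving choice, consistent
with stage 1's philosophy of relaxed constraints. Indexing follows the
narrative order: half-wave 1 precedes the vertex, half-wave 2 follows
it.

Thresholds (A₁ ∈ [20, 500] µV, A₂ ∈ [50, 500] µV, D₁ ≤ 200 ms,
D₂ ≤ 150 ms) are compared inclusively — again the
sensitivity-preserving reading. Note a geometric consequence of the
window: the measured D₁ can never exceed the 100 ms pre-vertex extent,
so the D₁ bound cannot bind at the default window, and relaxing it
never changes the candidate set.

## Stage 2: embedding and classification

**Intrinsic dimensionality.** `estimate_intrinsic_dim()` implements
the Levina–Bickel nearest-neighbour maximum-likelihood estimator in
its corrected form (averaging inverse estimates over points, then over
neighbourhood sizes k ∈ [6, 12] — the range its authors recommend),
rounded to an integer ≥ 1. Coincident points would produce zero
neighbour distances; they are perturbed by machine epsilon with a
warning.

**Locality preserving projection.** `fit_lpp()` builds a symmetric
k-NN graph (k = 7; an edge exists when either endpoint lists the
other) with heat-kernel weights exp(−‖xᵢ−xⱼ‖²/t), t defaulting to the
mean squared k-NN distance, and solves X L Xᵀ α = λ X D Xᵀ α via
Cholesky reduction to a symmetric ordinary eigenproblem. Graph
construction details are not canonical for this method; these defaults
follow the standard LPP literature and are fully configurable, and the
resolved values are stored on the fitted model. Eigenvalues are kept
in *ascending* order (the locality-preserving convention). Two
normalizations make fits bit-reproducible: each eigenvector satisfies
αᵀ(X D Xᵀ)α = 1 and has a positive first nonzero component. A singular
X D Xᵀ (m < d, or collinear waveforms) is ridged by 1e-9·trace/d with
a warning. The out-of-sample map y = Aᵀx is exact and linear, so the
default training mode is *inductive* — the projection is learnt from
training candidates only, keeping cross-validation leak-free. The
*transductive* mode (embedding learnt from training and test waveforms
jointly, labels never used) reproduces the joint-matrix training
diagram literally and is available as `mode = "transductive"` /
`--transductive`.

**Classifier.** A class-weighted RBF support vector machine
(`e1071::svm`, i.e. libsvm — the maximum-margin solver is deliberately
a standard library; the package's contribution is the calibration
around it). Class penalties follow the inverse class-size ratio,
normalized so the mean per-sample penalty is `c_base`: the positive
class (tens of spikes) must not be swamped by thousands of nonspecific
transients. The kernel width follows γ = 1/(k·l·log l)². Two details
are underdetermined and fixed as package conventions, recorded in the
model metadata: the logarithm is *natural* (configurable to base 10),
and "the fraction of training samples contained in the kernel" is read
as the fraction of training *pairs* within one kernel radius 1/√γ —
a scale-free quantity computable from training data alone. The
constant k is solved by bisection (the pair fraction is monotone in
k) to the 0.20 target; because the pair fraction is a step function,
the achieved fraction is reported and a warning is raised if the gap
exceeds max(0.01, one pair). The formula is undefined at l = 1
(log 1 = 0), which the calibration rejects.

## Evaluation protocol

Markers are first realigned to the deepest negative deflection within
±50 ms (`realign_markers()`), mirroring how imprecise manual marks are
corrected; ties take the earliest sample. Matching
(`match_events()`) is greedy one-to-one by increasing |Δt| among pairs
within the 50 ms latency, ties broken toward earlier events. Greedy
matching is not guaranteed maximum-cardinality in pathological
overlaps (two detections crowding one marker while a second marker
goes begging); the property tests compare it against a brute-force
optimal matcher on small random instances and verify the counting
identities, one-to-one-ness and maximality on every input. Metrics use
the 0/0 → 0 convention. Cross-validation of stage 2 uses *stratified*
folds (unstratified draws would frequently leave a fold without any of
the rare positives) from a caller-supplied seed, fits embedding and
classifier per fold on training data only, and reports pooled counts
(the default) alongside per-fold and fold-averaged metrics, since
either summary is defensible.

## The synthetic test bed

`generate_dataset()` emulates the statistical structure the detector
faces, with every draw derived from one seed:

* **Background**: stationary AR(2) noise, default coefficients
  (0.5, −0.2) with 5 µV innovation SD (≈5.6 µV RMS) — a quiet,
  REM/light-sleep-like floor. A 1/f^a spectral option covers heavier
  slow activity; optional mains and linear drift test the
  preprocessing stages.
* **Spikes**: piecewise raised-cosine triphasic templates whose knots
  snap to the sample grid, so the requested A₁/A₂ are reproduced
  exactly and D₁/D₂ within one sample period by the package's own
  half-wave measurement. Default parameter ranges (A₁ ∈ [40, 120] µV,
  A₂ ∈ [60, 150] µV, D ∈ [30, 80] ms) sit inside the threshold pass
  region with typical clinical morphology. The vertex depth is
  −min(A₁, A₂)/2, keeping both flanking peaks positive.
* **Distractors** violate exactly one bound each, by a wide margin
  (e.g. A₂ ∈ [15, 25] µV against the 50 µV floor) so that measurement
  noise cannot carry them back across the threshold. The D₂ violation
  is a slow-rising transient (D₂ ≈ 300 ms at the low legal A₂) because
  a marginal duration violation is masked by vertex-localization
  error; the D₁ bound is untestable inside the default window (see
  above) and is not a distractor target.
* **Confounders** (off by default) are high-amplitude slower
  transients — vertex-wave / K-complex-like events, A ≈ 150–400 µV,
  D ≈ 85–140 ms — that *pass* every stage-1 bound. They are the
  realistic negative class for stage 2, which never sees
  threshold-violating transients in the full pipeline.

What passing tests show — and what they do not: the synthetic bed
verifies the mechanics (planted events are recovered, violations are
rejected, the embedding separates morphologically distinct classes,
the protocol is leak-free and seeded). It does not emulate sleep-stage
dynamics, movement/EMG artifacts, inter-subject morphology variation,
or backgrounds whose slow waves themselves satisfy the thresholds —
on real N3 sleep the stage-1 false-positive rate is far higher and
stage 2 carries correspondingly more weight. Clinical performance
claims require clinical recordings.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use sizes chosen to
exercise every code path at desk scale: 30-minute synthetic recordings
for stage-1 recovery, 2000-candidate sets (200 spikes / 1800
transients, mirroring the ~2 % positive rate of a real candidate
stream) for cross-validated stage 2, 1000-point manifolds for the
dimensionality estimator, and ≤ 30-column matrices for brute-force
eigen-oracle comparisons. Tolerances: LPP residuals and oracle
agreement at 1e-8 (double-precision eigensolvers), template round-trip
exact in amplitude and one sample period in duration, kernel-fraction
calibration ±0.01. Degenerate inputs have defined behaviour rather
than crashes: empty peak lists, single-class training, coincident
embedding points, and markers outside the signal all raise typed
errors; waveforms without full window context are dropped and logged,
not fatal.

## Known limitations

Single-channel only; the multi-channel extension (per-channel runs
plus spatiotemporal fusion rules) is out of scope. Only the LPP
back-end ships, though the embedding step is isolated behind
`fit_lpp()`/`lpp_transform()` so alternative reducers can be slotted
in. Classifier persistence uses RDS (a fitted libsvm object has no
faithful flat-text form); the embedding serializes to portable JSON.
The greedy matcher can differ from optimal assignment on adversarial
event layouts, as documented above.
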