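---
title: "Methods: wavelet-packet EEG features for sleep apnea classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet-packet EEG features for sleep apnea classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apneawave)
```

## The problem and the pipeline

Sleep apnea is conventionally diagnosed from overnight polysomnography.
This package implements an EEG-only screening pipeline that assigns a
binary label (apnea vs normal) to a subject from a single EEG channel
(typically C3-A2). The stages are:

1. **Ingestion** — read the channel from an EDF file, attach the class
   label from a sidecar CSV, and cut the signal into 30-second epochs (the
   sleep-scoring convention). Trailing partial epochs are discarded rather
   than zero-padded so all per-epoch coefficient vectors have equal length.
2. **Preprocessing** — a 50 Hz notch removes powerline interference.
3. **Sub-band decomposition** — a wavelet packet decomposition (WPD)
   splits each epoch into equal-width frequency bins, which are grouped
   into the five clinical EEG bands: delta (< 4 Hz), theta (4–8 Hz), alpha
   (8–13 Hz), beta (14–32 Hz), gamma (> 32 Hz, capped at Nyquist).
4. **Features** — per band, the Shannon wavelet entropy and the energy
   (10 features), plus four band-energy ratio indices: heart rate
   \(\theta/\alpha\), brain perfusion \(\alpha/\delta\), neural activity
   \(\beta/\theta\), synchronization \(\delta/\theta\) — 14 features per
   recording.
5. **Classification** — SVM (linear, RBF, polynomial order 2 and 3
   kernels) and a 150-tree random forest, evaluated with accuracy,
   sensitivity and specificity under a stratified 90/10 hold-out split and
   stratified 10-fold cross-validation.

## Notch filtering

The filter is a second-order IIR biquad notch designed from the center
frequency `f0` (default 50 Hz, configurable to 60 Hz for other mains
regions) and quality factor `q` (default 30, i.e. a ≈ 1.7 Hz wide notch),
applied forward–backward with `signal::filtfilt()`. Zero-phase application
keeps epochs phase-aligned for the decomposition; the filter order and Q
are deliberate defaults — only the presence of a 50 Hz notch is fixed by
the method, and both knobs are exposed in the configuration. No band-pass
or artifact-rejection stage is added.

## Wavelet packet decomposition

A WPD recursively filters *both* the approximation and detail branches
with the quadrature pair of a Daubechies wavelet (db8 by default; the
analysis high-pass is \(g[n] = (-1)^n h[L-1-n]\)), so depth \(L\) yields
\(2^L\) terminal nodes of nominal width \(f_s/2^{L+1}\) Hz. Boundary
handling is periodization: coefficients are computed by circular
convolution and dyadic downsampling, which makes the transform orthonormal
and the Parseval identity \(\sum_{\text{nodes}} \|c\|^2 = \|x\|^2\) exact
(to machine precision) whenever the epoch length is divisible by
\(2^L\); odd intermediate lengths are extended by repeating the last
sample, the usual periodization convention, at the cost of exactness in
the last digits. The conservation test uses 4096-sample epochs at level 6,
where the identity is exact.

Two subtleties matter more than the transform itself:

* **Frequency ordering.** The recursion emits nodes in filter-path
  (natural/Paley) order, which *interleaves* frequencies: decimating a
  high-pass branch mirrors its sub-spectrum, so the children of every node
  sitting at an odd frequency position are swapped. Unrolling the
  recursion, the natural index is the binary-reflected Gray code of the
  frequency position; `frequency_order()` applies the inverse (Gray
  decode) so node \(k\) covers \([k, k+1) \cdot f_s/2^{L+1}\). Skipping
  this step silently scrambles the band assignment — this is verified by
  tone probes at every bin center for each supported sampling rate.
* **Node-to-band assignment.** Each node is assigned to the band with
  which its interval overlaps most, ties broken toward the lower band;
  nodes above every band go to gamma, and a band entirely above Nyquist is
  empty. The same rule resolves the 13–14 Hz gap between the conventional
  alpha and beta edges.

### Decomposition depth

A literal 3-level tree has \(f_s/16\)-wide bins — 12.5 Hz at 200 Hz — in
which delta, theta and most of alpha share a single node and cannot be
separated, at any of the sampling rates of the public sleep databases
(100, 200, 512 Hz). The default depth is therefore `"auto"`: the smallest
\(L\) with bin width ≤ 2 Hz (level 5 at 100 Hz, 6 at 200 Hz, 7 at
512 Hz), which resolves every band boundary to within one bin. Level 3
remains available for a literal three-level run; it emits a warning that
adjacent bands share nodes. All terminal-node coefficient vectors of the
frequency-ordered tree feed the features, grouped by band; the
approximation branch is not treated specially (every terminal node at
depth \(L\) is a filtered version of the signal).

## Features

The entropy of a band is computed on coefficients normalized to unit
\(L_2\) norm, so \(q_i = c_i^2/\sum c^2\) is a probability distribution
and \(H = -\sum_i q_i \ln q_i\) (with \(0\ln 0 = 0\)) is the standard
Shannon wavelet entropy: nonnegative, bounded by \(\ln N\), and invariant
to amplitude scaling. The unnormalized form would be scale-dependent and
could go negative, which contradicts how the feature is used here. The
natural logarithm is the default base.

Band energy is the plain sum of squared coefficients; by Parseval it is
the signal power captured by that band. The four ratio indices divide
band energies; denominators carry an additive guard of `1e-12` so
degenerate inputs (an empty or silent band) yield finite ratios instead
of errors. Features are computed per epoch and averaged per recording —
one row per subject for the classifier, matching subject-level evaluation;
per-epoch rows are available via `extract_features(per_epoch = TRUE)`.

## Classification and evaluation

SVM features are standardized to zero mean and unit variance using
statistics from the *training* rows only (refit inside every
cross-validation fold), since the energy features span orders of
magnitude; the forest receives raw features. Hyperparameters are deliberate
defaults, all exposed: cost \(C = 1\), RBF/polynomial
\(\gamma = 1/14\) (on standardized features), polynomial `coef0 = 1`. The
random forest uses the ordinary bootstrap (about 63% of rows in-bag per
tree, the remainder providing the out-of-bag error), 150 trees.

The hold-out split is stratified with per-class training count
\(\lfloor 0.9\, n_c \rfloor\); for an 89-subject cohort of 57 apnea and 32
normal subjects this yields a 10-subject test set. Cross-validation is
stratified 10-fold with folds cycled across class blocks, so `k = n`
degenerates to leave-one-out. Accuracy, sensitivity (apnea = positive
class) and specificity are reported; an undefined ratio (e.g. no apnea
subject in a fold) is `NaN` with a warning rather than a silent zero, and
fold means skip `NaN` values per metric. Whether headline figures should
come from the single split or from cross-validation is left to the user:
both are always computed and reported separately in `metrics.json`.

## The synthetic cohort generator

`generate_cohort()` emulates labeled single-channel recordings as sums of
band-limited Gaussian noise: per band, white noise filtered to the band's
range (order-4 zero-phase Butterworth; low-pass for delta, high-pass for
the Nyquist-capped gamma) and rescaled so its RMS is proportional to
\(\sqrt{\text{band power}}\), plus an optional 50 Hz mains sinusoid and
broadband white noise. Gaussian noise rather than pure tones keeps the
entropy features informative. Defaults are one fixed choice of study
conditions: 200 Hz sampling, 60 s per recording (two epochs), white-noise
sd 0.2, and a class contrast in which apnea-like recordings carry elevated
delta/theta power (4, 2, 0.5, 0.3, 0.1 across the five bands) and normal
recordings elevated alpha/beta power (1, 0.8, 2.5, 1.5, 0.3), with
per-recording lognormal jitter (sdlog 0.25) so features vary within class.
`cohort_profiles(separation)` interpolates between this contrast and its
class-free midpoint, which the monotonicity tests use as a separability
dial.

The contrast direction loosely mirrors the slow-wave shift reported for
disordered sleep, but it is an explicit synthetic convention, not a
physiological claim. The generator reproduces none of the structure of
real sleep EEG — no stages, spindles, K-complexes, artifacts, or apnea
event morphology — so a classifier that separates these cohorts
demonstrates that the pipeline's plumbing, features and evaluation are
correct, not that the method attains any particular clinical accuracy.

## Problem sizes and numerical choices

The test and acceptance workloads use a 40-recording cohort (20 per
class, 60 s each), 4096-sample epochs for the conservation checks, and
small 2–4-recording cohorts for the orchestration and determinism checks;
these sizes were chosen so the full validation cycle stays interactive
while every statistical check retains clear margins. Seeds are threaded
explicitly through every random step (splits, folds, forests, generator),
with each cohort member drawing from its own derived seed, so any run is
reproducible bit-for-bit from a single integer; repeated pipeline runs
produce byte-identical feature CSVs and metrics JSON. A single label
permutation's cross-validated accuracy has noticeably more variance than
a binomial draw (folds share training rows), so the chance-level check
averages over five permutations before comparing against the 95% binomial
interval around 0.5.

## Known limitations

* EDF support covers continuous recordings (EDF, not EDF+D), which is
  sufficient for the targeted sleep databases.
* Labels are taken from the sidecar table as given; no annotation
  parsing, sleep staging, or apnea–hypopnea index computation.
* No best-basis or undecimated wavelet variants; the full fixed-depth
  tree only.
* No hyperparameter search or probability calibration; reported metrics
  are accuracy, sensitivity and specificity only.
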