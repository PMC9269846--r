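---
title: "Sparse-coding classification of 12-lead ECG records: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-coding classification of 12-lead ECG records: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ecgpursuit)
```

## Overview

`ecgpursuit` implements a classical (non-deep-learning) pipeline for
classifying 10-second, 500 Hz, 12-lead ECG records by cardiac disease
class. The stages are:

1. **R-peak consensus detection.** Three single-lead detectors (two
   moving average, Christov adaptive threshold, Engelse–Zeelenberg with
   an adaptive-threshold modification) run on every lead, giving up to
   36 candidate peak lists. The beat count is estimated as the median of
   the 36 per-list counts, and peak positions are the centers of a 1-D
   k-means clustering of all pooled detections with k set to that
   median.
2. **QRS segmentation.** The record is cut at the midpoints between
   consecutive R-peaks; the first and last (boundary) segments are
   discarded, so each retained segment holds exactly one QRS complex,
   approximately centered. Each segment is linearly resampled to a fixed
   length L.
3. **Sparse coding.** Each segment is decomposed by Orthogonal Matching
   Pursuit (OMP) against a dictionary of unit-norm atoms — a parametric
   Gabor grid, a dictionary learned by alternating minimization (method
   of optimal directions, MOD), or one learned by KSVD.
4. **Aggregation and classification.** Per-segment coefficient vectors
   are collapsed to one record-level feature vector (`single`, `mean`,
   `max`) or kept per segment and combined at prediction time by
   probability averaging (`voting`), optionally concatenated with the
   raw resampled signal and record metadata (sex, age, BPM, resampling
   ratio), then fed to a classical classifier.

A synthetic 12-lead generator with exact R-peak ground truth makes every
stage testable without any data download.

## The synthetic generator and what it does (not) model

Each beat is a sum of five Gaussians (P, Q, R, S, T waves) with
per-wave amplitude (mV), center offset relative to R (s) and width (s),
plus an optional wide Gaussian between S and T that renders an
ST-level shift. A single cardiac source is projected onto 12 leads
through fixed positive weights; each lead then receives independent
baseline wander (0.05 mV at 0.25 Hz by default) and white noise
(0.02 mV by default). Beats are placed at RR intervals of
`60 * fs / bpm` samples with ±5% seeded uniform jitter; the first beat
sits half an interval into the record and a 150 ms end margin keeps the
final beat fully observable.

Class definitions perturb the template in caricature of the five
diagnostic superclasses of clinical 12-lead datasets: deepened Q,
reduced R and ST depression (infarction-like), ST elevation with
T-wave inversion (ST/T-change-like), QRS widening (conduction-
disturbance-like), and increased R and T amplitude (hypertrophy-like).
The 15-class variant grades each perturbation at three severities with
per-grade R/T signatures; the 2-class variant is normal versus a
combined abnormal morphology. `default_class_specs()` asserts at build
time that the mean pairwise RMS distance between noiseless class
templates exceeds five times the noise standard deviation, so
classification sanity checks downstream are meaningful.

What the generator does **not** model: genuine pathophysiology, rhythm
disorders (RR structure beyond jitter), inter-patient morphology
variability, electrode artifacts, or lead inversions. Passing tests on
synthetic data therefore demonstrate the *correctness of the pipeline
mechanics* (detection, segmentation, coding, aggregation, evaluation),
not clinical performance; real-data accuracy must be established on a
clinical corpus read through `load_metadata()` / `filter_records()` /
`load_signals()`.

## Detector settings

The three detectors follow their published designs with the tunables
pinned in an internal configuration block: two-moving-average uses an
8–20 Hz band-pass, 120 ms QRS window versus 600 ms beat window plus an
offset of 0.15 times the mean rectified amplitude, 80 ms minimum block
width, 300 ms refractory; Christov uses 20/28/40 ms moving averages, an
M + F + R combined adaptive threshold and 200 ms refractory; the
Engelse–Zeelenberg variant uses the `x[n] - x[n-4]` differentiator, the
[1 4 6 4 1] FIR smoother, a 160 ms positive-to-negative search window,
a 10 ms sustained negative excursion, and an adaptive threshold with
the same 200 ms hold / 1200 ms decay schedule as Christov. Threshold
crossings on delayed envelopes are refined to the dominant deflection
of the baseline-corrected raw lead nearby. The first and last 100 ms of
every lead are excluded from candidates (filter transients; the
segmentation stage discards boundary segments anyway).

## Consensus design

Pooling *all* (detector, lead) results — including empty ones, which
vote a count of zero — makes the beat-count estimate a median over 36
weak estimates, robust to one systematically failing detector or a flat
lead. The median uses the lower middle value on even-length lists:
under-counting merges clusters (benign), over-counting splits true
beats.

For localization, the package solves the 1-D k-means problem **exactly**
by dynamic programming over the sorted pool (optimal 1-D clusters are
contiguous, giving an O(k·n²) exact algorithm). This is deterministic
and never worse than an iterative scheme; at consensus pool sizes
(≤ ~1000 points) it is also fast. We chose exactness over classic Lloyd
iteration because detector disagreement produces clusters of unequal
population, exactly the regime where Lloyd with any fixed deterministic
initialization measurably lags the optimum. For pools beyond 2000
points a Lloyd fallback with quantile initialization and deterministic
merge–split refinement is retained. Cluster centers are rounded to
integer samples, deduplicated (reducing k if needed), and an annotation
is usable when k ≥ 3 — the minimum for one retained segment.

## Segmentation choices

The resampled length defaults to L = 128: shorter than the smallest
plausible RR interval at 500 Hz (≈136 samples at 220 BPM), a power of
two, and small enough to keep dictionaries compact. Interpolation is
linear (`resample_to_length()`), isolated behind one function; segments
are half-open `[m_{j-1}, m_j)` in 1-based sample indexing. The
per-record "resampling ratio" metadata is the mean of per-segment
ratios (original length / L); BPM is `60 * fs / mean RR`.

## Dictionaries

* **Gabor**: Gaussian-windowed cosines over a deterministic grid — five
  scales in a geometric ladder from L/32 to L/2, eight translations,
  equispaced frequencies in [0, 0.25] cycles/sample, phases {0, π/2} —
  enumerated lexicographically, with zero-norm atoms (zero frequency at
  quadrature phase) and near-duplicates skipped. The frequency count
  starts at `ceil(K/80)` and expands deterministically until K distinct
  atoms exist (the base grid loses exactly 40 atoms to the zero-norm
  rule, so e.g. K = 125 needs one extra frequency level).
* **MOD** (`learn_dictionary_mod`): alternate OMP coding of all training
  columns with the global least-squares dictionary update
  `D ← X Cᵀ (C Cᵀ + 1e-8 I)⁻¹`, column renormalization with
  compensating code rescaling, and replacement of unused atoms by the
  worst-reconstructed training column.
* **KSVD** (`learn_dictionary_ksvd`): same outer loop, but atoms update
  one at a time from the rank-1 SVD of the residual restricted to the
  signals using that atom.

Both learners initialize from a seeded permutation of the training
columns, greedily selecting K mutually incoherent normalized columns —
seeding two atoms on near-identical columns is the main cause of
duplicate-atom local minima. Three further stabilizers are standard
practice: (i) the coding step keeps, per training column, whichever of
the fresh OMP code and the previous iteration's code reconstructs
better under the current dictionary, which makes the coding step
non-increasing in the objective (greedy OMP alone has no such
guarantee); (ii) unused atoms are re-seeded at the worst-reconstructed
training columns; and (iii) atoms that collapse onto an earlier atom
(mutual coherence above 0.95) are likewise re-seeded. The Frobenius
objective is recorded once per iteration after the dictionary update.
Training data for learned dictionaries is a seeded subsample of
training-split segments only (default cap 20,000), never validation or
test — dictionary learning is a fitted component and is kept inside
the training fold.

## OMP numerics

Ties in the correlation step break toward the lowest atom index
(determinism). The active-set least squares uses a QR factorization;
an atom whose addition makes the active set numerically rank-deficient
(possible among near-duplicate Gabor atoms) is skipped in favor of the
next-best candidate. The relative early-stop tolerance defaults to
1e-7 so it never bites at the working sparsity levels (T = 5…40).

## Aggregation and metadata

`max` aggregates the *absolute* coefficient value (unsigned output);
`mean` aggregates signed values. Flattening is lead-major:
`index = (lead - 1) * K + atom`, fixed once and documented. Feature
blocks always concatenate in the order signal → coef → meta regardless
of request order. Sex is encoded 0/1 and age passes through unscaled —
the tree ensembles used by default are scale-free, and the adapters
that are not (k-NN, MLP) standardize internally.

## Experiment harness

Records split 70/15/15, stratified by class (the 15-class task has
small classes; stratification keeps every class represented in each
fold), with largest-remainder rounding so per-class proportions stay
within one record of the global fractions; splits are by record, not
by patient (the synthetic generator has no patient identity; for real
data this is a caveat worth knowing). Each experiment repeats over a
seed list (3 by default) and reports the across-seed mean of accuracy,
macro precision/recall/F1 and balanced accuracy (= macro recall; for
two classes the positive-class formulas are used). The validation
split is evaluated and returned per seed for model selection within
sweeps; the test split is touched only for the final metrics.
Classifier adapters wrap installed implementations (ranger, xgboost,
e1071 SVM and naive Bayes, rpart, caret k-NN, nnet MLP) with pinned
settings and single-threaded, seeded fits so a full run is
deterministic for a fixed configuration.

The voting aggregation trains the base model on the union of
per-segment vectors (records therefore weight the fit by their segment
counts — documented behavior) and predicts by averaging per-segment
class probabilities, ties toward the lowest class index.

## Problem sizes used by the tests and the acceptance script

The shipped verification uses synthetic corpora of 200 records
(5-class, 40 per class; also relabelled normal-vs-other) and 150
records (15-class, 10 per class), a 50-record noisy benchmark for the
consensus detector comparison, 20 random instances for the OMP
exhaustive-oracle check, and 5 seeds of the 64×32 planted-dictionary
recovery. These sizes were chosen to exercise every code path at
statistically meaningful scale while keeping a full run in the
minutes range on one CPU core.

## Known limitations

* Synthetic morphology is a caricature; class separability is by
  construction, so end-to-end accuracies on synthetic data are upper
  bounds on mechanism correctness, not clinical estimates.
* WFDB support covers format 16 (the format used by the target
  500 Hz corpus); int16 quantization bounds round-trip fidelity at
  half an LSB (1.25e-4 mV at the writer's gain of 4000 ADU/mV).
* No LightGBM or AdaBoost adapters (no installed R implementations);
  the registry accepts user-supplied adapters under the same contract.
* The Hamilton, Pan–Tompkins and wavelet detectors are not shipped;
  `register_detector()` accepts any function under the single-lead
  contract.
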