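---
title: "Frustum154: model, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frustum154: model, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frustum154)
```

## The problem and the model

Two-channel surface EMG of a grasp carries class information in both its
amplitude envelope and its spectral content. Frustum154 turns one labeled
trial into a large bank of hand-modeled features and then lets two
data-driven selection stages — a per-source loss ranking and an iterative
NCA sweep — decide which of them matter. Nothing in the feature generation
is trained; only shallow classifiers are fit, so the model runs on
commodity hardware and remains fully inspectable.

The pipeline, as implemented by `frustum154()`:

1. channel concatenation, `x = [ch1, ch2]`;
2. tunable Q-factor wavelet transform (TQWT) under four parameterizations,
   giving 153 subbands;
3. 414 features per source (384 frustum-pattern counts + 30 statistical
   moments) for the raw signal and each subband — 154 sources;
4. per-source column-wise min-max normalization;
5. per-source cross-validated misclassification under 1-NN (L1) and a
   cubic SVM; the family with the lower mean loss is kept, and the 20
   lowest-loss sources are merged into a 8280-column matrix;
6. NCA feature ranking plus a prefix-size sweep (INCA) picks the final
   feature subset;
7. the chosen classifier is cross-validated on the selected features.

## The frustum pattern

Each 49-sample window is reshaped row-major to a 7×7 matrix. The two
hexagons of a frustum and their connecting edges define three closed
six-edge walks over fixed grid cells; each directed edge `(a, s)` is
binarized twice, by an upper and a lower ternary comparator with the
signal-global threshold `d = sd(x)/2`. Zero differences and differences
inside `[-d, d]` yield 0 in both kernels, so the code of a flat region is
0. Six bits weighted `2^(j-1)` give one code in 0–63 per (graph, kernel);
histogramming the six code sequences yields 384 counts.

Two properties are useful for checking correctness and worth knowing when
interpreting features. The pattern is *invariant under positive affine
transforms* (`a·x + b`, `a > 0`): differences and the threshold scale
together, so electrode gain and offset do not move the features. And
*negating* the signal exactly swaps the upper- and lower-kernel histograms
of every graph. Both are enforced by tests, together with equality against
a naive per-window reference implementation.

Choices the definition leaves open, fixed here:

* **Fill order** of the 49 samples into the 7×7 grid: row-major.
  Any fixed order is internally consistent; row-major matches the natural
  index iteration.
* **Threshold scope**: `d` is computed once per source (signal or
  subband), not per window — "half of the standard deviation of the
  signal" reads as a global quantity.
* **Standard-deviation convention**: sample (`n − 1`), configurable via
  `sd_type = "population"`. Only codes at the exact `±d` boundary can
  differ between the two conventions.
* **Histogram order**: bottom-1, bottom-2, top-1, top-2, connection-1,
  connection-2; counts, not densities.

## TQWT

The transform is the radix-free frequency-domain two-channel filter bank:
at each level the current low-pass band of length `N` is split into a
low-pass band of length `2·round(α^j N/2)` and a high-pass band of length
`2·round(β α^(j−1) N/2)`, with Daubechies transition responses
`θ(ω) = ½(1+cos ω)√(2−cos ω)` satisfying `θ² + θ̃² = 1` on the overlap.
Under the unitary DFT normalization used here the frame is exactly
Parseval-tight, and synthesis is the adjoint, giving perfect
reconstruction to machine precision (tests require ≤ 1e−8 relative
max error and ≤ 1e−6 relative energy error; observed ≈ 1e−15).

Numerical details:

* Subband lengths are always derived from the *original* length, so
  analysis and synthesis agree on every rounding.
* Odd-length inputs are zero-padded by one sample; the pad is recorded in
  the subband object and dropped on reconstruction. (Both benchmark trial
  lengths, 6000 and 5000 concatenated samples, are even.)
* `J` is validated against `J_max(N) = ⌊log(βN/8)/log(1/α)⌋`; violations
  report both values.
* Because the frame is tight but *redundant*, reconstructing from a single
  band preserves energy only when that band's spectrum avoids the
  transition region; the test uses a DC-supported low-pass band, the
  canonical such case.

The four parameter sets (Q = 1..4, r = 2Q, J = 6/24/46/73) give
7 + 25 + 47 + 74 = 153 subbands. On 6000-sample inputs the deepest bands
hold ≈ 50–60 samples, so every source admits the 49-sample window; for
much shorter inputs the frustum half of a short band is computed on a
zero-padded copy with a warning (a guard for toy inputs only).

## Statistical features

The fifteen moments are computed on the raw source and on its absolute
value. The three entropies follow the unnormalized wavelet-entropy family
(squared-coefficient forms), the natural convention for wavelet
coefficients: Shannon `−Σ x²log x²`, log-energy `Σ log x²` (with
`0·log 0 := 0`, `log 0 := 0`), and SURE
`n − #{|x| ≤ ε} + Σ min(x², ε²)` with `ε = 3` by default. Kurtosis is the
Pearson (non-excess) population form, skewness the population third
standardized moment. The Higuchi fractal dimension uses `kmax = 10` and
returns 1 for constant signals by convention; its implementation is the
standard curve-length regression, validated against the known limits
(ramp → 1, white noise → 2). "Root mean square error" is interpreted as
the signal RMS, as no reference signal exists in this context.

## Selection stages

**Per-source losses.** Normalization precedes scoring (the pipeline's
step order), and scoring uses labels on the full dataset with stratified
k-fold CV — faithfully the original procedure, which selects inside the
same cross-validation universe. This is optimistic relative to nested
selection; for honest generalization estimates use `predict()` on records
the fit has never seen (the package's tests do exactly that).

**Greedy family choice.** `classifier = "auto"` keeps the family (1-NN or
cubic SVM) with the lower mean loss across all 154 sources, and uses it
for the INCA sweep and final classification. Rank ties are broken toward
the smaller source id.

**NCA.** The diagonal feature-weighting form with the weighted L1 distance
`d_ij = Σ_k w_k²|x_ik − x_jk|` — L1 to match the pipeline's 1-NN — and
soft-neighbour probabilities `p_ij ∝ exp(−d_ij/σ)`. Two scaling choices
make the optimization dimension-robust:

* `σ` defaults to the mean initial pairwise distance, so the soft
  assignments are neither saturated nor uniform regardless of `p`;
* the ridge penalty is `λ·mean(w²)` (λ = 1/n by default). With a sum-form
  penalty and thousands of features the penalty would dwarf the bounded
  leave-one-out term at the all-ones start and the only ascent direction
  would be uniform shrinkage, destroying the ranking; the mean form keeps
  the two gradients commensurate at every dimensionality.

Optimization is deterministic full-batch gradient ascent with
backtracking, a 100-iteration budget and a seeded ±1e−6 jitter on the
initial weights. Pairwise absolute differences are precomputed in feature
chunks so peak memory stays bounded (about `n²·p` doubles overall; ~150 MB
at n = 48, p = 8280).

**INCA sweep.** Sizes 100–512 by default, clipped to `[1, p]` (when the
lower bound exceeds `p`, the sweep starts at 1). `inca_stride` trades
sweep resolution for time; the default is every integer size. Folds are
fixed across sizes, and ties in the loss curve go to the smaller size.

**SVM kernel scale.** "Auto" divides the features by the median pairwise
L1 distance of a seeded subsample (≤ 1000 rows) before the degree-3
polynomial kernel `(1 + ⟨u, v⟩)³` with C = 1 and one-vs-one coding — a
documented approximation to environment-specific heuristics; a fixed
numeric scale can be supplied instead.

## The synthetic generator

`synth_dataset()` emulates what matters to this pipeline about sEMG:
band-limited colored noise with class-dependent spectral peaks and an
amplitude envelope. Each class is an AR(4) process (two complex pole
pairs, radii 0.92/0.85, angles spread across classes by `separation`
within the typical sEMG band) with unit-variance Gaussian innovations,
multiplied by a Hann-based envelope with a class-specific weight —
sEMG is commonly modeled as amplitude-modulated colored noise. Generation
is bit-reproducible from `seed` and leaves the caller's RNG untouched.

What it does **not** emulate: inter-subject variability, electrode-shift
and motion artifacts, non-stationarity within a trial beyond the fixed
envelope, power-line interference, and cross-channel correlation
structure. A perfect score on synthetic data therefore demonstrates the
pipeline's mechanics (determinism, separability given spectral structure),
not field performance; the latter is what `examples/replicate_uci.R`
assesses on the public recordings.

## Problem sizes and defaults

The package defaults reproduce the published configuration: four TQWT
parameterizations as above, top-20 merge, INCA range [100, 512], 10-fold
CV, 1-NN (k = 1, Manhattan, no weighting) and cubic SVM (C = 1). The test
suite exercises the full pipeline on 48 synthetic trials of 5 s per
channel (concatenated length 5000, the shortest length at which all 153
subbands still hold ≥ 49 samples), with 4 folds, an INCA stride of 32 and
a 60-iteration NCA budget — sizes chosen so the whole suite runs in a few
minutes while every stage executes on realistically shaped data.

## Known limitations

* The per-source loss ranking and INCA both see all labels; reported
  cross-validated accuracy is a model-selection criterion, not an unbiased
  generalization estimate.
* The MAT-file reader covers real 2-D numeric arrays of the level-5
  format (plain or zlib-compressed); v7.3/HDF5 files are rejected with a
  pointer to re-saving as level 5.
* Subbands shorter than 49 samples are zero-padded for the texture half
  only; with the default parameters this cannot occur on benchmark-length
  trials.
* Exact reproduction of published accuracies additionally depends on fold
  assignment, the std convention at the ternary boundary and the SVM
  kernel-scale heuristic, none of which are fully specified by the
  method's description; all three are exposed as arguments.
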