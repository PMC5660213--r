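---
title: "Metric learning on HSQC spectra: model, training protocol and evaluation"
author: "hsqcsiam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metric learning on HSQC spectra: model, training protocol and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A 1H–13C HSQC spectrum is a two-dimensional map of the directly bonded
C–H pairs in a molecule: each cross-peak sits at the proton shift
(horizontal, ppm) and carbon shift (vertical, ppm) of one C–H group. Because
most natural products have tens of protonated carbons and shifts are
resolvable to roughly 0.02 ppm (1H) and 0.1 ppm (13C), the spectrum acts as
a structural fingerprint: `grid_capacity(0.5, 9.5, 0.02, 10, 215, 0.1)`
counts 922,500 distinguishable cross-peak positions over the typical shift
windows. Dereplication — recognizing that a freshly isolated compound is a
known molecule or a close analogue of one — can therefore be phrased as
similarity search over HSQC spectra.

`hsqcsiam` implements that search as *metric learning*: a weight-sharing
(siamese) convolutional network maps each rasterized spectrum to a point in
a K-dimensional cluster space, trained so that spectra of structurally
related compounds (a *compound family*) lie close and unrelated spectra lie
far. Retrieval, cluster maps and all evaluation protocols operate on
Euclidean distances in that space.

## Input representation

Spectra enter the network as binary rasters (`spectrum_image`): foreground
(1) marks signal and noise, background (0) the empty spectral plane.
Orientation follows NMR convention — 1H shifts increase right-to-left, 13C
shifts top-to-bottom. The preprocessing chain is:

1. grayscale PNG loading with darkness normalized to [0, 1] (`load_spectrum_image`);
2. thresholding at 0.5 normalized darkness (`binarize`); the threshold is
   configurable because plot styles differ, 0.5 is the natural midpoint;
3. a cross-shaped 3×3 median filter (`median_filter_cross`) that removes
   isolated salt-and-pepper pixels while preserving contiguous peak
   footprints. Border pixels use edge replication; with a binary input the
   5-element median is simply a majority vote, so the operation is exact
   and idempotent-friendly.

Peak lists (CSV of 1H/13C shifts) are rasterized through the same axis
calibration: the default windows are 1H ∈ [0, 10] ppm and
13C ∈ [0, 182.857] ppm, so a 512-px raster realizes 51.2 px/ppm (1H) and
2.8 px/ppm (13C). The carbon window is genuinely uncertain — the stated
densities cover only ~183 ppm of the 10–215 ppm range carbons occupy — so
both window and raster size are configurable and all code derives pixel
positions from the calibration object. The ppm→pixel map uses half-open
floor binning with the exact upper boundary clamped into the last bin;
`rasterize_peaklist` paints a square footprint (default 3 px) per peak.

## The embedding network

`architecture_spec` fixes the embedding function \(G_W\): four
convolutional layers (8, 16, 16, 16 filters of 4×4, stride 1) each followed
by 4×4 max-pooling with stride 2, then three 128-unit fully connected
layers with dropout 0.5, and a final K-unit layer (default K = 10). Every
layer applies the hyperbolic tangent, including the output, so embeddings
live in \([-1,1]^K\) and no two spectra can be farther apart than
\(2\sqrt{K}\). Batch normalization follows every linear map except the
output layer. Design points the architecture table leaves open, resolved
here once:

* **Convolution padding** — size-preserving ("same") padding, with the
  asymmetric 1/2 split a 4-wide kernel requires; pooling is unpadded. At
  512 px input the map sides are 255/126/62/30; `input_side` is
  configurable and the flattened size adapts (four unpadded pool stages
  need at least 46 px of input).
* **Batch-norm placement** — after the linear map, before the tanh.
* **Initialization** — Xavier: zero-mean Gaussians with variance
  \(2/(\mathrm{fan_{in}}+\mathrm{fan_{out}})\); biases zero. Biases feeding
  a batch-norm layer are redundant (the mean subtraction absorbs them) and
  provably receive zero gradient; they are kept for the output layer where
  they are meaningful.

Training minimizes the margin-based contrastive (spring) energy over pairs:
for embedding distance \(d\) and margin \(m\) (default 1),

\[
L = \tfrac12 \max(0, d - m)^2 \ \text{(same family)},\qquad
L = \tfrac12 \max(0, m - d)^2 \ \text{(different families)} .
\]

The margin appears on *both* branches: same-family pairs are pulled until
they sit within \(m\), different-family pairs pushed until they are at
least \(m\) apart, and inside those regions the loss is flat. The margin is
a genuine hyperparameter with no canonical value; 1.0 is the package
default, sitting well inside the attainable distance range
\([0, 2\sqrt{K}]\).

The engine (in `src/nn.cpp`) implements forward and backward passes
explicitly: im2col convolution through BLAS GEMM, batch-norm with full
batch-statistics gradients, overlapping max-pool with argmax routing, and
inverted dropout. Because tanh is monotone increasing, pooling is applied
to the pre-activation and tanh to the pooled values — an exact identity
that avoids computing the activation over the full-resolution map. The
engine is templated on the floating type: single precision is the training
default (the large feature-map GEMMs dominate), and a double-precision
instantiation of the same code backs the finite-difference gradient
verification in the test suite (relative agreement better than 1e-4 at
step 1e-6 on smooth inputs; binary inputs put many exact ties inside pool
windows, where the loss is non-differentiable and finite differences are
not meaningful).

## Training protocol

* **Pairs** — every mini-batch is exactly half positive (two distinct
  spectra of one family, uniform over eligible same-family pairs) and half
  negative (spectra of different families), sampled with replacement;
  `batch_size` counts pairs and must be even.
* **Optimizer** — Adagrad with initial learning rate 0.001:
  the squared-gradient accumulator grows monotonically, so per-coordinate
  steps shrink automatically.
* **Cross-validation** — one random shuffle, 8:1:1
  train/validation/test; across 10 folds every spectrum is tested exactly
  once (`make_folds`, `crossvalidate`).
* **Early stopping** — every `eval_interval` iterations the validation
  spectra query the training corpus and the area under the retrieval
  precision–recall curve ("validation average precision") is recorded;
  training keeps the best-scoring weights, with batch-norm running
  statistics frozen at that checkpoint, and stops after `patience`
  evaluations without improvement. Dropout and batch statistics are active
  only in training passes; all evaluation embeddings are deterministic.

Desk-scale defaults: the packaged benchmarks train with batches of 32
pairs on 128-px (or 64-px) rasters for at most a few hundred iterations —
sizes at which the protocol, not the scale, is the object under test.
Full-scale corpora would use the reference values (batch 256, 512-px
input, thousands of iterations).

## Synthetic corpus generator

No public HSQC corpus with family labels exists (the original training
images were hand-curated from journal supplements), so the package ships a
generative stand-in whose statistical structure mirrors what matters for
metric learning:

* **Templates** — each family is a peak list drawn uniformly in the shift
  windows with a minimum inter-peak separation of two footprints, 8–30
  peaks (typical protonated-carbon counts).
* **Family sizes** — truncated geometric over [5, 25]: most families near
  the 5-member minimum, few near 25, matching the right-skewed membership
  distribution of real family-labelled corpora.
* **Members** — per spectrum, each template peak is dropped with
  probability 0.1 (functional-group changes remove C–H correlations),
  survivors are jittered by Gaussian ppm offsets (0.03 ppm 1H, 0.3 ppm 13C
  — the order of solvent-induced shift changes), Poisson(1) spurious peaks
  are added, and 0.2 % of pixels are flipped (salt-and-pepper) before the
  standard median filter.
* **Noise protocol** — spectral noise for the robustness experiment is an
  i.i.d. Gaussian matrix passed through a 2D FFT; its magnitude field is
  thresholded at the (1−fraction) quantile and the pixels above it are
  flipped, so the realized noise intensity is exactly the altered-pixel
  fraction — the same measure used to report it. The schedule is an
  arithmetic progression (default 140 levels, re-randomized 100 times:
  14,000 noisy spectra per compound; the top level flips half the raster).
  How the original real-valued noise matrix was combined with binary
  spectra is not specified anywhere; quantile-thresholded flips are this
  package's reading, chosen because they reproduce the published intensity
  measure exactly.

Everything is reproducible bit-for-bit from a master seed via counter-based
seed splitting (`derive_seed`), so any single spectrum can be regenerated
in isolation.

**What the generator does not emulate:** real lineshapes and J-coupling
multiplets, t1-noise ridges, solvent peaks, correlated shift changes from
shared substructures, or the fact that real family members are different
molecules rather than perturbed copies of one template. Passing the
packaged benchmarks therefore demonstrates that the pipeline learns and
evaluates correctly under controlled family structure — not that it
reaches any particular accuracy on real spectra.

One consequence deserves emphasis: with sub-pixel shift jitter at
desk-scale raster sizes, synthetic family members are *near-duplicate
images*, which makes the linear pixel-space PCA baseline exceptionally
strong (PR-AUC near 1). Real corpora, where within-family image variation
is large, are precisely the regime in which the learned embedding
outperforms the linear baseline; the synthetic benchmark records both
numbers side by side rather than claiming that ordering.

## Evaluation battery

All protocols live in `embedding_eval`-style functions and are verified
against brute-force enumerations in the test suite:

* `precision_recall_curve` — for each query, corpus spectra are retrieved
  inside an expanding hypersphere (equivalently, in distance order);
  precision = TP/(TP+FP) and recall = TP/(same-family corpus count) at
  every rank. Per-query curves are step-interpolated onto a fixed 101-point
  recall grid (the averaging scheme is unspecified in the source protocol;
  a common grid is the standard choice), averaged, and integrated by
  trapezoid. Queries are excluded from their own corpus; queries whose
  family is absent are skipped with a warning.
* `accuracy_vs_radius` — fraction of true family co-members within radius
  r of each node, averaged over nodes; non-decreasing in r.
* `closest_retrieval_curve` — corpus neighbours collapsed to distinct
  family labels in first-occurrence order give a ranked list of family
  predictions; the curve is the fraction of queries whose family appears
  in the top k. The `mo_baseline_curve` comparator predicts families in
  descending member count (ties broken by label), independent of the
  query.
* `pca_baseline` — pixel-space PCA to k = 10 dimensions, the linear
  comparator.
* `noise_experiment` — distances between noisy and clean embeddings per
  schedule entry, in the K-dim space or the 2D PCA cluster-map projection
  (the published distance axis is ambiguous between the two, so both are
  supported and the space is recorded in every result row; K-dim is the
  default).
* Ties everywhere break by ascending spectrum id, making every ranking
  permutation-invariant and bit-reproducible.

## Standard seeded experiments

`run_retrieval_benchmark` (20 families × 8 members, 128 px, batch 32,
at most 150 iterations with early stopping on a 25-iteration evaluation
grid) trains one fold and reports test PR-AUC for the siamese embedding
and the PCA baseline. `run_novel_family_experiment` derives a structurally
similar "sibling" of one family, withholds it from training entirely, and
checks that its members embed nearer the sibling cluster than the median
unrelated family — the novel-category placement test.
`run_noise_benchmark` trains a 64-px model and runs a 20-level × 10-rep
noise schedule against one held-out spectrum, reporting the per-level mean
distance trend (Spearman) and rank-1 retrieval accuracy. These problem
sizes are the package's desk-scale choices: large enough for the
qualitative behaviour (learning curves, placement, monotone noise
response) to be testable, small enough to run routinely.

## Numerical and degenerate-input choices

* Binarization threshold strictly inside (0, 1); exact 0/1 inputs are
  already fixed points.
* `rasterize_peaklist` refuses empty peak lists (a caller bug, not a
  spectrum); `render_member` redraws its drop mask until at least one peak
  survives, since an all-blank spectrum would never have entered a corpus.
* Pool-window ties take the first position in scan order; ranking ties
  take the smaller spectrum id; PCA component signs are fixed by making
  each component's largest-magnitude loading positive.
* Batch-norm epsilon 1e-5; running statistics updated with momentum 0.1.
* Contrastive-gradient at d = 0 uses the zero subgradient.
* Adagrad epsilon 1e-8 outside the square root.

## Known limitations

* The contrastive loss with a single margin enforces an ordering
  (same ≤ m ≤ different) but no gap, so retrieval quality relies on
  optimization dynamics rather than a guaranteed separation; convergence
  at desk scale is slow and the benchmark records the trajectory honestly.
* The published parameter count for the architecture (399,102, with a
  non-standard "triples under batch normalization" accounting) cannot be
  reconciled with the layer table under any standard convention; this
  package treats the layer table as normative and does not target the
  count.
* Single-precision training introduces relative errors around 1e-4 per
  pass; all determinism guarantees are within one build on one platform.
* The CLI (`inst/cli/hsqcsiam.R`) and the exported `cmd_*` functions cover
  simulate/train/embed-retrieve/evaluate; the interactive cluster-map
  browser of the original workflow is replaced by static TSV/PNG exports.
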