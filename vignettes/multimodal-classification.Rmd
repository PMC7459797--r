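---
title: "Multimodal brain-MRI tumor-type classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal brain-MRI tumor-type classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrimodal)
```

## The problem

Multimodal brain tumor imaging acquires each subject under four MRI
modalities — T1, contrast-enhanced T1 (T1CE), T2, and FLAIR — whose
tumor appearance differs systematically: tumors are hypo-intense and
low-contrast on T1, show an enhancing rim with a dark core on T1CE, and
are hyper-intense on both T2 and FLAIR, which differ mainly in fluid
signal (FLAIR suppresses ventricular CSF). Telling T2 from FLAIR, and
T1 from T1CE, is the hard part of automatic modality/tumor-type
classification. `mrimodal` implements a complete pipeline for this
4-class problem: contrast enhancement, deep-style feature extraction
behind a pluggable backbone contract, robust group-sparse feature
selection, two-block feature fusion, and an extreme learning machine
(ELM) classifier, together with simulators that make every stage
testable without access to gated clinical data.

## Contrast enhancement

Low-contrast slices hide exactly the intensity structure the features
need. `enhance()` runs three steps:

1. **K-means intensity split** (`kmeans_split()`): 1-D Lloyd iteration
   on pixel intensities with `K = 2` (a dark/bright split). Initial
   centroids sit at the 25th/75th intensity percentiles, so the split
   is deterministic; the seed only matters for the fallback
   initialization on pathological inputs. Convergence is assignment
   stability or 300 iterations.
2. **Edge-gated texture histogram equalization** (`texture_mask()`,
   `he_equalize()`): the gradient magnitude (central differences
   inside, one-sided at borders, unit spacing) is rescaled by its own
   maximum so the threshold `T = 0.55` is scale-free. Pixels at or
   above the threshold are "texture" pixels; each cluster's transfer
   function is built from the histogram of its texture pixels over 256
   grey levels, restricted to the occupied band `[alpha, beta]`, and
   maps that band to `[alpha, 255]` through the cumulative
   distribution. Applying the stretch to *all* cluster pixels (clamping
   outside the band) equalizes where the image carries structure while
   leaving flat regions untouched. An empty texture set means the
   cluster is returned unchanged. The opposite gating polarity
   (equalize the *smooth* pixels) is available via
   `edge_polarity = "below"`.
3. **DCT alpha-rooting** (`dct_plan()`, `dct_refine()`): the image is
   transformed with the orthonormal DCT-II basis (padded to square by
   edge replication when needed), every AC coefficient `c` is replaced
   by `c * (|c|/|DC|)^(r-1)`, and the transform inverted. Because
   `|c| <= |DC|` for non-negative images, `r < 1` amplifies all AC
   energy — a mild, global local-contrast boost. The default
   `r = 0.98` is deliberately gentle; `r = 1` is an exact identity, a
   useful switch for isolating the refinement's effect. The
   DC-normalized form matters: unnormalized rooting `sign(c)|c|^r` is
   scale-dependent and can *reduce* contrast when coefficients exceed
   one.

Enhancement is deterministic given its seed and preserves shape and the
`[0, 1]` range. It is not idempotent, and is not meant to be.

## Feature extraction

Backbones implement a small contract: consume a 224x224x3 tensor
(grayscale replicated to three channels, bilinear resize), emit a
1000-dimensional feature vector. Adapters named `vgg16`/`vgg19` are
reserved for published pretrained weights and fail with an explicit
message when the weights are absent; nothing in the package requires
them.

The **toy backbone** (`toy_backbone()`) is a deterministic, seeded
stand-in for a trained network's final fully-connected features. Its
input vector is the 32x32 block-mean downsampled image plus a 64-bin
intensity histogram; its bank has three kinds of units:

* 64 identity units over the histogram bins,
* sign-paired Gaussian projections of the pixel vector,
* sign-paired Gaussian projections of the histogram,

all followed by half-wave rectification. Two design points deserve
explanation. First, the histogram channel: a trained CNN's deep
features are position-tolerant, while raw coarse pixels are not; on
phantoms whose tumor location varies, pixel-only projections make the
4-class task nearly unlearnable from two dozen training images, whereas
intensity statistics carry the class signal regardless of where the
tumor sits. Second, sign pairing: `relu(Pz)` alone discards roughly
half of each projection's range, but `relu(Pz)` and `relu(-Pz)`
together preserve every linear functional of the input
(`relu(t) - relu(-t) = t`), so downstream linear stages lose nothing to
the rectification.

## Correntropy-based group-sparse selection

`run_selection()` chooses whole feature columns by minimizing

    f(W) = sum_{n,c} [ 1 - exp( -(Y - XW)_{nc}^2 / (2 sigma^2) ) ]
           + p0 * sum_j ||W_j||_2

over a weight matrix with one row per feature and one column per class
(one-hot targets, columns of `X` standardized). The first term is the
correntropy-induced (Welsch) loss: quadratic for small residuals,
saturating at 1 per entry for outliers, hence robust to grossly
mislabeled samples. The second is the group penalty whose proximal
operator (`group_prox()`) zeroes or radially shrinks whole rows, so a
feature is either in or out across all classes.

The solver is an accelerated proximal gradient loop: extrapolation from
the previous two iterates, a backtracking search over inverse step
sizes `LR * {1, 2, 3, ...}` (capped at 32x per call) accepting the
smallest candidate whose proximal step satisfies the quadratic
majorization, then the group prox with threshold `p0 / LR`. Two
momentum schedules are provided: the default drives the extrapolation
scalar from the iteration counter; the alternative (`fista_standard`)
uses the classical self-referential recurrence. When a momentum step
raises the penalized objective the step is retaken without
extrapolation and the momentum restarts — this is what makes the
objective trace provably non-increasing even though an ELM (below) sits
inside the loop.

Every iteration trains an ELM on the currently selected columns and
computes the mean squared error (MSER) between its one-hot training
predictions and the labels. The loop stops when MSER drops below the
target (default 0.1) **and** the iterate has stabilized (relative
weight change below `1e-3`), or at `max_iter`. The stabilization
condition is a deliberate design choice: with many more features than
samples the in-loop ELM fits the training data immediately, so an MSER
gate alone would stop the solver before any sparsification happened and
defeat the selection entirely.

Default hyper-parameters, and why:

* `sigma = 1` — the kernel width lives on the scale of the one-hot
  targets, whose residuals never exceed 1 in magnitude by much; `1`
  keeps the loss near-quadratic in the working range while still
  damping outliers. Estimating `sigma` from initial-fit residuals is
  tempting but unstable: the ridge initialization near-interpolates
  when features outnumber samples, the estimate collapses, and the
  saturated loss freezes the solver.
* `p0 = 0.2 * max_j ||grad_j f(0)||_2` — 20% of the critical penalty at
  which the all-zero solution becomes stationary, the standard
  fraction-of-lambda-max rule for group-sparse fits. It adapts to the
  data scale and yields sparse supports without tuning.
* `W` initialization by a ridge fit (`lambda = 1`) of the one-hot
  labels on the standardized features — well-posed and deterministic.
* Empty selection (penalty too strong) falls back to the single
  highest-norm row, so downstream stages always receive at least one
  column.

On simulated feature tables with 120 samples, 1000 columns and 10
informative columns at class-mean shift 5, these defaults recover 8-10
of the 10 informative columns while selecting at most ~11 overall,
across seeds.

## PLS fusion

`fit_fusion()` fuses two selected blocks (same samples, two backbones)
by partial least squares in its SVD form: both blocks are centered, and
the direction pairs `(u_i, v_i)` maximizing `Cov(A u, B v)` under unit
norms are the singular vectors of the cross-covariance
`A_c' B_c / (n - 1)`. All pairs come from one SVD — no deflation — and
`fuse_blocks()` concatenates the two score matrices into `2d` fused
columns (default `d = 8`, capped by rank). Scores, rather than
concatenated raw features, are what keeps the predictor count small.
Sign convention: the largest-magnitude entry of each `u_i` is positive.
A zero cross-covariance (nothing shared between blocks) is flagged
`informative = FALSE`.

## Extreme learning machine

`train_elm()` draws input weights and biases uniformly on `[-1, 1]`
(seeded, never trained), passes the standardized inputs through a
logistic sigmoid hidden layer of `L = 1000` nodes, and solves only the
output weights in closed form from the ridge system
`beta = (H'H + I/c)^{-1} H' T`, switching to the algebraically
identical dual `H'(HH' + I/c)^{-1} T` when samples are fewer than
nodes. The penalty `c` (default 1) trades training fit against the
norm of `beta`; training MSE is non-increasing in `c` on a fixed hidden
layer. Prediction takes the argmax score, ties resolved toward the
lowest class index. ReLU and tanh activations are selectable.

## Evaluation metrics

`evaluate_predictions()` reports accuracy (%) and FNR as
`100 - accuracy` (the convention of this benchmark family), plus the
confusion matrix in counts and row percentages.
`mcc()` is the covariance-of-indicators multiclass Matthews
coefficient, 0 when the denominator vanishes.
`summarize_runs()` condenses repeated runs into min/avg/max, variance,
standard deviation, and `SEM = sd / sqrt(n_runs)`. The published run
summaries the package ships (`reported_run_stats()`) are reproduced by
the **population** (divide-by-n) variance with n = 3 runs; the sample
(n-1) form is available via `var_type`. `ci_margin()` multiplies the
SEM by the standard-normal quantile (1.96 at 95%) — the Student-t
multiplier at 2 degrees of freedom (4.30) does not reproduce the
published margins, so normal theory is clearly what they used.
Presentation rounding is half-away-from-zero (`round_half_up()`).

## The simulators

`generate_phantom()` draws a 256x256 slice: elliptical "brain" at
mid-grey with smooth low-frequency texture, two ventricle ellipses near
the midline, and a tumor blob with soft edges, rendered per class —
T1: hypo-intense low-contrast blob; T1CE: dark core with bright rim;
T2: hyper-intense blob and bright ventricles; FLAIR: hyper-intense blob
with suppressed (dark) ventricles. T2 and FLAIR tumor intensities are
deliberately close (0.82 vs 0.78), so those classes genuinely overlap
and the ventricle signal is the discriminating cue — mirroring the real
difficulty. Gaussian pixel noise (sd 0.05 by default) is added and the
image clipped to `[0, 1]`. Batches vary tumor position and radius per
sample; everything is a pure function of the spec including its seed.

What the phantoms do **not** emulate: MRI physics (bias fields, partial
volume, coil inhomogeneity), anatomy beyond two ellipses, 3-D
structure, or inter-subject variability. A pipeline that passes on
phantoms has demonstrated its *mechanics* — that enhancement,
selection, fusion and classification compose correctly and that the
class-discriminative signal survives each stage — not clinical
performance.

`generate_feature_dataset()` builds feature tables with a known
informative-column subset: informative columns get per-class Gaussian
mean shifts of scale `delta` on unit noise; nuisance columns are pure
noise; the ground-truth index set is returned. Because the shifts are
random, an occasional instance contains an informative column whose
four class means happen to be nearly equal — unrecoverable in
principle, which is worth remembering when reading recovery counts.

`train_test_split()` provides the stratified 60:40 holdout used as the
default evaluation; `cv_folds()` provides stratified 10-fold indices
for users who prefer cross-validation. Both conventions are common in
this literature and the package simply offers both, with the holdout as
the default.

## The pipeline and its study sizes

`run_pipeline()` wires the stages together: simulate (or accept) 40
phantoms (10 per class), enhance, extract features with two
differently-seeded toy backbones, split 60:40 stratified, run selection
per block on the training split only, fit the fusion on the training
split, train the ELM on fused training scores, and evaluate both
splits. All randomness derives from one seed; two runs with the same
configuration are bit-identical. At these sizes the full run takes a
few seconds on one CPU; the tests use a reduced 20-phantom/96-pixel
version for the plumbing checks and the full 40-phantom study for the
end-to-end acceptance check. Typical held-out accuracy across seeds is
75-100% (mean near 87%) with training accuracy at 100%.

## Numerical notes

* The Welsch loss is evaluated with `expm1`; the naive
  `1 - exp(-z)` loses all precision for small `z` and silently breaks
  the wide-kernel (near-quadratic) regime, including the backtracking
  acceptance test.
* `dct_plan()` builds the orthonormal basis explicitly; orthogonality
  is tested to 1e-10 and round trips to 1e-8.
* Equalization quantizes to 256 grey levels with half-up rounding;
  the transfer function is monotone by construction (cumulative sums).
* Ties in ELM prediction go to the lowest class index, making
  degenerate models (zero output weights) deterministic.
* Backtracking warns when it hits its 32x-per-call cap; early
  iterations of the selection commonly ratchet the step size upward
  until it reaches the loss's curvature scale, after which the cap is
  no longer touched.

## Known limitations

* The `vgg16`/`vgg19` adapters require externally supplied pretrained
  weights; without them the package's evidence comes entirely from
  synthetic data.
* Selection hyper-parameters are not cross-validated; the defaults are
  scale-adaptive rules, not tuned optima.
* Fusion handles exactly two blocks; no NIPALS/deflation variant.
* Enhancement operates on 2-D slices only; no volumetric processing,
  bias-field correction, or skull stripping.
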