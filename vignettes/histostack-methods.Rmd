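---
title: "Building 2.5D cores from serial sections: models, parameters and design choices"
author: "HistoStack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building 2.5D cores from serial sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(HistoStack)
```

# The problem

A needle-core biopsy is one physical object, but routine processing cuts
it into 6–16 serial ribbons that are stained, mounted and scanned as
independent 2-D whole-slide images. Structures of diagnostic interest —
glands, cribriform patterns, perineural invasion — continue across
ribbons, and both human readers and patch-based models lose that
continuity. HistoStack reconstructs a *2.5D core*: the serial sections
co-registered into an ordered image volume, with the z axis being section
order rather than a true third imaging dimension.

Two constraints shape the whole design:

* **Morphology must be preserved.** Alignment exists to serve diagnosis,
  so a registration that "succeeds" by deforming glands into agreement is
  worse than a looser one. The rigid stage therefore allows only
  rotation, isotropic scale and translation (the similarity group: its
  linear part has determinant $s^2 > 0$, so shear and reflection are
  unrepresentable), and the deformable stage is driven *only* by the
  ribbon outline.
* **Everything must be testable without a slide archive.** There is no
  public serial-section dataset with ground-truth correspondence, so the
  package ships a phantom generator whose misalignments, warps and
  landmarks are known exactly; every stage is validated against it.

# The phantom generator

`phantomSpec()` / `generatePhantomCore()` emulate one serially sectioned
H&E-stained core:

* **Tissue shape.** A curved band: a circular-arc centerline (radius
  0.57·L, angular half-span 0.7 rad on a canvas of side L = 384 px) with
  an elliptically tapered half-width of 0.06·L. Real ribbons are
  millimetres wide, centimetres long, and bow as they come off the
  microtome; the curvature also matters methodologically, because a
  curved outline exposes boundary normals over a wide angular range —
  precisely the information a boundary-driven deformable registration
  can use. (A straight ribbon's long edges share one normal direction,
  leaving the along-ribbon component of any deformation invisible to the
  outline; we verified with ground-truth oracles that no estimator can
  recover it from the boundary alone.)
* **Appearance.** White background (255); eosin-pink stroma with
  low-frequency shading and mid-frequency mottle; dark-purple
  nucleus-like speckle of varying size and darkness, fixed across depth
  so neighbouring sections share matchable structure; elliptical gland
  lumens whose size drifts ±10% through the stack (the "slightly morphed
  with depth" signal).
* **Corruption.** Section 1 is the reference. Every other section is
  pushed through a ground-truth similarity (rotation ≤ 10°, scale in
  [0.97, 1.03], translation ≤ 20 px, drawn uniformly about the canvas
  center) and, when `warpAmplitude > 0`, a smooth non-rigid warp: a
  random field on a 64 px B-spline control grid, rescaled so its *peak*
  displacement magnitude equals the requested amplitude (default 6 px).
  Additive Gaussian intensity noise (sd 3) is applied last.
* **Ground truth.** `trueTransforms[[t]]` maps section-t coordinates into
  reference coordinates — exactly what registration must recover;
  landmarks (12 band-edge points + gland centers) are carried through
  both corruptions, inverting the backward warp by fixed-point iteration.

What the phantom does *not* emulate: stain variability between sections,
tissue folds and tears, out-of-plane structure change beyond the gentle
gland drift, pen marks and coverslip artifacts. Passing tests on phantoms
therefore demonstrates the correctness of the algorithms under controlled
geometry, not robustness to every slide-archive pathology.

# Tissue masking and ribbons

`computeTissueMask()` converts to HSV and thresholds hue. The stain hue
is not hard-coded: with `hueWindow = "auto"` the threshold is Otsu's
split of the hue histogram restricted to non-white pixels (saturation
> 0.05), keeping the majority side — in H&E both eosin (~0.88) and
hematoxylin (~0.74) hues sit high, and the majority rule selects the
stain mode robustly across batches. One morphological closing with a
disk (default radius 5 px at the working resolution) fills nucleus-scale
holes without bridging the gap between adjacent ribbons. Connected
components with at least 0.1% of the image area become ribbons, ordered
by bounding-box top then left coordinate. All coordinates in the package
are 0-based, x = column (rightward), y = row (downward), boxes half-open.

# Serial rigid registration

There is no maintained R binding for a classical scale-invariant feature
detector, so the detector is implemented here: Harris corner responses
on the blurred luminance image, 3×3 non-maximum suppression, sub-pixel
refinement by a 2-D quadratic fit of the response surface (this matters:
integer-pixel corners leave ~0.3 px of per-link error that accumulates
along the serial chain), a dominant gradient orientation per keypoint,
and a 4×4-cell × 8-orientation gradient-histogram descriptor sampled on
a rotated grid (support ≈ 26 px), L2-normalized and clipped at 0.2.

Matching is deterministic mutual-nearest-neighbour with Lowe's ratio
test (default 0.75), one-to-one by construction. The original framework
this package re-implements uses a learned optimal-transport matcher; the
matcher here sits behind the same contract (one-to-one assignments into
a robust fit), so a learned back-end could be substituted without
touching the rest of the chain.

The similarity fit uses the complex-number least-squares form: writing
points as complex numbers, the best-fit rotation+scale+translation is
the regression $w = a z + b$ with $a = s\,e^{i\theta}$ — reflections are
not in the model class. The fit runs inside a seeded two-point
random-sample consensus loop (default 300 draws, 3 px inlier tolerance),
followed by a least-squares refit on consensus inliers and one tightened
refit at half tolerance, which suppresses the bias of sloppy
correspondences.

The chain is serial by construction: section k is registered against the
*rendered* (already-transformed) section k−1, so each fitted transform
maps directly into the reference frame and composition error cannot
accumulate algebraically. Transforms estimated on a downsampled level
propagate by multiplying the translation by the factor (`rescaleTransform`);
θ and s are resolution-independent.

# Boundary-driven deformable refinement

Ribbon masks are *re-detected* on the rigidly aligned renderings rather
than resampled (nearest-neighbour resampling stair-steps the outline and
the quantization noise would be fit as signal). `extractBoundary()`
keeps the largest component, fills holes, traces the inner contour
(tissue pixels with a 4-neighbour outside) and computes the signed
distance transform, negative inside, ±0.5 on contour pixels.
`boundaryLength()` reports contour length with Kulpa's corrected chain
weights (0.948/1.343), nearly unbiased for smooth shapes.

`estimateDisplacement()` fits a backward-mapping cubic B-spline
free-form deformation by minimizing the weighted mean squared difference
of the two (lightly smoothed) signed distance transforms in a Gaussian
band around the fixed outline, plus two penalties:

* **bending energy** of the control grid, expressed in curvature units
  (second differences divided by spacing², weight 0.1), and
* a small **ridge** on the control displacements themselves
  (`l2Weight = 0.002`). This term is load-bearing: displacement
  components tangential to the outline are weakly observable, and
  without a prior toward zero they drift and corrupt the interior. The
  default was calibrated on ground-truth-field recovery experiments with
  the phantom generator.

The solver is damped Gauss–Newton (Levenberg–Marquardt) over the control
points — the objective is a least-squares form with ~160 parameters, so
second-order steps converge in a handful of iterations where plain
gradient descent stalls — with one multi-resolution level (spacing 2s
then s, default s = 64 px) and band pixels subsampled on a stride-2
lattice. Only improving steps are accepted, so the objective trace is
non-increasing; the returned field carries the trace and a convergence
flag. The original pipeline calls into an elastix-style optimizer here;
no such binding exists in R, and the explicit Gauss–Newton fit also makes
the estimator fully deterministic.

The fitted field is applied once to the original full-color rendering
(`warpDense`, bilinear; masks nearest-neighbour), so stain texture is
resampled a single time by the deformable stage. On phantom fixtures the
Jacobian determinant of (identity + field) stays within [0.5, 2] — no
folding — and in practice within a few percent of 1.

# The registration-error statistic

For each pair of subsequent sections, keypoints are detected on both
final images, matched (mutual NN + ratio only — no consensus gating, so
the statistic is not clipped by the fit's own inlier tolerance), and the
median matched-pair distance in microns is recorded;
`coreRegistrationError()` aggregates per-pair medians weighted by match
counts. Both the registered and unregistered conditions are scored by
the same procedure, so comparisons are on the same match population. On
default warped phantoms the ordering unregistered > rigid ≥ non-rigid
holds with the deformable stage removing roughly a third to a half of
the residual rigid error; the absolute values depend on the phantom's
warp settings and are not comparable to any particular tissue cohort.

# 2.5D patches

`extractPatches()` tiles the union-mask bounding box with non-overlapping
P×P windows (default 256), discarding partial edge tiles, and keeps a
patch only when its tissue fraction strictly exceeds `minFraction`
(default 0.6) — a window at exactly the threshold is excluded. The
fraction is the mean over the Z per-section masks of the in-window
tissue fraction: symmetric in depth, no privileged reference section.
Per-section gating (any section below threshold rejects the patch) is
available by filtering on the per-section masks directly; the stack-mean
default was chosen because a single thin section should not veto an
otherwise tissue-rich column.

# The depth encoder, distillation and rollout

`encoderConfig()` fixes the geometry: P×P tiles, embedding dimension D
(divisible by the head count A), L blocks, F depth slices, N tiles per
slice. Defaults (D = 64, A = 4, L = 2) are a desk-scale reference —
large-scale pretraining is explicitly out of scope, and every weight is
drawn from a seeded generator so all tests pin exact arrays.

Each block applies **depth attention** — query (p, t) attends to the
classification token plus the F tokens at its own spatial position
(F + 1 logits, scaled 1/√Dh) — then **spatial attention** — the
classification token plus the N tokens of its own slice — then a
two-layer GELU MLP, each with residual connections and pre-layer-norm
q/k/v projections. The classification token's own path through divided
attention is genuinely under-determined by the defining equations (they
give its key but not its query route); we pass it through the depth step
unchanged and let it attend over *all* tokens in the spatial step, which
keeps every key set consistent and gives the token one full view per
block. The correctness anchor is the masked-full-attention equivalence:
an independent naive implementation with explicit key masks agrees with
the divided path to 1e-5 across seeded configurations.

Distillation follows the momentum self-distillation recipe: global views
(full spatial extent; the second with light photometric jitter) feed the
teacher, tile-aligned local crops (full depth — depth is the signal this
encoder exists for) feed the student, and the loss is the cross-entropy
between the teacher's centered, sharpened distribution (τ_t = 0.04) and
the student's (τ_s = 0.1). The teacher is an exact elementwise
exponential moving average of the student; the center is an EMA (0.9) of
teacher logits. At this scale the trainable student part is the
projection head, updated with its analytic gradient (verified against
finite differences in the tests); the toy demonstrations use momentum
0.9 and learning rate 0.1, where 30 steps visibly reduce the loss —
the published large-scale value 0.996 remains the documented default for
the momentum parameter.

For attribution, head-averaged attention with the classification key
dropped and rows renormalized gives S[i,j,p] and T[p,j,q]; the combined
matrix W[(i,j),(p,q)] = S[i,j,p]·T[p,j,q] is row-stochastic (each factor
is), and rollout multiplies the per-layer matrices from the input layer
up. An option mixes in the identity (residual-path correction), off by
default because the combined-attention definition contains no identity
term.

# ABMIL and the agreement statistics

`abmilPool()` is the gated-attention variant: instance scores
w′(tanh(Vh) ⊙ σ(Uh)), softmax over the bag, weighted feature sum, linear
classifier. It is permutation-invariant by construction and its analytic
backpropagation (used by `trainAbmil`) is verified against numerical
gradients. The training loop — full-batch gradient descent with weight
decay and early stopping on a held-out validation split — exists for the
synthetic demonstration: bags are positive iff they contain instances
from a mean-shifted Gaussian (shift 3 on 2 of 10 dimensions; at this
shift the Bayes-optimal bag classifier is essentially perfect, so the
demonstration measures the model, not the task draw).

`binarizeCS()` maps grade groups to the clinical-significance threshold
(GG ≥ 2). `evaluateMulticlass()` reports one-vs-rest AUC weighted by
class support (the averaging scheme is configurable in the sense that
per-class AUCs are returned), support-weighted precision/recall/F1, and
confusion matrices. `mcnemarChi2()` implements χ² = (b−c)²/(b+c) on the
discordant counts with the continuity correction off by default, and
`quadraticWeightedKappa()` the O/E form with squared-distance weights;
both are cross-checked in the tests against `stats::mcnemar.test` and a
large-n independence simulation respectively.

# Numerical choices and degenerate inputs

* Bilinear interpolation everywhere for intensities, nearest for masks;
  out-of-bounds samples fill white (255) for images and 0 for masks.
* Empty keypoint sets, empty match sets and empty masks are values, not
  errors, wherever the pipeline can continue; fewer than 3 match pairs,
  coincident correspondences, all-empty mask stacks and zero discordant
  pairs raise informative errors.
* Registration determinism: the only stochastic component is the
  consensus sampling, seeded per link; reruns are bit-identical.
* Problem sizes in tests and the acceptance script: 384 px phantoms with
  6–8 sections, cohorts of 10–20 phantoms, encoder configurations with
  N ≤ 9, F ≤ 4, D ≤ 32, ABMIL with 200 bags. These sizes exercise every
  code path at full fidelity while keeping a complete run inside a
  coffee break on one CPU.

# Known limitations

* The deformable stage can only recover deformation components visible
  in the outline; for pathological geometries (perfectly straight,
  featureless ribbons) the tangential component is unidentifiable and
  the ridge prior leaves it at zero rather than guessing.
* The keypoint detector assumes stained texture; on near-blank sections
  the rigid chain will fail loudly (or fall through to the previous
  transform when `fallthrough = TRUE`).
* Cross-slide z-ordering of ribbons is not inferred; the caller supplies
  section order.
* The encoder and MIL components are reference implementations for
  correctness and interpretability work, not performance-tuned trainers.
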