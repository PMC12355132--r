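# HistoStack

Routine pathology digitizes tissue as independent two-dimensional slides,
even though a needle-core biopsy is serially sectioned into 6–16 ribbons
of one three-dimensional specimen. HistoStack reconstructs that lost depth
axis at desk scale: it co-aligns a z-ordered stack of serial H&E section
images into a *2.5D core* — a registered image volume that approximates
the tissue block without 3-D imaging hardware — and provides the
downstream machinery that makes such volumes useful: 2.5D patch
extraction, a depth-aware transformer encoder, and attention-based
multiple-instance aggregation to a core-level grade.

It is aimed at computational-pathology researchers who want a fully
scriptable, dependency-light reference implementation of the 2.5D
construction recipe, with a synthetic phantom generator so every stage is
testable without any slide archive.

## What it computes

**Morphology-preserving alignment.** Sections are masked by hue
thresholding in HSV space with morphological closing, and ribbons are
labelled as connected components. Rigid registration is serial: the first
section is the reference, and each section *k* is registered to the
already-registered rendering of section *k−1* through keypoint matching
(Harris corners with orientation-normalized gradient-histogram
descriptors, mutual-nearest-neighbour + Lowe-ratio matching) and a robust
closed-form similarity fit. The transform family is deliberately
restricted to rotation θ, isotropic scale *s* and translation *t* —

  p′ = s·R(θ)·p + t,  det = s² > 0 —

so the rigid stage cannot shear or reflect tissue. Translations scale
linearly across resolution levels (θ and *s* are resolution-free), so
transforms estimated on downsampled images propagate to full resolution.

The non-rigid stage never reads interior texture. Ribbon boundaries are
re-detected on the rigidly aligned images, and a cubic B-spline free-form
displacement field u(x) is fit by damped Gauss–Newton to minimize

  Σ w(x)·[ SDT_fixed(x) − SDT_moving(x + u(x)) ]² + bending + ridge,

where SDT is the signed distance transform of the ribbon outline. Only
the outline drives the deformation, which is what preserves glandular and
nuclear morphology inside the tissue.

**Registration error.** For each pair of subsequent sections the error is
the median distance (μm) between matched keypoints; the core-level error
is the match-count-weighted mean of the per-pair medians.

**2.5D patches.** The aligned core is tiled by non-overlapping
P×P×Z patches anchored at the tissue bounding box; a patch is kept only
if its stack-mean tissue fraction strictly exceeds 60%.

**Depth encoder, rollout, ABMIL.** A desk-scale divided depth/space
attention encoder (tokenization z⁰ = E·x + e_pos; per-block temporal
attention over same-position tokens across depth, then spatial attention
within each section, then an MLP), DINO-style momentum self-distillation,
combined space–time attention W[(i,j),(p,q)] = S[i,j,p]·T[p,j,q] with
recursive rollout for attribution, and gated-attention
multiple-instance pooling with the agreement statistics used for grading
studies (support-weighted multiclass metrics, McNemar χ² = (b−c)²/(b+c),
quadratic-weighted kappa).

## Worked example

```r
library(HistoStack)

# a synthetic serial-section core with known ground truth:
# 6 ribbons, up to 10 deg rotation / 3% scale / 20 px shift per section,
# plus a smooth 6 px sectioning warp
ph <- generatePhantomCore(phantomSpec(nSections = 6, seed = 11))
ph
#> PhantomStack with 6 sections, 18 landmarks/section

masks  <- lapply(ph@sections, computeTissueMask)
before <- stackRegistrationError(ph@sections, masks)
before
#> RegistrationReport: 5 pairs, core error 13.43 um

res <- alignStack(ph@sections, seed = 11, rigidReport = TRUE)
sprintf("unregistered %.1f um | rigid %.2f um | non-rigid %.2f um",
        coreError(before), coreError(res$rigidReport), coreError(res$report))
#> "unregistered 13.4 um | rigid 0.74 um | non-rigid 0.38 um"

res$transforms[[2]]   # recovered section-2 -> reference similarity
#> SimilarityTransform2D theta 8.7702 deg, scale 0.99884, t (27.85, -43.53) px @ 0.500 um/px

res$core
#> Core25D Z=6, 384 x 384 px @ 0.500 um/px
length(extractPatches(res$core, patchPx = 32, minFraction = 0.6))
#> [1] 7
```

The numbers read as follows: before alignment, matched keypoints of
neighbouring sections sit a median 13.4 μm apart; serial rigid
registration brings that to 0.74 μm, and the boundary-driven deformable
stage roughly halves the remaining error to 0.38 μm while leaving
interior texture untouched. The recovered similarity for section 2 is
the generator's ground-truth misalignment to within a few hundredths of
a degree and a fraction of a pixel.

A command-line wrapper over the same functions is installed at
`inst/cli/histostack` (commands `phantom`, `align`, `patch`, `eval-reg`,
`encode-demo`, `grade-demo`); every command echoes its resolved
configuration as YAML and is byte-reproducible given a seed.

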