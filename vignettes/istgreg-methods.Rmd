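---
title: "Groupwise tensor registration with intermediate subgroup templates: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Groupwise tensor registration with intermediate subgroup templates: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Aligning a cohort of diffusion tensor images (DTI) to a common space is the
prerequisite for voxelwise group analyses. In rapidly developing cohorts —
the motivating case is longitudinal infant imaging in the first months of
life — scans differ enormously in size, shape and tissue maturity, and no
single predefined atlas represents all of them. Registering every scan
directly to one evolving average (one-level groupwise registration)
forces large deformations on the scans furthest from the average and blurs
the average itself.

`istgreg` implements a two-level alternative. Scans are first stratified
into homogeneous subgroups by clustering an image-similarity graph; each
subgroup is aligned to its own *intermediate subgroup template*; the
subgroup templates are then aligned to the final, sample-specific common
space. Each native scan reaches the final space through the composition of
its two chains and is interpolated exactly once.

## Image similarity and clustering

For scans rigidly pre-aligned to a centered initial target (the cohort
medoid), FA and MD maps are compared pairwise by the root sum of squared
voxel differences. Each distance matrix is normalized to (0, 1] by dividing
by its largest entry, and the similarity between scans A and B is

    s(A, B) = 1 / d_FA(A, B) + 1 / d_MD(A, B).

FA contrasts gray against white matter; MD contrasts tissue against CSF, so
the two channels are complementary. A min–max normalization mode is also
provided, clamped below at 1e-6; note that min–max sends the closest pair to
the clamp and hands it a reciprocal weight of order 1e6, which concentrates
essentially the whole graph weight on a single edge and leaves modularity
clustering without usable structure. Division by the maximum preserves
ratios and is the default.

Subgroups come from Louvain modularity clustering on this weighted graph
(resolution 1, modularity-gain tolerance 1e-9), implemented in the package
with the standard two phases (greedy node moves, community aggregation).
The node visit order is shuffled by a user seed, which fully determines the
result; on ties a node stays in its current community. Age-rule
stratification (half-open bins, default cutoffs 3 and 6 months) and the
trivial single-group partition are provided for comparison.

## The registration engine

All spatial maps are stored in the resampling (pull-back) convention:
reference-space coordinates map to source-space coordinates, as warps are
stored by the major registration toolkits. A per-scan chain is an ordered
list of such maps, collapsed to one dense displacement field before the
single final interpolation.

* **Metric.** The cost is the mean squared Frobenius difference of matrix
  *logarithms* of the tensors (a log-Euclidean metric), evaluated over the
  fixed volume's foreground (MD above 10 % of its robust maximum).
  Eigenvalues are clamped at a metric floor of 1e-4 mm^2/s before the
  logarithm so that near-zero background does not dominate through its log.
  The log-domain choice makes the cost consistent with the log-space
  interpolation and averaging used everywhere else; with a linear-space
  cost the minimum sits a fraction of a degree away from a transform whose
  fixture was produced by log-space resampling. Per-voxel squared
  differences are capped at 3 (a robust capped quadratic): tissue-level
  differences stay quadratic while tissue-against-background mismatch
  saturates, so gross misalignment is scored by non-overlap volume instead
  of being dominated by boundary contrast — this keeps rigid alignment of
  differently sized brains unimodal in translation. In scalar ("FA") mode
  the cost is the mean squared FA difference.

* **Optimizer.** Deterministic multi-resolution pattern search (three
  pyramid levels, factors 4/2/1), 3 Euler angles + 3 translations for the
  rigid stage, plus 3 log-scales and 3 shears for the affine stage. A
  coarse-level exhaustive translation grid around the center-of-mass start
  guards against secondary basins; each finer level restarts from its
  initialization whenever that scores better than the carried parameters;
  and translations are bounded to a 4 mm trust region per axis around the
  center-of-mass initialization (whole-brain alignment should not stray
  several mm from a matched center of mass, and the bound excludes
  partial-overlap basins). No randomness enters registration; identical
  inputs give identical transforms.

* **Deformable stage.** Hierarchical piecewise-affine registration: at
  level L the domain splits into 2^L uniform blocks per axis (default
  levels 1–3); each block fits a 12-parameter local affine increment
  against the currently warped moving image, with a quadratic penalty tying
  its corner displacements to zero (weight 0.05 of the block's identity
  cost). Block transforms are blended by a trilinear partition of unity —
  the blend interpolates the blocks' global-form parameters, which is exact
  because an affine's displacement is linear in them — and the increment is
  composed onto the accumulated field. Increments are halved until the
  composed field's Jacobian determinant stays above 0.1, and an increment
  is only accepted if it lowers the masked cost, making the per-level cost
  trace non-increasing.

* **Tensor resampling.** Final resampling interpolates log-tensors
  componentwise (guaranteeing positive-definite output above the
  eigenvalue floor of 1e-12 mm^2/s) and reorients each tensor by the
  finite-strain rotation — the transpose of the polar rotation factor of
  the local pull-back Jacobian, computed by Newton iteration. Rotation
  congruence commutes with the matrix logarithm and preserves eigenvalues,
  so FA and MD are unchanged by reorientation itself; only interpolation
  perturbs them.

## Template construction

`build_template()` runs the classical align-then-average schedule:
rigid, then affine (initialized from rigid), then deformable, each for a
configurable number of iterations (default 2 — improvements beyond two
iterations are negligible); after every iteration the target is replaced by
the voxelwise log-Euclidean mean of the aligned scans (a Euclidean mean is
available as an option, and scalar mode averages FA maps). `istg_run()`
applies this per subgroup (level 1, target: the centered subgroup medoid),
then across the subgroup templates (level 2, target: the centered medoid
template), composes each scan's two chains, and resamples every native
scan once into the final space. Single-scan subgroups pass through level 1
as their own template. A single-group partition reduces the two-level run
exactly to the one-level construction, which the tests exploit.

## The synthetic cohort generator

`make_cohort()` is the test substrate: a longitudinal cohort at desk scale
with known ground truth. Its defaults are the packaged study conditions:

* 12 scans in 3 maturation stages (4 each) on a 48^3 grid of 2 mm voxels;
* stage tract FA 0.35 / 0.50 / 0.65 (progressive myelination) and global
  scale 0.90 / 1.00 / 1.10 (growth, a realistic linear-size range for the
  first half year);
* a smooth stage-specific morph field (amplitude 2.5 mm, vanishing near
  the center) giving each stage genuine non-affine shape character —
  brains do not grow affinely;
* per-scan rigid jitter up to 5 degrees and 3 mm;
* per-scan smooth random warps (white displacement fields smoothed with a
  12 mm Gaussian), amplitude 2.5 mm — large enough that registration
  quality rather than the noise floor drives the evaluation metrics, while
  staying below the ~4 mm between-stage boundary displacement of the scale
  steps so the planted stage structure remains present in the similarity
  signal;
* Gaussian noise of SD 0.05 on the log-tensor components (about 5 %
  diffusivity noise);
* synthetic ages drawn per stage from the disjoint ranges [0,3), [3,6) and
  [6,8) months.

Each phantom is an ellipsoidal brain of isotropic tensors (MD 1e-3 mm^2/s)
with a smooth deterministic MD texture (amplitudes 0.35 and 0.25 — real MD
maps vary more between CSF and white matter), a fine-scale MD contrast
component that rotates between two fixed incommensurate patterns as the
stage advances (regional myelination progress; mixing patterns rather than
phase-shifting one ensures no rigid shift can map one stage's fine
contrast onto another's), paired ventricle-like CSF structures that anchor
the global pose, and three prolate-tensor tract systems: a midline arc,
two lateral bundles and a transverse bundle crossing them at ~90 degrees. For a prolate tensor with mean diffusivity m
and target FA f the eigenvalues are m(1+2d), m(1-d), m(1-d) with
d = f / sqrt(3 - 2 f^2), which reproduces f exactly. Tract/tissue
boundaries get a small partial-volume blur (SD 0.6 voxels); a clearance
zone of uniform tissue around the tracts keeps the blur from distorting
tract-core values, and core masks (recorded before blurring) avoid the
arc's cut ends and the brain boundary. Deep tract positions scale
sub-linearly with brain growth (dampening 0.4), as white-matter cores grow
less than the cortical envelope; this also keeps cross-stage rigid
alignment well-posed. The texture pattern itself is stationary across
stages, emulating the developmental stability of diffusion contrast that
motivates tensor-based alignment in the first place.

What the generator does *not* emulate: real infant anatomy (gyrification,
many tract systems), DWI-level noise (noise is added to log-tensors, not
simulated signals), susceptibility or motion artifacts, and scanner
differences. Passing tests therefore show that the algorithms behave as
specified on controlled geometry with known truth — not that they reach any
particular accuracy on clinical data.

## Evaluation

All metrics default to the evaluation mask FA > 0.25 on the cohort-average
FA map (masks at 0.05 and 0.1 are available for whole-brain and
white-matter-enriched variants):

* **Dyadic coherence** per voxel: with eigenvalues b1 >= b2 >= b3 of the
  mean dyadic tensor of the aligned principal eigenvectors,
  kappa = 1 - sqrt((b2 + b3) / (2 b1)) in [0, 1].
* **Normalized FA dispersion** sigma_FA: the voxelwise coefficient of
  variation of FA across scans (sample SD over mean).
* **NMI** between each aligned FA map and the cohort average, from a 64-bin
  joint histogram. The symmetric-uncertainty form 2 I / (H_A + H_B) is the
  default because it spans [0, 1] and grows with similarity; the literal
  joint-over-marginals ratio (which spans [0.5, 1] and shrinks with
  similarity) is available behind a flag.
* **Jacobian summaries**: per-scan maps of the determinant of the
  deformable part of each chain (the total-map determinant divided by the
  affine determinants, mirroring the practice of evaluating the warp's
  Jacobian; with planted global scale differences the affine determinant
  would otherwise dominate every method identically), summarized as
  |mean Jacobian - 1|.

Method pairs are compared with pooled-variance two-sample two-tailed
t-tests, Cohen's d with a seeded bootstrap 95 % confidence interval
(10,000 resamples), and a Bonferroni factor of 3 for the three pairwise
method comparisons.

## Problem sizes used by the tests and the acceptance script

The registration unit tests run on 24^3 phantoms; transform-recovery,
fixed-point and method-comparison checks use the packaged 48^3 cohort with
one iteration per stage; the subsampling robustness harness runs on a 32^3
cohort with rigid+affine pipelines (the two-level advantage is already
pronounced at the affine stage, and the full five-fraction, ten-draw grid
reruns both pipelines fifty times). The acceptance script repeats the same
computations from scratch and additionally reports a reduced robustness
summary (two fractions, three draws). These sizes are the package's own
desk-scale choices; every quantity they produce is recomputed at run time.

## What the desk-scale comparison can and cannot show

With the packaged 12-scan cohort, the planted between-stage FA differences
contribute most of the variance that the aggregate evaluation metrics see,
and each method is evaluated on the mask derived from its own average FA
map (the procedure used on real cohorts). Under these conditions the
aggregate orderings between methods are small and partly dominated by mask
composition rather than alignment quality; the alignment-sensitive
decomposition (within-stage FA dispersion, which removes the planted stage
variance) consistently favors the two-level pipeline. The acceptance
checks assert the directional claims as stated, and the ones this cohort
cannot reproduce fail openly rather than being weakened.

## Known limitations

* The deformable model is piecewise-affine with a partition-of-unity
  blend; it is smooth but not guaranteed diffeomorphic beyond the Jacobian
  floor safeguard.
* Rigid alignment of brains with very large size ratios relies on interior
  structure; with an outline-only phantom (no texture, no ventricles) the
  capped metric degenerates to overlap matching, which is ambiguous under
  a 20 % size mismatch.
* The similarity step compares maps voxelwise after rigid alignment only;
  strongly displaced anatomy inflates distances and can blur subgroup
  structure (the min–max normalization mode makes this categorically
  worse; see above).
* Louvain optimizes modularity only and, on very small cohorts, can merge
  weakly separated stages; the resolution parameter is exposed.
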