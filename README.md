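# istgreg

Groupwise registration of diffusion tensor image (DTI) cohorts to a
sample-specific common space using **intermediate subgroup templates**.

Registering longitudinal infant DTI is hard: brain size, shape and tissue
contrast change dramatically over the first months of life, so no single
predefined template represents every scan, and one-level groupwise
registration (align everything to one evolving average) forces large
deformations on the scans furthest from the average. `istgreg` implements a
two-level strategy for scientists who need accurate voxelwise
correspondence in heterogeneous tensor cohorts:

1. **Cluster** scans into homogeneous subgroups. After rigid pre-alignment
   to the cohort medoid, pairwise FA and MD map distances
   `d(A,B) = sqrt(sum_v (A_v - B_v)^2)` are normalized to (0, 1] and
   combined into similarity weights `s(A,B) = 1/d_FA + 1/d_MD`; Louvain
   modularity clustering (resolution 1, gain tolerance 1e-9) on this graph
   yields the subgroups. Age-rule and single-group partitions are available
   for comparison.
2. **Level 1**: within each subgroup, iterative align-then-average template
   construction (rigid 6-dof, affine 12-dof, hierarchical piecewise-affine
   deformable; log-Euclidean tensor averaging) produces an intermediate
   subgroup template.
3. **Level 2**: the subgroup templates are aligned to the final
   sample-specific common space by the same construction; each native scan
   reaches the final space through its composed chain with a single
   log-space tensor interpolation and finite-strain reorientation.

The registration engine is tensor-aware throughout: the cost is the masked
mean squared Frobenius difference of (clamped) log-tensors with a robust
per-voxel cap, optimized by a deterministic multi-resolution pattern
search; a scalar mode registers FA maps for the conventional
scalar-baseline comparison. Evaluation follows the field's standard
battery: dyadic coherence `kappa = 1 - sqrt((b2+b3)/(2 b1))` of aligned
principal eigenvectors, normalized FA dispersion `sigma_FA` (voxelwise
coefficient of variation), normalized mutual information between each
aligned FA map and the cohort average, Jacobian determinant summaries,
empirical CDFs, and pooled-variance t-tests with Cohen's d and bootstrap
confidence intervals.

A synthetic longitudinal phantom cohort generator (`make_cohort()`)
provides the test substrate: maturation stages differing in tract FA and
global size, ventricle-like CSF anchors, stage-stable coarse and
stage-varying fine tissue texture, per-scan rigid jitter and smooth random
warps with recorded ground truth, and seeded tensor-valued noise.

## Worked example

```r
library(istgreg)

co <- make_cohort(cohort_spec(n_scans = 12, n_groups = 3, seed = 42))
ex <- run_experiment(co$scans,
                     methods = c("tensor-onelevel", "istg-louvain"),
                     iters = c(rigid = 1, affine = 1, deform = 1),
                     cluster_seed = 1)
ex$partitions$louvain
#> <scan_partition> 12 scans, 3 subgroups (louvain), Q = 0.2819
print(ex)
```

The partition recovers the three planted maturation stages exactly. The
summary table prints one row per method — mean `sigma_FA` (lower is
better), median `kappa` (higher is better), mean NMI (higher is better) and
the mean absolute deviation of the Jacobian determinant from 1 (lower means
less deformation) — and `ex$comparisons` holds the pairwise t-tests on the
per-scan NMI values and Jacobian deviations.

Individual steps are exported too: `register_rigid()`,
`register_affine()`, `register_deformable()`, `apply_transform()`,
`build_template()`, `istg_run()`, `compute_fa()`, `dyadic_coherence()`,
`nmi()`, and so on. A thin command-line wrapper for simulation, cohort runs
and pairwise registration lives in `inst/cli/istg.R`.

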