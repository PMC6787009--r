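---
title: "Methods: functional-space alignment and network analysis of individual DMN maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional-space alignment and network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Group analyses of resting-state functional MRI conventionally align
subjects through their anatomy (a structural template such as MNI152).
Small functional areas — basal-forebrain and thalamic nuclei, mammillary
bodies — are a few voxels across, and the residual inter-individual
misalignment after anatomical normalisation is of the same order as their
size.  In a group average or median they are therefore washed out, even
when every single subject shows them clearly.  `dmnalign` implements a
pipeline that (i) maps each subject's default-mode network (DMN) by
seed-based correlation, (ii) aligns subjects *by those functional maps
themselves* through iterative groupwise nonlinear registration, (iii)
quantifies what the functional alignment changed — voxelwise paired
statistics under permutation family-wise error (FWE) control,
region-of-interest (ROI) connectivity matrices, atlas-overlap statistics —
and (iv) characterises the network's structural hubs from streamline
tractography and binary graph metrics.  Every stage is exercised end to end
on synthetic cohorts with known ground truth.

## Data model

All volumetric classes share one geometry convention: 0-based voxel
indices, a 4×4 voxel-to-world affine in RAS+ millimetres, and displacement
fields stored in voxel units of the reference grid under the *pull*
convention (the resampled value at reference voxel $x$ is taken from the
moving image at $x + u(x)$).  A single convention everywhere avoids the
mixed FSL/ANTs conventions that plague this kind of pipeline.  Samples
falling outside a moving image are 0 (connectivity maps are near zero at
the brain edge); displacement-field *components* are interpolated with
edge clamping instead, because a smooth warp should not be dragged to zero
at the boundary.  Smoothing uses separable Gaussians under reflect
boundaries, which preserves the global mean exactly.  Interpolation is
trilinear for maps and nearest-neighbour for masks; no higher-order
schemes are offered.

## Individual DMN maps

Confound time courses (motion-like regressors, tissue eigenvariates
obtained with `maskEigenvariate()`, optionally their first derivatives by
convolution with a (−1, 0, 1) kernel) are removed voxelwise by ordinary
least squares.  Each of the 40 seed masks (20 per hemisphere) yields a
Pearson correlation map of its mean time course against every voxel, and
the individual DMN map is the voxelwise **median** of the 40 seed maps; the
group map is the voxelwise median across subjects.  The median is used
instead of the mean because it is robust to an outlying seed or subject at
these sample sizes.  Two conventions worth stating: an even number of maps
uses the midpoint of the two central order statistics, and zero-variance
voxels get r = 0 (with a logged count) rather than an error, because
masked-out background is ubiquitous.  Raw r (not Fisher z) is carried into
the maps, since the 0.3 threshold downstream is stated on connectivity
strength.

## Functional-space template construction

`buildFunctionalTemplate()` starts from the voxelwise median of the
individual maps and iterates four times (`nTemplateIters = 4`): register
every map to the current template, subtract the voxelwise mean field from
every subject's field so the template cannot drift, warp, and recompute
the median.  The registration in `registerPair()` is a greedy
demons-style scheme: intensity-difference forces along the fixed-image
gradient, per-iteration updates capped at 0.5 voxel and smoothed with a
fluid Gaussian (σ = 1 voxel), the accumulated field smoothed with a
diffusion Gaussian (σ = 1 voxel), run over a 3-level coarse-to-fine
pyramid with a 30/20/10 iteration schedule.  Same-modality scalar maps
make this adequate at desk scale; global normalized cross-correlation
(NCC) with the template is tracked at the finest level, the best iterate
is kept, and a field that would degrade the initial NCC is replaced by the
zero field, so similarity is never made worse.  The per-iteration template
statistic is the median by default (a `templateStat = "mean"` switch is
provided, since template-building tools conventionally use the mean
internally).  Inverse warps come from `invertField()`, a fixed-point
iteration $v \leftarrow -u(x + v(x))$ (30 sweeps, 0.01-voxel tolerance)
that reports its round-trip residual and warns rather than failing
silently.

## Statistical comparison of the two alignments

The structural-space and functional-space cohorts are compared voxelwise
with a paired t statistic on the per-subject differences.  FWE correction
uses sign-flipping of the paired differences with the maximum-|t| null:
corrected $p(v) = (1 + \#\{\max|t^\*| \ge |t(v)|\})/(B + 1)$ over $B$
random sign patterns, or exhaustive enumeration of all $2^n$ patterns when
that is cheaper.  The max-statistic approach was chosen because it is
exact under exchangeability, needs no Gaussian-field assumptions, and
matches the permutation machinery the tract-map analysis uses anyway; no
TFCE or cluster-mass variant is implemented.  Cluster reporting thresholds
the corrected p-map, labels 26-connected components, and reports voxel
count, minimum corrected p, paired Cohen's d (mean/sd of the differences)
at the peak-|t| voxel — the natural reading of an otherwise unlabelled
"effect size" of this magnitude — and a |t|-weighted centre of gravity in
world mm (FSL cluster conventions).

Binarised tract visitation maps are tested with a one-sample t whose
variance image is Gaussian-smoothed (σ = 4 mm) before forming the
statistic — near-binary data make raw voxelwise variances degenerate
(a voxel shared by *all* subjects has zero variance and would otherwise be
untestable); smoothing borrows variance from neighbours, and is re-applied
inside every permutation.

## ROI connectivity

ROIs come from the 0.3-thresholded group map (strictly greater than — one
rule pipeline-wide), labelled by 26-connectivity and split at the world
x = 0 plane when a component straddles the midline; manually supplied
masks (the subcortical nuclei) are appended and may overlap (with a
warning).  Mean ROI series give full Pearson matrices; partial
correlations are computed per subject by inverting the correlation matrix,
$\rho_{ij} = -P_{ij}/\sqrt{P_{ii}P_{jj}}$, with a decade-stepped ridge
(from 1e-8, at most 0.1, logged) only when the condition number exceeds
1e8 — with 33 ROIs and a few hundred time points the problem is well
posed, but synthetic edge cases need the guard.  Cells are Fisher
z-transformed (|r| = 1 clipped first) before paired and one-sample t tests
at the Bonferroni per-comparison level `familyAlpha / (n(n−1)/2)`; for 33
regions and family alpha 0.05 that is 0.05/528 ≈ 9.47 × 10⁻⁵.  Computing
partial correlations per subject and testing across subjects (rather than
pooling series) is the only reading consistent with a one-sample test on
the cells.

## Anatomical validation

Subject masks (maps thresholded at the same 0.3) are brought to the group
grid through the individual inverse warps; `densityMap()` reports the
percentage of subjects covering each voxel, and `overlapStats()` the
percentage of subjects intersecting each nucleus plus median
[25th–75th percentile, linear interpolation] of the per-subject percentage
and absolute (mm³) intersection volumes.  Probabilistic atlas inputs are
expected to be binarised (default 0.5) before intersection.

## Tractography and graph metrics

The tracker consumes a supplied unit direction field (the product of a
spherical-deconvolution reconstruction, which is out of scope) and
preserves the integration and stopping rules exactly: Euler steps of
0.85 mm in both directions from each seed, directions interpolated
componentwise and sign-aligned with the previous step, termination on mask
exit, a per-step turn above 35°, or the 250 mm length budget (shared
across the two half-tracks), and a 20 mm minimum retained length.
Streamlines are selected by crossing two ROIs; endpoint connectomes count
a streamline in cell (i, j) only when its *first* and *last* points fall
in ROI i and ROI j (overlapping ROIs resolve to the first in declared
order, with a warning; no endpoint dilation).  Counts are binarised at
threshold 1 — a single streamline is evidence of connection, and counts do
not measure strength; the stability of the resulting networks between
thresholds 1 and 5 is itself checked on Poisson-count simulations.  Node
degree is the adjacency row sum; betweenness centrality is computed on the
unweighted graph (all shortest paths, endpoints excluded) and reported
both raw and normalised by (n−1)(n−2)/2 — published hub values of order
0.1 on 33 nodes are only consistent with the normalised convention, so
that is primary.  Group summaries are per-node medians across subjects
with range/median/IQR of the node distributions.  The test suite checks
degree and betweenness against an independent oracle that enumerates every
simple path on small random graphs.

## The synthetic cohort and what it does (not) show

`simulateCohort()` generates the conditions the pipeline is scored
against: a 32³ grid of 2 mm voxels; six large cortical-like blobs
(support radius 7 voxels, amplitude 0.9) and two small subcortical-like
blobs (support radius 3 voxels, amplitude 0.4).  Template blobs are
isotropic Gaussians whose stated *radius* is the ~97%-mass support radius
(σ = radius/3), so a "radius" reads like the visible extent of the
structure.  Twenty subjects receive smooth diffeomorphic warps modelled as
a bulk quasi-translation (0.6–1 × the maximum, random direction) plus
smoothed-noise local deformation (σ = 6 voxels), rescaled so the maximum
displacement is 2 voxels.  The bulk component matters: pure
max-rescaled smoothed noise has typical point displacements of only
~0.2–0.3 of its maximum, which would leave small structures essentially
aligned and the whole misalignment problem moot; with the bulk term the
typical displacement is comparable to the small blobs' width, which is
exactly the regime the functional alignment exists to fix.  The
subcortical amplitude 0.4 puts the blob's peak seed correlation near 0.44
— above the 0.3 threshold when aligned, below it once displaced by a
typical warp.

BOLD-like series (T = 200, about two-thirds of a typical 10-minute run,
chosen to keep the full experiment a few minutes on one CPU) are
`template × s(t)` plus confounds and white noise, with `s` a standardised
AR(1) latent signal (ρ = 0.3, mimicking BOLD autocorrelation) and noise
sd 1/snr so a template-1 voxel has correlation snr/√(1+snr²) with the
signal (snr = 1.5 → r ≈ 0.83).  Per-subject seed masks are 2-voxel-radius
spheres at the warped seed centres.  The generator does **not** model
haemodynamic convolution, spatially correlated noise, scanner drift
beyond a linear term, susceptibility dropout, or any diffusion signal —
so passing tests demonstrate that the algorithms recover known structure
under realistic statistical behaviour, not that the pipeline is robust to
every artefact of real data.

## Numerical choices and degenerate inputs

Zero-variance voxels: r = 0 in maps, t = 0 and exclusion from permutation
inference.  Constant images: zero field with a warning from registration;
excluded (warned) from template building.  Non-invertible affines,
empty seeds/ROIs/nuclei, asymmetric adjacencies and violated warp
invertibility margins raise errors.  Exactly-at-threshold values are
excluded everywhere (strict >).  All generators are pure functions of
their seed, and registration is deterministic given its inputs.

## Problem sizes used in validation

The shipped validation uses a 20-subject cohort on a 32³ grid with 4
template iterations (a few minutes on one CPU); FWE calibration uses 200
null simulations of 10 pairs × 500 voxels × 1000 sign flips; the
permutation oracle compares 10⁴ sampled flips with the exhaustive 2⁸
enumeration; the graph oracle enumerates all simple paths on 200 random
graphs of up to 7 nodes; partial-correlation recovery uses a 33-node
chain precision at T = 2000.  These sizes were chosen so the whole suite
runs comfortably at a desk while leaving each statistical check enough
resolution to fail visibly if an algorithm were wrong.

## Known limitations

The demons-style registration is not a reproduction of greedy SyN — it is
a same-modality surrogate with the same role (nonlinear alignment driven
by a cross-correlation-style similarity), adequate for scalar correlation
maps but not for multi-modal or large-deformation problems.  Field
inversion is fixed-point, accurate for the smooth, small-displacement
warps used here (round-trip residual < 0.1 voxel at ≤ 2-voxel warps).
Betweenness ties are not broken: hub identity should be read from the
full median table.  TCK I/O implements the common Float32LE layout only.
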