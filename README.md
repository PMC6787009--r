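# dmnalign

Group studies of resting-state fMRI usually align subjects through their
anatomy. Small functional structures — basal-forebrain nuclei, anterior and
mediodorsal thalamus, mammillary bodies — are only a few voxels across, and
the residual misalignment left by anatomical normalisation is of the same
order as their size, so they vanish from group maps even when every subject
shows them. `dmnalign` implements, in R, a desk-scale pipeline that fixes
this by aligning subjects *by their functional maps themselves*, and then
quantifies what changed:

1. **Individual DMN maps** — per-voxel Pearson correlation with each of 40
   seed regions after confound regression; the individual map is the
   voxelwise *median* of the 40 seed maps, the group map the median across
   subjects.
2. **Functional-space alignment** — iterative (n = 4) groupwise template
   construction: each subject's map is nonlinearly registered
   (greedy demons-style, cross-correlation-tracked, diffeomorphic) to the
   evolving median template, with drift control and inverse warps.
3. **Statistics** — voxelwise paired t-maps with family-wise error control
   by sign-flip maximum-statistic permutation (exhaustive when 2^n is
   small), cluster tables with Cohen's d and centres of gravity; one-sample
   t-maps with 4 mm variance smoothing for binarised tract maps.
4. **ROI connectivity** — ROIs from the r > 0.3 thresholded group map
   (midline-split connected components, plus manual subcortical masks),
   full and partial correlation matrices per subject, Fisher-z t-tests at
   the Bonferroni level α/(n(n−1)/2): for 33 ROIs, 0.05/528 ≈ 9.47 × 10⁻⁵.
5. **Anatomical validation** — subject masks mapped back through inverse
   warps, subject-density maps, and per-nucleus overlap statistics
   (percent of subjects intersecting; median [IQR] percent and mm³).
6. **Structural hubs** — deterministic streamline tracking on a direction
   field (step 0.85 mm, angle 35°, min length 20 mm), endpoint connectomes
   binarised at count ≥ 1, node degree and normalised betweenness
   centrality with group medians.
7. **Ground-truth synthesis** — cohorts with a known network template,
   subject-specific diffeomorphic warps, AR(1) latent BOLD-like signals,
   synthetic atlas nuclei and Poisson streamline-count connectomes, so
   every stage above is testable without any download.

The core containers are S4 classes (`ScalarVolume`, `TimeSeriesVolume`,
`DisplacementField`, `ROISet`, `CorrelationMatrix`, `Connectome`,
`StreamlineSet`) with validity checks, accessors and NIfTI-1 / TCK I/O.
See the methods vignette (`vignettes/functional-alignment-methods.Rmd`)
for the model, parameter and design rationale.

## Worked example

Six synthetic subjects, mapped and aligned:

```r
library(dmnalign)

cohort <- simulateCohort(nSubjects = 6L, T = 120L, seed = 42L)
maps <- lapply(1:6, function(i) {
  ts <- regressConfounds(subjectTimeseries(cohort, i), cohort@confounds)
  individualDmnMap(ts, subjectSeedSet(cohort, i))
})
fit <- buildFunctionalTemplate(maps, registrationParams(nTemplateIters = 2L))
aligned <- Map(resampleVolume, maps, fit@forwardWarps)

pairs <- combn(6, 2)
dice <- function(ms) mean(apply(pairs, 2, function(p)
  diceCoefficient(dmnMask(ms[[p[1]]]), dmnMask(ms[[p[2]]]))))
cat("mean pairwise Dice before alignment:", round(dice(maps), 3), "\n")
cat("mean pairwise Dice after alignment: ", round(dice(aligned), 3), "\n")
```

```
mean pairwise Dice before alignment: 0.629
mean pairwise Dice after alignment:  0.889
```

The 0.3-thresholded individual maps overlap far better after functional
alignment — the misaligned cohort has been pulled onto a common functional
template. Structural hubs from simulated streamline-count connectomes:

```r
conn <- simulateConnectome(cohort@trueAdjacency, meanCount = 50,
                           nSubjects = 6, seed = 43L)
gm <- graphMetrics(lapply(conn, binarizeConnectome))
gm$groupMedian
```

```
    node degree betweenness
1 mpfc_l      2   0.0000000
2 mpfc_r      2   0.0000000
3  pcc_l      2   0.0000000
4  pcc_r      2   0.0000000
5  ppc_l      1   0.0000000
6  ppc_r      1   0.0000000
7 thal_l      7   0.9047619
8 thal_r      1   0.0000000
```

The planted thalamic hub is recovered with the highest degree and all of
the network's betweenness — the pattern that marks a node as a structural
hub of the network.

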