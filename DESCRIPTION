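Package: dmnalign
Title: Functional-Space Alignment and Network Analysis of Individual
    Default-Mode Connectivity Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds individual default-mode-network (DMN) connectivity maps
    from resting-state time series by seed-based correlation, aligns them in
    a functional space through iterative groupwise diffeomorphic template
    construction, and compares the structural- and functional-space
    alignments with voxelwise paired statistics under sign-flip permutation
    family-wise error control.  Region-of-interest connectivity is
    quantified with full and partial correlation matrices and
    Bonferroni-corrected tests, anatomical plausibility with atlas-overlap
    statistics and subject-density maps, and structural hubs with
    deterministic streamline tractography, endpoint connectomes and graph
    metrics (degree, betweenness centrality).  A synthetic-cohort generator
    with known ground truth (shared network template, subject-specific
    smooth warps, latent BOLD-like signals, streamline-count connectomes)
    makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils-internal.R'
    'volumes.R'
    'nifti-io.R'
    'config.R'
    'synthetic.R'
    'cohort.R'
    'dmn-mapping.R'
    'registration.R'
    'voxel-stats.R'
    'roi-analysis.R'
    'atlas-overlap.R'
    'tractography.R'
    'graph-metrics.R'
    'pipeline.R'
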