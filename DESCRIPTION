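Package: aftract
Title: Along-Tract Tractometry of the Arcuate Fasciculus with Spectral
    Parameterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Along-tract analysis of white-matter bundles from diffusion
    tensor imaging (DTI). A thresholded tract density volume is
    parameterized into a one-dimensional coordinate with the Fiedler
    vector of its voxel-adjacency graph Laplacian and divided into
    equally spaced segments; per-segment median DTI measures (FA, MD,
    AD, RD) form along-tract profiles. Healthy-control profiles define
    outlier-robust normative ranges from which abnormal-segment counts
    are derived for patients; an fMRI laterality index summarizes
    hemispheric language dominance; exact Mann-Whitney tests,
    Benjamini-Hochberg false discovery rate control, and Spearman rank
    correlations compare patient groups. A synthetic phantom generator
    (curved tube density maps, DTI cohorts with focal lesions,
    lateralized activation maps) provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
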