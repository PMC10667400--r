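Package: radrepro
Title: Test-Retest Reproducibility of Radiomics Features Across Pre-Processing Settings
Version: 0.1.0
Authors@R: person("radrepro", "developers", role = c("aut", "cre"),
    email = "radrepro@example.org")
Description: A pipeline for studying how image pre-processing choices affect the
    test-retest reproducibility of radiomics features extracted from paired 3D
    scans (e.g., T2-weighted prostate MRI acquired twice). Implements a 48-setting
    pre-processing grid (fixed-bin-number and fixed-bin-size gray-level
    discretization, dual-reference signal-intensity normalization, and
    mean +/- 3 sigma intensity outlier re-segmentation), a self-contained engine
    for 107 radiomics features in 7 groups (first-order, GLCM, GLDM, GLRLM, GLSZM,
    NGTDM, 3D shape), inter-scan reliability scoring with the two-way random
    single-measurement intra-class correlation coefficient ICC(2,1), selection of
    the best pre-processing setting, nonparametric group comparisons
    (Mann-Whitney U, Kruskal-Wallis) with Benjamini-Hochberg correction, and a
    synthetic paired-cohort simulator with known true reliability for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
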