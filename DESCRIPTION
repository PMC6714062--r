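Package: longaxis
Title: Connectivity-Based Parcellation of the Hippocampal Long Axis and
    Seed-Based Group Inference for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Resting-state functional-connectivity analysis of an elongated
    region of interest along its long axis: temporal cleaning of BOLD time
    series (band-pass filtering, CompCor-style nuisance extraction, artifact
    spike regressors, mask-normalized Gaussian smoothing), k-means
    parcellation of the group-averaged second-order correlation matrix of
    voxel connectivity fingerprints, seed-based group contrasts with
    permutation cluster-extent inference and FDR correction, small-volume
    correction, sphere-seed ROI-to-ROI connectivity, brain-behavior
    correlation against neuropsychological factor scores, and the
    contingency-table and ANOVA statistics used for cohort demographics.
    Includes a synthetic multi-subject phantom generator with planted
    anterior/posterior network structure, nuisance components and behavior
    coupling, so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    signal,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
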