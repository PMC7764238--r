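Package: fconnet
Title: Resting-State Functional Connectome Construction and Group Network Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds weighted functional brain networks from regional BOLD
    time series and tests treatment effects on their topology. Covers
    physiological (RETROICOR-style) and motion confound regression, temporal
    cleaning (demean, detrend, de-spike, band-pass), atlas parcellation,
    squared-correlation similarity graphs thresholded at the percolation
    (connectedness-preserving) edge weight, node-level graph metrics
    (strength, eigenvector, betweenness, weighted clustering), and a
    mixed-design repeated-measures ANOVA with a baseline-controlled
    interaction contrast and false-discovery-rate correction. A synthetic
    cohort generator with known ground-truth covariance structure and
    planted group-by-time network effects makes every stage testable without
    access to subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
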