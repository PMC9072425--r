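Package: pvsmorph
Title: Detection, Morphometry and Longitudinal Analysis of White-Matter
    Perivascular Spaces on T1-Weighted MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated detection of MRI-visible white-matter perivascular
    spaces (PVS) in 3D T1-weighted volumes via local-neighborhood intensity
    filtering (rank-percentile and percent-contrast criteria inside an
    eroded white-matter mask), 26-connected clustering, and per-cluster
    shape descriptors (volume, length, width, linearity). Computes the five
    standard subject-session PVS outcome metrics with white-matter and
    intracranial-volume normalization, and provides the longitudinal cohort
    machinery used in spaceflight neuroimaging studies: ICC(3,k) test-retest
    reliability gating, pre- to post-flight change models with stepwise AIC
    covariate selection, prior-experience and ventricular-volume
    correlations, and subgroup contrasts. Includes a synthetic 3D phantom
    generator with known tubular ground truth and a longitudinal cohort
    simulator so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
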