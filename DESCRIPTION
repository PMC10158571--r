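Package: natisc
Title: Leave-One-Out Inter-Subject Correlation Analysis for Naturalistic fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying stimulus tracking in functionally localized
    brain networks during naturalistic fMRI paradigms. Implements temporal
    preprocessing (noise-ROI principal components, motion and outlier
    regressors, zero-phase band-pass filtering), localizer GLMs with
    group-constrained subject-specific functional ROI definition,
    leave-one-out inter-subject correlations (ISC) with Fisher
    transformation, significance testing against phase-randomization
    surrogate nulls with analytic combination across participants, and
    linear mixed-effects network-by-condition contrasts with Satterthwaite
    degrees of freedom. Ships a synthetic multi-subject BOLD generator with
    known planted structure so the full pipeline is testable without any
    imaging data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    signal,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
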