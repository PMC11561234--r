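Package: cogreserve
Title: Multivariate Moderation Modelling of Cognitive Reserve from Task fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating a cognitive-reserve (CR) activity pattern from
    task fMRI contrast maps in the Alzheimer's disease continuum. A one-dimensional
    pathological-load score is derived from CSF amyloid, CSF p-tau and hippocampal
    volume by nonlinear embedding; a principal-component moderation regression finds
    the voxel-level activity pattern whose expression attenuates the effect of
    pathology on cognitive performance; bootstrap resampling provides voxelwise
    confidence intervals and cluster descriptives; individual CR scores are validated
    cross-sectionally and longitudinally with linear mixed-effects models. A seeded
    synthetic-cohort generator with known ground truth supports end-to-end testing
    without access-restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    RNifti,
    Rtsne,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
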