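Package: molarAge
Title: Forensic Age Prediction from MRI Third-Molar Tissue Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting whether a sub-adult is older than 18 years
    from MRI-derived third-molar tissue volumes. Implements intensity-threshold
    segmentation of tooth voxel images into pulp, predentine and hard tooth
    tissue; enumeration of tissue-volume transformation outcomes with
    Pearson-correlation redundancy filtering; weighted least-squares model
    selection over sex structures and variance weightings by AIC; ranking of
    tooth combinations by the age p-value; and Bayesian inversion of the
    selected regression into a posterior age distribution on a bounded uniform
    prior, reporting the probability of majority. A synthetic-cohort and
    voxel-phantom generator with the assumed statistical structure makes the
    whole pipeline testable without subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
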