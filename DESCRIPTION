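Package: agiletms
Title: Data-Driven Target Selection for Theta-Burst Stimulation from
    Normative Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Normative modelling of resting-state functional connectivity
    for individualized transcranial magnetic stimulation (TMS) target
    selection. Parcel-averaged BOLD time series are turned into shrunk
    correlation matrices, embedded in the tangent space at the geometric
    mean of a healthy reference cohort, and scored edge-wise against a
    per-edge Gaussian normative model with 3-sigma outlier calling and
    exclusion of the most variable third of edges. Anomalous parcels are
    ranked by their in-network anomaly column counts ('agile' target
    selection), assigned continuous or intermittent theta-burst protocols
    by the hyper/hypo-connectivity majority, and planned into an
    accelerated 5 x 5 session course. Includes a synthetic-cohort
    generator for end-to-end validation and the paired-sample outcome
    statistics (mean imputation, paired t, repeated-measures ANOVA) used
    to evaluate treatment response.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
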