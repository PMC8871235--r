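Package: ctriage
Title: Normative-Atlas Anomaly Detection and Triage for Head CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Weakly supervised anomaly detection for head computed
    tomography. Fits a voxel-wise Gaussian normative atlas from spatially
    normalized normal scans, flags voxels falling outside per-voxel
    confidence bounds, summarises them into a patient-level anomaly score
    (the ratio of outlier voxels to brain volume), and calibrates a pair of
    score thresholds that triage scans into normal, inconclusive and
    pathological under a zero false-omission-rate constraint. Ships a
    synthetic CT phantom generator with focal hyper- and hypodense lesions,
    a simplified pluggable affine registration, a reader-study simulator,
    and the diagnostic-accuracy, test-yield, completeness and
    reporting-time statistics used to evaluate triage support.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
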