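Package: tlefocus
Title: Multimodal Lateralization of the Temporal Lobe Epilepsy Focus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Lateralizes the epileptogenic focus in temporal lobe epilepsy
    (TLE) by correlating three analyses: hippocampal volumetry and pixel
    statistics on T2-weighted MRI with a linear discriminant classifier,
    simplified voxel-based morphometry (VBM) comparing a single patient's
    gray-matter map against a control cohort with cluster-extent
    thresholding, and ictal EEG channel-energy asymmetry over symmetric
    bipolar pairs. Per-analysis LEFT/RIGHT labels are fused by a signed
    label sum. Includes seeded synthetic-data generators for every
    modality so the full pipeline is testable without patient data, plus
    readers and writers for NIfTI volumes and CSV EEG recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    MASS,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
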