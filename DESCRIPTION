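Package: dosetex
Title: Texture Analysis and Variability of 3D Radiotherapy Dose Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Treats a 3D radiotherapy dose distribution as an image whose voxel
    intensity is absolute dose in Gy and extracts IBSI-style texture features
    (intensity statistics, grey-level co-occurrence, run-length and size-zone
    families; 212 features by default) from contoured regions of interest.
    Quantifies feature reproducibility, stability and sensitivity across plan
    cohorts with coefficient-of-variation analysis, threshold-based feature
    selection, set intersection and intraclass correlation. Ships a synthetic
    cylindrical-phantom and plan-cohort generator emulating head-and-neck
    planning conditions, plus minimal DICOM RT-Dose and RT Structure Set
    readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
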