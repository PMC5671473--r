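Package: taupvc
Title: ROI Construction and Geometric Transfer Matrix Partial Volume
    Correction for Tau PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds partial-volume-correction-ready regions of interest from
    structural segmentations and tau PET images, including off-target-binding
    regions (extra-cortical hotspots in skull and meninges, a high/low split
    of the choroid plexus, high/low CSF and bone+meninges classes, and a
    SUIT-based inferior cerebellar gray reference region cleaned of rare
    hotspots), and applies Rousset geometric transfer matrix (GTM) partial
    volume correction. Provides the calculated pre-PVC residual diagnostic
    (normalized within-ROI residual standard deviation, PVCnstd) for
    comparing ROI configurations, a declarative set of ten standard ROI
    configurations, and a synthetic phantom generator with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
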