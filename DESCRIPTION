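Package: qvbridge
Title: PACS-Style Quantitative Visualization Pipeline for CT Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained, testable re-implementation of a DICOM-compatible
    quantitative-visualization pipeline for CT segmentation algorithms: route and
    anonymize an incoming CT series, detect series completion by timeout, assemble
    the DICOM slice stack into a geometric volume (the DICOM-to-NIfTI step), run a
    pluggable segmentation stage, encode the resulting mask as a DICOM SEG object
    linked to the source study, extract the segmented volume in milliliters, and
    emit a DICOM structured report carrying the measurement. A synthetic CT phantom
    generator with ellipsoidal lesions of known analytic volume makes every stage
    exercisable without any external dataset. DICOM part-10 reading and writing
    (Explicit VR Little Endian, including sequences and bit-packed binary
    segmentation frames) is implemented in the package.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
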