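Package: somatrace
Title: Online Cell Detection, Tracking, and Trace Extraction for Two-Photon Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A detector-agnostic pipeline for frame-by-frame analysis of
    two-photon calcium imaging movies. Neuronal somata are located as scored
    bounding boxes (via a pluggable detector; a multiscale Laplacian-of-Gaussian
    reference detector is included), duplicate boxes are suppressed with
    non-maximum suppression on a sum-of-areas overlap ratio, persistent cell
    identities are tracked across detection updates, each box is dynamically
    segmented per frame between the 80th and 95th intensity percentiles, and
    background-subtracted fluorescence traces are extracted online or offline.
    Includes a synthetic movie generator with exportable ground truth, tiled
    detection for mesoscopic fields of view, rigid registration by phase
    correlation, detection metrics, calcium event detection, and
    correlation/dendrogram analytics, plus a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    signal,
    stats,
    tiff,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
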