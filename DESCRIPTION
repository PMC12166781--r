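Package: pdl1tps
Title: PD-L1 Tumor Proportion Scoring from IHC Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cell-count-based estimation of the PD-L1 tumor proportion score
    (TPS) from immunohistochemistry-stained slide images. Implements tissue
    detection by Otsu thresholding with a sub-patch coverage rule, patch-level
    tumor detection with a pluggable per-pixel classification backend, nucleus
    instance detection with a hematoxylin-transform fallback, four-class cell
    typing by per-cell softmax averaging, TPS aggregation, and an
    AI-versus-pathologist concordance layer with discrepancy flagging, cutoff
    concordance and correlation summaries. Ships a synthetic-slide generator
    with known ground truth so the whole pipeline is testable without any
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr,
    optparse
Config/testthat/edition: 3
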