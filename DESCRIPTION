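Package: glomap
Title: Mirror-Symmetric Glomerular Activity Mapping from Widefield
    Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for odor-evoked glomerular calcium signals
    imaged from the dorsal olfactory bulb and, via a mirror-coated prism,
    from its medial wall. Implements block-wise single-exponential
    photobleaching correction with block-noise trial exclusion,
    respiration-triggered trial alignment, trial-averaged dF/F0 activity
    mapping with fixed response and baseline windows, and comparison of
    mirror-symmetric glomerular maps: vertical flip of the through-prism
    view, anterior-posterior registration, glomerulus detection, homologous
    ensemble matching, chemotopic gradient and concentration-response
    quantification. Ships a synthetic-movie generator with full ground
    truth so every stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    png,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
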