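Package: faceseeg
Title: Intracranial Evoked-Potential Analysis of Responses to Emotional
    Facial Expressions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical pipeline for stereo-electroencephalographic (SEEG)
    recordings acquired during the observation of emotional facial
    expressions. Provides per-lead event-related potential (iERP)
    computation with subtractive baseline correction, a consecutive-bin
    responsiveness criterion, repeated-measures Condition-by-Time
    selectivity testing with planned post-hoc contrasts, peak-latency
    classification, geodesic logistic-kernel continuous cortical surface
    maps (sampling density, overall and relative responsiveness),
    parcellation-level regional summaries with chi-squared lateralization
    tests, high-frequency electrical-stimulation outcome tabulation, and
    thresholding plus hierarchical clustering of cortico-cortical
    evoked-potential connectivity-probability matrices. A synthetic-data
    module generates meshes, lead placements, epoched recordings and
    block-structured connectivity matrices with the statistical structure
    the analyses assume.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xml2,
    igraph,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
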