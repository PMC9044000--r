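Package: mprct
Title: Major Pathologic Response Calculation and Tumor-Bed Sampling Simulation for Resected NSCLC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies pathologic response of non-small cell lung cancer resected
    after neoadjuvant therapy. Implements per-slide capture and validation of
    tumor-bed measurements (percent viable tumor, necrosis and stroma with the
    stroma percentage derived so the three always sum to 100), unweighted and
    tumor-bed-area-weighted mean viable tumor, classification of major pathologic
    response (MPR, at most 10 percent viable tumor by default) and pathologic
    complete response (pCR, no viable tumor cells), tumor-bed sampling plans
    (entire bed at 3 cm or less or with suspected pCR, at least 50 percent from
    alternate sections above 3 cm), a deterministic rules table for challenging
    tissue elements (extracellular mucin, fibrovascular cores, cystic cavities,
    hilar and nodal scenarios), a seeded tumor-bed simulator with virtual
    sectioning and an observer-rounding model for benchmarking sampling
    strategies, and interobserver agreement statistics (Bland-Altman limits of
    agreement, two-way absolute-agreement intraclass correlation, Cohen's kappa
    on the MPR dichotomy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
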