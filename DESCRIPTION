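Package: silis
Title: Quantification of RNA Modifications with Biosynthetic Stable-Isotope-Labeled Internal Standards
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for absolute and relative LC-MS/MS quantification of modified
    ribonucleosides against a biosynthetic, uniformly 13C-labeled internal
    standard (SIL-IS). Covers isotopologue mass and abundance modeling for a
    nucleoside registry, derivation of multiple-reaction-monitoring
    transitions via the ribose neutral loss, external calibration with
    linear-dynamic-range and LOD/LOQ estimation, nucleoside-isotope factors
    (NIF) and relative response factors (rRFN), UV-based determination of
    injected RNA amounts, modification yields and enzymatic turnover,
    double-normalized fold changes between samples with background flagging,
    and a seeded instrument simulator reproducing ion suppression, detector
    saturation and inter-session drift for validation of the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    jsonlite,
    Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
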