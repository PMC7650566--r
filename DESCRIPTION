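Package: cantrace
Title: DNA-Based Traceability of Canned Tuna from Cytochrome b Mini-Barcodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the loss of DNA-based species traceability
    along the tuna canning chain. Implements a fixed-coordinate cytochrome b
    reference panel, pairwise p-distance and barcode-gap analysis, diagnostic
    nucleotide position discovery, per-specimen nucleotide substitution (NS)
    accounting relative to the frozen baseline, percent-identity species
    assignment with a 98 percent similarity rule, concordance and
    misidentification bookkeeping, and Poisson mixed-model inference on
    substitution counts. A seeded simulator generates reference panels with a
    planted barcode gap and degrades specimens level by level with
    level-dependent substitution and fragment-amplifiability models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
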