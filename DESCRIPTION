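Package: seedscreen
Title: miRNA Direct-Target Discovery from Pulsed-SILAC Proteomic Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for identifying direct microRNA targets from a pulsed-SILAC
    (pSILAC) overexpression experiment: parsing and median-log normalization of
    heavy/medium protein ratio tables, derivation of a downregulation cut-off
    from an internal positive-control target, exhaustive seed-match scanning of
    3'UTR sequences (complete 7-nt and partial 6-nt Watson-Crick sites),
    direct/indirect/unchanged classification and intensity-based candidate
    ranking. Includes a synthetic-data generator with planted ground truth for
    end-to-end validation, recovery metrics, and dual-luciferase reporter
    normalization arithmetic for downstream target validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
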