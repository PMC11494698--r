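Package: represskit
Title: Quantification and Sequence-Based Design of Plant Transcriptional Repression Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for reporter-assay characterization of short
    transcriptional repression motifs (EAR-type peptides fused to a Gal4
    DNA-binding domain) and for the sequence-based design of synthetic
    repressors. Quantifies plate-reader fluorescence into per-construct
    repression summaries with Gal4/SRDX control normalization, scans for
    canonical EAR patterns (LxLxL, DLNxxP) with exact enrichment tests,
    classifies amino-acid n-grams by strength-quartile representation,
    assembles synthetic repression motifs (SynEARs) in predicted strength
    classes, and evaluates predictions with accuracy-maximizing ordinal
    binning, confusion matrices, and permutation and bootstrap null models.
    A synthetic-data module simulates the assay (including qPCR delta-delta-Cq
    fixtures) so the whole pipeline runs and is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
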