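Package: zftfscreen
Title: Combinatorial Zinc-Finger Transcription-Factor Library Design and
    Resistance-Signature Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models combinatorial zinc-finger transcription-factor (ZF-TF)
    libraries (catalog parsing, array enumeration, degenerate binding-site
    prediction and FASTA scanning) and implements the expression-analysis
    pipeline used to characterise ZF-TF-induced drug resistance: trimmed-mean
    scaling, per-probe-set mean-shift batch correction, variance filtering,
    median polish, row standardisation, average-linkage clustering with
    correlation distance, direction-labelled cluster extraction and projection
    onto external datasets, hypergeometric gene-set enrichment with Holm
    family-wise error control, and metagene-based survival stratification with
    one-sided log-rank testing.  A synthetic-data generator produces
    expression experiments with planted gene modules and batch effects,
    gene-set databases with known enrichments, and survival cohorts with
    metagene-linked hazards, so every stage can be validated against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    Biostrings,
    fgsea,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
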