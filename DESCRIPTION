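Package: notchopa
Title: Genotyping and Phenotype Scoring for the Notch opa Triplet Repeats
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for genotyping the polyglutamine-encoding opa (5'-CAX)
    triplet repeats of Drosophila Notch from Sanger clone libraries.
    Implements the pQ-configuration nomenclature for opa alleles, anchor-based
    extraction of the repeat run from clone sequences, rule-based genotype
    calling with an explicit PCR-slippage (stutter) and contamination error
    model, population summaries including X-linked Hardy-Weinberg
    expectations, the 13-position macrochaete phenotype scoring system, and a
    seeded synthetic-data generator that emulates Sanger clone libraries with
    configurable contraction, expansion and contamination rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
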