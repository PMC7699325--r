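Package: chemosensr
Title: Chemosensory Gene Family Classification and Tissue-Enrichment
    Analysis for Insect Transcriptomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for annotating insect chemosensory gene families from
    assembled transcriptomes and for calling tissue-enriched expression.
    Implements gap-constrained cysteine-signature classification of odorant
    binding proteins (Classical, Minus-C, and dimer subclasses) and
    chemosensory proteins, domain- and transmembrane-based assignment of
    odorant, gustatory, and ionotropic receptor families with
    phylogeny-inclusion filters, TPM/FPKM abundance measures, trimmed mean
    of M-values (TMM) normalization, a no-replicate negative-binomial
    conditional exact test with Benjamini-Hochberg correction,
    expression-cluster partitioning, and Newick tree post-processing
    (midpoint and outgroup rooting, long-branch flagging). Seeded synthetic
    data generators with planted truth support end-to-end validation of
    every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    jsonlite
Config/testthat/edition: 3
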