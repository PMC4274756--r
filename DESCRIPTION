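Package: qtlprio
Title: QTL Candidate Gene Prioritization by Biological-Process Overrepresentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate genes in quantitative trait locus (QTL)
    regions by associating traits with Gene Ontology biological-process (BP)
    terms. For each trait, genes from all of its QTL regions are pooled and
    BP-term overrepresentation is assessed with one-sided Fisher exact tests
    against the genome-wide background, with Benjamini-Hochberg correction
    pooled across all traits and terms. Associations are filtered on FDR, on
    the fraction of the trait's regions in which a term occurs, and on term
    generality; genes annotated with an associated term are the prioritized
    candidates. Includes permutation-based validation against reference gene
    sets (fine-mapped genes, GWAS SNP neighborhoods), annotation
    randomization null runs, transcription-factor profiling, a parameter
    sweep, a synthetic-data generator with planted trait-BP signal, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    optparse,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
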