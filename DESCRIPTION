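Package: TrioSeg
Title: Trio-Based Recessive Variant Discovery and Frameshift Consequence
    Annotation
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering autosomal-recessive disease variants from
    whole-genome sequencing of small pedigrees. Implements per-trio recessive
    segregation filtering of multi-sample VCF genotypes, intersection across
    trios sharing the same parents, private-variant exclusion against a panel
    of additional genomes, transcript-level consequence prediction for
    frameshift and substitution variants (including right-aligned indel
    normalization in mononucleotide repeats and premature-stop truncation
    metrics), effect-score classification, disease-gene list intersection,
    genotype-phenotype concordance testing under a full-penetrance recessive
    model, and small quantification helpers (delta-delta-Ct relative
    expression, rod-count inference, background-corrected autofluorescence).
    A seeded simulator generates every pipeline input, emulating a family
    quartet segregating a single-cytosine insertion in a seven-cytosine
    repeat of an ABCA4-like transcript.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: VariantAnnotation, Genetics, Sequencing, Software
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
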