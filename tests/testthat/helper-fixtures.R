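## Shared fixtures and independent oracles used across the suite.

## write a minimal VCF file from record lines; returns the path
writeToyVcf <- function(records, samples = "S1",
                        formats = "GT", path = tempfile(fileext = ".vcf")) {
    hdr <- c("##fileformat=VCFv4.2",
        "##INFO=<ID=EXONIC,Number=0,Type=Flag,Description=\"Exonic\">",
        "##INFO=<ID=NONSYN,Number=0,Type=Flag,Description=\"Nonsynonymous\">",
        "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        if ("DP" %in% formats)
            "##FORMAT=<ID=DP,Number=1,Type=String,Description=\"Depth\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", samples), collapse = "\t"))
    writeLines(c(hdr, records), path)
    path
}

## hand-written standard genetic code, independent of Biostrings
.ORACLE_CODE <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L",
    CTT = "L", CTC = "L", CTA = "L", CTG = "L",
    ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V",
    TCT = "S", TCC = "S", TCA = "S", TCG = "S",
    CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T",
    GCT = "A", GCC = "A", GCA = "A", GCG = "A",
    TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
    AAT = "N", AAC = "N", AAA = "K", AAG = "K",
    GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W",
    CGT = "R", CGC = "R", CGA = "R", CGG = "R",
    AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracleTranslate <- function(dna) {
    n <- nchar(dna) %/% 3L
    vapply(seq_len(n), function(i)
        unname(.ORACLE_CODE[substr(dna, 3L * i - 2L, 3L * i)]), "")
}

## brute-force consequence oracle: apply the edit, re-translate codon by
## codon, and derive (kind, mutLength, stopPosition) from first principles
oracleConsequence <- function(cds, pos, ref, alt) {
    stopifnot(substr(cds, pos, pos + nchar(ref) - 1L) == ref)
    mut <- paste0(substr(cds, 1L, pos - 1L), alt,
                  substr(cds, pos + nchar(ref), nchar(cds)))
    wtAa <- oracleTranslate(cds)
    mutAa <- oracleTranslate(mut)
    wtStop <- match("*", wtAa)
    wtLen <- if (is.na(wtStop)) length(wtAa) else wtStop - 1L
    mutStop <- match("*", mutAa)
    mutLen <- if (is.na(mutStop)) length(mutAa) else mutStop - 1L
    net <- nchar(alt) - nchar(ref)
    if (net %% 3L != 0L) {
        kind <- "frameshift"
    } else if (net != 0L) {
        kind <- "inframe_indel"
    } else {
        nCmp <- min(length(wtAa), length(mutAa))
        fc <- which(wtAa[seq_len(nCmp)] != mutAa[seq_len(nCmp)])[1]
        kind <- if (is.na(fc)) "synonymous"
            else if (mutAa[fc] == "*" && fc <= wtLen) "stop_gained"
            else if (wtAa[fc] == "*") "stop_lost"
            else "missense"
    }
    list(kind = kind, mutLength = mutLen, stopPosition = mutStop)
}

## random CDS: ATG + sense codons + one stop, no internal stop
.SENSE <- names(.ORACLE_CODE)[.ORACLE_CODE != "*"]
.STOPS <- names(.ORACLE_CODE)[.ORACLE_CODE == "*"]
makeRandomCds <- function(nCodons) {
    paste0("ATG",
           paste(sample(.SENSE, nCodons - 1L, replace = TRUE),
                 collapse = ""),
           sample(.STOPS, 1L))
}

## wrap a bare CDS string as a single-exon plus-strand transcript
wrapCds <- function(cds, contig = "ctg") {
    genome <- Biostrings::DNAStringSet(stats::setNames(cds, contig))
    tm <- transcriptModel("TOY", "toy.1", contig, "+", 1L, nchar(cds))
    list(genome = genome, tm = tm)
}

## independent truth-table rule for the recessive trio filter
oracleTrioKeep <- function(sire, dam, offspring) {
    if (anyNA(c(sire, dam, offspring))) return(FALSE)
    sire == 1L && dam == 1L && offspring == 2L
}

## independent per-variant linear scan for the panel privacy rule
oraclePanelKeep <- function(key, panelKeys, panelGeno) {
    idx <- which(panelKeys == key)
    if (!length(idx)) return(TRUE)
    !any(panelGeno[idx, ] == 2L, na.rm = TRUE)
}

## independent per-dog concordance rule
oracleConcordant <- function(phenotype, genotype) {
    if (phenotype == "affected") genotype == "hom_alt"
    else genotype %in% c("het", "hom_ref")
}

## quartet genotype matrix from an explicit dose table (variants on chrA
## at successive positions with alternating ref/alt)
makeQuartetMatrix <- function(doses, exonic = TRUE, nonsynonymous = TRUE,
                              contig = "chrA") {
    n <- nrow(doses)
    gr <- variantGRanges(contig, seq_len(n) * 10L,
                         rep(c("A", "C"), length.out = n),
                         rep(c("G", "T"), length.out = n),
                         exonic = exonic, nonsynonymous = nonsynonymous)
    genotypeMatrix(gr, doses)
}
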