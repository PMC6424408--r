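#' @import methods
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
NULL

#' Multi-sample diploid genotype matrix over normalized biallelic variants
#'
#' `GenotypeMatrix` extends
#' [SummarizedExperiment::RangedSummarizedExperiment]: rows are biallelic
#' variants (a `GRanges` whose metadata columns carry the `ref` and `alt`
#' alleles plus optional `id`, `exonic`, `nonsynonymous` and `gene`
#' annotations) and columns are samples. The `"GT"` assay stores the
#' alternate-allele dose per call: 0 (hom-ref), 1 (het), 2 (hom-alt) or
#' `NA` (any missing allele makes the whole call missing). Additional VCF
#' FORMAT fields read from a file are preserved opaquely as extra character
#' assays and written back verbatim.
#'
#' Rows are kept in genomic sort order (contig, position, ref, alt) and the
#' (contig, position, ref, alt) key is unique; both are enforced by the
#' constructor/validity. All coordinates are 1-based inclusive.
#'
#' @seealso [genotypeMatrix()], [readVcfMatrix()], [writeVcfMatrix()]
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
    msg <- character()
    if (!"GT" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'GT' is required")
    mc <- mcols(SummarizedExperiment::rowRanges(object))
    if (!all(c("ref", "alt") %in% colnames(mc)))
        msg <- c(msg, "rowRanges metadata must have 'ref' and 'alt' columns")
    if (length(msg) == 0L) {
        gt <- SummarizedExperiment::assay(object, "GT")
        if (!all(gt %in% c(0L, 1L, 2L, NA)))
            msg <- c(msg, "GT doses must be 0, 1, 2 or NA")
        bad <- !grepl("^[ACGT]+$", mc$ref) | !grepl("^[ACGT]+$", mc$alt)
        if (any(bad))
            msg <- c(msg, "ref/alt alleles must be non-empty uppercase A/C/G/T")
        if (any(mc$ref == mc$alt))
            msg <- c(msg, "ref and alt alleles must differ")
        if (anyDuplicated(variantKeys(object)))
            msg <- c(msg, "duplicate (contig, pos, ref, alt) keys")
    }
    if (length(msg)) msg else TRUE
})

#' Transcript model: exon structure mapping genome to coding coordinates
#'
#' Holds the exon layout of a single protein-coding transcript. Exons are
#' `GRanges` on one contig and one strand, ordered and non-overlapping;
#' here the exons are the coding exons, so their concatenation
#' (reverse-complemented on the minus strand) is the CDS, which must begin
#' with a start codon and end with a stop codon in the reference and have
#' length divisible by 3 (checked when sequence is available, see
#' [extractCds()]). Coordinates are 1-based inclusive.
#'
#' @slot gene gene symbol.
#' @slot txId transcript identifier.
#' @slot exons `GRanges` of coding exons (single contig/strand).
#' @seealso [transcriptModel()], [extractCds()], [projectToCds()]
#' @exportClass TranscriptModel
setClass("TranscriptModel",
    representation(gene = "character", txId = "character", exons = "GRanges"))

setValidity("TranscriptModel", function(object) {
    ex <- object@exons
    msg <- character()
    if (length(ex) == 0L)
        return("transcript must have at least one exon")
    if (length(unique(as.character(seqnames(ex)))) != 1L)
        msg <- c(msg, "all exons must lie on one contig")
    st <- unique(as.character(strand(ex)))
    if (length(st) != 1L || !st %in% c("+", "-"))
        msg <- c(msg, "strand must be a single '+' or '-'")
    if (is.unsorted(start(ex)) ||
        any(start(ex)[-1] <= end(ex)[-length(ex)]))
        msg <- c(msg, "exons must be ordered and non-overlapping")
    if (length(msg)) msg else TRUE
})

#' Classified effect of a coding variant on the translated product
#'
#' Produced by [callConsequence()]. Protein lengths never count the stop
#' codon. For a frameshift that reaches a new stop, `mutLength` is
#' `stopPosition - 1` and `residuesLost` is `wtLength - mutLength`, i.e. the
#' number of wild-type C-terminal residues missing from the truncated
#' product (substituted residues between the first changed position and the
#' new stop are counted separately via `firstChanged`).
#'
#' @slot kind one of `synonymous`, `missense`, `frameshift`, `stop_gained`,
#'   `stop_lost`, `inframe_indel`, `start_lost`.
#' @slot cName HGVS-style coding name (e.g. `"c.4176insC"`).
#' @slot pName protein-level name; by default the absolute-stop dialect
#'   `"p.F1393Lfs*1395"` where the number after `*` is the absolute codon
#'   index of the new stop (see [callConsequence()] for the standard
#'   HGVS-style alternative).
#' @slot wtLength,mutLength wild-type / mutant product length in residues.
#' @slot stopPosition absolute codon index of the new stop, or `NA`.
#' @slot residuesLost `wtLength - mutLength`.
#' @slot firstChanged 1-based index of the first residue differing from
#'   wild type, or `NA` for synonymous changes.
#' @exportClass ProteinConsequence
setClass("ProteinConsequence",
    representation(kind = "character", cName = "character",
                   pName = "character", wtLength = "integer",
                   mutLength = "integer", stopPosition = "integer",
                   residuesLost = "integer", firstChanged = "integer"))

#' Genotype-phenotype concordance under a full-penetrance recessive model
#'
#' Produced by [concordanceTest()]. `perDog` has one row per animal with a
#' known phenotype and non-missing genotype; `nConcordant + nDiscordant`
#' always equals `nrow(perDog)`.
#'
#' @slot perDog data.frame with columns `id`, `phenotype`, `genotype`,
#'   `concordant`.
#' @slot nConcordant,nDiscordant totals.
#' @slot discordantIds ids of discordant animals (candidate-exclusion
#'   decisions are left to the caller).
#' @exportClass ConcordanceResult
setClass("ConcordanceResult",
    representation(perDog = "data.frame", nConcordant = "integer",
                   nDiscordant = "integer", discordantIds = "character"))
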