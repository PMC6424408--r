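## Transcript models and coding/protein consequence prediction.

#' Construct a TranscriptModel
#'
#' @param gene gene symbol.
#' @param txId transcript identifier.
#' @param contig contig name.
#' @param strand `"+"` or `"-"`.
#' @param exonStarts,exonEnds 1-based inclusive coding-exon bounds, in
#'   genomic order.
#' @return a [TranscriptModel-class].
#' @examples
#' tm <- transcriptModel("TOY", "toy.1", "chrA", "+", c(1, 10), c(6, 15))
#' cdsLength(tm)
#' @export
transcriptModel <- function(gene, txId, contig, strand, exonStarts, exonEnds) {
    ex <- GRanges(contig, IRanges(as.integer(exonStarts),
                                  as.integer(exonEnds)), strand = strand)
    new("TranscriptModel", gene = gene, txId = txId, exons = ex)
}

#' @describeIn transcriptModel coding-exon `GRanges` accessor.
#' @param tm a `TranscriptModel`.
#' @export
exons <- function(tm) tm@exons

#' @describeIn transcriptModel gene symbol accessor.
#' @export
geneSymbol <- function(tm) tm@gene

#' @describeIn transcriptModel total CDS length in nucleotides.
#' @export
cdsLength <- function(tm) sum(width(tm@exons))

setMethod("show", "TranscriptModel", function(object) {
    cat(sprintf("TranscriptModel %s (%s): %d exon(s), CDS %d nt, %s strand %s\n",
                object@txId, object@gene, length(object@exons),
                cdsLength(object),
                as.character(seqnames(object@exons))[1],
                as.character(strand(object@exons))[1]))
})

#' Read/write transcript models as a tab-delimited exon table
#'
#' Minimal dialect: columns `gene`, `transcript`, `contig`, `strand`,
#' `exon_start`, `exon_end`; one row per coding exon, 1-based inclusive
#' coordinates, rows of one transcript contiguous and in genomic order.
#'
#' @param path file path.
#' @return `readTranscriptTable`: named list of [TranscriptModel-class];
#'   `writeTranscriptTable`: `path`, invisibly.
#' @export
readTranscriptTable <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene", "transcript", "contig", "strand",
              "exon_start", "exon_end")
    if (!all(need %in% colnames(tab)))
        stop("transcript table must have columns: ",
             paste(need, collapse = ", "))
    lapply(split(tab, tab$transcript), function(d) {
        transcriptModel(d$gene[1], d$transcript[1], d$contig[1],
                        d$strand[1], d$exon_start, d$exon_end)
    })
}

#' @rdname readTranscriptTable
#' @param tms list of `TranscriptModel`.
#' @export
writeTranscriptTable <- function(tms, path) {
    rows <- do.call(rbind, lapply(tms, function(tm) {
        ex <- tm@exons
        data.frame(gene = tm@gene, transcript = tm@txId,
                   contig = as.character(seqnames(ex)),
                   strand = as.character(strand(ex)),
                   exon_start = start(ex), exon_end = end(ex))
    }))
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

## ---- sequence helpers ------------------------------------------------------

.revcomp <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

## translate a DNA string codon-wise; returns a character vector of
## one-letter residues including '*' for stops; trailing partial codon dropped
.translateAa <- function(dna) {
    n <- 3L * (nchar(dna) %/% 3L)
    if (n == 0L) return(character())
    aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(dna, 1L, n)), no.init.codon = TRUE))
    strsplit(aa, "")[[1]]
}

#' Extract the strand-corrected CDS of a transcript
#'
#' Concatenates the coding exons in genomic order and reverse-complements
#' on the minus strand. Errors if the CDS length is not divisible by 3;
#' warns if it does not begin with ATG, does not end in a stop codon, or
#' contains an internal in-frame stop.
#'
#' @param tm a [TranscriptModel-class].
#' @param genome named `DNAStringSet` (or coercible) of contig sequences.
#' @return the CDS as a single character string.
#' @export
extractCds <- function(tm, genome) {
    genome <- Biostrings::DNAStringSet(genome)
    ex <- tm@exons
    ctg <- as.character(seqnames(ex))[1]
    if (!ctg %in% names(genome))
        stop("contig not in reference: ", ctg)
    sq <- as.character(genome[[ctg]])
    if (max(end(ex)) > nchar(sq))
        stop("exon coordinates exceed contig length")
    cds <- paste(substring(sq, start(ex), end(ex)), collapse = "")
    if (as.character(strand(ex))[1] == "-")
        cds <- .revcomp(cds)
    if (nchar(cds) %% 3L != 0L)
        stop("transcript model error: CDS length not divisible by 3")
    aa <- .translateAa(cds)
    if (aa[1] != "M")
        warning("CDS of ", tm@txId, " does not begin with a start codon")
    if (aa[length(aa)] != "*")
        warning("CDS of ", tm@txId, " does not end with a stop codon")
    if (any(aa[-length(aa)] == "*"))
        warning("internal stop codon in reference frame of ", tm@txId)
    cds
}

## genomic position -> 1-based CDS position (NA if not in an exon)
.genomicToCds <- function(tm, gpos) {
    ex <- tm@exons
    cumBefore <- c(0L, cumsum(width(ex)))[seq_along(ex)]
    total <- sum(width(ex))
    minus <- as.character(strand(ex))[1] == "-"
    vapply(gpos, function(g) {
        j <- which(g >= start(ex) & g <= end(ex))
        if (length(j) != 1L) return(NA_integer_)
        plusPos <- cumBefore[j] + (g - start(ex)[j] + 1L)
        if (minus) total - plusPos + 1L else plusPos
    }, 0L)
}

#' Map CDS positions to genomic positions
#'
#' Inverse of the genomic-to-coding projection used by [projectToCds()].
#'
#' @param tm a [TranscriptModel-class].
#' @param cpos 1-based CDS position(s).
#' @return genomic position(s), 1-based.
#' @export
cdsToGenomic <- function(tm, cpos) {
    ex <- tm@exons
    cumBefore <- c(0L, cumsum(width(ex)))[seq_along(ex)]
    total <- sum(width(ex))
    minus <- as.character(strand(ex))[1] == "-"
    vapply(as.integer(cpos), function(cp) {
        if (is.na(cp) || cp < 1L || cp > total)
            stop("CDS position out of range: ", cp)
        plusPos <- if (minus) total - cp + 1L else cp
        j <- max(which(cumBefore < plusPos))
        start(ex)[j] + (plusPos - cumBefore[j] - 1L)
    }, 0L)
}

#' Project a genomic variant into coding coordinates
#'
#' Maps a variant through a transcript model, honoring strand, and emits
#' its coding-space spelling and HGVS-style name. Indels are 3'-shifted
#' *in transcript coordinates* so that the insertion of a cytosine inside
#' the seven-cytosine run ending at c.4176 is named `c.4176insC` (the
#' insertion is reported after the last base of the run; the standard HGVS
#' alternative `c.4176_4177insC` is available via `dialect = "hgvs"`).
#' SNVs are named `c.<pos><ref>><alt>`. A variant not fully inside the
#' coding exons is reported as non-coding rather than an error.
#'
#' @param v a single-row variant `GRanges` (see [variantGRanges()]).
#' @param tm a [TranscriptModel-class].
#' @param genome named `DNAStringSet` (or coercible).
#' @param dialect `"paper"` (absolute-anchor insertion names, default) or
#'   `"hgvs"`.
#' @return a list with elements `coding` (logical), and when coding:
#'   `cPos`, `cRef`, `cAlt` (coding-space anchored spelling), `cName`,
#'   and `type` (`"snv"`, `"ins"`, `"del"`, `"delins"`).
#' @export
projectToCds <- function(v, tm, genome, dialect = c("paper", "hgvs")) {
    dialect <- match.arg(dialect)
    genome <- Biostrings::DNAStringSet(genome)
    stopifnot(length(v) == 1L)
    ctg <- as.character(seqnames(v))
    if (ctg != as.character(seqnames(tm@exons))[1])
        return(list(coding = FALSE))
    pos <- start(v)
    ref <- mcols(v)$ref; alt <- mcols(v)$alt
    span <- pos:(pos + nchar(ref) - 1L)
    cspan <- .genomicToCds(tm, span)
    if (anyNA(cspan))
        return(list(coding = FALSE))
    minus <- as.character(strand(tm@exons))[1] == "-"
    cds <- extractCds(tm, genome)
    if (minus) {
        cPos <- cspan[length(cspan)]
        cRef <- .revcomp(ref); cAlt <- .revcomp(alt)
    } else {
        cPos <- cspan[1]
        cRef <- ref; cAlt <- alt
    }
    if (substr(cds, cPos, cPos + nchar(cRef) - 1L) != cRef)
        stop("reference mismatch in CDS projection at c.", cPos)
    nv <- .normalizeInString(cds, cPos, cRef, cAlt, "right")
    cPos <- nv$pos; cRef <- nv$ref; cAlt <- nv$alt
    nr <- nchar(cRef); na <- nchar(cAlt)
    if (nr == 1L && na == 1L) {
        type <- "snv"
        cName <- sprintf("c.%d%s>%s", cPos, cRef, cAlt)
    } else if (na > nr && substr(cAlt, 1L, nr) == cRef && nr == 1L) {
        type <- "ins"
        core <- substr(cAlt, 2L, na)
        cName <- if (dialect == "paper")
            sprintf("c.%dins%s", cPos, core)
        else sprintf("c.%d_%dins%s", cPos, cPos + 1L, core)
    } else if (nr > na && substr(cRef, 1L, na) == cAlt && na == 1L) {
        type <- "del"
        from <- cPos + 1L; to <- cPos + nr - 1L
        cName <- if (from == to) sprintf("c.%ddel", from)
                 else sprintf("c.%d_%ddel", from, to)
    } else {
        type <- "delins"
        cName <- sprintf("c.%d_%ddelins%s", cPos, cPos + nr - 1L, cAlt)
    }
    list(coding = TRUE, cPos = cPos, cRef = cRef, cAlt = cAlt,
         cName = cName, type = type)
}

#' Predict the protein-level consequence of a coding variant
#'
#' Applies the variant to the CDS, translates wild-type and mutant with
#' the standard nuclear genetic code, locates the first changed residue
#' and any new stop, and classifies the effect. Protein lengths exclude
#' the stop codon. For a frameshift the default protein name uses the
#' absolute-stop dialect, e.g. `p.F1393Lfs*1395` where 1395 is the
#' absolute codon index of the premature stop; `dialect = "hgvs"` counts
#' the stop from the first changed residue instead (`p.F1393Lfs*3`).
#' `residuesLost` is defined as `wtLength - mutLength` (e.g. a 2,268-aa
#' product truncated to 1,394 aa loses 874 C-terminal residues).
#'
#' @inheritParams projectToCds
#' @return a [ProteinConsequence-class].
#' @examples
#' genome <- Biostrings::DNAStringSet(c(chrA = "ATGAAATTTGGCTAA"))
#' tm <- transcriptModel("TOY", "toy.1", "chrA", "+", 1, 15)
#' v <- variantGRanges("chrA", 5, "A", "AG")   # 1-bp insertion
#' callConsequence(v, tm, genome)
#' @export
callConsequence <- function(v, tm, genome, dialect = c("paper", "hgvs")) {
    dialect <- match.arg(dialect)
    genome <- Biostrings::DNAStringSet(genome)
    cv <- projectToCds(v, tm, genome, dialect)
    if (!isTRUE(cv$coding))
        stop("variant does not overlap the coding exons of ", tm@txId)
    cds <- extractCds(tm, genome)
    mut <- paste0(substr(cds, 1L, cv$cPos - 1L), cv$cAlt,
                  substr(cds, cv$cPos + nchar(cv$cRef), nchar(cds)))
    wtAa <- .translateAa(cds)
    mutAa <- .translateAa(mut)
    wtStopIdx <- match("*", wtAa)
    wtLen <- if (is.na(wtStopIdx)) length(wtAa) else wtStopIdx - 1L
    mutStopIdx <- match("*", mutAa)
    mutLen <- if (is.na(mutStopIdx)) length(mutAa) else mutStopIdx - 1L
    nCmp <- min(length(wtAa), length(mutAa))
    diffs <- which(wtAa[seq_len(nCmp)] != mutAa[seq_len(nCmp)])
    fc <- if (length(diffs)) diffs[1] else NA_integer_
    netDiff <- nchar(cv$cAlt) - nchar(cv$cRef)

    mk <- function(kind, pName, mutLength, stopPosition, firstChanged)
        new("ProteinConsequence", kind = kind, cName = cv$cName,
            pName = pName, wtLength = as.integer(wtLen),
            mutLength = as.integer(mutLength),
            stopPosition = as.integer(stopPosition),
            residuesLost = as.integer(wtLen - mutLength),
            firstChanged = as.integer(firstChanged))

    if (!is.na(fc) && fc == 1L && wtAa[1] == "M" && mutAa[1] != "M")
        return(mk("start_lost", "p.M1?", 0L, NA, 1L))

    if (netDiff %% 3L != 0L) {                      # frameshift
        if (is.na(fc)) fc <- mutLen + 1L            # stop hit immediately
        pName <- if (!is.na(mutStopIdx) && mutStopIdx == fc)
            sprintf("p.%s%d*", wtAa[fc], fc)
        else if (is.na(mutStopIdx))
            sprintf("p.%s%d%sfs*?", wtAa[fc], fc, mutAa[fc])
        else if (dialect == "paper")
            sprintf("p.%s%d%sfs*%d", wtAa[fc], fc, mutAa[fc], mutStopIdx)
        else
            sprintf("p.%s%d%sfs*%d", wtAa[fc], fc, mutAa[fc],
                    mutStopIdx - fc + 1L)
        return(mk("frameshift", pName,
                  if (is.na(mutStopIdx)) length(mutAa) else mutStopIdx - 1L,
                  mutStopIdx, fc))
    }
    if (netDiff != 0L) {                            # in-frame indel
        if (is.na(fc)) fc <- NA_integer_
        pName <- if (netDiff > 0L)
            sprintf("p.%d_%dins(%d)",
                    if (is.na(fc)) cv$cPos %/% 3L else fc - 1L,
                    if (is.na(fc)) cv$cPos %/% 3L + 1L else fc,
                    netDiff %/% 3L)
        else
            sprintf("p.%d_%ddel",
                    if (is.na(fc)) cv$cPos %/% 3L else fc,
                    (if (is.na(fc)) cv$cPos %/% 3L else fc) -
                        netDiff %/% 3L - 1L)
        return(mk("inframe_indel", pName, mutLen, mutStopIdx, fc))
    }
    ## substitution in frame
    if (is.na(fc)) {
        codon <- (cv$cPos + 2L) %/% 3L
        return(mk("synonymous", sprintf("p.%s%d=", wtAa[codon], codon),
                  wtLen, wtStopIdx, NA))
    }
    if (mutAa[fc] == "*" && fc <= wtLen)
        return(mk("stop_gained", sprintf("p.%s%d*", wtAa[fc], fc),
                  fc - 1L, fc, fc))
    if (wtAa[fc] == "*")
        return(mk("stop_lost",
                  sprintf("p.*%d%sext*?", fc, mutAa[fc]), mutLen,
                  mutStopIdx, fc))
    mk("missense", sprintf("p.%s%d%s", wtAa[fc], fc, mutAa[fc]),
       wtLen, wtStopIdx, fc)
}

#' @describeIn callConsequence accessors for [ProteinConsequence-class].
#' @param pc a `ProteinConsequence`.
#' @export
consequenceKind <- function(pc) pc@kind

#' @describeIn callConsequence protein name accessor.
#' @export
proteinName <- function(pc) pc@pName

#' @describeIn callConsequence coding name accessor.
#' @export
codingName <- function(pc) pc@cName

#' @describeIn callConsequence truncation metrics as a named list.
#' @export
truncationMetrics <- function(pc)
    list(wtLength = pc@wtLength, mutLength = pc@mutLength,
         stopPosition = pc@stopPosition, residuesLost = pc@residuesLost)

setMethod("show", "ProteinConsequence", function(object) {
    cat(sprintf("ProteinConsequence: %s (%s, %s)\n", object@pName,
                object@kind, object@cName))
    cat(sprintf("  wt %d aa -> mut %d aa; stop at codon %s; %d residue(s) lost\n",
                object@wtLength, object@mutLength,
                ifelse(is.na(object@stopPosition), "none",
                       object@stopPosition),
                object@residuesLost))
})
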