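## VCF genotype I/O, variant representation and indel normalization.
## Coordinates are 1-based inclusive throughout (VCF convention).

#' Build a variant GRanges
#'
#' Convenience constructor for the row space of a [GenotypeMatrix-class]:
#' a `GRanges` whose width equals `nchar(ref)` and whose metadata columns
#' hold the alleles and optional annotations.
#'
#' @param contig,pos,ref,alt vectors describing each variant; `pos` is the
#'   1-based position of the first `ref` base.
#' @param id optional variant labels (`NA` for none).
#' @param exonic,nonsynonymous optional logical annotation flags (the
#'   cascade consumes these rather than re-deriving annotation).
#' @param gene optional gene symbol per variant.
#' @return `GRanges` with mcols `ref`, `alt`, `id`, `exonic`,
#'   `nonsynonymous`, `gene`.
#' @examples
#' variantGRanges("chrA", 100, "C", "CC", gene = "ABCA4")
#' @export
variantGRanges <- function(contig, pos, ref, alt, id = NA_character_,
                           exonic = NA, nonsynonymous = NA,
                           gene = NA_character_) {
    n <- max(length(contig), length(pos), length(ref), length(alt))
    gr <- GRanges(rep_len(contig, n),
                  IRanges(start = rep_len(as.integer(pos), n),
                          width = nchar(rep_len(ref, n))))
    mcols(gr)$ref <- toupper(rep_len(ref, n))
    mcols(gr)$alt <- toupper(rep_len(alt, n))
    mcols(gr)$id <- rep_len(as.character(id), n)
    mcols(gr)$exonic <- rep_len(as.logical(exonic), n)
    mcols(gr)$nonsynonymous <- rep_len(as.logical(nonsynonymous), n)
    mcols(gr)$gene <- rep_len(as.character(gene), n)
    gr
}

#' Construct a GenotypeMatrix
#'
#' Rows are sorted into genomic order (contig, position, ref, alt); the
#' genotype matrix and any extra FORMAT assays are reordered along.
#'
#' @param variants `GRanges` as from [variantGRanges()].
#' @param genotypes integer matrix of alt-allele doses (0/1/2/`NA`),
#'   rows matching `variants`, columns named by sample.
#' @param extraFormat named list of character matrices (opaque VCF FORMAT
#'   fields preserved for round-trip).
#' @return a [GenotypeMatrix-class].
#' @examples
#' v <- variantGRanges("chrA", c(10, 5), c("A", "C"), c("G", "CC"))
#' gm <- genotypeMatrix(v, matrix(c(1L, 2L, 0L, 1L), 2,
#'                      dimnames = list(NULL, c("s1", "s2"))))
#' variantKeys(gm)
#' @export
genotypeMatrix <- function(variants, genotypes, extraFormat = list()) {
    if (is.null(dim(genotypes)))
        genotypes <- matrix(genotypes, nrow = length(variants))
    storage.mode(genotypes) <- "integer"
    ord <- order(as.character(seqnames(variants)), start(variants),
                 mcols(variants)$ref, mcols(variants)$alt)
    assays <- c(list(GT = genotypes[ord, , drop = FALSE]),
                lapply(extraFormat, function(m) m[ord, , drop = FALSE]))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = assays, rowRanges = variants[ord])
    new("GenotypeMatrix", se)
}

#' @describeIn genotypeMatrix the variant rows as a `GRanges`.
#' @param x,gm a `GenotypeMatrix`.
#' @export
variantRanges <- function(x) SummarizedExperiment::rowRanges(x)

#' @describeIn genotypeMatrix canonical `"contig:pos:ref:alt"` key strings.
#' @export
variantKeys <- function(x) {
    gr <- SummarizedExperiment::rowRanges(x)
    paste(as.character(seqnames(gr)), start(gr),
          mcols(gr)$ref, mcols(gr)$alt, sep = ":")
}

#' @describeIn genotypeMatrix the integer dose matrix (0/1/2/`NA`).
#' @export
genotypes <- function(x) SummarizedExperiment::assay(x, "GT")

#' @describeIn genotypeMatrix sample identifiers.
#' @export
sampleIds <- function(x) colnames(x)

setMethod("show", "GenotypeMatrix", function(object) {
    cat(sprintf("GenotypeMatrix: %d variant(s) x %d sample(s)\n",
                nrow(object), ncol(object)))
    if (nrow(object)) {
        k <- variantKeys(object)
        cat("  ", paste(utils::head(k, 4), collapse = ", "),
            if (nrow(object) > 4) ", ..." else "", "\n", sep = "")
    }
    cat("  samples: ", paste(utils::head(colnames(object), 8),
                             collapse = ", "), "\n", sep = "")
})

## ---- VCF reading -----------------------------------------------------------

#' Read a multi-sample VCF into a GenotypeMatrix
#'
#' Parsing is delegated to [VariantAnnotation::readVcf]; this function then
#' recodes genotypes to alt-allele doses. Multiallelic records are split
#' into one biallelic row per alternate allele; in each split row, alleles
#' belonging to a *different* alternate are recoded as reference, which
#' keeps downstream segregation filters binary. Phased (`|`) and unphased
#' (`/`) separators are treated identically. A call containing any missing
#' allele (`.`) becomes missing. INFO flags `EXONIC` and `NONSYN` and the
#' string field `GENE`, when declared, populate the corresponding
#' annotation columns.
#'
#' @param path path to a VCF v4.2 file (plain text or bgzipped).
#' @param genome genome label passed to `readVcf` (metadata only).
#' @return a [GenotypeMatrix-class].
#' @examples
#' vcf <- tempfile(fileext = ".vcf")
#' writeLines(c("##fileformat=VCFv4.2",
#'   "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
#'   "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
#'   "chrA\t5\t.\tC\tT\t.\t.\t.\tGT\t0/1"), vcf)
#' readVcfMatrix(vcf)
#' @export
readVcfMatrix <- function(path, genome = "unknown") {
    vcf <- VariantAnnotation::readVcf(path, genome = genome)
    gen <- VariantAnnotation::geno(vcf)
    if (!"GT" %in% names(gen))
        stop("VCF format error: records carry no GT FORMAT field")
    gt <- gen[["GT"]]
    samples <- colnames(gt)
    rr <- SummarizedExperiment::rowRanges(vcf)
    contig <- as.character(seqnames(rr))
    pos <- start(rr)
    ref <- as.character(VariantAnnotation::ref(vcf))
    altL <- lapply(VariantAnnotation::alt(vcf), as.character)
    inf <- VariantAnnotation::info(vcf)
    getInfo <- function(nm, default) {
        if (nm %in% colnames(inf)) inf[[nm]] else
            rep(default, length(rr))
    }
    exonic <- getInfo("EXONIC", NA)
    nonsyn <- getInfo("NONSYN", NA)
    geneSym <- as.character(getInfo("GENE", NA_character_))
    ids <- names(rr)
    autoIds <- paste0(contig, ":", pos, "_", ref, "/",
                      vapply(altL, paste, "", collapse = ","))
    ids[!is.na(ids) & ids == autoIds] <- NA_character_

    extraNames <- setdiff(names(gen), "GT")
    flat <- function(field, i) {
        ## collapse record i of a FORMAT field to one string per sample
        vapply(seq_along(samples), function(j) {
            v <- if (length(dim(field)) == 3L) field[i, j, ]
                 else field[i, j]
            if (is.list(v)) v <- unlist(v, use.names = FALSE)
            if (length(v) == 0L || all(is.na(v))) "." else
                paste(v, collapse = ",")
        }, "")
    }

    out <- list(contig = character(), pos = integer(), ref = character(),
                alt = character(), id = character(), exonic = logical(),
                nonsyn = logical(), gene = character())
    doses <- list()
    extra <- stats::setNames(rep(list(list()), length(extraNames)),
                             extraNames)

    tok <- strsplit(gt, "[/|]")
    dim(tok) <- dim(gt)
    for (i in seq_along(rr)) {
        alts <- altL[[i]]
        keep <- grepl("^[ACGT]+$", alts)
        if (!all(keep))
            warning("dropping non-ACGT alternate allele(s) at ",
                    contig[i], ":", pos[i])
        rowTok <- tok[i, ]
        pl <- lengths(rowTok)
        if (any(pl != 2L))
            stop("unsupported ploidy: GT '", gt[i, which(pl != 2L)[1]],
                 "' at ", contig[i], ":", pos[i])
        for (k in seq_along(alts)) {
            if (!keep[k]) next
            d <- vapply(rowTok, function(tk) {
                if (any(tk == ".")) return(NA_integer_)
                sum(tk == as.character(k))
            }, 0L)
            out$contig <- c(out$contig, contig[i])
            out$pos <- c(out$pos, pos[i])
            out$ref <- c(out$ref, ref[i])
            out$alt <- c(out$alt, alts[k])
            out$id <- c(out$id, ids[i])
            out$exonic <- c(out$exonic, as.logical(exonic[i]))
            out$nonsyn <- c(out$nonsyn, as.logical(nonsyn[i]))
            out$gene <- c(out$gene, geneSym[i])
            doses[[length(doses) + 1L]] <- d
            for (nm in extraNames)
                extra[[nm]][[length(doses)]] <- flat(gen[[nm]], i)
        }
    }
    gr <- variantGRanges(out$contig, out$pos, out$ref, out$alt,
                         id = out$id, exonic = out$exonic,
                         nonsynonymous = out$nonsyn, gene = out$gene)
    gtm <- do.call(rbind, c(doses, list(deparse.level = 0)))
    if (is.null(gtm)) gtm <- matrix(integer(), 0, length(samples))
    colnames(gtm) <- samples
    extraM <- lapply(extra, function(l) {
        m <- do.call(rbind, c(l, list(deparse.level = 0)))
        if (is.null(m)) m <- matrix(character(), 0, length(samples))
        colnames(m) <- samples
        m
    })
    genotypeMatrix(gr, gtm, extraFormat = extraM)
}

## ---- VCF writing -----------------------------------------------------------

#' Write a GenotypeMatrix as a VCF v4.2 file
#'
#' Emits one biallelic record per variant row with a GT field
#' (`0/0`, `0/1`, `1/1`, `./.`) plus any opaque FORMAT assays carried by
#' the object. Annotation columns `exonic`, `nonsynonymous` and `gene`
#' are written as INFO flags/fields so that a round trip through
#' [readVcfMatrix()] reproduces the object exactly.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeVcfMatrix <- function(gm, path) {
    gr <- variantRanges(gm)
    mc <- mcols(gr)
    extraNames <- setdiff(SummarizedExperiment::assayNames(gm), "GT")
    hdr <- c("##fileformat=VCFv4.2",
        "##INFO=<ID=EXONIC,Number=0,Type=Flag,Description=\"Exonic variant\">",
        "##INFO=<ID=NONSYN,Number=0,Type=Flag,Description=\"Nonsynonymous variant\">",
        "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        sprintf("##FORMAT=<ID=%s,Number=.,Type=String,Description=\"Preserved field\">",
                extraNames),
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", colnames(gm)), collapse = "\t"))
    gt <- genotypes(gm)
    lines <- vapply(seq_len(nrow(gm)), function(i) {
        info <- c(if (isTRUE(mc$exonic[i])) "EXONIC",
                  if (isTRUE(mc$nonsynonymous[i])) "NONSYN",
                  if (!is.na(mc$gene[i])) paste0("GENE=", mc$gene[i]))
        info <- if (length(info)) paste(info, collapse = ";") else "."
        gtStr <- ifelse(is.na(gt[i, ]), "./.",
                        c("0/0", "0/1", "1/1")[gt[i, ] + 1L])
        calls <- gtStr
        for (nm in extraNames)
            calls <- paste(calls, SummarizedExperiment::assay(gm, nm)[i, ],
                           sep = ":")
        paste(c(as.character(seqnames(gr))[i], start(gr)[i],
                ifelse(is.na(mc$id[i]), ".", mc$id[i]),
                mc$ref[i], mc$alt[i], ".", ".", info,
                paste(c("GT", extraNames), collapse = ":"), calls),
              collapse = "\t")
    }, "")
    writeLines(c(hdr, lines), path)
    invisible(path)
}

## ---- Interval arithmetic ---------------------------------------------------

#' Length of a 1-based inclusive genomic interval
#'
#' Under the 1-based inclusive convention the length is
#' `end - start + 1`; e.g. the seven-cytosine repeat
#' Chr6:55,146,550-55,146,556 has length 7.
#'
#' @param start,end 1-based inclusive bounds (vectors allowed).
#' @return integer length(s).
#' @examples
#' intervalLength(55146550, 55146556)  # 7
#' @export
intervalLength <- function(start, end) {
    start <- as.integer(start); end <- as.integer(end)
    if (any(is.na(start) | is.na(end)))
        stop("invalid interval: NA bound")
    if (any(start < 1L))
        stop("invalid interval: start must be >= 1")
    if (any(end < start))
        stop("invalid interval: end < start")
    end - start + 1L
}

## ---- Indel normalization ---------------------------------------------------

## Shift an anchored variant (pos, ref, alt) within sequence string `sq`
## to its 3'-most ("right") or 5'-most ("left") equivalent spelling.
## Returns list(pos, ref, alt). Used both on genomic contigs and on CDS
## strings (where "right" means 3'-most in transcript coordinates).
.normalizeInString <- function(sq, pos, ref, alt, align = "right") {
    base <- function(p) substr(sq, p, p)
    ## trim shared suffix then prefix down to a minimal representation
    while (nchar(ref) > 1L && nchar(alt) > 1L &&
           substr(ref, nchar(ref), nchar(ref)) ==
           substr(alt, nchar(alt), nchar(alt))) {
        ref <- substr(ref, 1L, nchar(ref) - 1L)
        alt <- substr(alt, 1L, nchar(alt) - 1L)
    }
    while (nchar(ref) > 1L && nchar(alt) > 1L &&
           substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
        ref <- substr(ref, 2L, nchar(ref))
        alt <- substr(alt, 2L, nchar(alt))
        pos <- pos + 1L
    }
    if (nchar(ref) == nchar(alt))          # SNV / MNV: position is fixed
        return(list(pos = pos, ref = ref, alt = alt))

    ins <- nchar(alt) > nchar(ref)
    long <- if (ins) alt else ref
    short <- if (ins) ref else alt
    if (substr(long, 1L, nchar(short)) != short)
        return(list(pos = pos, ref = ref, alt = alt))  # complex indel: leave
    core <- substr(long, nchar(short) + 1L, nchar(long))
    anchor <- pos + nchar(short) - 1L      # base just before the event
    if (align == "right") {
        nxt <- function() anchor + (if (ins) 1L else nchar(core) + 1L)
        while (nxt() <= nchar(sq) && base(nxt()) == substr(core, 1L, 1L)) {
            core <- paste0(substr(core, 2L, nchar(core)), base(nxt()))
            anchor <- anchor + 1L
        }
    } else {
        while (anchor >= 1L &&
               base(anchor) == substr(core, nchar(core), nchar(core))) {
            core <- paste0(base(anchor),
                           substr(core, 1L, nchar(core) - 1L))
            anchor <- anchor - 1L
        }
    }
    if (anchor < 1L)
        stop("indel shifted past the start of the sequence")
    a <- base(anchor)
    if (ins)
        list(pos = anchor, ref = a, alt = paste0(a, core))
    else
        list(pos = anchor, ref = paste0(a, core), alt = a)
}

#' Normalize variants against a reference sequence
#'
#' Produces a unique canonical spelling among all equivalent placements of
#' an indel inside a repeat run. The default dialect right-aligns
#' (3'-shifts) indels so that an insertion in a mononucleotide run is
#' anchored on the run's last base -- the convention under which a
#' cytosine insertion in a seven-cytosine run at c.4170-c.4176 is named
#' c.4176insC. `align = "left"` gives the VCF left-aligned spelling for
#' interoperability. SNVs are returned unchanged. The operation is
#' idempotent.
#'
#' @param gr variant `GRanges` (see [variantGRanges()]).
#' @param genome named `DNAStringSet` (or coercible) of contig sequences.
#' @param align `"right"` (default, 3'-most) or `"left"`.
#' @return `GRanges` of the same length with normalized `pos`/`ref`/`alt`.
#' @examples
#' genome <- Biostrings::DNAStringSet(c(chrA = "TTACCCCCCCTGAA"))
#' v <- variantGRanges("chrA", 5, "C", "CC")  # insertion inside the C run
#' normalizeVariant(v, genome)                 # anchored at the run's end
#' @export
normalizeVariant <- function(gr, genome, align = c("right", "left")) {
    align <- match.arg(align)
    genome <- Biostrings::DNAStringSet(genome)
    mc <- mcols(gr)
    newPos <- start(gr); newRef <- mc$ref; newAlt <- mc$alt
    for (i in seq_along(gr)) {
        ctg <- as.character(seqnames(gr))[i]
        if (!ctg %in% names(genome))
            stop("contig not in reference: ", ctg)
        sq <- as.character(genome[[ctg]])
        pos <- start(gr)[i]; ref <- mc$ref[i]; alt <- mc$alt[i]
        if (substr(sq, pos, pos + nchar(ref) - 1L) != ref)
            stop("reference mismatch at ", ctg, ":", pos,
                 " (expected ", ref, ")")
        nv <- .normalizeInString(sq, pos, ref, alt, align)
        newPos[i] <- nv$pos; newRef[i] <- nv$ref; newAlt[i] <- nv$alt
    }
    out <- GRanges(seqnames(gr), IRanges(newPos, width = nchar(newRef)),
                   strand = strand(gr))
    mc$ref <- newRef
    mc$alt <- newAlt
    mcols(out) <- mc
    out
}
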