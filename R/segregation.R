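## Per-trio autosomal-recessive filtering, trio intersection,
## panel-privacy exclusion and cascade summary.

#' Read a pedigree table
#'
#' Six-column tab-delimited file: `id`, `sire`, `dam`, `sex`, `phenotype`
#' (`affected`/`unaffected`/`unknown`), `role` (free-text cohort role,
#' e.g. `quartet`, `panel`, `validation`). Missing parents are `.` or
#' empty. Parent references must resolve and no sample may be its own
#' ancestor.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readPedigree <- function(path) {
    ped <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    need <- c("id", "sire", "dam", "sex", "phenotype", "role")
    if (!all(need %in% colnames(ped)))
        stop("pedigree must have columns: ", paste(need, collapse = ", "))
    ped$sire[ped$sire %in% c("", ".")] <- NA
    ped$dam[ped$dam %in% c("", ".")] <- NA
    for (p in c(ped$sire, ped$dam))
        if (!is.na(p) && !p %in% ped$id)
            stop("pedigree parent not found: ", p)
    ## ancestor-cycle check by iterated parent lookup
    parentOf <- function(id) stats::na.omit(
        c(ped$sire[ped$id == id], ped$dam[ped$id == id]))
    for (id in ped$id) {
        seen <- character(); frontier <- parentOf(id)
        while (length(frontier)) {
            if (id %in% frontier)
                stop("pedigree cycle: ", id, " is its own ancestor")
            seen <- union(seen, frontier)
            frontier <- setdiff(unlist(lapply(frontier, parentOf)), seen)
        }
    }
    ped
}

#' Derive analysis trios from a pedigree
#'
#' One trio per affected offspring with both parents present, each trio a
#' named character vector `c(sire=, dam=, offspring=)`. Two affected
#' siblings of the same parents yield two trios sharing sire and dam.
#'
#' @param ped pedigree data.frame as from [readPedigree()].
#' @return list of named character vectors.
#' @export
pedigreeTrios <- function(ped) {
    aff <- ped[ped$phenotype == "affected" &
               !is.na(ped$sire) & !is.na(ped$dam), , drop = FALSE]
    lapply(seq_len(nrow(aff)), function(i)
        c(sire = aff$sire[i], dam = aff$dam[i], offspring = aff$id[i]))
}

## default sex-chromosome names excluded from the autosomal-recessive filter
.defaultSexContigs <- c("X", "Y", "chrX", "chrY", "ChrX", "ChrY")

#' Autosomal-recessive trio filter
#'
#' Retains exactly the variants where the affected offspring is
#' homozygous-alternate and *both* parents are heterozygous -- the
#' obligate-carrier configuration for unaffected parents of an affected
#' offspring under full penetrance. A homozygous parent (either allele)
#' is non-Mendelian for that configuration and excluded. By default a
#' variant with any missing call among the three is dropped (conservative
#' for a discovery filter); `keepMissing = TRUE` lets such variants pass.
#' Variants on sex chromosomes (by contig name) are excluded.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param trio named character vector `c(sire=, dam=, offspring=)`.
#' @param keepMissing if `TRUE`, variants with a missing call in the trio
#'   are retained rather than dropped.
#' @param excludeContigs contig names treated as non-autosomal.
#' @return the retained subset, a `GenotypeMatrix`.
#' @export
trioArFilter <- function(gm, trio, keepMissing = FALSE,
                         excludeContigs = .defaultSexContigs) {
    need <- c("sire", "dam", "offspring")
    if (!all(need %in% names(trio)))
        stop("trio must be named c(sire=, dam=, offspring=)")
    absent <- setdiff(unname(trio[need]), colnames(gm))
    if (length(absent))
        stop("trio sample(s) absent from genotype matrix: ",
             paste(absent, collapse = ", "))
    gt <- genotypes(gm)
    s <- gt[, trio[["sire"]]]
    d <- gt[, trio[["dam"]]]
    o <- gt[, trio[["offspring"]]]
    anyMiss <- is.na(s) | is.na(d) | is.na(o)
    pattern <- !anyMiss & s == 1L & d == 1L & o == 2L
    keep <- if (keepMissing) pattern | anyMiss else pattern
    keep <- keep & !as.character(seqnames(variantRanges(gm))) %in%
        excludeContigs
    gm[keep, ]
}

#' Intersect two trio-filtered variant subsets
#'
#' Variants present in both subsets (by contig/pos/ref/alt key), order
#' preserved from the first argument. Symmetric as a set operation.
#'
#' @param a,b `GenotypeMatrix` subsets of the same parent matrix.
#' @return a `GenotypeMatrix`.
#' @export
intersectTrios <- function(a, b) {
    a[variantKeys(a) %in% variantKeys(b), ]
}

#' Exclude variants homozygous-alternate in a comparison panel
#'
#' A candidate is dropped if at least one panel genome is
#' homozygous-alternate for it. Heterozygous panel carriers do *not*
#' cause exclusion -- a recessive causal allele may legitimately
#' segregate in carriers of the wider population. Variants absent from
#' the panel genotypes are retained (absence of a record means nobody was
#' observed homozygous).
#'
#' @param s candidate `GenotypeMatrix` subset.
#' @param panel a `GenotypeMatrix` of panel genomes, or a list of
#'   single-genome `GenotypeMatrix` objects.
#' @return the retained subset.
#' @export
panelPrivacyFilter <- function(s, panel) {
    if (!is.list(panel)) panel <- list(panel)
    keys <- variantKeys(s)
    homAnywhere <- rep(FALSE, length(keys))
    for (p in panel) {
        idx <- match(variantKeys(p), keys)
        hit <- which(!is.na(idx))
        if (!length(hit)) next
        anyHom <- apply(genotypes(p)[hit, , drop = FALSE], 1,
                        function(z) any(!is.na(z) & z == 2L))
        homAnywhere[idx[hit]] <- homAnywhere[idx[hit]] | anyHom
    }
    s[!homAnywhere, ]
}

#' Summarize a filtering cascade
#'
#' Counts variants at each named stage, broken down into SNVs, INDELs and
#' nonsynonymous variants (when the annotation column is present).
#' Stages are assumed to be successive subsets; a count that increases
#' along the cascade within a variant class raises an
#' internal-consistency error.
#'
#' @param stages named, ordered list of `GenotypeMatrix` stages.
#' @return data.frame with columns `stage`, `n`, `n_snv`, `n_indel`,
#'   `n_nonsynonymous`.
#' @export
summarizeCascade <- function(stages) {
    stopifnot(is.list(stages), length(names(stages)) == length(stages))
    rows <- lapply(names(stages), function(nm) {
        gm <- stages[[nm]]
        mc <- mcols(variantRanges(gm))
        isSnv <- nchar(mc$ref) == 1L & nchar(mc$alt) == 1L
        data.frame(stage = nm, n = nrow(gm),
                   n_snv = sum(isSnv), n_indel = sum(!isSnv),
                   n_nonsynonymous =
                       if ("nonsynonymous" %in% colnames(mc))
                           sum(mc$nonsynonymous %in% TRUE)
                       else NA_integer_)
    })
    out <- do.call(rbind, rows)
    ## parallel per-trio branches are not subsets of one another; skip the
    ## comparison between consecutive AR_trio stages
    parallel <- grepl("^AR_trio", out$stage)
    cmp <- which(!(parallel[-nrow(out)] & parallel[-1]))
    for (col in c("n", "n_snv", "n_indel")) {
        v <- out[[col]]
        if (any((diff(v) > 0)[cmp]))
            stop("internal-consistency error: cascade counts increase in '",
                 col, "'")
    }
    out
}

#' Run the full discovery cascade
#'
#' Convenience wrapper chaining the exonic restriction (via the `exonic`
#' annotation flag), the per-trio autosomal-recessive filters, the
#' trio intersection and the panel-privacy exclusion; the candidate set
#' is then restricted to nonsynonymous variants when that flag is
#' available.
#'
#' @param gm quartet [GenotypeMatrix-class].
#' @param trios list of trios as from [pedigreeTrios()].
#' @param panel panel genotypes (see [panelPrivacyFilter()]), or `NULL`
#'   to skip the privacy stage.
#' @param requireExonic drop variants not flagged exonic first (flags are
#'   consumed from the input annotation; `NA` flags count as non-exonic).
#' @param requireNonsynonymous restrict final candidates to
#'   nonsynonymous-flagged variants.
#' @return list with `stages` (named list of `GenotypeMatrix`),
#'   `summary` (from [summarizeCascade()]) and `candidates`.
#' @export
runCascade <- function(gm, trios, panel = NULL, requireExonic = TRUE,
                       requireNonsynonymous = TRUE) {
    stages <- list(total = gm)
    cur <- gm
    if (requireExonic) {
        cur <- cur[mcols(variantRanges(cur))$exonic %in% TRUE, ]
        stages$exonic <- cur
    }
    filtered <- lapply(trios, function(tr) trioArFilter(cur, tr))
    names(filtered) <- paste0("AR_trio", seq_along(filtered))
    stages <- c(stages, filtered)
    cur <- Reduce(intersectTrios, filtered)
    stages$shared <- cur
    if (!is.null(panel)) {
        cur <- panelPrivacyFilter(cur, panel)
        stages$private <- cur
    }
    if (requireNonsynonymous) {
        cur <- cur[mcols(variantRanges(cur))$nonsynonymous %in% TRUE, ]
        stages$nonsynonymous <- cur
    }
    list(stages = stages, summary = summarizeCascade(stages),
         candidates = cur)
}
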