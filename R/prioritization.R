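## Effect-score classification, disease-gene intersection and
## genotype-phenotype concordance.

#' Classify variant effect from supplied predictor scores
#'
#' Scores are pipeline *inputs* (computed upstream by PolyPhen-2 and
#' PROVEAN); this function only bands them. Defaults follow the tools'
#' published cutoffs: PROVEAN is damaging at or below -2.5, and
#' PolyPhen-2 (HumDiv) is "benign" below 0.446 and "probably damaging"
#' at or above 0.908. With both scores present a variant is `damaging`
#' only if both agree (provean <= cutoff AND polyphen2 >= upper band),
#' `neutral` only if both are benign (provean > cutoff AND polyphen2 <
#' lower band), and `indeterminate` otherwise. With one score present
#' that score's bands decide alone. Frameshift and stop-gain variants
#' are `damaging` regardless of scores; a missense variant with neither
#' score is `indeterminate` with a warning.
#'
#' Classification is monotone: making provean more negative or
#' polyphen2 larger never flips damaging to neutral.
#'
#' @param polyphen2 numeric in `[0, 1]` or `NA`.
#' @param provean numeric (more negative is more damaging) or `NA`.
#' @param kind consequence kind per variant (`"missense"` etc.;
#'   `"frameshift"`/`"stop_gained"` force `damaging`). Recycled.
#' @param proveanCutoff,pp2Benign,pp2Damaging band edges.
#' @return character vector in `{damaging, neutral, indeterminate}`.
#' @examples
#' classifyEffect(0.065, -2.333)           # neutral
#' classifyEffect(0.97, -4.933)            # damaging
#' classifyEffect(NA, NA, kind = "frameshift")
#' @export
classifyEffect <- function(polyphen2, provean, kind = "missense",
                           proveanCutoff = -2.5, pp2Benign = 0.446,
                           pp2Damaging = 0.908) {
    n <- max(length(polyphen2), length(provean), length(kind))
    polyphen2 <- rep_len(as.numeric(polyphen2), n)
    provean <- rep_len(as.numeric(provean), n)
    kind <- rep_len(kind, n)
    if (any(!is.na(polyphen2) & (polyphen2 < 0 | polyphen2 > 1)))
        stop("polyphen2 scores must lie in [0, 1]")
    out <- character(n)
    for (i in seq_len(n)) {
        if (kind[i] %in% c("frameshift", "stop_gained", "start_lost")) {
            out[i] <- "damaging"
        } else if (is.na(polyphen2[i]) && is.na(provean[i])) {
            warning("no effect score for a ", kind[i],
                    " variant; classifying as indeterminate")
            out[i] <- "indeterminate"
        } else if (!is.na(polyphen2[i]) && !is.na(provean[i])) {
            out[i] <- if (provean[i] <= proveanCutoff &&
                          polyphen2[i] >= pp2Damaging) "damaging"
                else if (provean[i] > proveanCutoff &&
                         polyphen2[i] < pp2Benign) "neutral"
                else "indeterminate"
        } else if (!is.na(provean[i])) {
            out[i] <- if (provean[i] <= proveanCutoff) "damaging"
                else "neutral"
        } else {
            out[i] <- if (polyphen2[i] >= pp2Damaging) "damaging"
                else if (polyphen2[i] < pp2Benign) "neutral"
                else "indeterminate"
        }
    }
    out
}

#' Read a tab-delimited effect-score table
#'
#' Columns: `variant` (key or id), `gene`, `polyphen2`, `provean`
#' (empty/NA allowed, e.g. for frameshifts which the predictors do not
#' score).
#'
#' @param path file path.
#' @return data.frame.
#' @export
readEffectScores <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             na.strings = c("NA", "", "."))
    need <- c("variant", "polyphen2", "provean")
    if (!all(need %in% colnames(tab)))
        stop("effect-score table must have columns: ",
             paste(need, collapse = ", "))
    tab
}

#' Intersect candidate genes with a disease-gene list
#'
#' Symbols are matched case-insensitively (normalized to uppercase);
#' input order of the candidates is preserved and duplicates retained as
#' given, so the operation is idempotent and order-preserving.
#'
#' @param candidates character vector of candidate gene symbols.
#' @param diseaseGenes character vector of disease-associated symbols
#'   (e.g. a retinal-disease gene list read with [readGeneList()]).
#' @return the candidates present in the list, original spelling.
#' @examples
#' intersectDiseaseGenes(c("KIAA1549", "USH2A", "ABCA4", "TTN"),
#'                       c("ABCA4", "USH2A", "KIAA1549"))
#' @export
intersectDiseaseGenes <- function(candidates, diseaseGenes) {
    candidates[toupper(candidates) %in% toupper(diseaseGenes)]
}

#' @rdname intersectDiseaseGenes
#' @param path plain-text file, one gene symbol per line (`#` comments
#'   allowed).
#' @export
readGeneList <- function(path) {
    x <- trimws(readLines(path))
    x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a cohort genotype/phenotype table
#'
#' Tab-delimited columns: `id`, `phenotype`
#' (`affected`/`unaffected`/`unknown`) and `genotype` -- either a class
#' string (`hom_ref`, `het`, `hom_alt`, `missing`) or an alt-allele dose
#' 0/1/2.
#'
#' @param path file path.
#' @return data.frame with `genotype` normalized to class strings.
#' @export
readCohortTable <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             na.strings = c("NA", "", "."))
    need <- c("id", "phenotype", "genotype")
    if (!all(need %in% colnames(tab)))
        stop("cohort table must have columns: ",
             paste(need, collapse = ", "))
    tab$genotype <- .normalizeGenotypeClass(tab$genotype)
    tab
}

.normalizeGenotypeClass <- function(g) {
    g <- as.character(g)
    map <- c("0" = "hom_ref", "1" = "het", "2" = "hom_alt",
             hom_ref = "hom_ref", het = "het", hom_alt = "hom_alt",
             missing = NA)
    out <- unname(map[g])
    bad <- !is.na(g) & !g %in% names(map)
    if (any(bad))
        stop("unrecognized genotype class: ",
             paste(unique(g[bad]), collapse = ", "))
    out
}

#' Test genotype-phenotype concordance under a recessive model
#'
#' Full penetrance, no phenocopies: an affected animal is concordant iff
#' homozygous-alternate; an unaffected animal is concordant iff
#' heterozygous or homozygous-reference. Animals with unknown phenotype
#' or missing genotype are excluded with a warning. Discordant animals
#' are listed by id -- whether a discordant variant is then dropped is
#' the caller's decision.
#'
#' @param cohort data.frame with columns `id`, `phenotype`, `genotype`
#'   (see [readCohortTable()]).
#' @return a [ConcordanceResult-class].
#' @examples
#' cohort <- data.frame(id = c("d1", "d2", "d3"),
#'                      phenotype = c("affected", "unaffected", "unaffected"),
#'                      genotype = c("hom_alt", "het", "hom_ref"))
#' concordanceTest(cohort)
#' @export
concordanceTest <- function(cohort) {
    cohort$genotype <- .normalizeGenotypeClass(cohort$genotype)
    unknown <- !cohort$phenotype %in% c("affected", "unaffected")
    if (any(unknown))
        warning("excluding ", sum(unknown),
                " animal(s) with unknown phenotype: ",
                paste(cohort$id[unknown], collapse = ", "))
    miss <- is.na(cohort$genotype)
    if (any(miss & !unknown))
        warning("excluding ", sum(miss & !unknown),
                " animal(s) with missing genotype")
    d <- cohort[!unknown & !miss, , drop = FALSE]
    conc <- ifelse(d$phenotype == "affected",
                   d$genotype == "hom_alt",
                   d$genotype %in% c("het", "hom_ref"))
    perDog <- data.frame(id = d$id, phenotype = d$phenotype,
                         genotype = d$genotype, concordant = conc,
                         row.names = NULL)
    new("ConcordanceResult", perDog = perDog,
        nConcordant = as.integer(sum(conc)),
        nDiscordant = as.integer(sum(!conc)),
        discordantIds = as.character(d$id[!conc]))
}

#' @describeIn concordanceTest concordant/discordant totals as a named
#'   vector.
#' @param cr a `ConcordanceResult`.
#' @export
concordanceTotals <- function(cr)
    c(concordant = cr@nConcordant, discordant = cr@nDiscordant)

setMethod("show", "ConcordanceResult", function(object) {
    cat(sprintf("ConcordanceResult: %d concordant, %d discordant (n = %d)\n",
                object@nConcordant, object@nDiscordant,
                nrow(object@perDog)))
    if (length(object@discordantIds))
        cat("  discordant:", paste(object@discordantIds, collapse = ", "),
            "\n")
})
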