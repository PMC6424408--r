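## End-to-end orchestration: generate fixture bundles and run the
## discovery cascade from files to a machine-readable report.

#' Generate a complete synthetic fixture bundle
#'
#' Writes every input the discovery pipeline consumes -- reference FASTA,
#' transcript exon table, quartet and panel VCFs, pedigree, effect-score
#' table, disease-gene list, validation cohort, and the three
#' phenotype-quantification tables -- plus a ground-truth manifest naming
#' the planted causal variant and effects. Output is byte-identical for
#' a given configuration seed.
#'
#' @param cfg a [simConfig()] configuration.
#' @param outDir output directory.
#' @param force overwrite into a non-empty existing directory.
#' @return invisibly, a named list of file paths plus the manifest.
#' @export
runGenerate <- function(cfg, outDir, force = FALSE) {
    if (dir.exists(outDir) && length(list.files(outDir)) && !force)
        stop("output directory exists and is not empty (use force = TRUE): ",
             outDir)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(outDir, f)

    construct <- buildConstruct(cfg)
    sim <- simulateQuartetPanel(cfg, construct)
    cohort <- simulateCohort(cfg)
    pheno <- simulatePhenotypeTables(cfg)

    Biostrings::writeXStringSet(construct$genome, p("reference.fa"))
    writeTranscriptTable(list(construct$transcript), p("transcripts.tsv"))
    writeVcfMatrix(sim$quartet, p("quartet.vcf"))
    writeVcfMatrix(sim$panel, p("panel.vcf"))
    wt <- function(d, f) utils::write.table(
        d, p(f), sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
    wt(sim$pedigree, "pedigree.tsv")
    wt(cohort, "cohort.tsv")
    wt(pheno$ct, "ct.tsv")
    wt(pheno$counts, "counts.tsv")
    wt(pheno$fluor, "fluor.tsv")

    nuis <- sim$manifest$nuisance
    scores <- .withStream(cfg$seed, 5L, {
        data.frame(
            variant = c(sim$manifest$causal, nuis$key),
            gene = c(cfg$gene,
                     mcols(variantRanges(sim$quartet))$gene[
                         match(nuis$key, variantKeys(sim$quartet))]),
            kind = c("frameshift",
                     ifelse(nuis$violates == "synonymous", "synonymous",
                            "missense")),
            polyphen2 = c(NA, round(stats::runif(nrow(nuis)), 3)),
            provean = c(NA, round(stats::runif(nrow(nuis), -6, 2), 3)),
            stringsAsFactors = FALSE)
    })
    wt(scores, "scores.tsv")
    writeLines(c(cfg$gene, "USH2A", "KIAA1549", "RPE65", "PRCD"),
               p("genes.txt"))
    jsonlite::write_json(sim$manifest, p("manifest.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    invisible(list(dir = outDir, manifest = sim$manifest,
                   files = list.files(outDir, full.names = TRUE)))
}

#' Run the discovery pipeline from input files
#'
#' Executes the full cascade -- exonic restriction, per-trio
#' autosomal-recessive filtering, trio intersection, panel-privacy
#' exclusion, nonsynonymous restriction -- then annotates surviving
#' candidates with transcript consequences, classifies them with the
#' supplied effect scores, intersects genes with the disease-gene list,
#' and (when a cohort table is supplied) reports genotype-phenotype
#' concordance. Output is reproducible given identical inputs and
#' configuration; all thresholds are echoed into the report provenance.
#'
#' @param config named list (or path to a JSON file encoding one) with
#'   elements: `vcf`, `pedigree`, `reference`, `transcripts` (paths,
#'   required); `panelVcf`, `scores`, `geneList`, `cohort` (paths,
#'   optional); `usePanel`, `requireExonic`, `requireNonsynonymous`
#'   (logical toggles, default `TRUE`); `proveanCutoff`, `pp2Benign`,
#'   `pp2Damaging` (threshold overrides).
#' @param outFile optional path for the JSON run report.
#' @return the run report: a list with `filterSummary`, `candidates`
#'   (data.frame), `concordance` (or `NULL`) and `provenance`.
#' @export
runDiscovery <- function(config, outFile = NULL) {
    if (is.character(config) && length(config) == 1L)
        config <- jsonlite::read_json(config, simplifyVector = TRUE)
    for (f in c("vcf", "pedigree", "reference", "transcripts"))
        if (is.null(config[[f]]))
            stop("config is missing required input path: ", f)
    for (f in c("vcf", "pedigree", "reference", "transcripts",
                "panelVcf", "scores", "geneList", "cohort"))
        if (!is.null(config[[f]]) && !file.exists(config[[f]]))
            stop("input not readable: ", config[[f]])
    opt <- function(nm, default) if (is.null(config[[nm]])) default
        else config[[nm]]

    gm <- readVcfMatrix(config$vcf)
    ped <- readPedigree(config$pedigree)
    trios <- pedigreeTrios(ped)
    if (!length(trios))
        stop("pedigree defines no affected offspring with both parents")
    panel <- if (!is.null(config$panelVcf) && isTRUE(opt("usePanel", TRUE)))
        readVcfMatrix(config$panelVcf) else NULL
    casc <- runCascade(gm, trios, panel,
                       requireExonic = isTRUE(opt("requireExonic", TRUE)),
                       requireNonsynonymous =
                           isTRUE(opt("requireNonsynonymous", TRUE)))

    genome <- Biostrings::readDNAStringSet(config$reference)
    names(genome) <- sub("\\s.*$", "", names(genome))
    tms <- readTranscriptTable(config$transcripts)
    scores <- if (!is.null(config$scores)) readEffectScores(config$scores)
        else NULL
    diseaseGenes <- if (!is.null(config$geneList))
        readGeneList(config$geneList) else character()

    cand <- casc$candidates
    keys <- variantKeys(cand)
    rows <- lapply(seq_len(nrow(cand)), function(i) {
        v <- variantRanges(cand)[i]
        pc <- NULL
        for (tm in tms) {
            cv <- projectToCds(v, tm, genome)
            if (isTRUE(cv$coding)) {
                pc <- callConsequence(v, tm, genome)
                break
            }
        }
        gene <- mcols(v)$gene
        sc <- if (!is.null(scores)) {
            hit <- scores[scores$variant == keys[i], , drop = FALSE]
            if (nrow(hit)) hit[1, ] else NULL
        } else NULL
        kind <- if (!is.null(pc)) pc@kind
            else if (!is.null(sc) && "kind" %in% names(sc)) sc$kind
            else "missense"
        label <- classifyEffect(
            if (is.null(sc)) NA else sc$polyphen2,
            if (is.null(sc)) NA else sc$provean, kind,
            proveanCutoff = opt("proveanCutoff", -2.5),
            pp2Benign = opt("pp2Benign", 0.446),
            pp2Damaging = opt("pp2Damaging", 0.908))
        data.frame(
            variant = keys[i],
            gene = if (is.na(gene) && !is.null(sc)) sc$gene else gene,
            cName = if (is.null(pc)) NA_character_ else pc@cName,
            pName = if (is.null(pc)) NA_character_ else pc@pName,
            kind = kind, effect = label,
            inDiseaseList = !is.na(gene) &&
                length(intersectDiseaseGenes(gene, diseaseGenes)) > 0,
            stringsAsFactors = FALSE)
    })
    candidates <- if (length(rows)) do.call(rbind, rows)
        else data.frame(variant = character(), gene = character(),
                        cName = character(), pName = character(),
                        kind = character(), effect = character(),
                        inDiseaseList = logical())
    if (nrow(candidates) == 0L)
        warning("cascade returned zero candidates")

    concordance <- if (!is.null(config$cohort)) {
        cr <- concordanceTest(readCohortTable(config$cohort))
        list(concordant = cr@nConcordant, discordant = cr@nDiscordant,
             discordantIds = cr@discordantIds)
    } else NULL

    report <- list(
        filterSummary = casc$summary,
        candidates = candidates,
        concordance = concordance,
        provenance = list(
            package = "TrioSeg",
            version = as.character(utils::packageVersion("TrioSeg")),
            config = config,
            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
    if (!is.null(outFile))
        jsonlite::write_json(report, outFile, auto_unbox = TRUE,
                             digits = NA, dataframe = "rows", null = "null",
                             force = TRUE)
    report
}
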