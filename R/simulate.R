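## Seeded simulator for every pipeline input: toy reference genome,
## ABCA4-like transcript construct, quartet + panel + cohort genotypes,
## effect scores and phenotype-quantification fixtures.

.SENSE_CODONS <- {
    b <- c("A", "C", "G", "T")
    all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
    setdiff(all64, c("TAA", "TAG", "TGA"))
}
.STOP_CODONS <- c("TAA", "TAG", "TGA")

## evaluate `expr` under a deterministic RNG substream derived from
## (seed, offset), restoring the caller's RNG state afterwards; `expr` is
## evaluated lazily, i.e. after the substream seed is set
.withStream <- function(seed, offset, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed((as.integer(seed) * 1009L + as.integer(offset)) %% 2147483647L)
    expr
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions of the canine recessive retinal
#' degeneration analysed by this package: a CDS of 2,268 codons with a
#' seven-cytosine run at c.4170-c.4176, first changed codon 1,393
#' (wild-type Phe, TTC) and an engineered first +1-frame stop at codon
#' 1,395; a family quartet (two unaffected carrier parents, two affected
#' offspring); a 23-genome comparison panel; and a validation cohort of
#' 8 affected plus 14 unaffected animals. Nuisance variants each violate
#' exactly one cascade condition. Phenotype fixtures plant a 4-fold
#' expression knockdown in the homozygote, a 46% reduction of
#' outer-nuclear-layer nuclei and a 7-fold autofluorescence contrast.
#'
#' @param seed master integer seed; all generator substreams derive from
#'   it deterministically.
#' @param cdsCodons CDS length in codons (stop codon excluded).
#' @param repeatRunStart,repeatRunLength coding coordinates of the
#'   cytosine mononucleotide run.
#' @param firstChangedCodon codon index of the first residue changed by
#'   the frameshift (wild-type TTC/Phe).
#' @param frameshiftStopCodon absolute codon index of the first
#'   +1-frame stop downstream of the run.
#' @param nPanel number of comparison-panel genomes.
#' @param nAffected,nUnaffected validation-cohort composition.
#' @param nuisance character vector naming the cascade condition each
#'   nuisance variant violates; any multiset from `{trio1, trio2,
#'   panel_hom, non_exonic, synonymous}`.
#' @param causalPanelFreq causal allele frequency in the panel
#'   (carriers only; the causal allele is never homozygous there).
#' @param nuisanceAfRange uniform range for nuisance panel allele
#'   frequencies.
#' @param genomeLength,nExons toy contig size (nt) and exon count of the
#'   construct.
#' @param ctNoiseSd qPCR Ct noise SD (cycles).
#' @param expressionFold planted homozygote expression fold (het is the
#'   intermediate 0.5).
#' @param onlReduction planted fractional ONL nuclei reduction in the
#'   homozygote.
#' @param fluorContrast planted autofluorescence fold contrast.
#' @param countNoiseSd,fluorNoiseSd noise SDs for the counting and
#'   fluorescence fixtures.
#' @param nReplicates technical replicates per group in the phenotype
#'   fixtures.
#' @param gene gene symbol given to the construct.
#' @return a list of class `SimulationConfig`.
#' @export
simConfig <- function(seed = 1L, cdsCodons = 2268L,
                      repeatRunStart = 4170L, repeatRunLength = 7L,
                      firstChangedCodon = 1393L,
                      frameshiftStopCodon = 1395L,
                      nPanel = 23L, nAffected = 8L, nUnaffected = 14L,
                      nuisance = c("trio1", "trio2", "panel_hom",
                                   "non_exonic", "synonymous"),
                      causalPanelFreq = 0.1,
                      nuisanceAfRange = c(0, 0.3),
                      genomeLength = 100000L, nExons = 50L,
                      ctNoiseSd = 0.2, expressionFold = 0.25,
                      onlReduction = 0.46, fluorContrast = 7,
                      countNoiseSd = 3, fluorNoiseSd = 1,
                      nReplicates = 6L, gene = "ABCA4") {
    cfg <- list(seed = as.integer(seed), cdsCodons = as.integer(cdsCodons),
                repeatRunStart = as.integer(repeatRunStart),
                repeatRunLength = as.integer(repeatRunLength),
                firstChangedCodon = as.integer(firstChangedCodon),
                frameshiftStopCodon = as.integer(frameshiftStopCodon),
                nPanel = as.integer(nPanel),
                nAffected = as.integer(nAffected),
                nUnaffected = as.integer(nUnaffected),
                nuisance = nuisance, causalPanelFreq = causalPanelFreq,
                nuisanceAfRange = nuisanceAfRange,
                genomeLength = as.integer(genomeLength),
                nExons = as.integer(nExons), ctNoiseSd = ctNoiseSd,
                expressionFold = expressionFold,
                onlReduction = onlReduction,
                fluorContrast = fluorContrast,
                countNoiseSd = countNoiseSd, fluorNoiseSd = fluorNoiseSd,
                nReplicates = as.integer(nReplicates), gene = gene)
    runEnd <- cfg$repeatRunStart + cfg$repeatRunLength - 1L
    if (runEnd > 3L * cfg$cdsCodons)
        stop("repeat run must lie inside the CDS")
    if (cfg$frameshiftStopCodon <= cfg$firstChangedCodon)
        stop("frameshift stop codon must lie beyond the first changed codon")
    if (any(c(cfg$cdsCodons, cfg$nPanel, cfg$nAffected, cfg$nUnaffected,
              cfg$genomeLength, cfg$nExons, cfg$nReplicates) <= 0L))
        stop("counts must be positive")
    class(cfg) <- "SimulationConfig"
    cfg
}

## pick a sense codon whose base at `offset` is not `avoid`
.codonAvoiding <- function(offset, avoid) {
    ok <- .SENSE_CODONS[substr(.SENSE_CODONS, offset, offset) != avoid]
    sample(ok, 1L)
}

#' Build the toy genome and ABCA4-like transcript construct
#'
#' Generates a random contig carrying a multi-exon plus-strand transcript
#' whose CDS satisfies, by construction: codon `firstChangedCodon` is TTC
#' (Phe); coding positions `repeatRunStart..repeatRunStart +
#' repeatRunLength - 1` are all cytosine with non-cytosine flanks (so the
#' run length is exact); the wild-type frame contains no internal stop;
#' and inserting one cytosine after the run places the *first* +1-frame
#' stop exactly at codon `frameshiftStopCodon`. All constraints are
#' re-verified by exhaustive scan before returning; violation is a
#' generation error. Exon boundaries never split the repeat run.
#'
#' @param cfg a [simConfig()] configuration.
#' @return list with `genome` (named `DNAStringSet`), `transcript`
#'   ([TranscriptModel-class]), `cds` (character), and `causal` (the
#'   right-normalized genomic cytosine-insertion `GRanges`).
#' @export
buildConstruct <- function(cfg) .withStream(cfg$seed, 1L, {
    nCod <- cfg$cdsCodons
    rs <- cfg$repeatRunStart
    re <- rs + cfg$repeatRunLength - 1L
    fc <- cfg$firstChangedCodon
    s <- cfg$frameshiftStopCodon
    if (re %% 3L != 0L || fc != re %/% 3L + 1L)
        stop("generation error: repeat run must end on a codon boundary ",
             "immediately before the first changed codon")
    if (s < fc + 2L || s > nCod)
        stop("generation error: +1-frame stop codon index unsatisfiable")

    codons <- sample(.SENSE_CODONS, nCod, replace = TRUE)
    codons[1] <- "ATG"
    codonAt <- function(p) (p + 2L) %/% 3L   # codon index of CDS base p
    offsetAt <- function(p) p - 3L * (codonAt(p) - 1L)
    ## non-C flank before the run (the flank after is codon fc's T)
    if (rs > 1L) {
        cb <- codonAt(rs - 1L)
        codons[cb] <- .codonAvoiding(offsetAt(rs - 1L), "C")
    }
    ## the cytosine run, codon-aligned at its 3' end
    runCodons <- codonAt(rs):codonAt(re)
    cds0 <- codons
    cds0[runCodons] <- "CCC"
    ## partial first run codon: restore non-run bases then force run bases
    firstRunCodon <- codonAt(rs)
    pre <- substr(codons[firstRunCodon], 1L, offsetAt(rs) - 1L)
    cds0[firstRunCodon] <- paste0(pre, strrep("C", 3L - nchar(pre)))
    codons <- cds0
    ## frameshift engineering: wild-type TTC at fc; downstream third bases
    ## avoid T so no +1-frame stop can form before the target codon
    codons[fc] <- "TTC"
    if (s > fc + 2L)
        for (j in (fc + 1L):(s - 2L))
            codons[j] <- .codonAvoiding(3L, "T")
    codons[s - 1L] <- "GAT"
    codons[s] <- "AAA"
    cds <- paste0(paste(codons, collapse = ""), sample(.STOP_CODONS, 1L))

    ## verify every constraint by exhaustive scan
    aaWt <- .translateAa(cds)
    if (any(aaWt[-length(aaWt)] == "*") || aaWt[length(aaWt)] != "*")
        stop("generation error: wild-type frame stop-codon constraint failed")
    if (substr(cds, 3L * fc - 2L, 3L * fc) != "TTC")
        stop("generation error: first changed codon is not TTC")
    run <- substr(cds, rs, re)
    if (run != strrep("C", cfg$repeatRunLength) ||
        (rs > 1L && substr(cds, rs - 1L, rs - 1L) == "C") ||
        substr(cds, re + 1L, re + 1L) == "C")
        stop("generation error: repeat run constraint failed")
    mut <- paste0(substr(cds, 1L, re), "C", substr(cds, re + 1L, nchar(cds)))
    aaMut <- .translateAa(mut)
    if (match("*", aaMut) != s)
        stop("generation error: first +1-frame stop is not at codon ", s)

    ## embed the CDS into a random contig as nExons exons whose boundaries
    ## avoid the repeat run
    cdsLen <- nchar(cds)
    nEx <- min(cfg$nExons, cdsLen %/% 3L)
    repeat {
        cuts <- sort(sample(cdsLen - 1L, nEx - 1L))
        if (!any(cuts >= rs - 2L & cuts <= re + 1L)) break
    }
    sizes <- diff(c(0L, cuts, cdsLen))
    introns <- sample(100:500, nEx - 1L, replace = TRUE)
    txStart <- 2001L
    span <- sum(sizes) + sum(introns)
    if (txStart + span + 1000L > cfg$genomeLength)
        stop("generation error: construct does not fit the toy genome")
    genomeChars <- sample(c("A", "C", "G", "T"), cfg$genomeLength,
                          replace = TRUE)
    exStart <- integer(nEx); exEnd <- integer(nEx)
    gpos <- txStart; cpos <- 1L
    for (j in seq_len(nEx)) {
        exStart[j] <- gpos
        exEnd[j] <- gpos + sizes[j] - 1L
        genomeChars[gpos:exEnd[j]] <-
            strsplit(substr(cds, cpos, cpos + sizes[j] - 1L), "")[[1]]
        cpos <- cpos + sizes[j]
        gpos <- exEnd[j] + 1L + if (j < nEx) introns[j] else 0L
    }
    tm <- transcriptModel(cfg$gene, paste0(cfg$gene, ".tx1"), "chrA", "+",
                          exStart, exEnd)
    genome <- Biostrings::DNAStringSet(
        stats::setNames(paste(genomeChars, collapse = ""), "chrA"))
    ## guard against the intron/flank re-extending the run genomically
    ganchor <- cdsToGenomic(tm, re)
    sq <- genomeChars
    if (sq[ganchor + 1L] == "C") {
        genomeChars[ganchor + 1L] <- "T"   # only possible at an exon edge
        genome <- Biostrings::DNAStringSet(
            stats::setNames(paste(genomeChars, collapse = ""), "chrA"))
    }
    causal <- variantGRanges("chrA", ganchor, "C", "CC",
                             exonic = TRUE, nonsynonymous = TRUE,
                             gene = cfg$gene)
    list(genome = genome, transcript = tm, cds = cds, causal = causal)
})

## random SNV rows in (exonic) or outside (intergenic) the construct
.nuisanceSites <- function(cfg, construct, n, exonic) {
    tm <- construct$transcript
    sq <- as.character(construct$genome[[1]])
    rs <- cfg$repeatRunStart
    re <- rs + cfg$repeatRunLength - 1L
    if (exonic) {
        avoid <- (rs - 10L):(re + 10L)
        cpos <- sample(setdiff(seq_len(cdsLength(tm)), avoid), n)
        gpos <- cdsToGenomic(tm, cpos)
    } else {
        gpos <- sample(100:1500, n)
    }
    ref <- substring(sq, gpos, gpos)
    alt <- vapply(ref, function(r)
        sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
    list(pos = gpos, ref = ref, alt = unname(alt))
}

#' Simulate quartet and panel genotypes
#'
#' Plants the causal cytosine insertion segregating as expected in the
#' quartet (both parents heterozygous, both affected offspring
#' homozygous-alternate) plus one nuisance variant per requested
#' violation, each failing exactly one cascade condition:
#' `trio1`/`trio2` break the recessive pattern in that trio only,
#' `panel_hom` passes both trios but is homozygous in at least one panel
#' genome, `non_exonic` and `synonymous` pass all genotype filters and
#' carry the corresponding annotation flag. Panel genotypes are drawn
#' from Hardy-Weinberg proportions at uniform allele frequencies, with
#' the causal allele present in carriers only (never homozygous).
#'
#' @param cfg a [simConfig()] configuration.
#' @param construct result of [buildConstruct()].
#' @return list with `quartet` and `panel` ([GenotypeMatrix-class]),
#'   `pedigree` (data.frame) and `manifest` (planted ground truth).
#' @export
simulateQuartetPanel <- function(cfg, construct) .withStream(cfg$seed, 2L, {
    quartet <- c("SIRE", "DAM", "AFF1", "AFF2")
    nNuis <- length(cfg$nuisance)
    exonicNuis <- cfg$nuisance != "non_exonic"
    sites <- list(pos = integer(nNuis), ref = character(nNuis),
                  alt = character(nNuis))
    if (any(exonicNuis)) {
        ex <- .nuisanceSites(cfg, construct, sum(exonicNuis), TRUE)
        sites$pos[exonicNuis] <- ex$pos
        sites$ref[exonicNuis] <- ex$ref
        sites$alt[exonicNuis] <- ex$alt
    }
    if (any(!exonicNuis)) {
        nx <- .nuisanceSites(cfg, construct, sum(!exonicNuis), FALSE)
        sites$pos[!exonicNuis] <- nx$pos
        sites$ref[!exonicNuis] <- nx$ref
        sites$alt[!exonicNuis] <- nx$alt
    }
    nuisGR <- if (nNuis)
        variantGRanges("chrA", sites$pos, sites$ref, sites$alt,
                       exonic = exonicNuis,
                       nonsynonymous = exonicNuis &
                           cfg$nuisance != "synonymous",
                       gene = ifelse(exonicNuis,
                                     paste0("NUIS", seq_len(nNuis)),
                                     NA_character_))
    else NULL
    allGR <- if (is.null(nuisGR)) construct$causal
             else c(construct$causal, nuisGR)

    arPattern <- c(1L, 1L, 2L, 2L)
    quartetGeno <- function(violation) {
        switch(violation,
               trio1 = c(1L, 1L, 1L, 2L),     # AFF1 het: fails trio 1 only
               trio2 = c(1L, 1L, 2L, 1L),     # AFF2 het: fails trio 2 only
               arPattern)                      # passes both trios
    }
    gQuartet <- rbind(arPattern,
                      if (nNuis) t(vapply(cfg$nuisance, quartetGeno,
                                          integer(4))))
    colnames(gQuartet) <- quartet

    panelIds <- sprintf("P%02d", seq_len(cfg$nPanel))
    drawPanel <- function(af, homAllowed) {
        g <- stats::rbinom(cfg$nPanel, 2L, af)
        if (!homAllowed) g[g == 2L] <- 1L
        g
    }
    gPanel <- matrix(0L, nrow = 1L + nNuis, ncol = cfg$nPanel,
                     dimnames = list(NULL, panelIds))
    gPanel[1, ] <- drawPanel(cfg$causalPanelFreq, FALSE)
    if (nNuis) for (i in seq_len(nNuis)) {
        af <- stats::runif(1, cfg$nuisanceAfRange[1], cfg$nuisanceAfRange[2])
        hom <- cfg$nuisance[i] == "panel_hom"
        g <- drawPanel(af, hom)
        if (hom && !any(g == 2L))
            g[sample(cfg$nPanel, 1L)] <- 2L
        gPanel[1L + i, ] <- g
    }

    pedigree <- data.frame(
        id = c(quartet, panelIds),
        sire = c(NA, NA, "SIRE", "SIRE", rep(NA, cfg$nPanel)),
        dam = c(NA, NA, "DAM", "DAM", rep(NA, cfg$nPanel)),
        sex = c("M", "F", "F", "M",
                sample(c("M", "F"), cfg$nPanel, replace = TRUE)),
        phenotype = c("unaffected", "unaffected", "affected", "affected",
                      rep("unknown", cfg$nPanel)),
        role = c(rep("quartet", 4), rep("panel", cfg$nPanel)),
        stringsAsFactors = FALSE)

    keys <- function(gr) paste(as.character(seqnames(gr)), start(gr),
                               mcols(gr)$ref, mcols(gr)$alt, sep = ":")
    manifest <- list(
        causal = keys(construct$causal),
        causalGene = cfg$gene,
        nuisance = if (nNuis)
            data.frame(key = keys(nuisGR), violates = cfg$nuisance,
                       stringsAsFactors = FALSE)
        else data.frame(key = character(), violates = character()),
        plantedEffects = list(expressionFold = cfg$expressionFold,
                              onlReduction = cfg$onlReduction,
                              fluorContrast = cfg$fluorContrast))
    list(quartet = genotypeMatrix(allGR, gQuartet),
         panel = genotypeMatrix(allGR, gPanel),
         pedigree = pedigree, manifest = manifest)
})

#' Simulate the validation cohort table
#'
#' Affected animals are homozygous-alternate; unaffected animals are
#' heterozygous or homozygous-reference at random (seeded). The
#' `discordant` injector appends that many affected heterozygotes for
#' negative testing.
#'
#' @param cfg a [simConfig()] configuration.
#' @param discordant number of discordant affected heterozygotes to
#'   inject (default 0).
#' @return data.frame with `id`, `phenotype`, `genotype`.
#' @export
simulateCohort <- function(cfg, discordant = 0L) .withStream(cfg$seed, 3L, {
    d <- data.frame(
        id = c(sprintf("AFF%02d", seq_len(cfg$nAffected)),
               sprintf("UNAFF%02d", seq_len(cfg$nUnaffected))),
        phenotype = c(rep("affected", cfg$nAffected),
                      rep("unaffected", cfg$nUnaffected)),
        genotype = c(rep("hom_alt", cfg$nAffected),
                     sample(c("het", "hom_ref"), cfg$nUnaffected,
                            replace = TRUE)),
        stringsAsFactors = FALSE)
    if (discordant > 0L)
        d <- rbind(d, data.frame(
            id = sprintf("DISC%02d", seq_len(discordant)),
            phenotype = "affected", genotype = "het",
            stringsAsFactors = FALSE))
    d
})

#' Simulate phenotype-quantification fixtures
#'
#' Three tables over the genotype groups `wt`, `het` and `hom`: a
#' replicate qPCR Ct table (reference amplicon `GAPDH`, three target
#' amplicons) with planted expression folds (1, 0.5,
#' `cfg$expressionFold`); a nuclei-count table with a planted fractional
#' ONL reduction in the homozygote and cones absent there; and an
#' autofluorescence table with a planted region/background contrast.
#' With all noise SDs at 0 the planted effects are recovered exactly by
#' the quantification functions.
#'
#' @param cfg a [simConfig()] configuration.
#' @return list of data.frames `ct`, `counts`, `fluor`.
#' @export
simulatePhenotypeTables <- function(cfg) .withStream(cfg$seed, 4L, {
    groups <- c(wt = 1, het = 0.5, hom = cfg$expressionFold)
    amplicons <- c("ex2-3", "ex27-28", "ex47-48")
    nR <- cfg$nReplicates
    noise <- function(n, sd) if (sd > 0) stats::rnorm(n, 0, sd) else
        numeric(n)
    ct <- do.call(rbind, lapply(names(groups), function(g) {
        refCt <- 20
        tgtCt <- 24 - log2(groups[[g]])
        rbind(
            data.frame(sample = toupper(g), genotype = g,
                       gene = "reference", amplicon = "GAPDH",
                       replicate = seq_len(nR),
                       ct = refCt + noise(nR, cfg$ctNoiseSd)),
            do.call(rbind, lapply(amplicons, function(a)
                data.frame(sample = toupper(g), genotype = g,
                           gene = "target", amplicon = a,
                           replicate = seq_len(nR),
                           ct = tgtCt + noise(nR, cfg$ctNoiseSd)))))
    }))
    rownames(ct) <- NULL

    onlBase <- 100; inlBase <- 60; coneBase <- 10
    counts <- do.call(rbind, lapply(names(groups), function(g) {
        onl <- if (g == "hom") onlBase * (1 - cfg$onlReduction) else onlBase
        cones <- if (g == "hom") 0 else coneBase
        onlN <- round(onl + noise(nR, cfg$countNoiseSd))
        coneN <- round(pmax(0, cones + noise(nR, cfg$countNoiseSd / 3)))
        coneN <- pmin(coneN, onlN)
        data.frame(image = sprintf("%s_%02d", g, seq_len(nR)),
                   genotype = g,
                   onl_nuclei = pmax(0, onlN),
                   inl_nuclei = pmax(0, round(inlBase +
                                              noise(nR, cfg$countNoiseSd))),
                   cone_count = coneN, width_um = 67)
    }))
    rownames(counts) <- NULL

    bg <- 20; base <- 10
    fluor <- do.call(rbind, lapply(names(groups), function(g) {
        signal <- if (g == "hom") base * cfg$fluorContrast else base
        bgN <- pmax(0, bg + noise(nR, cfg$fluorNoiseSd))
        data.frame(image = sprintf("%s_%02d", g, seq_len(nR)),
                   genotype = g,
                   region_mean = pmax(0, bgN + signal +
                                      noise(nR, cfg$fluorNoiseSd)),
                   background_mean = bgN)
    }))
    rownames(fluor) <- NULL
    list(ct = ct, counts = counts, fluor = fluor)
})
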