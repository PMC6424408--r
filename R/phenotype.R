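## Molecular/cellular quantification formulas: delta-delta-Ct relative
## expression, rod-count inference, background-corrected autofluorescence
## and percent-change summaries.

#' Relative expression by the delta-delta-Ct method
#'
#' `2^-ddCt` with `dCt = Ct_target - Ct_reference` per sample and
#' `ddCt = dCt_sample - dCt_calibrator`. Amplification efficiency is
#' fixed at the ideal 2.0 (plain delta-delta-Ct; efficiency correction is
#' out of scope). Adding a constant to both the target and reference Ct
#' of the same sample leaves the result unchanged.
#'
#' @param targetCt,referenceCt sample Ct values (cycles) for the target
#'   and reference (housekeeping) amplicons.
#' @param calTargetCt,calReferenceCt calibrator-sample Ct values.
#' @return fold change(s) relative to the calibrator.
#' @examples
#' relativeExpression(25, 20, 24, 20)  # ddCt = 1 -> 0.5
#' @export
relativeExpression <- function(targetCt, referenceCt,
                               calTargetCt, calReferenceCt) {
    if (any(c(targetCt, referenceCt, calTargetCt, calReferenceCt) <= 0,
            na.rm = TRUE))
        stop("Ct values must be positive")
    2^-((targetCt - referenceCt) - (calTargetCt - calReferenceCt))
}

#' Summarize a replicate Ct table into relative expression
#'
#' For each (sample, amplicon), mean Ct of target and reference
#' replicates are combined via [relativeExpression()] against a
#' calibrator sample. Table columns: `sample`, `gene`
#' (`target`/`reference`), `amplicon`, `ct`.
#'
#' @param ct data.frame of replicate Ct values.
#' @param calibrator sample id used as calibrator (fold = 1 by
#'   construction).
#' @return data.frame with `sample`, `amplicon`, `fold`.
#' @export
relativeExpressionTable <- function(ct, calibrator) {
    need <- c("sample", "gene", "amplicon", "ct")
    if (!all(need %in% colnames(ct)))
        stop("Ct table must have columns: ", paste(need, collapse = ", "))
    if (!calibrator %in% ct$sample)
        stop("calibrator sample not in table: ", calibrator)
    meanCt <- function(smp, gene, amp) {
        sel <- ct$sample == smp & ct$gene == gene &
            (gene == "reference" | ct$amplicon == amp)
        mean(ct$ct[sel])
    }
    grid <- unique(ct[ct$gene == "target", c("sample", "amplicon")])
    grid$fold <- mapply(function(smp, amp)
        relativeExpression(meanCt(smp, "target", amp),
                           meanCt(smp, "reference", amp),
                           meanCt(calibrator, "target", amp),
                           meanCt(calibrator, "reference", amp)),
        grid$sample, grid$amplicon)
    rownames(grid) <- NULL
    grid
}

#' Infer rod photoreceptor count from layer nuclei counts
#'
#' Rods are inferred by subtracting PNA-identified cone nuclei from the
#' total nuclei counted in the outer nuclear layer of a fixed-width
#' region. A zero cone count is valid (in a severely degenerated retina
#' cones can be so rare that all ONL nuclei are rods).
#'
#' @param onlNuclei total nuclei in the outer nuclear layer.
#' @param coneCount cone nuclei in the same region.
#' @return inferred rod count(s); always `onlNuclei - coneCount`.
#' @examples
#' inferRodCount(100, 10)  # 90
#' @export
inferRodCount <- function(onlNuclei, coneCount) {
    if (any(onlNuclei < 0 | coneCount < 0, na.rm = TRUE))
        stop("counts must be non-negative")
    if (any(coneCount > onlNuclei, na.rm = TRUE))
        stop("cone count exceeds ONL nuclei count")
    onlNuclei - coneCount
}

#' Background-corrected mean autofluorescence intensity
#'
#' Region mean minus the mean of the adjacent background region, in the
#' same arbitrary units. A negative corrected intensity is returned
#' as-is but flagged with a warning.
#'
#' @param regionMean,backgroundMean mean intensities (arbitrary units).
#' @return corrected intensity (vectorized).
#' @examples
#' correctedAutofluorescence(70, 10)  # 60
#' @export
correctedAutofluorescence <- function(regionMean, backgroundMean) {
    if (any(regionMean < 0 | backgroundMean < 0, na.rm = TRUE))
        stop("intensities must be non-negative")
    out <- regionMean - backgroundMean
    if (any(out < 0, na.rm = TRUE))
        warning("negative background-corrected intensity")
    out
}

#' Percent reduction / remainder relative to a reference mean
#'
#' `percentReduction(a, b)` is `100 * (b - a) / b`, the percentage by
#' which group mean `a` is reduced relative to reference mean `b`;
#' `percentRemaining` is its complement, and the two always sum to 100.
#'
#' @param meanA group mean.
#' @param meanB reference group mean (must be positive).
#' @return percentage(s).
#' @examples
#' percentReduction(54, 100)  # 46
#' @export
percentReduction <- function(meanA, meanB) {
    if (any(meanB <= 0, na.rm = TRUE))
        stop("reference mean must be positive")
    100 * (meanB - meanA) / meanB
}

#' @rdname percentReduction
#' @export
percentRemaining <- function(meanA, meanB) {
    100 - percentReduction(meanA, meanB)
}

#' Group mean and standard deviation over technical replicates
#'
#' @param values numeric vector of replicate measurements.
#' @param group grouping factor (e.g. genotype).
#' @return data.frame with `group`, `n`, `mean`, `sd`.
#' @export
replicateSummary <- function(values, group) {
    agg <- split(values, group)
    data.frame(group = names(agg),
               n = vapply(agg, length, 0L),
               mean = vapply(agg, mean, 0),
               sd = vapply(agg, stats::sd, 0),
               row.names = NULL)
}
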