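#' Assemble a run summary
#'
#' Aggregates the outputs of a full pipeline run into one per-sample
#' table plus a set of global readouts, mirroring the headline numbers
#' of an embryo time-course analysis: total transcripts and mRNA mass
#' per embryo, detection limits, temporal group sizes, the
#' zygotic-early gene count, motif enrichment statistics, and the
#' successive-sample Spearman correlations.  Optional stages that were
#' not run yield `NA` fields flagged in the narrative, not errors.
#'
#' @param x an [EmbryoExperiment-class] processed through
#'   [detectionCall()] and [toAbsolute()].
#' @param labels factor from [classifyTemporal()] (optional).
#' @param zygoticEarly character vector from [identifyZygoticEarly()]
#'   (optional).
#' @param enrichment list from [setEnrichment()] (optional).
#' @param positional list from [positionalEnrichment()] (optional).
#' @param mass list from [transcriptsToMass()] (optional).
#' @param correlations numeric vector from [successiveCorrelation()]
#'   (optional).
#' @return A `RunSummary`: list with `samples` (data.frame), `global`
#'   (list) and `text` (character narrative, values rounded to 3
#'   significant figures).
#' @export
buildSummary <- function(x, labels = NULL, zygoticEarly = NULL,
                         enrichment = NULL, positional = NULL,
                         mass = NULL, correlations = NULL) {
    stopifnot(is(x, "EmbryoExperiment"))
    if (!("absolute" %in% assayNames(x)))
        stop("run toAbsolute() first")
    gene <- !isSpike(x)
    absGenes <- assay(x, "absolute")[gene, , drop = FALSE]
    det <- detectedMatrix(x, genesOnly = TRUE)
    cf <- metadata(x)$conversionFactors
    thr <- metadata(x)$detectionThreshold
    lim <- detectionLimit(cf, thr)

    if (!is.null(labels) &&
        !setequal(names(labels), rownames(absGenes)))
        stop("gene universe of labels does not match the experiment")
    if (!is.null(mass) &&
        !identical(colnames(mass$mass), colnames(x)))
        stop("sample set of mass table does not match the experiment")

    samples <- data.frame(
        sample = colnames(x),
        timepoint = timepoints(x),
        totalAlignedReads = unname(totalAlignedReads(x)),
        totalTranscripts = unname(colSums(absGenes)),
        totalMassNg = if (is.null(mass)) NA_real_ else unname(mass$total),
        detectionLimit = unname(lim$perSample),
        genesDetected = unname(colSums(det)),
        stringsAsFactors = FALSE)

    groupCounts <- if (is.null(labels)) NULL else table(labels)
    global <- list(
        nGenes = nrow(absGenes),
        groupCounts = groupCounts,
        zygoticEarlyCount = if (is.null(zygoticEarly)) NA_integer_
                            else length(zygoticEarly),
        motifEnrichmentP = if (is.null(enrichment)) NA_real_
                           else enrichment$p,
        motifOddsRatio = if (is.null(enrichment)) NA_real_
                         else enrichment$oddsRatio,
        positionalP = if (is.null(positional)) NA_real_
                      else positional$p,
        meanDetectionLimit = lim$mean,
        successiveSpearman = correlations)

    s3 <- function(v) formatC(signif(v, 3), format = "fg")
    txt <- c(
        sprintf("Samples: %d timepoints (%s h AEL), %d genes, %d spike-ins",
                ncol(x), paste(timepoints(x), collapse = ", "),
                nrow(absGenes), sum(!gene)),
        sprintf("Mean detection limit: %s transcripts/embryo",
                s3(lim$mean)),
        sprintf("Total transcripts/embryo: %s",
                paste(s3(samples$totalTranscripts), collapse = ", ")),
        if (is.null(mass)) "Total mRNA mass: [not computed]"
        else sprintf("Total mRNA (ng/embryo): %s",
                     paste(s3(mass$total), collapse = ", ")),
        if (is.null(labels)) "Temporal groups: [not computed]"
        else sprintf("Temporal groups: %s",
                     paste(names(groupCounts), as.integer(groupCounts),
                           sep = "=", collapse = ", ")),
        if (is.null(zygoticEarly)) "Zygotic-early genes: [not computed]"
        else sprintf("Zygotic-early genes: %d", length(zygoticEarly)),
        if (is.null(enrichment)) "Motif enrichment: [not computed]"
        else sprintf("Motif enrichment: OR=%s, one-sided p=%s",
                     s3(enrichment$oddsRatio), s3(enrichment$p)),
        if (is.null(correlations)) "Successive Spearman: [not computed]"
        else sprintf("Successive Spearman: %s",
                     paste(s3(correlations), collapse = ", ")))
    out <- list(samples = samples, global = global, text = txt)
    class(out) <- "RunSummary"
    out
}

#' @export
print.RunSummary <- function(x, ...) {
    cat(x$text, sep = "\n")
    invisible(x)
}

#' Write a run summary to disk
#'
#' @param summary a `RunSummary` from [buildSummary()].
#' @param tsvPath path for the per-sample table (TSV).
#' @param txtPath optional path for the plain-text narrative.
#' @return `tsvPath`, invisibly.
#' @export
writeSummary <- function(summary, tsvPath, txtPath = NULL) {
    utils::write.table(summary$samples, tsvPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(txtPath))
        writeLines(summary$text, txtPath)
    invisible(tsvPath)
}
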