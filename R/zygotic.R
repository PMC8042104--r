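#' Identify zygotic-early genes by detectability
#'
#' A gene is called zygotic-early when it is undetected at every sample
#' taken at or before `earlyMaxTime` hours AEL (the window in which the
#' zygotic genome is still silent, so everything detectable is
#' maternal) and detected at one or more later samples — implying
#' transcription from the zygotic genome.
#'
#' @param x an [EmbryoExperiment-class] processed by [detectionCall()],
#'   or a logical gene x sample detection matrix.
#' @param tp numeric timepoints (matrix input only).
#' @param earlyMaxTime latest time (h AEL) of the maternal-only window.
#' @return character vector of zygotic-early gene IDs.
#' @export
identifyZygoticEarly <- function(x, tp = NULL, earlyMaxTime = 2) {
    if (is(x, "EmbryoExperiment")) {
        det <- detectedMatrix(x, genesOnly = TRUE)
        tp <- timepoints(x)
    } else {
        det <- as.matrix(x)
        if (is.null(tp))
            stop("matrix input requires 'tp'")
    }
    early <- tp <= earlyMaxTime
    if (!any(early))
        stop("no sample at or before ", earlyMaxTime, " h AEL")
    if (all(early))
        stop("no sample after ", earlyMaxTime, " h AEL")
    keep <- rowSums(det[, early, drop = FALSE]) == 0L &
        rowSums(det[, !early, drop = FALSE]) > 0L
    rownames(det)[keep]
}

#' Intron-read fraction per gene
#'
#' Pools exonic and intronic read counts over the samples in which each
#' gene is detected and reports the intron-read fraction
#' `intronic / (exonic + intronic)` — elevated values indicate nascent
#' transcripts and hence active (zygotic) transcription.  Genes whose
#' representative transcript has a single exon cannot show intron
#' signal and are flagged not-applicable.
#'
#' @param x an [EmbryoExperiment-class] with `"counts"` and
#'   `"intronic"` assays (the counts assay holds total reads; exonic
#'   reads are `counts - intronic`); detection calls restrict pooling
#'   to detected samples when present.
#' @param models optional [GeneModels-class] used to flag intron-free
#'   genes.
#' @return data.frame per gene: `exonicReads`, `intronicReads`,
#'   `fraction` (`NA` when no reads), `applicable` (`FALSE` for
#'   single-exon genes when `models` is given).
#' @export
intronReadFraction <- function(x, models = NULL) {
    stopifnot(is(x, "EmbryoExperiment"))
    if (!("intronic" %in% assayNames(x)))
        stop("experiment carries no 'intronic' assay")
    gene <- !isSpike(x)
    cts <- assay(x, "counts")[gene, , drop = FALSE]
    intr <- assay(x, "intronic")[gene, , drop = FALSE]
    if (any(intr < 0) || any(cts < 0))
        stop("negative counts")
    use <- if ("detected" %in% assayNames(x))
        detectedMatrix(x, genesOnly = TRUE)
    else matrix(TRUE, nrow(cts), ncol(cts))
    intrPooled <- rowSums(intr * use)
    totPooled <- rowSums(cts * use)
    exonic <- totPooled - intrPooled
    frac <- ifelse(totPooled > 0, intrPooled / totPooled, NA_real_)
    applicable <- rep(NA, nrow(cts))
    if (!is.null(models)) {
        nEx <- exonCount(models)[rownames(cts)]
        applicable <- !is.na(nEx) & nEx > 1L
        frac[!applicable %in% TRUE] <- NA_real_
    }
    data.frame(geneId = rownames(cts), exonicReads = exonic,
               intronicReads = intrPooled, fraction = frac,
               applicable = applicable, stringsAsFactors = FALSE,
               row.names = rownames(cts))
}

#' Mann-Whitney rank-sum comparison
#'
#' Two-sample rank-sum (Wilcoxon) test with average ranks for ties.
#' P-values come from exact enumeration when both groups have at most
#' 10 observations and no ties occur, otherwise from the normal
#' approximation with tie correction and continuity correction.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param alternative direction of the one-sided test for `a` relative
#'   to `b` (`"less"`: `a` tends below `b`).
#' @param exact force (`TRUE`/`FALSE`) or auto-select (`NULL`) the
#'   exact branch.
#' @return list with `U` (Mann-Whitney statistic of `a`), `pOneSided`,
#'   `pTwoSided`, and `exact` (which branch was used).
#' @examples
#' rankSumCompare(c(1, 2, 3), c(4, 5, 6))  # exact one-sided p = 0.05
#' @export
rankSumCompare <- function(a, b, alternative = c("less", "greater"),
                           exact = NULL) {
    if (length(a) == 0L || length(b) == 0L)
        stop("both groups must be non-empty")
    alternative <- match.arg(alternative)
    ties <- anyDuplicated(c(a, b)) > 0L
    if (is.null(exact))
        exact <- length(a) <= 10L && length(b) <= 10L && !ties
    if (exact && ties)
        stop("exact enumeration is undefined in the presence of ties")
    one <- stats::wilcox.test(a, b, alternative = alternative,
                              exact = exact, correct = TRUE)
    two <- stats::wilcox.test(a, b, alternative = "two.sided",
                              exact = exact, correct = TRUE)
    p1 <- one$p.value
    p2 <- two$p.value
    # fully tied data: zero-variance normal approximation; U sits exactly
    # at its null mean, so the test carries no evidence
    if (!is.finite(p1)) p1 <- 1
    if (!is.finite(p2)) p2 <- 1
    list(U = unname(one$statistic), pOneSided = p1,
         pTwoSided = p2, exact = exact)
}

#' Compare gene architecture between gene sets
#'
#' Tests whether one gene set (typically zygotic-early genes) has
#' shorter representative transcripts and fewer exons than a background
#' set, using one-sided rank-sum tests.
#'
#' @param models a [GeneModels-class].
#' @param zygoticSet,backgroundSet character vectors of gene IDs, both
#'   present in `models`.
#' @param exact passed to [rankSumCompare()].
#' @return data.frame with one row per property (`txLength`,
#'   `exonCount`): group medians, `U`, one- and two-sided p-values.
#' @export
architectureCompare <- function(models, zygoticSet, backgroundSet,
                                exact = NULL) {
    if (length(zygoticSet) == 0L || length(backgroundSet) == 0L)
        stop("both gene sets must be non-empty")
    missing <- setdiff(c(zygoticSet, backgroundSet), names(models))
    if (length(missing))
        stop("gene(s) absent from models: ",
             paste(utils::head(missing, 10), collapse = ", "))
    props <- list(txLength = txLength(models),
                  exonCount = exonCount(models))
    rows <- lapply(names(props), function(p) {
        va <- unname(props[[p]][zygoticSet])
        vb <- unname(props[[p]][backgroundSet])
        rs <- rankSumCompare(va, vb, alternative = "less", exact = exact)
        data.frame(property = p,
                   medianZygotic = stats::median(va),
                   medianBackground = stats::median(vb),
                   U = rs$U, pOneSided = rs$pOneSided,
                   pTwoSided = rs$pTwoSided,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
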