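#' Parameters for temporal gene classification
#'
#' Thresholds that quantify the four verbal trajectory groups of an
#' embryo time course (maternal-downregulated, persistent, transient,
#' zygotic).
#'
#' @param maternalFold minimum fold change first/last timepoint for a
#'   maternally degraded gene (> 1).
#' @param persistentLog2SdMax maximum standard deviation of
#'   `log2(m + 1)` over the 3-5 h samples for a persistent gene.
#' @param transientPeakFold minimum ratio of the unique peak to the mean
#'   of all other timepoints for a transient gene (> 1).
#' @param zygoticOnsetTime earliest activation time (h AEL): the onset
#'   index is the first sample with `timepoint >= zygoticOnsetTime`.
#' @return a validated parameter list.
#' @export
temporalClassParams <- function(maternalFold = 2.0,
                                persistentLog2SdMax = 0.25,
                                transientPeakFold = 2.0,
                                zygoticOnsetTime = 4) {
    if (maternalFold <= 1 || transientPeakFold <= 1)
        stop("fold thresholds must exceed 1")
    if (persistentLog2SdMax <= 0)
        stop("persistentLog2SdMax must be positive")
    list(maternalFold = maternalFold,
         persistentLog2SdMax = persistentLog2SdMax,
         transientPeakFold = transientPeakFold,
         zygoticOnsetTime = zygoticOnsetTime)
}

#' Classify genes by temporal expression dynamics
#'
#' Assigns each gene exactly one of five labels by rules applied in
#' precedence order:
#' \enumerate{
#'   \item \strong{zygotic} — undetected at every sample before the
#'     onset index (first sample at or after `zygoticOnsetTime`) and
#'     detected at one or more samples from it onward;
#'   \item \strong{maternal_down} — detected at the first timepoint,
#'     trajectory maximum at the first or third timepoint (the third
#'     allows for the global poly(A) rebound), and first-timepoint
#'     abundance at least `maternalFold` times the last;
#'   \item \strong{transient} — detected somewhere, with a unique
#'     maximum at least `transientPeakFold` times the mean of all other
#'     timepoints;
#'   \item \strong{persistent} — detected at every timepoint with
#'     standard deviation of `log2(m + 1)` over the 3-5 h samples at
#'     most `persistentLog2SdMax`;
#'   \item \strong{unclassified} otherwise.
#' }
#' Zygotic takes precedence because it is defined purely by
#' detectability and is the most consequential call of the
#' maternal-to-zygotic transition analysis.
#'
#' @param x an [EmbryoExperiment-class] carrying `"absolute"` and
#'   `"detected"` assays, or a numeric matrix of transcripts per embryo
#'   (genes x samples).
#' @param detected logical matrix matching `x` (ignored when `x` is an
#'   experiment).
#' @param tp numeric timepoints (h AEL; ignored when `x` is an
#'   experiment).
#' @param params a [temporalClassParams()] list.
#' @return named factor along genes with levels `maternal_down`,
#'   `persistent`, `transient`, `zygotic`, `unclassified`.
#' @export
classifyTemporal <- function(x, detected = NULL, tp = NULL,
                             params = temporalClassParams()) {
    if (is(x, "EmbryoExperiment")) {
        if (!("absolute" %in% assayNames(x)))
            stop("run toAbsolute() first")
        m <- assay(x, "absolute")[!isSpike(x), , drop = FALSE]
        detected <- detectedMatrix(x, genesOnly = TRUE)
        tp <- timepoints(x)
    } else {
        m <- as.matrix(x)
        if (is.null(detected) || is.null(tp))
            stop("matrix input requires 'detected' and 'tp'")
    }
    nT <- ncol(m)
    if (nT < 3L)
        stop("temporal classification requires at least 3 timepoints")
    onsetIdx <- match(TRUE, tp >= params$zygoticOnsetTime)
    if (is.na(onsetIdx) || onsetIdx == 1L)
        stop("zygotic onset must fall strictly inside the time course")
    midIdx <- which(tp >= 3 & tp <= 5)
    if (length(midIdx) < 2L)
        midIdx <- seq_len(nT)  # degenerate design: use all samples

    labels <- rep("unclassified", nrow(m))
    preOnset <- seq_len(onsetIdx - 1L)

    zyg <- rowSums(detected[, preOnset, drop = FALSE]) == 0L &
        rowSums(detected[, -preOnset, drop = FALSE]) > 0L

    peakIdx <- max.col(m, ties.method = "first")
    uniqueMax <- rowSums(m == m[cbind(seq_len(nrow(m)), peakIdx)]) == 1L
    mat <- detected[, 1L] & peakIdx %in% c(1L, 3L) &
        m[, 1L] >= params$maternalFold * m[, nT]

    otherMean <- (rowSums(m) - m[cbind(seq_len(nrow(m)), peakIdx)]) /
        (nT - 1L)
    tra <- rowSums(detected) > 0L & uniqueMax &
        m[cbind(seq_len(nrow(m)), peakIdx)] >=
            params$transientPeakFold * otherMean

    lg <- log2(m[, midIdx, drop = FALSE] + 1)
    midSd <- apply(lg, 1L, stats::sd)
    per <- rowSums(detected) == nT & midSd <= params$persistentLog2SdMax

    labels[per] <- "persistent"
    labels[tra] <- "transient"
    labels[mat] <- "maternal_down"
    labels[zyg] <- "zygotic"
    factor(stats::setNames(labels, rownames(m)),
           levels = c("maternal_down", "persistent", "transient",
                      "zygotic", "unclassified"))
}

#' Cluster temporal expression profiles
#'
#' Deterministic profile clustering: each gene's trajectory is
#' transformed to the z-score of `log2(m + 1)`, genes are agglomerated
#' with average linkage on the distance `1 - Pearson correlation`, and
#' the tree is cut into `k` clusters.  Constant (zero-variance)
#' trajectories cannot be correlated and are assigned to a dedicated
#' flat cluster `0` before clustering.
#'
#' @param x an [EmbryoExperiment-class] with an `"absolute"` assay, or
#'   a numeric matrix (genes x samples).
#' @param k number of clusters among non-flat genes (>= 1).
#' @return named integer vector of cluster labels (0 = flat).
#' @export
clusterProfiles <- function(x, k) {
    m <- if (is(x, "EmbryoExperiment"))
        assay(x, "absolute")[!isSpike(x), , drop = FALSE]
    else as.matrix(x)
    stopifnot(k >= 1)
    lg <- log2(m + 1)
    sds <- apply(lg, 1L, stats::sd)
    flat <- sds == 0 | !is.finite(sds)
    out <- stats::setNames(integer(nrow(m)), rownames(m))
    active <- which(!flat)
    if (k > length(active))
        stop("k exceeds the number of non-flat genes (", length(active),
             ")")
    if (length(active)) {
        z <- t(scale(t(lg[active, , drop = FALSE])))
        d <- stats::as.dist(1 - stats::cor(t(z)))
        hc <- stats::hclust(d, method = "average")
        out[active] <- stats::cutree(hc, k = k)
    }
    out
}

#' Spearman correlation between successive samples
#'
#' Quality-control statistic for the sampling density of a time course:
#' the Spearman rank correlation over genes between each adjacent pair
#' of samples (ties receive average ranks).  Samples taken close enough
#' to resolve the transcriptome dynamics correlate highly (around 0.96
#' or better in hourly embryo series).
#'
#' @param x an [EmbryoExperiment-class] with an `"absolute"` assay, or
#'   a numeric matrix (genes x samples).
#' @return named numeric vector, one entry per adjacent sample pair
#'   (`NA` with a warning for constant columns).
#' @export
successiveCorrelation <- function(x) {
    m <- if (is(x, "EmbryoExperiment"))
        assay(x, "absolute")[!isSpike(x), , drop = FALSE]
    else as.matrix(x)
    if (ncol(m) < 2L)
        stop("need at least 2 samples")
    out <- numeric(ncol(m) - 1L)
    nm <- character(ncol(m) - 1L)
    cn <- colnames(m)
    if (is.null(cn)) cn <- paste0("s", seq_len(ncol(m)))
    for (j in seq_len(ncol(m) - 1L)) {
        a <- m[, j]; b <- m[, j + 1L]
        if (stats::sd(a) == 0 || stats::sd(b) == 0) {
            warning("constant sample column; correlation undefined for ",
                    cn[j], " vs ", cn[j + 1L])
            out[j] <- NA_real_
        } else {
            out[j] <- stats::cor(a, b, method = "spearman")
        }
        nm[j] <- paste0(cn[j], ":", cn[j + 1L])
    }
    stats::setNames(out, nm)
}

#' Rank genes by expression stability
#'
#' Identifies candidate reference genes (e.g. for qPCR normalisation):
#' among genes detected at every timepoint, ranks by the coefficient of
#' variation on the log scale — the standard deviation of
#' `log2(m + 1)` across timepoints divided by its mean — ascending,
#' with ties broken by gene ID.
#'
#' @param x an [EmbryoExperiment-class] with `"absolute"` and
#'   `"detected"` assays, or a numeric matrix (genes x samples).
#' @param detected logical matrix (matrix input only).
#' @param topN number of genes to return.
#' @return data.frame with `geneId` and `score`, most stable first.
#' @export
stabilityRanking <- function(x, detected = NULL, topN = 10) {
    if (is(x, "EmbryoExperiment")) {
        m <- assay(x, "absolute")[!isSpike(x), , drop = FALSE]
        detected <- detectedMatrix(x, genesOnly = TRUE)
    } else {
        m <- as.matrix(x)
        if (is.null(detected))
            stop("matrix input requires 'detected'")
    }
    eligible <- rowSums(detected) == ncol(m)
    if (!any(eligible))
        stop("no gene detected at all timepoints")
    lg <- log2(m[eligible, , drop = FALSE] + 1)
    score <- apply(lg, 1L, stats::sd) / rowMeans(lg)
    ord <- order(score, rownames(lg))
    top <- utils::head(ord, topN)
    data.frame(geneId = rownames(lg)[top], score = unname(score[top]),
               stringsAsFactors = FALSE)
}
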