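#' Relative abundance in RPG10K units
#'
#' Converts raw counts to Reads Per Gene per 10,000 aligned reads:
#' `rho_ij = c_ij / N_j * 1e4`, where `N_j` is the total aligned reads
#' of sample `j` including spike-in reads, so gene and spike-in relative
#' scales share one denominator.  The result is stored as assay
#' `"rpg10k"`.
#'
#' @param x an [EmbryoExperiment-class] with a `"counts"` assay.
#' @return `x` with an added `"rpg10k"` assay.
#' @examples
#' sim <- simulateExperiment(simulationConfig(nGenes = 50, nSpikes = 10),
#'                           withPromoters = FALSE)
#' ee <- computeRPG10K(sim$experiment)
#' colSums(assay(ee, "rpg10k"))  # 10,000 per sample
#' @export
computeRPG10K <- function(x) {
    stopifnot(is(x, "EmbryoExperiment"))
    N <- totalAlignedReads(x)
    if (any(N == 0))
        stop("sample(s) with zero total reads: ",
             paste(colnames(x)[N == 0], collapse = ", "))
    cts <- assay(x, "counts")
    # multiply first: c * 1e4 is exact in doubles for any realistic count
    rho <- sweep(cts * 1e4, 2, N, `/`)
    assay(x, "rpg10k") <- rho
    x
}

#' Detection calls at an RPG10K sensitivity floor
#'
#' Flags each feature in each sample as detected when its relative
#' abundance reaches the sensitivity floor: `rho_ij >= threshold`
#' (closed boundary, so a value exactly at the floor is detectable).
#' The default floor of 0.01 RPG10K corresponds to about 2 mapped reads
#' at a depth of 2 million aligned reads.
#'
#' @param x an [EmbryoExperiment-class]; the `"rpg10k"` assay is
#'   computed on the fly if absent.
#' @param threshold detection floor in RPG10K units (> 0).
#' @return `x` with an added logical `"detected"` assay; the threshold
#'   is recorded in `metadata(x)$detectionThreshold`.
#' @seealso [detectedMatrix()]
#' @export
detectionCall <- function(x, threshold = 0.01) {
    stopifnot(is(x, "EmbryoExperiment"), threshold > 0)
    if (!("rpg10k" %in% assayNames(x)))
        x <- computeRPG10K(x)
    assay(x, "detected") <- assay(x, "rpg10k") >= threshold
    metadata(x)$detectionThreshold <- threshold
    x
}

#' Extract the detection matrix
#'
#' @param x an [EmbryoExperiment-class] processed by [detectionCall()].
#' @param genesOnly drop spike-in rows (the default: downstream gene
#'   analyses never see spike-ins).
#' @return logical matrix, features x samples.
#' @export
detectedMatrix <- function(x, genesOnly = TRUE) {
    if (!("detected" %in% assayNames(x)))
        stop("run detectionCall() first")
    det <- assay(x, "detected")
    if (genesOnly) det[!isSpike(x), , drop = FALSE] else det
}
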