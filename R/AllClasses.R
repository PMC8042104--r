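#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assay<- assays<- rowData colData assayNames
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width
#'   strand strand<-
#' @importFrom BiocGenerics unstrand
#' @importFrom IRanges IRanges
NULL

#' Container for an embryo time-course experiment
#'
#' `EmbryoExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment-class] for gene x sample
#' read counts from a spike-in calibrated embryo time course.  Rows are
#' features (genes and ERCC-style spike-ins, distinguished by
#' `rowData(x)$featureType`), columns are samples ordered by developmental
#' time.  The `"counts"` assay holds raw aligned-read counts; downstream
#' steps add `"rpg10k"` (relative abundance), `"detected"` (logical) and
#' `"absolute"` (transcripts per embryo) assays.  An optional `"intronic"`
#' assay carries the intron-overlapping read counts used for nascent
#' transcription analysis.
#'
#' Column metadata must contain `timepoint` (hours after egg laying,
#' strictly increasing across the ordered samples) and `embryosPooled`
#' (positive integer).  `totalAlignedReads` is derived from the column
#' sums of the counts assay.
#'
#' @aliases EmbryoExperiment-class
#' @exportClass EmbryoExperiment
setClass("EmbryoExperiment", contains = "SummarizedExperiment")

.validEmbryoExperiment <- function(object) {
    msg <- NULL
    if (!("counts" %in% assayNames(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- assay(object, "counts")
        if (anyNA(cts) || any(cts < 0) || any(cts != round(cts)))
            msg <- c(msg, "counts must be nonnegative integers")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate feature IDs")
    cd <- colData(object)
    if (!all(c("timepoint", "embryosPooled") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'timepoint' and 'embryosPooled'")
    else {
        tp <- cd$timepoint
        if (length(tp) > 1L && any(diff(tp) <= 0))
            msg <- c(msg, "timepoints must be strictly increasing")
        if (any(tp <= 0))
            msg <- c(msg, "timepoints must be positive")
        if (any(cd$embryosPooled < 1))
            msg <- c(msg, "embryosPooled must be >= 1")
    }
    if (!("featureType" %in% colnames(rowData(object))))
        msg <- c(msg, "rowData must contain 'featureType'")
    else if (!all(rowData(object)$featureType %in% c("gene", "spike")))
        msg <- c(msg, "featureType must be 'gene' or 'spike'")
    if ("intronic" %in% assayNames(object)) {
        intr <- assay(object, "intronic")
        if (any(intr < 0) || any(intr > assay(object, "counts")))
            msg <- c(msg, "intronic counts must lie in [0, counts]")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("EmbryoExperiment", .validEmbryoExperiment)

#' Construct an EmbryoExperiment
#'
#' @param counts integer matrix of aligned-read counts, features x samples,
#'   with feature IDs as rownames and sample IDs as colnames.
#' @param timepoint numeric vector of sampling times (hours after egg
#'   laying), one per sample, strictly increasing.
#' @param embryosPooled integer vector (or scalar) of embryos pooled per
#'   sample.
#' @param spikeIds character vector of feature IDs that are spike-ins;
#'   defaults to rownames matching `^ERCC-`.
#' @param intronic optional matrix, same shape as `counts`, of reads
#'   overlapping intronic intervals (a subset of `counts`).
#'
#' @return An [EmbryoExperiment-class] object.
#' @examples
#' cts <- matrix(rpois(12, 20), nrow = 4,
#'               dimnames = list(c(paste0("g", 1:3), "ERCC-00001"),
#'                               paste0("s", 1:3)))
#' ee <- EmbryoExperiment(cts, timepoint = 1:3)
#' ee
#' @export
EmbryoExperiment <- function(counts, timepoint, embryosPooled = 1L,
                             spikeIds = NULL, intronic = NULL) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        stop("counts must have feature IDs as rownames")
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
    if (is.null(spikeIds))
        spikeIds <- grep("^ERCC-", rownames(counts), value = TRUE)
    ftype <- ifelse(rownames(counts) %in% spikeIds, "spike", "gene")
    embryosPooled <- rep_len(as.integer(embryosPooled), ncol(counts))
    cd <- DataFrame(timepoint = as.numeric(timepoint),
                    embryosPooled = embryosPooled,
                    row.names = colnames(counts))
    assays <- list(counts = counts)
    if (!is.null(intronic)) {
        intronic <- as.matrix(intronic)
        stopifnot(identical(dim(intronic), dim(counts)))
        assays$intronic <- intronic
    }
    se <- SummarizedExperiment(
        assays = assays,
        rowData = DataFrame(featureType = ftype, row.names = rownames(counts)),
        colData = cd)
    new("EmbryoExperiment", se)
}

#' Per-sample conversion factors from spike-in calibration
#'
#' Holds, for each sample, the intercept `beta_j` of the intercept-only
#' Poisson log-linear fit of spike-in relative abundance (RPG10K) against
#' an offset of log known molecules per embryo.  `exp(-beta_j)` converts
#' one RPG10K unit into transcripts per embryo.
#'
#' @slot beta named numeric, one log-link intercept per sample.
#' @slot nSpikes integer, number of spike-in species entering each fit
#'   (zero-count spikes included).
#' @aliases ConversionFactors-class
#' @exportClass ConversionFactors
setClass("ConversionFactors",
         representation(beta = "numeric", nSpikes = "integer"))

setValidity("ConversionFactors", function(object) {
    msg <- NULL
    if (any(!is.finite(object@beta)))
        msg <- c(msg, "beta must be finite")
    if (is.null(names(object@beta)))
        msg <- c(msg, "beta must be named by sample")
    if (length(object@nSpikes) != length(object@beta))
        msg <- c(msg, "nSpikes must match beta in length")
    if (is.null(msg)) TRUE else msg
})

#' Per-gene transcript models derived from GFF3 annotation
#'
#' For each gene, the strand-aware transcription start site (TSS), the
#' representative transcript (the longest isoform by summed exon length),
#' its spliced length and exon count, and the intron intervals of that
#' isoform.  Drives promoter extraction, transcript-mass conversion and
#' gene-architecture comparisons.
#'
#' @slot genes a [GenomicRanges::GRanges] with one range per gene (the
#'   representative transcript's genomic span), named by gene ID, with
#'   metadata columns `tss`, `txLength` and `exonCount`.
#' @slot introns a [GenomicRanges::GRangesList] of intron intervals of the
#'   representative transcript, named by gene ID (empty for single-exon
#'   genes).
#' @aliases GeneModels-class
#' @exportClass GeneModels
setClass("GeneModels",
         representation(genes = "GRanges", introns = "GRangesList"))

setValidity("GeneModels", function(object) {
    msg <- NULL
    if (is.null(names(object@genes)) || anyDuplicated(names(object@genes)))
        msg <- c(msg, "genes must be uniquely named by gene ID")
    need <- c("tss", "txLength", "exonCount")
    if (!all(need %in% colnames(mcols(object@genes))))
        msg <- c(msg, "genes must carry mcols tss, txLength, exonCount")
    if (!all(names(object@introns) %in% names(object@genes)))
        msg <- c(msg, "intron names must be a subset of gene names")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "EmbryoExperiment", function(object) {
    callNextMethod()
    nsp <- sum(rowData(object)$featureType == "spike")
    cat(sprintf("features: %d genes, %d spike-ins\n",
                nrow(object) - nsp, nsp))
    cat("timepoints (h AEL):",
        paste(colData(object)$timepoint, collapse = ", "), "\n")
})

setMethod("show", "ConversionFactors", function(object) {
    cat("ConversionFactors for", length(object@beta), "samples\n")
    print(data.frame(beta = object@beta,
                     scale = exp(-object@beta),
                     nSpikes = object@nSpikes))
})

setMethod("show", "GeneModels", function(object) {
    cat("GeneModels with", length(object@genes), "genes;",
        sum(lengths(object@introns) > 0), "have introns\n")
})

#' @describeIn GeneModels-class number of genes
#' @param x a `GeneModels` object
#' @export
setMethod("length", "GeneModels", function(x) length(x@genes))

#' @describeIn GeneModels-class gene IDs
#' @export
setMethod("names", "GeneModels", function(x) names(x@genes))
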