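#' Accessors for spike-in calibrated experiments
#'
#' `isSpike` flags spike-in rows; `spikeIds` and `geneIds` return the
#' corresponding feature IDs; `timepoints` returns the sampling times in
#' hours after egg laying; `totalAlignedReads` the per-sample column sums
#' of the counts assay.
#'
#' @param x an [EmbryoExperiment-class] object.
#' @return `isSpike`: logical vector along rows; `spikeIds`, `geneIds`:
#'   character vectors; `timepoints`, `totalAlignedReads`: numeric vectors
#'   along samples.
#' @name embryo-accessors
NULL

#' @rdname embryo-accessors
#' @export
setGeneric("isSpike", function(x) standardGeneric("isSpike"))

#' @rdname embryo-accessors
#' @export
setMethod("isSpike", "EmbryoExperiment", function(x)
    rowData(x)$featureType == "spike")

#' @rdname embryo-accessors
#' @export
setGeneric("spikeIds", function(x) standardGeneric("spikeIds"))

#' @rdname embryo-accessors
#' @export
setMethod("spikeIds", "EmbryoExperiment", function(x)
    rownames(x)[isSpike(x)])

#' @rdname embryo-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname embryo-accessors
#' @export
setMethod("geneIds", "EmbryoExperiment", function(x)
    rownames(x)[!isSpike(x)])

#' @rdname embryo-accessors
#' @export
setGeneric("timepoints", function(x) standardGeneric("timepoints"))

#' @rdname embryo-accessors
#' @export
setMethod("timepoints", "EmbryoExperiment", function(x)
    colData(x)$timepoint)

#' @rdname embryo-accessors
#' @export
setGeneric("totalAlignedReads", function(x)
    standardGeneric("totalAlignedReads"))

#' @rdname embryo-accessors
#' @export
setMethod("totalAlignedReads", "EmbryoExperiment", function(x)
    colSums(assay(x, "counts")))

#' Accessors for conversion factors
#'
#' `convBeta` returns the per-sample log-link intercepts; `convScale`
#' returns `exp(-beta)`, the number of transcripts per embryo represented
#' by one RPG10K unit; `nSpikesUsed` the number of spike-in species that
#' entered each fit.
#'
#' @param x a [ConversionFactors-class] object.
#' @return named numeric (or integer) vector along samples.
#' @name conversion-accessors
NULL

#' @rdname conversion-accessors
#' @export
setGeneric("convBeta", function(x) standardGeneric("convBeta"))

#' @rdname conversion-accessors
#' @export
setMethod("convBeta", "ConversionFactors", function(x) x@beta)

#' @rdname conversion-accessors
#' @export
setGeneric("convScale", function(x) standardGeneric("convScale"))

#' @rdname conversion-accessors
#' @export
setMethod("convScale", "ConversionFactors", function(x) exp(-x@beta))

#' @rdname conversion-accessors
#' @export
setGeneric("nSpikesUsed", function(x) standardGeneric("nSpikesUsed"))

#' @rdname conversion-accessors
#' @export
setMethod("nSpikesUsed", "ConversionFactors", function(x) x@nSpikes)

#' Accessors for gene models
#'
#' `tss` returns the strand-aware transcription start site of each gene's
#' representative transcript; `txLength` its spliced (summed-exon) length;
#' `exonCount` its exon count; `geneStrand` the coding strand;
#' `intronRanges` the intron intervals as a
#' [GenomicRanges::GRangesList] (genes without introns have zero-length
#' elements).
#'
#' @param x a [GeneModels-class] object.
#' @return named vectors along genes, or a `GRangesList` for
#'   `intronRanges`.
#' @name genemodel-accessors
NULL

#' @rdname genemodel-accessors
#' @export
setGeneric("tss", function(x) standardGeneric("tss"))

#' @rdname genemodel-accessors
#' @export
setMethod("tss", "GeneModels", function(x)
    stats::setNames(mcols(x@genes)$tss, names(x@genes)))

#' @rdname genemodel-accessors
#' @export
setGeneric("txLength", function(x) standardGeneric("txLength"))

#' @rdname genemodel-accessors
#' @export
setMethod("txLength", "GeneModels", function(x)
    stats::setNames(mcols(x@genes)$txLength, names(x@genes)))

#' @rdname genemodel-accessors
#' @export
setGeneric("exonCount", function(x) standardGeneric("exonCount"))

#' @rdname genemodel-accessors
#' @export
setMethod("exonCount", "GeneModels", function(x)
    stats::setNames(mcols(x@genes)$exonCount, names(x@genes)))

#' @rdname genemodel-accessors
#' @export
setGeneric("geneStrand", function(x) standardGeneric("geneStrand"))

#' @rdname genemodel-accessors
#' @export
setMethod("geneStrand", "GeneModels", function(x)
    stats::setNames(as.character(strand(x@genes)), names(x@genes)))

#' @rdname genemodel-accessors
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname genemodel-accessors
#' @export
setMethod("geneRanges", "GeneModels", function(x) x@genes)

#' @rdname genemodel-accessors
#' @export
setGeneric("intronRanges", function(x) standardGeneric("intronRanges"))

#' @rdname genemodel-accessors
#' @export
setMethod("intronRanges", "GeneModels", function(x) {
    out <- x@introns
    missing <- setdiff(names(x@genes), names(out))
    if (length(missing)) {
        empty <- GRangesList(rep(list(GRanges()), length(missing)))
        names(empty) <- missing
        out <- c(out, empty)
    }
    out[names(x@genes)]
})
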