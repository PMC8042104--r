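#' Avogadro's number (1/mol)
#' @keywords internal
.AVOGADRO <- 6.02214076e23

#' Read a gene x sample count table
#'
#' Reads a TSV count table (header row of sample IDs, first column feature
#' IDs, integer cells) into an [EmbryoExperiment-class].  Lines starting
#' with `#` are treated as comments.  Spike-in rows are recognised by ID
#' (default: `ERCC-` prefix).
#'
#' @param path path to the TSV file.
#' @param timepoint numeric vector of sampling times (h AEL), one per
#'   sample column; defaults to `1..n_samples`.
#' @param embryosPooled embryos pooled per sample (scalar or vector).
#' @param spikeIds feature IDs to treat as spike-ins; `NULL` uses the
#'   `ERCC-` prefix convention.
#' @param intronicPath optional TSV of the same shape holding
#'   intron-overlapping read counts.
#' @return An [EmbryoExperiment-class].
#' @seealso [writeCountMatrix()]
#' @export
readCountMatrix <- function(path, timepoint = NULL, embryosPooled = 1L,
                            spikeIds = NULL, intronicPath = NULL) {
    mat <- .readTsvMatrix(path)
    if (is.null(timepoint))
        timepoint <- seq_len(ncol(mat))
    intr <- if (!is.null(intronicPath)) .readTsvMatrix(intronicPath) else NULL
    if (!is.null(intr))
        intr <- intr[rownames(mat), colnames(mat), drop = FALSE]
    EmbryoExperiment(mat, timepoint = timepoint,
                     embryosPooled = embryosPooled, spikeIds = spikeIds,
                     intronic = intr)
}

.readTsvMatrix <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            comment.char = "#", check.names = FALSE,
                            colClasses = "character")
    if (nrow(df) == 0L)
        stop("no features in ", path)
    ids <- df[[1L]]
    if (anyDuplicated(ids))
        stop("duplicate feature IDs in ", path, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    body <- df[, -1L, drop = FALSE]
    num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
    num <- matrix(num, nrow = nrow(body),
                  dimnames = list(ids, colnames(body)))
    bad <- which(is.na(num) | num != round(num), arr.ind = TRUE)
    if (nrow(bad) > 0L)
        stop(sprintf("non-integer count at feature '%s', sample '%s'",
                     ids[bad[1L, 1L]], colnames(num)[bad[1L, 2L]]))
    storage.mode(num) <- "integer"
    num
}

#' Write a count table to TSV
#'
#' Inverse of [readCountMatrix()]: feature IDs in the first column
#' (`feature`), one column per sample.  Optional comment lines (prefixed
#' `#`) record provenance.
#'
#' @param x an [EmbryoExperiment-class] or a counts matrix.
#' @param path output file path.
#' @param assayName which assay to write when `x` is an experiment.
#' @param comments character vector written as `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
writeCountMatrix <- function(x, path, assayName = "counts",
                             comments = character()) {
    mat <- if (is(x, "SummarizedExperiment")) assay(x, assayName) else x
    con <- file(path, "w")
    on.exit(close(con))
    for (cm in comments) writeLines(paste0("# ", cm), con)
    df <- data.frame(feature = rownames(mat), mat, check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a spike-in concentration table
#'
#' Reads a two-column TSV (spike ID, known molecules per embryo
#' equivalent) into a data frame keyed by spike ID.  Comment lines
#' (`#`) are skipped.
#'
#' @param path path to the TSV file.
#' @return A data.frame with columns `spikeId` (character) and
#'   `molecules` (positive numeric), row names set to `spikeId`.
#' @seealso [erccSpikeTable()] for the bundled 92-species table,
#'   [attomolesToMolecules()] to derive molecule numbers from
#'   concentrations.
#' @export
readSpikeInTable <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            comment.char = "#", check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
        stop("spike-in table needs columns: spike ID, molecules")
    out <- data.frame(spikeId = as.character(df[[1L]]),
                      molecules = as.numeric(df[[2L]]),
                      stringsAsFactors = FALSE)
    .validateSpikeTable(out)
    rownames(out) <- out$spikeId
    out
}

.validateSpikeTable <- function(df) {
    if (anyDuplicated(df$spikeId))
        stop("duplicate spike IDs")
    if (anyNA(df$molecules) || any(df$molecules <= 0))
        stop("spike-in molecule counts must be positive")
    invisible(df)
}

#' Write a spike-in concentration table
#' @param spikes data.frame with `spikeId` and `molecules` columns.
#' @param path output file path.
#' @param comments character vector written as `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
writeSpikeInTable <- function(spikes, path, comments = character()) {
    con <- file(path, "w")
    on.exit(close(con))
    for (cm in comments) writeLines(paste0("# ", cm), con)
    utils::write.table(spikes[, c("spikeId", "molecules")], con,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Bundled 92-species spike-in table
#'
#' Returns the packaged spike-in concentration table: 92 species, the
#' size of the External RNA Control Consortium (ERCC) spike-in mix.  The
#' molecule numbers are synthetic — a geometric ladder spanning
#' 1e2 to 1e7 molecules per embryo equivalent that mimics the wide
#' dynamic range of ERCC Mix 1 — because vendor concentrations are not
#' redistributed here.  For real experiments, supply your own table via
#' [readSpikeInTable()].
#'
#' @return A data.frame as from [readSpikeInTable()], 92 rows.
#' @export
erccSpikeTable <- function() {
    path <- system.file("extdata", "ercc92_synthetic.tsv",
                        package = "embryoQuant", mustWork = TRUE)
    readSpikeInTable(path)
}

#' Convert a spike-in concentration to molecules per embryo
#'
#' Helper for building spike-in tables from vendor concentration sheets:
#' converts (attomoles/uL, volume added, dilution, embryos pooled) into
#' molecules per embryo equivalent using Avogadro's number.
#'
#' @param attomolesPerUl concentration of the stock (attomol/uL).
#' @param volumeUl volume of (diluted) stock added (uL).
#' @param dilution fold dilution applied to the stock before addition.
#' @param embryos number of embryos the volume was added to.
#' @return molecules per embryo (numeric).
#' @examples
#' attomolesToMolecules(1)  # 1 attomole in 1 embryo -> 602214 molecules
#' @export
attomolesToMolecules <- function(attomolesPerUl, volumeUl = 1,
                                 dilution = 1, embryos = 1) {
    if (any(dilution <= 0) || any(embryos <= 0) || any(volumeUl <= 0))
        stop("volume, dilution and embryos must be positive")
    attomolesPerUl * volumeUl / dilution * 1e-18 * .AVOGADRO / embryos
}

#' Read gene models from GFF3
#'
#' Imports a GFF3 annotation (1-based inclusive coordinates) and reduces
#' it to per-gene transcript models: the representative transcript is the
#' isoform with the largest summed exon length; its strand-aware 5' end
#' is the TSS; introns are the gaps between its consecutive exons.
#'
#' @param path path to a GFF3 file with gene/mRNA/exon features linked by
#'   `ID`/`Parent` attributes.
#' @return A [GeneModels-class] object.
#' @export
readGeneModels <- function(path) {
    gr <- rtracklayer::import(path, format = "gff3")
    type <- as.character(gr$type)
    tx <- gr[type %in% c("mRNA", "transcript")]
    exons <- gr[type == "exon"]
    if (length(tx) == 0L || length(exons) == 0L)
        stop("GFF3 must contain mRNA/transcript and exon features")
    if (any(as.character(strand(tx)) == "*"))
        stop("transcript with missing strand: ",
             paste(utils::head(tx$ID[as.character(strand(tx)) == "*"]),
                   collapse = ", "))
    txParent <- vapply(tx$Parent, function(p) p[1L], character(1))
    names(tx) <- as.character(tx$ID)
    exonParent <- vapply(exons$Parent, function(p) p[1L], character(1))
    keep <- exonParent %in% names(tx)
    exons <- exons[keep]
    exonParent <- exonParent[keep]
    # exon containment within parent transcript bounds
    pidx <- match(exonParent, names(tx))
    pstart <- start(tx)[pidx]
    pend <- end(tx)[pidx]
    bad <- start(exons) < pstart | end(exons) > pend
    if (any(bad))
        stop("exon outside parent transcript bounds for transcript(s): ",
             paste(unique(exonParent[bad]), collapse = ", "))
    exonsByTx <- split(GenomicRanges::granges(exons), exonParent)
    .buildGeneModels(exonsByTx,
                     txGene = stats::setNames(txParent, names(tx)),
                     txStrand = stats::setNames(as.character(strand(tx)),
                                                names(tx)))
}

# Assemble a GeneModels object from per-transcript exon sets.
# exonsByTx: GRangesList named by transcript; txGene: tx -> gene id;
# txStrand: tx -> "+"/"-".  Representative transcript = longest summed
# exon length, ties broken by transcript ID.
.buildGeneModels <- function(exonsByTx, txGene, txStrand) {
    exonsByTx <- sort(GenomicRanges::GRangesList(lapply(exonsByTx,
        function(g) { strand(g) <- "*"; g })), ignore.strand = TRUE)
    txLen <- sum(width(exonsByTx))
    txIds <- names(exonsByTx)
    ord <- order(txGene[txIds], -txLen[txIds], txIds)
    txIds <- txIds[ord]
    repTx <- txIds[!duplicated(txGene[txIds])]
    geneId <- unname(txGene[repTx])

    ex <- exonsByTx[repTx]
    spans <- unlist(range(ex), use.names = FALSE)
    strnd <- unname(txStrand[repTx])
    introns <- GenomicRanges::psetdiff(spans, ex)
    intStrand <- rep(strnd, lengths(introns))
    intronsFlat <- unlist(introns, use.names = FALSE)
    strand(intronsFlat) <- intStrand
    introns <- IRanges::relist(intronsFlat, introns)
    names(introns) <- geneId

    strand(spans) <- strnd
    names(spans) <- geneId
    mcols(spans)$tss <- ifelse(strnd == "+", start(spans), end(spans))
    mcols(spans)$txLength <- unname(txLen[repTx])
    mcols(spans)$exonCount <- unname(lengths(ex))
    new("GeneModels", genes = spans, introns = introns)
}
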