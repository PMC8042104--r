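suppressPackageStartupMessages({
    library(SummarizedExperiment)
    library(GenomicRanges)
    library(Biostrings)
})

# tiny count experiment with a controllable filler row so per-sample
# totals (and hence exact RPG10K values) can be dialled in
tinyExperiment <- function(geneCounts, totals, timepoint = NULL,
                           spikeCounts = NULL) {
    geneCounts <- as.matrix(geneCounts)
    if (is.null(rownames(geneCounts)))
        rownames(geneCounts) <- paste0("g", seq_len(nrow(geneCounts)))
    if (is.null(colnames(geneCounts)))
        colnames(geneCounts) <- paste0("s", seq_len(ncol(geneCounts)))
    mat <- geneCounts
    if (!is.null(spikeCounts)) {
        spikeCounts <- as.matrix(spikeCounts)
        rownames(spikeCounts) <- sprintf("ERCC-%05d",
                                         seq_len(nrow(spikeCounts)))
        colnames(spikeCounts) <- colnames(geneCounts)
        mat <- rbind(mat, spikeCounts)
    }
    filler <- totals - colSums(mat)
    stopifnot(all(filler >= 0))
    mat <- rbind(mat, filler = filler)
    if (is.null(timepoint))
        timepoint <- seq_len(ncol(mat))
    EmbryoExperiment(mat, timepoint = timepoint)
}

# hand-rolled GeneModels for coordinate-level tests
makeModels <- function(tss, strand, txLength, exonCount,
                       chrom = "chr1", geneId = NULL) {
    n <- length(tss)
    if (is.null(geneId)) geneId <- paste0("g", seq_len(n))
    genes <- GRanges(chrom, IRanges(start = pmax(1, tss - 10),
                                    end = tss + 10), strand = strand)
    names(genes) <- geneId
    mcols(genes)$tss <- tss
    mcols(genes)$txLength <- txLength
    mcols(genes)$exonCount <- exonCount
    introns <- GRangesList(rep(list(GRanges()), n))
    names(introns) <- geneId
    new("GeneModels", genes = genes, introns = introns)
}

writeGff <- function(lines) {
    path <- tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3", lines), path)
    path
}

# naive sliding-window IUPAC matcher: the independent oracle for
# scanMotif (N in the sequence never matches)
naiveScan <- function(seq, motif, bothStrands = TRUE) {
    matchOne <- function(s, pat) {
        sets <- strsplit(Biostrings::IUPAC_CODE_MAP[
            strsplit(pat, "")[[1]]], "")
        sc <- strsplit(s, "")[[1]]
        L <- length(sets)
        hits <- integer(0)
        if (length(sc) >= L)
            for (i in seq_len(length(sc) - L + 1)) {
                ok <- TRUE
                for (k in seq_len(L))
                    if (!(sc[i + k - 1] %in% sets[[k]])) {
                        ok <- FALSE; break
                    }
                if (ok) hits <- c(hits, i)
            }
        hits
    }
    fw <- matchOne(seq, motif)
    rv <- integer(0)
    if (bothStrands) {
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(motif)))
        rv <- matchOne(seq, rc)
    }
    list(forward = fw, reverse = rv)
}

# exact rank-sum enumeration oracle: P(U <= observed) over all
# assignments of the pooled ranks to group A (tie-free data only)
enumRankSumP <- function(a, b) {
    pooled <- c(a, b)
    stopifnot(!anyDuplicated(pooled))
    na <- length(a)
    r <- rank(pooled)
    uObs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    combos <- utils::combn(length(pooled), na)
    us <- apply(combos, 2, function(idx)
        sum(r[idx]) - na * (na + 1) / 2)
    mean(us <= uObs)
}

# random-abundance instance generator for calibration oracle checks
randomSpikeInstance <- function(n = 20) {
    S <- 10^runif(n, 2, 6)
    r <- rpois(n, S / 5000) + runif(n) * 0.01
    list(r = r, S = S)
}

# independent Poisson-IRLS (Fisher scoring) fit of the intercept-only
# log-link model with offset log(S); deliberately not glm() and not the
# closed form
irlsIntercept <- function(r, S, tol = 1e-12, maxit = 100) {
    beta <- 0
    for (i in seq_len(maxit)) {
        mu <- exp(beta + log(S))
        score <- sum(r - mu)
        info <- sum(mu)
        step <- score / info
        beta <- beta + step
        if (abs(step) < tol) break
    }
    beta
}
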