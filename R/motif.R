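#' Extract promoter sequences upstream of TSSs
#'
#' Cuts the `window` bases immediately upstream of each gene's
#' strand-aware transcription start site out of the genome and orients
#' them 5' to 3' toward the TSS, so position `window` of every returned
#' sequence is the base adjacent to the TSS.  For a plus-strand gene
#' with TSS `t` this is the interval `[t - window, t - 1]` (1-based
#' inclusive); for a minus-strand gene, `[t + 1, t + window]`
#' reverse-complemented.  Windows are clipped at contig edges; clipped
#' promoters shorter than `minWidth` are dropped with a warning.
#'
#' @param models a [GeneModels-class].
#' @param genome a [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param window promoter width in bp.
#' @param minWidth minimum clipped width to keep.
#' @return named [Biostrings::DNAStringSet] of promoters.
#' @export
extractPromoters <- function(models, genome, window = 1000,
                             minWidth = 50) {
    if (is.character(genome))
        genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
    chrom <- as.character(seqnames(geneRanges(models)))
    strnd <- geneStrand(models)
    t0 <- tss(models)
    missing <- setdiff(unique(chrom), names(genome))
    if (length(missing))
        stop("contig(s) absent from genome: ",
             paste(missing, collapse = ", "))
    clen <- Biostrings::width(genome)[match(chrom, names(genome))]
    if (any(t0 < 1 | t0 > clen))
        stop("TSS outside contig bounds for gene(s): ",
             paste(names(models)[t0 < 1 | t0 > clen], collapse = ", "))
    plus <- strnd == "+"
    from <- ifelse(plus, pmax(1, t0 - window), t0 + 1)
    to <- ifelse(plus, t0 - 1, pmin(clen, t0 + window))
    w <- to - from + 1
    keep <- w >= minWidth
    if (any(!keep))
        warning(sum(!keep), " promoter(s) shorter than ", minWidth,
                " bp after clipping, dropped: ",
                paste(utils::head(names(models)[!keep], 5),
                      collapse = ", "))
    idx <- which(keep)
    seqs <- Biostrings::subseq(genome[chrom[idx]],
                               start = from[idx], end = to[idx])
    minus <- !plus[idx]
    seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
    names(seqs) <- names(models)[idx]
    seqs
}

.checkMotif <- function(motif) {
    motif <- toupper(motif)
    codes <- names(Biostrings::IUPAC_CODE_MAP)
    chars <- strsplit(motif, "")[[1L]]
    if (!all(chars %in% codes))
        stop("invalid IUPAC code(s) in motif: ",
             paste(setdiff(chars, codes), collapse = ", "))
    if (nchar(motif) < 4L)
        stop("motif must be at least 4 bases long")
    motif
}

#' Scan sequences for an IUPAC motif
#'
#' Reports every match position of a degenerate IUPAC pattern (e.g.
#' TAGteam `CAGGTAG`, or `CAGGTAB` with B = C/G/T) in a promoter set.
#' Overlapping matches are all reported.  With `bothStrands`, matches
#' of the reverse complement are reported too, in forward coordinates.
#' Ambiguity codes are interpreted in the pattern only, so `N` in a
#' sequence never matches.
#'
#' @param seqs a [Biostrings::DNAStringSet] (or character vector) over
#'   A/C/G/T/N.
#' @param motif IUPAC pattern string, length >= 4.
#' @param bothStrands scan the reverse strand as well.
#' @return data.frame with `seqname`, `start` (1-based, forward
#'   coordinates) and `strand` per hit.
#' @examples
#' scanMotif(c(p1 = "AACAGGTAGTT"), "CAGGTAG")
#' @export
scanMotif <- function(seqs, motif, bothStrands = TRUE) {
    motif <- .checkMotif(motif)
    if (is.character(seqs))
        seqs <- Biostrings::DNAStringSet(seqs)
    if (is.null(names(seqs)))
        names(seqs) <- paste0("seq", seq_along(seqs))
    hits <- .strandHits(seqs, motif, "+")
    if (bothStrands) {
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(motif)))
        hits <- rbind(hits, .strandHits(seqs, rc, "-"))
    }
    hits <- hits[order(match(hits$seqname, names(seqs)), hits$start), ,
                 drop = FALSE]
    rownames(hits) <- NULL
    hits
}

.strandHits <- function(seqs, pattern, strand) {
    ml <- Biostrings::vmatchPattern(pattern, seqs, fixed = "subject")
    starts <- IRanges::start(ml)
    n <- lengths(starts)
    data.frame(seqname = rep(names(seqs), n),
               start = unlist(starts, use.names = FALSE),
               strand = if (sum(n)) strand else character(0),
               stringsAsFactors = FALSE)
}

#' Motif enrichment between two promoter sets
#'
#' Dichotomises each promoter by the presence of at least one motif
#' match and tests whether set A is enriched relative to set B with a
#' one-sided Fisher exact test (hypergeometric tail).  The odds ratio
#' uses the sample cross-product, with a Haldane correction (+0.5 to
#' every cell) when any cell is zero.
#'
#' @param setA,setB [Biostrings::DNAStringSet] promoter sets (e.g.
#'   zygotic-early vs maternally degraded genes).
#' @param motif IUPAC pattern string.
#' @param bothStrands scan both strands.
#' @return list with `table` (2 x 2 counts: rows set A/B, columns
#'   with/without motif), `oddsRatio`, and `p` (one-sided, enrichment
#'   in A).
#' @export
setEnrichment <- function(setA, setB, motif, bothStrands = TRUE) {
    if (length(setA) == 0L || length(setB) == 0L)
        stop("both promoter sets must be non-empty")
    hitA <- .hasHit(setA, motif, bothStrands)
    hitB <- .hasHit(setB, motif, bothStrands)
    tab <- matrix(c(sum(hitA), sum(!hitA), sum(hitB), sum(!hitB)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("setA", "setB"),
                                  c("withMotif", "withoutMotif")))
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    or <- if (any(tab == 0))
        (tab[1, 1] + 0.5) * (tab[2, 2] + 0.5) /
            ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
    else tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1])
    list(table = tab, oddsRatio = or, p = p)
}

.hasHit <- function(seqs, motif, bothStrands) {
    motif <- .checkMotif(motif)
    if (is.character(seqs))
        seqs <- Biostrings::DNAStringSet(seqs)
    n <- Biostrings::vcountPattern(motif, seqs, fixed = "subject")
    if (bothStrands) {
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(motif)))
        n <- n + Biostrings::vcountPattern(rc, seqs, fixed = "subject")
    }
    n > 0
}

#' Positional enrichment of motif hits near the TSS
#'
#' Pools hit positions across a promoter set and asks whether they
#' concentrate in the `proximalWindow` bases nearest the TSS.  Under
#' the uniform null a hit is proximal with probability
#' `proximalWindow / promoterLength`; the p-value is the one-sided
#' binomial tail for an excess of proximal hits (1 when there are no
#' hits).
#'
#' @param hits data.frame from [scanMotif()], or a numeric vector of
#'   hit start positions.
#' @param proximalWindow width (bp) of the TSS-proximal zone.
#' @param promoterLength full promoter width; position `promoterLength`
#'   abuts the TSS, so a hit is proximal when
#'   `start > promoterLength - proximalWindow`.
#' @return list with `observed` (proximal hits), `total` (all hits),
#'   `expected` (under the uniform null) and `p`.
#' @export
positionalEnrichment <- function(hits, proximalWindow = 300,
                                 promoterLength = 1000) {
    if (proximalWindow > promoterLength)
        stop("proximal window exceeds promoter length")
    pos <- if (is.data.frame(hits)) hits$start else as.numeric(hits)
    n <- length(pos)
    p0 <- proximalWindow / promoterLength
    obs <- sum(pos > promoterLength - proximalWindow)
    p <- if (n == 0L) 1
    else stats::pbinom(obs - 1L, n, p0, lower.tail = FALSE)
    list(observed = obs, total = n, expected = n * p0, p = p)
}
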