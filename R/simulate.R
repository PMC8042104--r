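#' Configuration of a synthetic embryo time-course experiment
#'
#' Bundles the parameters of the generative model used by
#' [simulateExperiment()].  Defaults emulate an hourly 1-6 h after egg
#' laying (AEL) embryo time course: a maternal transcript pool with a
#' global poly(A) dip at 2 h and rebound at 3 h, zygotic genes first
#' detectable from 4 h with shorter transcripts and fewer exons, 92
#' spike-in species spanning five orders of magnitude, and promoters with
#' CAGGTAG sites planted close to the TSS of zygotic genes.
#'
#' @param nGenes number of genes.
#' @param proportions named fractions of maternal / persistent /
#'   transient / zygotic genes (must sum to 1).
#' @param timepoints sampling times, hours AEL, strictly increasing.
#' @param globalScale per-sample global scaling of the non-zygotic pool;
#'   the default is the per-embryo mRNA-mass profile
#'   (1.26, 0.61, 1.49, 1.32, 1.20, 0.93 ng) rescaled to 1 at the first
#'   timepoint — a stylised dip/rebound shape, not a fitted curve.
#' @param nSpikes number of spike-in species.
#' @param spikeRange range (molecules per embryo) of the log-uniform
#'   spike-in concentrations.
#' @param depth expected aligned reads per sample.
#' @param onsetTimes candidate activation times (h AEL) for zygotic
#'   genes.
#' @param intronProb per-group probability that a read is intronic
#'   (nascent-transcript signal); applies only to multi-exon genes.
#' @param plantRate fraction of zygotic promoters receiving one planted
#'   CAGGTAG site within the proximal window.
#' @param promoterLength promoter width in bp.
#' @param proximalWindow bp nearest the TSS in which sites are planted.
#' @param gc background GC content of simulated promoters.
#' @param lengthMeanlog,lengthSdlog log-normal parameters of transcript
#'   length; zygotic lengths are multiplied by `zygoticLengthFactor`.
#' @param zygoticLengthFactor length multiplier for zygotic transcripts.
#' @param seed integer seed governing all randomness.
#' @return A `SimulationConfig` (a validated list).
#' @export
simulationConfig <- function(nGenes = 2000,
                             proportions = c(maternal = 0.50,
                                             persistent = 0.25,
                                             transient = 0.15,
                                             zygotic = 0.10),
                             timepoints = 1:6,
                             globalScale = c(1.00, 0.49, 1.18,
                                             1.05, 0.95, 0.74),
                             nSpikes = 92,
                             spikeRange = c(1e2, 1e7),
                             depth = 2e6,
                             onsetTimes = c(4, 5, 6),
                             intronProb = c(maternal = 0.02,
                                            persistent = 0.02,
                                            transient = 0.02,
                                            zygotic = 0.15),
                             plantRate = 0.5,
                             promoterLength = 1000,
                             proximalWindow = 300,
                             gc = 0.40,
                             lengthMeanlog = log(2000),
                             lengthSdlog = 0.5,
                             zygoticLengthFactor = 0.6,
                             seed = 1L) {
    if (abs(sum(proportions) - 1) > 1e-8)
        stop("group proportions must sum to 1")
    if (any(proportions < 0))
        stop("group proportions must be nonnegative")
    if (length(globalScale) != length(timepoints))
        stop("globalScale must match timepoints in length")
    if (any(globalScale <= 0) || any(depth <= 0) || any(spikeRange <= 0))
        stop("scales, depths and spike concentrations must be positive")
    if (plantRate < 0 || plantRate > 1)
        stop("plantRate must lie in [0, 1]")
    if (any(diff(timepoints) <= 0))
        stop("timepoints must be strictly increasing")
    cfg <- list(nGenes = nGenes, proportions = proportions,
                timepoints = timepoints, globalScale = globalScale,
                nSpikes = nSpikes, spikeRange = spikeRange,
                depth = rep_len(depth, length(timepoints)),
                onsetTimes = onsetTimes, intronProb = intronProb,
                plantRate = plantRate, promoterLength = promoterLength,
                proximalWindow = proximalWindow, gc = gc,
                lengthMeanlog = lengthMeanlog, lengthSdlog = lengthSdlog,
                zygoticLengthFactor = zygoticLengthFactor,
                seed = as.integer(seed))
    class(cfg) <- "SimulationConfig"
    cfg
}

#' @export
print.SimulationConfig <- function(x, ...) {
    cat("SimulationConfig:", x$nGenes, "genes,", x$nSpikes, "spikes,",
        length(x$timepoints), "timepoints, seed", x$seed, "\n")
    invisible(x)
}

#' Simulate a spike-in calibrated embryo time-course experiment
#'
#' Draws a full synthetic experiment with known ground truth.  The
#' generative model: per-gene baseline abundance `b_i ~ logN(7, 1.5)`
#' (transcripts per embryo); maternal trajectories
#' `b_i * g_j * decay^t` with per-gene decay in `[0.6, 0.95]`;
#' persistent `b_i * g_j`; transient `b_i * g_j * (1 + A exp(-(t -
#' t_peak)^2 / 2 sigma^2))` with `A ~ U[4, 20]`, `sigma = 0.5`; zygotic
#' genes are exactly zero before a per-gene onset in `onsetTimes`, then
#' ramp as `b_i * (t - onset + 1)`.  Spike-in molecule numbers are
#' log-uniform over `spikeRange` and identical across samples (per-embryo
#' spiking).  Read counts are `Poisson(depth_j * m_ij / sum_k m_kj)`
#' where the normalising sum runs over genes and spikes; no length bias
#' is applied (full-length reads are treated as molecule counts).
#' Intronic reads are `Binomial(c_ij, pi_group)` for multi-exon genes.
#' Gene models draw spliced lengths log-normally (zygotic shortened) and
#' exon counts `1 + Poisson(5)` (non-zygotic) vs `1 + Poisson(1)`
#' (zygotic).  Promoters are i.i.d. nucleotides at the configured GC,
#' with one CAGGTAG planted uniformly within the proximal window for a
#' `plantRate` fraction of zygotic genes.
#'
#' All randomness flows from `config$seed`; promoter sequences are drawn
#' last, so `withPromoters = FALSE` leaves every other output unchanged.
#'
#' @param config a [simulationConfig()].
#' @param withPromoters generate promoter sequences (set `FALSE` to skip
#'   the most expensive step when only counts are needed).
#' @return A list with elements `experiment` (an
#'   [EmbryoExperiment-class] with `counts` and `intronic` assays),
#'   `spikes` (spike-in table), `models` ([GeneModels-class]),
#'   `promoters` ([Biostrings::DNAStringSet] or `NULL`), and `truth`
#'   (list: per-gene data.frame `genes` with group / onset / planted
#'   flags, matrix `trajectory` of true transcripts per embryo, numeric
#'   `trueScale` = true molecules per RPG10K unit per sample, and the
#'   `config`).
#' @seealso [writeFixture()], [simulatePromoters()]
#' @export
simulateExperiment <- function(config = simulationConfig(),
                               withPromoters = TRUE) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed)
    tp <- config$timepoints
    nT <- length(tp)
    nG <- config$nGenes

    nPer <- .apportion(config$proportions, nG)
    group <- rep(names(nPer), nPer)
    geneId <- sprintf("gene%05d", seq_len(nG))

    b <- stats::rlnorm(nG, meanlog = 7, sdlog = 1.5)
    traj <- matrix(0, nG, nT, dimnames = list(geneId, NULL))
    g <- config$globalScale

    isMat <- group == "maternal"
    decay <- stats::runif(sum(isMat), 0.6, 0.95)
    traj[isMat, ] <- outer(b[isMat], rep(1, nT)) *
        outer(decay, tp, `^`) * rep(g, each = sum(isMat))

    isPer <- group == "persistent"
    traj[isPer, ] <- outer(b[isPer], g)

    isTra <- group == "transient"
    nTra <- sum(isTra)
    A <- stats::runif(nTra, 4, 20)
    tPeak <- sample(tp, nTra, replace = TRUE)
    bump <- 1 + A * exp(-(outer(rep(1, nTra), tp) - tPeak)^2 / (2 * 0.5^2))
    traj[isTra, ] <- outer(b[isTra], g) * bump

    isZyg <- group == "zygotic"
    nZyg <- sum(isZyg)
    onset <- rep(NA_real_, nG)
    onset[isZyg] <- sample(config$onsetTimes, nZyg, replace = TRUE)
    ramp <- outer(rep(1, nZyg), tp) - onset[isZyg] + 1
    ramp[ramp < 0 | outer(rep(1, nZyg), tp) < onset[isZyg]] <- 0
    traj[isZyg, ] <- b[isZyg] * ramp

    # spike-ins: identical molecule numbers across samples
    spikeId <- sprintf("ERCC-%05d", seq_len(config$nSpikes))
    S <- 10^stats::runif(config$nSpikes, log10(config$spikeRange[1L]),
                         log10(config$spikeRange[2L]))
    spikes <- data.frame(spikeId = spikeId, molecules = S,
                         stringsAsFactors = FALSE)
    rownames(spikes) <- spikeId

    # Poisson read sampling against the total molecule pool
    totals <- colSums(traj) + sum(S)
    pool <- rbind(traj, matrix(S, config$nSpikes, nT,
                               dimnames = list(spikeId, NULL)))
    lambda <- sweep(pool, 2, config$depth / totals, `*`)
    counts <- matrix(stats::rpois(length(lambda), lambda),
                     nrow(lambda), nT, dimnames = dimnames(lambda))
    colnames(counts) <- sprintf("t%g", tp)

    # gene architecture
    len <- stats::rlnorm(nG, config$lengthMeanlog, config$lengthSdlog)
    len[isZyg] <- len[isZyg] * config$zygoticLengthFactor
    len <- pmax(100L, as.integer(round(len)))
    nEx <- 1L + stats::rpois(nG, ifelse(isZyg, 1, 5))

    # intronic reads: only multi-exon genes can produce them
    piGene <- unname(config$intronProb[group])
    piGene[nEx == 1L] <- 0
    intronic <- matrix(0L, nG + config$nSpikes, nT,
                       dimnames = dimnames(counts))
    gc_counts <- counts[seq_len(nG), , drop = FALSE]
    intronic[seq_len(nG), ] <- stats::rbinom(length(gc_counts), gc_counts,
                                             rep(piGene, nT))

    models <- .simulateGeneModels(geneId, len, nEx, config$promoterLength)

    ee <- EmbryoExperiment(counts, timepoint = tp, embryosPooled = 1L,
                           spikeIds = spikeId, intronic = intronic)

    planted <- logical(nG)
    promoters <- NULL
    if (withPromoters) {
        plantZyg <- isZyg & stats::runif(nG) < config$plantRate
        pr <- simulatePromoters(nG, width = config$promoterLength,
                                gc = config$gc,
                                plant = plantZyg,
                                proximalWindow = config$proximalWindow)
        promoters <- pr$sequences
        names(promoters) <- geneId
        planted <- pr$planted
    }

    truthGenes <- data.frame(geneId = geneId, group = group,
                             baseline = b, onset = onset,
                             txLength = len, exonCount = nEx,
                             motifPlanted = planted,
                             stringsAsFactors = FALSE)
    truth <- list(genes = truthGenes, trajectory = traj,
                  trueScale = stats::setNames(totals / 1e4,
                                              colnames(counts)),
                  config = config)
    list(experiment = ee, spikes = spikes, models = models,
         promoters = promoters, truth = truth)
}

# largest-remainder apportionment of nGenes across groups
.apportion <- function(p, n) {
    raw <- p * n
    base <- floor(raw)
    rem <- n - sum(base)
    if (rem > 0) {
        extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
    }
    stats::setNames(as.integer(base), names(p))
}

# lay genes along one synthetic contig, splitting each spliced length
# into roughly equal exons separated by introns of 100-500 bp
.simulateGeneModels <- function(geneId, len, nEx, promoterLength) {
    nG <- length(geneId)
    strand <- rep(c("+", "-"), length.out = nG)
    gap <- promoterLength + 1500L
    spanStart <- numeric(nG)
    spanEnd <- numeric(nG)
    intStart <- vector("list", nG)
    intEnd <- vector("list", nG)
    cursor <- gap
    for (i in seq_len(nG)) {
        k <- nEx[i]
        exLen <- rep(len[i] %/% k, k)
        exLen[seq_len(len[i] %% k)] <- exLen[seq_len(len[i] %% k)] + 1L
        intLen <- if (k > 1L)
            rep(100L + ((i * 97L) %% 401L), k - 1L) else integer(0)
        starts <- cursor + c(0L, cumsum(exLen[-k] + intLen))
        ends <- starts + exLen - 1L
        spanStart[i] <- cursor
        spanEnd[i] <- ends[k]
        if (k > 1L) {
            intStart[[i]] <- ends[-k] + 1L
            intEnd[[i]] <- starts[-1L] - 1L
        }
        cursor <- ends[k] + gap
    }
    genes <- GRanges("chrS", IRanges(spanStart, spanEnd), strand = strand)
    names(genes) <- geneId
    mcols(genes)$tss <- ifelse(strand == "+", spanStart, spanEnd)
    mcols(genes)$txLength <- len
    mcols(genes)$exonCount <- nEx
    intGene <- factor(rep(geneId, lengths(intStart)), levels = geneId)
    intFlat <- GRanges("chrS",
                       IRanges(unlist(intStart), unlist(intEnd)),
                       strand = rep(strand, lengths(intStart)))
    introns <- S4Vectors::split(intFlat, intGene)
    new("GeneModels", genes = genes, introns = introns)
}

#' Simulate promoter sequences with optional planted motif sites
#'
#' Draws i.i.d. nucleotide sequences at a given GC content and plants a
#' single CAGGTAG site (forward strand, uniform start position within
#' the proximal window nearest the TSS) into the selected sequences.
#' Position `width` of each sequence is the base immediately upstream of
#' the TSS.
#'
#' @param n number of promoters.
#' @param width promoter length (bp).
#' @param gc GC content of the background.
#' @param plant logical vector (length `n`) or a fraction in `[0,1]` of
#'   promoters to receive a planted site.
#' @param proximalWindow bp nearest the TSS eligible for planting.
#' @param motif the literal site to plant.
#' @return list with `sequences` (a [Biostrings::DNAStringSet]) and
#'   `planted` (logical vector).
#' @export
simulatePromoters <- function(n, width = 1000, gc = 0.40, plant = 0,
                              proximalWindow = 300, motif = "CAGGTAG") {
    if (is.numeric(plant) && length(plant) == 1L)
        plant <- stats::runif(n) < plant
    stopifnot(length(plant) == n, proximalWindow <= width,
              nchar(motif) <= proximalWindow)
    bases <- c("A", "C", "G", "T")
    prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    draw <- sample(bases, n * width, replace = TRUE, prob = prob)
    seqs <- matrix(draw, nrow = n)
    mlen <- nchar(motif)
    mchars <- strsplit(motif, "")[[1L]]
    idx <- which(plant)
    if (length(idx)) {
        startMin <- width - proximalWindow + 1L
        startMax <- width - mlen + 1L
        starts <- startMin +
            floor(stats::runif(length(idx)) * (startMax - startMin + 1L))
        for (k in seq_along(idx))
            seqs[idx[k], starts[k]:(starts[k] + mlen - 1L)] <- mchars
    }
    strings <- apply(seqs, 1L, paste, collapse = "")
    list(sequences = Biostrings::DNAStringSet(strings), planted = plant)
}

#' Write a simulated experiment to a fixture directory
#'
#' Writes the outputs of [simulateExperiment()] as plain-text files that
#' round-trip through the package readers: `counts.tsv`, `intronic.tsv`,
#' `spikes.tsv`, `models.gff3`, `promoters.fa` (when present),
#' `truth.tsv` and `config.json`.
#'
#' @param sim result of [simulateExperiment()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeFixture <- function(sim, dir) {
    if (!dir.exists(dir) &&
        !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create directory ", dir)
    hdr <- sprintf("embryoQuant simulateExperiment seed=%d",
                   sim$truth$config$seed)
    writeCountMatrix(sim$experiment, file.path(dir, "counts.tsv"),
                     comments = hdr)
    writeCountMatrix(sim$experiment, file.path(dir, "intronic.tsv"),
                     assayName = "intronic", comments = hdr)
    writeSpikeInTable(sim$spikes, file.path(dir, "spikes.tsv"),
                      comments = hdr)
    writeGeneModels(sim$models, file.path(dir, "models.gff3"))
    if (!is.null(sim$promoters))
        Biostrings::writeXStringSet(sim$promoters,
                                    file.path(dir, "promoters.fa"))
    utils::write.table(sim$truth$genes, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cfg <- sim$truth$config
    class(cfg) <- NULL
    jsonlite::write_json(cfg, file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}

#' Write gene models as GFF3
#'
#' Exports the representative transcript of each gene as
#' gene/mRNA/exon features (1-based inclusive), the inverse of
#' [readGeneModels()].
#'
#' @param models a [GeneModels-class].
#' @param path output GFF3 path.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(models, path) {
    genes <- geneRanges(models)
    gid <- names(genes)
    introns <- intronRanges(models)[gid]
    spans <- GenomicRanges::granges(genes, use.mcols = FALSE)
    names(spans) <- NULL
    ex <- GenomicRanges::psetdiff(BiocGenerics::unstrand(spans),
                                  BiocGenerics::unstrand(introns))
    nEx <- lengths(ex)
    exFlat <- unlist(ex, use.names = FALSE)
    strand(exFlat) <- rep(as.character(strand(spans)), nEx)
    exIdx <- sequence(nEx)
    exGene <- rep(seq_along(gid), nEx)

    rows <- c(spans, spans, exFlat)
    type <- c(rep("gene", length(gid)), rep("mRNA", length(gid)),
              rep("exon", sum(nEx)))
    id <- c(gid, paste0(gid, ".t1"),
            paste0(gid[exGene], ".t1.e", exIdx))
    parent <- c(rep(NA_character_, length(gid)), gid,
                paste0(gid[exGene], ".t1"))
    # order rows gene-by-gene, parents before children
    key <- c(seq_along(gid), seq_along(gid), exGene)
    rank <- c(rep(1L, length(gid)), rep(2L, length(gid)),
              rep(3L, sum(nEx)))
    ord <- order(key, rank)
    rows <- rows[ord]
    mcols(rows)$type <- type[ord]
    mcols(rows)$ID <- id[ord]
    plist <- as.list(parent[ord])
    plist[is.na(parent[ord])] <- list(character(0))
    mcols(rows)$Parent <- IRanges::CharacterList(plist)
    rtracklayer::export(rows, path, format = "gff3")
    invisible(path)
}
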