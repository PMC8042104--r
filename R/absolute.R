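#' Conversion factor for a single sample
#'
#' The closed-form maximum-likelihood intercept of the intercept-only
#' Poisson log-link model with offset `log(S)`:
#' `beta = log(sum(r) / sum(S))` (the score equation
#' `sum(r) - e^beta * sum(S) = 0` has this unique root).  Spike-ins
#' with zero observed reads stay in both sums — they carry calibration
#' information.
#'
#' @param r relative abundances (RPG10K) of the spike-ins in one
#'   sample.
#' @param S known molecules per embryo equivalent, matched to `r`.
#' @return the log-link intercept `beta` (numeric scalar).
#' @examples
#' conversionFactor(c(0.01, 0.1, 1.0), c(100, 1000, 10000))  # log(1e-4)
#' @export
conversionFactor <- function(r, S) {
    if (length(r) != length(S))
        stop("r and S must have equal length")
    if (any(S <= 0))
        stop("spike-in molecule counts must be positive")
    if (any(r < 0))
        stop("relative abundances must be nonnegative")
    if (sum(r) == 0)
        stop("no spike-in signal")
    log(sum(r) / sum(S))
}

#' Fit per-sample conversion factors from spike-ins
#'
#' For each sample, fits the intercept-only Poisson log-linear model of
#' spike-in relative abundance against known molecule numbers,
#' `r_qj ~ offset(log(S_q))` with a log link.  The intercept `beta_j` is
#' the conversion factor: one RPG10K unit corresponds to
#' `exp(-beta_j)` transcripts per embryo.  The maximum-likelihood
#' intercept has the closed form
#' `beta_j = log(sum_q r_qj / sum_q S_q)` (setting the score
#' `sum_q r_qj - e^beta sum_q S_q` to zero), which this function uses
#' directly — no iterative fitting, hence no optimiser tolerance in the
#' pipeline.  Spike-ins with zero reads stay in both sums.
#'
#' @param x an [EmbryoExperiment-class]; the `"rpg10k"` assay is
#'   computed on the fly if absent.
#' @param spikes spike-in table as from [readSpikeInTable()] mapping
#'   spike IDs to known molecules per embryo equivalent.  Every spike-in
#'   feature present in `x` must appear here.
#' @return A [ConversionFactors-class] object.
#' @examples
#' sim <- simulateExperiment(simulationConfig(nGenes = 100, nSpikes = 20),
#'                           withPromoters = FALSE)
#' cf <- fitConversionFactors(sim$experiment, sim$spikes)
#' convScale(cf)  # transcripts per embryo per RPG10K unit
#' @export
fitConversionFactors <- function(x, spikes) {
    stopifnot(is(x, "EmbryoExperiment"))
    .validateSpikeTable(spikes)
    if (!("rpg10k" %in% assayNames(x)))
        x <- computeRPG10K(x)
    sid <- spikeIds(x)
    if (length(sid) == 0L)
        stop("experiment contains no spike-in features")
    missing <- setdiff(sid, spikes$spikeId)
    if (length(missing))
        stop("spike-in(s) absent from concentration table: ",
             paste(missing, collapse = ", "))
    S <- spikes$molecules[match(sid, spikes$spikeId)]
    r <- assay(x, "rpg10k")[sid, , drop = FALSE]
    rSums <- colSums(r)
    if (any(rSums == 0))
        stop("no spike-in signal in sample(s): ",
             paste(colnames(x)[rSums == 0], collapse = ", "))
    beta <- vapply(seq_len(ncol(r)),
                   function(j) conversionFactor(r[, j], S), numeric(1))
    names(beta) <- colnames(r)
    new("ConversionFactors", beta = beta,
        nSpikes = rep(length(sid), length(beta)))
}

#' Convert relative to absolute abundance
#'
#' Applies the spike-in calibration `m_ij = rho_ij * exp(-beta_j)` to
#' every feature, yielding transcripts per embryo.  Spike-in rows are
#' converted too (their recovered molecule numbers against the known
#' inputs are the standard calibration QC); downstream gene analyses
#' exclude them via [geneIds()] / [detectedMatrix()].
#'
#' @param x an [EmbryoExperiment-class]; the `"rpg10k"` assay is
#'   computed on the fly if absent.
#' @param cf a [ConversionFactors-class] with a factor for every sample
#'   of `x`.
#' @return `x` with an added `"absolute"` assay (transcripts per
#'   embryo); `cf` is recorded in `metadata(x)$conversionFactors`.
#' @export
toAbsolute <- function(x, cf) {
    stopifnot(is(x, "EmbryoExperiment"), is(cf, "ConversionFactors"))
    if (!("rpg10k" %in% assayNames(x)))
        x <- computeRPG10K(x)
    beta <- convBeta(cf)
    missing <- setdiff(colnames(x), names(beta))
    if (length(missing))
        stop("no conversion factor for sample(s): ",
             paste(missing, collapse = ", "))
    scale <- exp(-beta)[colnames(x)]
    assay(x, "absolute") <- sweep(assay(x, "rpg10k"), 2, scale, `*`)
    metadata(x)$conversionFactors <- cf
    x
}

#' Recover relative abundance from absolute abundance
#'
#' Exact inverse of [toAbsolute()]: returns the RPG10K matrix whose
#' image under the stored per-sample scaling reproduces the
#' `"absolute"` assay bit for bit.  Naive division `m / exp(-beta)`
#' lands one unit in the last place away from the original value for a
#' few percent of entries (floating-point multiplication is not exactly
#' invertible, and adjacent representable values can even collide onto
#' one product), so each quotient is resolved against the preimage set
#' of the forward map: candidates within a few ulp of the quotient —
#' plus the count-derived relative value when the experiment carries
#' counts, which settles collisions — are forward-multiplied and the
#' first that reproduces the stored product is returned.
#'
#' @param x an [EmbryoExperiment-class] processed by [toAbsolute()].
#' @return numeric matrix of RPG10K values, features x samples.
#' @export
absoluteToRelative <- function(x) {
    if (!("absolute" %in% assayNames(x)))
        stop("run toAbsolute() first")
    cf <- metadata(x)$conversionFactors
    scale <- exp(-convBeta(cf))[colnames(x)]
    m <- assay(x, "absolute")
    rhoCounts <- if ("counts" %in% assayNames(x)) {
        N <- totalAlignedReads(x)
        sweep(assay(x, "counts") * 1e4, 2, N, `/`)
    } else NULL
    out <- m
    for (j in seq_len(ncol(m))) {
        s <- scale[j]
        q <- m[, j] / s
        # true preimages lie within a few ulp of the quotient
        d <- abs(q) * .Machine$double.eps / 2
        cand <- q + outer(d, c(0, 1, -1, 2, -2, 3, -3, 4, -4))
        if (!is.null(rhoCounts))
            cand <- cbind(rhoCounts[, j], cand)
        hit <- cand * s == m[, j]
        pick <- max.col(hit, ties.method = "first")
        fallback <- !hit[cbind(seq_along(q), pick)]
        pickCol <- if (is.null(rhoCounts)) 1L else 2L
        pick[fallback] <- pickCol
        out[, j] <- cand[cbind(seq_along(q), pick)]
    }
    out
}

#' Detection limit in transcripts per embryo
#'
#' Translates the RPG10K sensitivity floor into absolute units:
#' `limit_j = threshold * exp(-beta_j)`, plus the unweighted mean over
#' samples.
#'
#' @param cf a [ConversionFactors-class].
#' @param threshold detection floor in RPG10K units.
#' @return list with `perSample` (named numeric, transcripts per
#'   embryo) and `mean` (arithmetic mean over samples).
#' @export
detectionLimit <- function(cf, threshold = 0.01) {
    stopifnot(is(cf, "ConversionFactors"), threshold >= 0)
    lim <- threshold * convScale(cf)
    list(perSample = lim, mean = mean(lim))
}

#' Convert transcript numbers to mRNA mass
#'
#' Converts transcripts per embryo into nanograms per embryo using the
#' single-stranded RNA molecular-weight convention
#' `MW(L) = 320.5 * L + 159` g/mol for a transcript of length `L`
#' nucleotides: `mass_ij = m_ij * MW(L_i) / N_A * 1e9` ng.  Per-sample
#' totals sum over genes (spike-ins excluded).
#'
#' @param x an [EmbryoExperiment-class] processed by [toAbsolute()], or
#'   a numeric matrix of transcripts per embryo (genes x samples).
#' @param models a [GeneModels-class] supplying representative
#'   transcript lengths.
#' @param permissive drop genes missing from `models` with a warning
#'   instead of failing.
#' @param mwPerNt,mwEnd molecular-weight constants (g/mol per
#'   nucleotide, terminal correction).
#' @return list with `mass` (ng per embryo, genes x samples) and
#'   `total` (named numeric, ng per embryo per sample).
#' @export
transcriptsToMass <- function(x, models, permissive = FALSE,
                              mwPerNt = 320.5, mwEnd = 159) {
    m <- if (is(x, "EmbryoExperiment")) {
        if (!("absolute" %in% assayNames(x)))
            stop("run toAbsolute() first")
        assay(x, "absolute")[!isSpike(x), , drop = FALSE]
    } else as.matrix(x)
    L <- txLength(models)
    missing <- setdiff(rownames(m), names(L))
    if (length(missing)) {
        if (!permissive)
            stop("gene(s) missing from models: ",
                 paste(utils::head(missing, 10), collapse = ", "),
                 if (length(missing) > 10) ", ...")
        warning(length(missing), " gene(s) missing from models, dropped")
        m <- m[setdiff(rownames(m), missing), , drop = FALSE]
    }
    mw <- mwPerNt * L[rownames(m)] + mwEnd
    mass <- m * (mw / .AVOGADRO * 1e9)
    list(mass = mass, total = colSums(mass))
}

#' Volume-scaled mass comparison between species
#'
#' Scales a per-embryo mRNA mass by the ratio of embryo volumes so that
#' masses of differently sized embryos can be compared directly:
#' `scaled = mass * targetVolume / sourceVolume`.  Reported values are
#' rounded to 3 significant figures; raw values are returned alongside.
#'
#' @param massNg per-embryo mRNA mass (ng) measured in the source
#'   species.
#' @param sourceVolume,targetVolume embryo volumes (mm^3) of the source
#'   and comparison species.
#' @return list with `scaledMass`, `volumeRatio` (raw) and `reported`
#'   (both rounded to 3 significant figures).
#' @examples
#' volumeScaledMass(1.26, sourceVolume = 0.025, targetVolume = 0.268)
#' @export
volumeScaledMass <- function(massNg, sourceVolume, targetVolume) {
    if (sourceVolume <= 0 || targetVolume <= 0)
        stop("volumes must be positive")
    ratio <- targetVolume / sourceVolume
    scaled <- massNg * ratio
    list(scaledMass = scaled, volumeRatio = ratio,
         reported = c(scaledMass = signif(scaled, 3),
                      volumeRatio = signif(ratio, 3)))
}
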