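test_that("promoter extraction is strand-aware and clipped", {
    genome <- Biostrings::DNAStringSet(c(chr1 = "AAACCCGGGTTT"))
    plus <- makeModels(tss = 7, strand = "+", txLength = 3,
                       exonCount = 1L, geneId = "gp")
    expect_equal(as.character(extractPromoters(plus, genome,
                                               window = 3,
                                               minWidth = 1)[["gp"]]),
                 "CCC")
    minus <- makeModels(tss = 6, strand = "-", txLength = 3,
                        exonCount = 1L, geneId = "gm")
    expect_equal(as.character(extractPromoters(minus, genome,
                                               window = 3,
                                               minWidth = 1)[["gm"]]),
                 "CCC")
    # window clipped at the contig edge and dropped when too short
    edge <- makeModels(tss = 2, strand = "+", txLength = 3,
                       exonCount = 1L, geneId = "ge")
    expect_warning(out <- extractPromoters(edge, genome, window = 1000),
                   "dropped")
    expect_length(out, 0)

    far <- makeModels(tss = 99, strand = "+", txLength = 3,
                      exonCount = 1L, geneId = "gf")
    expect_error(extractPromoters(far, genome), "outside contig")
})

test_that("IUPAC scanning matches literal and degenerate patterns", {
    hits <- scanMotif(c(p = "AACAGGTAGTT"), "CAGGTAG")
    expect_equal(hits$start, 3)
    expect_equal(hits$strand, "+")

    # A is not in B = {C,G,T}
    expect_equal(nrow(scanMotif(c(p = "CAGGTAA"), "CAGGTAB",
                                bothStrands = FALSE)), 0)
    expect_equal(nrow(scanMotif(c(p = "CAGGTAC"), "CAGGTAB",
                                bothStrands = FALSE)), 1)

    # reverse-complement of CAGGTAG found on the minus strand
    rc <- scanMotif(c(p = "CTACCTG"), "CAGGTAG")
    expect_equal(rc$start, 1)
    expect_equal(rc$strand, "-")

    # N never matches; overlapping matches all reported
    expect_equal(nrow(scanMotif(c(p = "CANGTAG"), "CAGGTAG")), 0)
    expect_equal(scanMotif(c(p = "AAAAAA"), "AAAA",
                           bothStrands = FALSE)$start, 1:3)

    expect_error(scanMotif(c(p = "ACGT"), "CAGX"), "IUPAC")
    expect_error(scanMotif(c(p = "ACGTACGT"), "CAG"), "at least 4")
})

test_that("scanning agrees with a naive sliding-window oracle", {
    set.seed(23)
    alphabet <- c("A", "C", "G", "T", "N")
    for (motif in c("CAGGTAB", "CAYGTR")) {
        for (i in 1:150) {
            s <- paste(sample(alphabet, 40, replace = TRUE,
                              prob = c(.24, .24, .24, .24, .04)),
                       collapse = "")
            hits <- scanMotif(stats::setNames(s, "x"), motif)
            oracle <- naiveScan(s, motif)
            expect_identical(hits$start[hits$strand == "+"],
                             oracle$forward)
            expect_identical(hits$start[hits$strand == "-"],
                             oracle$reverse)
        }
    }
})

test_that("hit counts are strand-symmetric under both-strand scanning", {
    set.seed(29)
    pr <- simulatePromoters(50, width = 200, plant = 0.3,
                            proximalWindow = 100)$sequences
    fwd <- nrow(scanMotif(pr, "CAGGTAG"))
    rcSeqs <- Biostrings::reverseComplement(pr)
    rev <- nrow(scanMotif(rcSeqs, "CAGGTAG"))
    expect_equal(fwd, rev)
})

test_that("set enrichment reproduces the hypergeometric tail", {
    withM <- paste0(strrep("A", 20), "CAGGTAG", strrep("A", 20))
    without <- strrep("A", 47)
    setA <- Biostrings::DNAStringSet(c(rep(withM, 8), rep(without, 2)))
    setB <- Biostrings::DNAStringSet(c(rep(withM, 2), rep(without, 8)))
    en <- setEnrichment(setA, setB, "CAGGTAG")
    expect_equal(unname(en$table[1, ]), c(8, 2))
    # sum_{k>=8} C(10,k) C(10,10-k) / C(20,10)
    expect_equal(en$p, (2025 + 100 + 1) / 184756, tolerance = 1e-10)
    expect_equal(en$oddsRatio, 16)

    nullEn <- setEnrichment(setA, setA, "CAGGTAG")
    expect_equal(nullEn$oddsRatio, 1)
    expect_gte(nullEn$p, 0.5)

    extreme <- setEnrichment(
        Biostrings::DNAStringSet(rep(withM, 10)),
        Biostrings::DNAStringSet(rep(without, 10)), "CAGGTAG")
    expect_equal(extreme$p, 1 / choose(20, 10), tolerance = 1e-10)
    expect_equal(extreme$oddsRatio, 10.5^2 / 0.25)
    expect_error(setEnrichment(setA[0], setB, "CAGGTAG"), "non-empty")
})

test_that("positional enrichment uses the uniform binomial null", {
    out <- positionalEnrichment(c(rep(950, 9), 100),
                                proximalWindow = 300,
                                promoterLength = 1000)
    expect_equal(out$observed, 9)
    expect_equal(out$expected, 3)
    expect_equal(out$p, 10 * 0.3^9 * 0.7 + 0.3^10, tolerance = 1e-12)

    nullCase <- positionalEnrichment(c(rep(950, 3), rep(100, 7)))
    expect_gte(nullCase$p, 0.5)
    expect_equal(positionalEnrichment(numeric(0))$p, 1)
    expect_error(positionalEnrichment(1, proximalWindow = 2000),
                 "exceeds")
})

test_that("planted sites make zygotic promoters enriched end to end", {
    sim <- simulateExperiment(simulationConfig(seed = 42))
    tg <- sim$truth$genes
    en <- setEnrichment(sim$promoters[tg$geneId[tg$group == "zygotic"]],
                        sim$promoters[tg$geneId[tg$group == "maternal"]],
                        "CAGGTAB")
    expect_lt(en$p, 1e-10)
    hits <- scanMotif(sim$promoters[tg$geneId[tg$motifPlanted]],
                      "CAGGTAG", bothStrands = FALSE)
    pos <- positionalEnrichment(hits)
    expect_lt(pos$p, 1e-6)
})
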