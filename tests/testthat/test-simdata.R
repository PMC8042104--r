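smallConfig <- function(...) simulationConfig(nGenes = 200, seed = 11, ...)

test_that("simulation is deterministic under a fixed seed", {
    a <- simulateExperiment(smallConfig())
    b <- simulateExperiment(smallConfig())
    expect_identical(assay(a$experiment, "counts"),
                     assay(b$experiment, "counts"))
    expect_identical(as.character(a$promoters),
                     as.character(b$promoters))
    expect_identical(a$truth$genes, b$truth$genes)
})

test_that("dropping promoter generation leaves all other draws intact", {
    full <- simulateExperiment(smallConfig())
    lean <- simulateExperiment(smallConfig(), withPromoters = FALSE)
    expect_identical(assay(full$experiment, "counts"),
                     assay(lean$experiment, "counts"))
    expect_null(lean$promoters)
})

test_that("group sizes follow the configured proportions", {
    sim <- simulateExperiment(smallConfig(), withPromoters = FALSE)
    counts <- table(sim$truth$genes$group)
    expected <- c(maternal = 100, persistent = 50, transient = 30,
                  zygotic = 20)
    expect_equal(as.vector(counts[names(expected)]),
                 unname(expected))
    expect_error(simulationConfig(proportions = c(maternal = 0.9,
                                                  persistent = 0.9,
                                                  transient = 0,
                                                  zygotic = 0)),
                 "sum to 1")
})

test_that("zygotic trajectories are exactly zero before onset", {
    cfg <- simulationConfig(nGenes = 100, seed = 5,
                            proportions = c(maternal = 0, persistent = 0,
                                            transient = 0, zygotic = 1))
    sim <- simulateExperiment(cfg, withPromoters = FALSE)
    tp <- cfg$timepoints
    onset <- sim$truth$genes$onset
    for (i in seq_len(nrow(sim$truth$trajectory))) {
        pre <- tp < onset[i]
        expect_true(all(sim$truth$trajectory[i, pre] == 0))
        expect_true(all(sim$truth$trajectory[i, !pre] > 0))
    }
})

test_that("planted motif sites always land in the proximal window", {
    cfg <- simulationConfig(nGenes = 100, seed = 5, plantRate = 1)
    sim <- simulateExperiment(cfg)
    zyg <- sim$truth$genes$geneId[sim$truth$genes$group == "zygotic"]
    expect_true(all(sim$truth$genes$motifPlanted[
        sim$truth$genes$group == "zygotic"]))
    for (g in zyg) {
        hits <- scanMotif(sim$promoters[g], "CAGGTAG",
                          bothStrands = FALSE)
        expect_true(any(hits$start > 1000 - 300))
    }
})

test_that("sequencing totals concentrate around the configured depth", {
    sim <- simulateExperiment(simulationConfig(seed = 3),
                              withPromoters = FALSE)
    d <- sim$truth$config$depth
    N <- totalAlignedReads(sim$experiment)
    expect_true(all(abs(N - d) <= 5 * sqrt(d)))
})

test_that("spike-in read share matches its molecular share", {
    sim <- simulateExperiment(simulationConfig(seed = 3),
                              withPromoters = FALSE)
    cts <- assay(sim$experiment, "counts")
    spikeShare <- colSums(cts[isSpike(sim$experiment), ]) / colSums(cts)
    molShare <- sum(sim$spikes$molecules) /
        (colSums(sim$truth$trajectory) + sum(sim$spikes$molecules))
    expect_equal(unname(spikeShare), unname(molShare), tolerance = 0.01)
})

test_that("fixtures write completely and round-trip through the readers", {
    sim <- simulateExperiment(smallConfig())
    dir <- tempfile()
    writeFixture(sim, dir)
    expect_true(all(file.exists(file.path(dir,
        c("counts.tsv", "spikes.tsv", "models.gff3", "promoters.fa",
          "truth.tsv", "config.json")))))

    cts <- read.delim(file.path(dir, "counts.tsv"), comment.char = "#")
    expect_equal(nrow(cts), 200 + 92)

    ee <- readCountMatrix(file.path(dir, "counts.tsv"),
                          timepoint = sim$truth$config$timepoints,
                          intronicPath = file.path(dir, "intronic.tsv"))
    expect_identical(assay(ee, "counts"),
                     assay(sim$experiment, "counts"))
    expect_identical(assay(ee, "intronic"),
                     assay(sim$experiment, "intronic"))
    spikes <- readSpikeInTable(file.path(dir, "spikes.tsv"))
    expect_equal(spikes$molecules, sim$spikes$molecules)

    gm <- readGeneModels(file.path(dir, "models.gff3"))
    expect_identical(sort(names(gm)), sort(names(sim$models)))
    expect_equal(txLength(gm)[names(sim$models)],
                 txLength(sim$models))
    expect_equal(exonCount(gm)[names(sim$models)],
                 exonCount(sim$models))
    expect_equal(tss(gm)[names(sim$models)], tss(sim$models))

    truth <- read.delim(file.path(dir, "truth.tsv"))
    expect_equal(table(truth$group), table(sim$truth$genes$group))
})

test_that("intronic reads only arise from multi-exon genes", {
    sim <- simulateExperiment(smallConfig(), withPromoters = FALSE)
    intr <- assay(sim$experiment, "intronic")
    single <- sim$truth$genes$geneId[sim$truth$genes$exonCount == 1L]
    expect_true(all(intr[single, ] == 0))
    expect_true(all(intr <= assay(sim$experiment, "counts")))
})
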