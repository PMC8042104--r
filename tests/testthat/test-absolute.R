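test_that("closed-form conversion factor matches its analytic values", {
    # sum(r)/sum(S) = 1.11/11100 = 1e-4
    expect_equal(conversionFactor(c(0.01, 0.1, 1.0),
                                  c(100, 1000, 10000)),
                 log(1e-4))
    # r numerically equal to S: beta = 0, scale = 1
    S <- c(3, 14, 159)
    expect_equal(conversionFactor(S, S), 0)
    expect_error(conversionFactor(c(0, 0), c(1, 2)), "no spike-in")
    expect_error(conversionFactor(c(1, 1), c(1, -2)), "positive")
})

test_that("closed form equals an independent IRLS fit with offset", {
    set.seed(42)
    for (i in 1:20) {
        inst <- randomSpikeInstance(20)
        beta <- conversionFactor(inst$r, inst$S)
        expect_equal(beta, irlsIntercept(inst$r, inst$S),
                     tolerance = 1e-8)
        fit <- suppressWarnings(
            glm(inst$r ~ 1 + offset(log(inst$S)), family = poisson()))
        expect_equal(beta, unname(coef(fit)[1]), tolerance = 1e-8)
    }
})

test_that("rescaling spike abundances shifts beta by exactly log(c)", {
    set.seed(7)
    inst <- randomSpikeInstance(30)
    b0 <- conversionFactor(inst$r, inst$S)
    for (cc in c(0.1, 2, 1000))
        expect_equal(conversionFactor(cc * inst$r, inst$S),
                     b0 + log(cc), tolerance = 1e-12)
})

test_that("per-sample fitting validates the spike universe", {
    ee <- tinyExperiment(rbind(g1 = c(10, 10)), totals = c(1e4, 1e4),
                         spikeCounts = rbind(a = c(5, 5), b = c(2, 0)))
    spikes <- data.frame(spikeId = c("ERCC-00001", "ERCC-00002"),
                         molecules = c(1e4, 1e3))
    cf <- fitConversionFactors(ee, spikes)
    r <- assay(computeRPG10K(ee), "rpg10k")
    expect_equal(unname(convBeta(cf)),
                 unname(log(colSums(r[c("ERCC-00001", "ERCC-00002"), ]) /
                            1.1e4)))
    expect_equal(unname(nSpikesUsed(cf)), c(2L, 2L))

    expect_error(fitConversionFactors(ee, spikes[1, ]),
                 "absent.*ERCC-00002")
    dead <- tinyExperiment(rbind(g1 = c(10)), totals = 1e4,
                           spikeCounts = rbind(a = 0))
    expect_error(fitConversionFactors(dead,
                                      data.frame(spikeId = "ERCC-00001",
                                                 molecules = 10)),
                 "no spike-in signal")
})

test_that("absolute conversion is rho times exp(-beta)", {
    ee <- tinyExperiment(rbind(g1 = 50), totals = 1e6)  # rho = 0.5
    cf <- new("ConversionFactors", beta = c(s1 = -log(1e4)),
              nSpikes = 1L)
    ee <- toAbsolute(ee, cf)
    expect_equal(assay(ee, "absolute")["g1", "s1"], 5000)
    zero <- tinyExperiment(rbind(g1 = 0), totals = 1e6)
    expect_equal(assay(toAbsolute(zero, cf), "absolute")["g1", "s1"], 0)
    # missing factor
    two <- tinyExperiment(rbind(g1 = c(1, 1)), totals = c(10, 10))
    expect_error(toAbsolute(two, cf), "no conversion factor.*s2")
})

test_that("relative -> absolute -> relative is bit-for-bit exact", {
    sim <- simulateExperiment(simulationConfig(nGenes = 300, seed = 4),
                              withPromoters = FALSE)
    ee <- computeRPG10K(sim$experiment)
    cf <- fitConversionFactors(ee, sim$spikes)
    ee <- toAbsolute(ee, cf)
    expect_identical(absoluteToRelative(ee), assay(ee, "rpg10k"))
})

test_that("detection limits convert the floor and scale linearly", {
    cf <- new("ConversionFactors", beta = c(s1 = -log(111000)),
              nSpikes = 92L)
    lim <- detectionLimit(cf, 0.01)
    expect_equal(unname(lim$perSample), 1110)
    expect_equal(detectionLimit(cf, 0)$perSample, c(s1 = 0))
    l2 <- detectionLimit(cf, 0.05)
    expect_equal(unname(l2$perSample), 5 * unname(lim$perSample))

    multi <- new("ConversionFactors",
                 beta = c(a = -log(1e4), b = -log(3e4)),
                 nSpikes = c(92L, 92L))
    expect_equal(detectionLimit(multi, 0.01)$mean,
                 mean(c(100, 300)))
})

test_that("transcript mass uses the ssRNA molecular-weight convention", {
    models <- makeModels(tss = 1000, strand = "+", txLength = 1000,
                         exonCount = 1L, geneId = "g1")
    m <- matrix(1e9, 1, 1, dimnames = list("g1", "s1"))
    out <- transcriptsToMass(m, models)
    # MW = 320.5*1000 + 159 = 320659 g/mol
    expect_equal(out$mass["g1", "s1"],
                 1e9 * 320659 / 6.02214076e23 * 1e9)
    expect_equal(unname(out$total), 0.5325, tolerance = 1e-4)
    expect_equal(transcriptsToMass(m * 0, models)$total, c(s1 = 0))
    expect_equal(unname(transcriptsToMass(m * 2, models)$total),
                 2 * unname(out$total))
})

test_that("mass conversion flags genes absent from the models", {
    models <- makeModels(tss = 1000, strand = "+", txLength = 1000,
                         exonCount = 1L, geneId = "g1")
    m <- matrix(1, 2, 1, dimnames = list(c("g1", "gX"), "s1"))
    expect_error(transcriptsToMass(m, models), "gX")
    expect_warning(out <- transcriptsToMass(m, models, permissive = TRUE),
                   "dropped")
    expect_equal(rownames(out$mass), "g1")
})

test_that("volume scaling reports the printed ratio convention", {
    v <- volumeScaledMass(1.26, sourceVolume = 0.025,
                          targetVolume = 0.268)
    expect_equal(unname(v$reported["volumeRatio"]), 10.7)
    expect_equal(unname(v$reported["scaledMass"]), 13.5)
    expect_equal(v$volumeRatio, 10.72)
    same <- volumeScaledMass(2.5, 0.1, 0.1)
    expect_equal(same$scaledMass, 2.5)
    expect_error(volumeScaledMass(1, 0, 1), "positive")
})

test_that("calibrated totals reproduce the configured dip and rebound", {
    sim <- simulateExperiment(simulationConfig(seed = 8),
                              withPromoters = FALSE)
    ee <- toAbsolute(computeRPG10K(sim$experiment),
                     fitConversionFactors(sim$experiment, sim$spikes))
    mass <- transcriptsToMass(ee, sim$models)
    # global poly(A) dip at 2 h, rebound at 3 h
    expect_equal(which.min(mass$total), c(t2 = 2L))
    expect_gt(mass$total[["t3"]], mass$total[["t2"]])
    expect_gt(mass$total[["t1"]], mass$total[["t2"]])
})
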