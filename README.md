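# embryoQuant

Absolute quantification of embryo transcriptomes from spike-in
calibrated RNA-seq, with downstream analyses of the maternal-to-zygotic
transition (MZT).

## The problem

Relative RNA-seq normalisation breaks down in systems whose *global*
transcript content changes — exactly what happens in early embryos,
where bulk poly(A) RNA dips and rebounds within hours of egg laying.
Adding a known quantity of External RNA Control Consortium (ERCC)
spike-in RNAs per embryo before library preparation provides an internal
standard that converts relative abundance into **transcripts per
embryo**, making timepoints directly comparable.

embryoQuant implements that conversion and the analyses built on it, for
anyone profiling an embryonic (or otherwise globally shifting) time
course with spike-ins:

1. **Relative abundance** — RPG10K, reads per gene per 10,000 aligned
   reads: rho_ij = c_ij / N_j x 10^4 (N_j includes spike-in reads), plus
   detection calls at a configurable sensitivity floor (default 0.01
   RPG10K, ~2 mapped reads at 2M-read depth).
2. **Conversion factors** — per sample j, the intercept beta_j of the
   intercept-only Poisson log-link model
   `r_qj ~ offset(log(S_q))`
   over spike-ins q with known molecules S_q. The maximum-likelihood
   intercept is closed-form, beta_j = log(sum_q r_qj / sum_q S_q), so no
   iterative fitter sits in the pipeline (the IRLS route survives as an
   independent test oracle). Absolute abundance is
   m_ij = rho_ij e^(-beta_j), the per-sample detection limit is
   0.01 e^(-beta_j), and masses follow from MW(L) = 320.5 L + 159 g/mol.
3. **Temporal dynamics** — rule-based classification of genes into
   maternal-downregulated / persistent / transient / zygotic groups,
   deterministic correlation-based profile clustering, successive-sample
   Spearman QC, and reference-gene stability ranking.
4. **Zygotic-early genes** — genes undetected through 2 h after egg
   laying but detected later, corroborated by intron-read fractions
   (nascent transcription) and gene-architecture rank-sum tests (early
   zygotic genes are shorter, with fewer exons).
5. **TAGteam promoters** — strand-aware promoter extraction, IUPAC motif
   scanning (CAGGTAG / degenerate CAGGTAB), Fisher-exact set enrichment
   and binomial TSS-proximal positional enrichment.
6. **Synthetic experiments** — `simulateExperiment()` draws a full
   experiment (counts, spike table, gene models, promoters) with known
   ground truth emulating an hourly 1–6 h embryo series, so every stage
   is testable without any sequencing data.

## Worked example

```r
library(embryoQuant)

sim <- simulateExperiment(simulationConfig(seed = 1))
ee  <- detectionCall(computeRPG10K(sim$experiment))
cf  <- fitConversionFactors(ee, sim$spikes)
ee  <- toAbsolute(ee, cf)

round(convScale(cf))            # transcripts/embryo per RPG10K unit
#>    t1    t2    t3    t4    t5    t6
#> 10911 10500 11091 10933 10987 10722

detectionLimit(cf, threshold = 0.01)$mean
#> [1] 108.6                     # transcripts/embryo, mean over samples

signif(transcriptsToMass(ee, sim$models)$total, 3)
#>      t1      t2      t3      t4      t5      t6
#> 0.00892 0.00400 0.01040 0.00936 0.00957 0.00574   # ng/embryo

table(classifyTemporal(ee))
#> maternal_down    persistent     transient       zygotic  unclassified
#>           861           209           370           213           347

zyg <- identifyZygoticEarly(ee)
length(zyg)
#> [1] 255

lab <- classifyTemporal(ee)
en  <- setEnrichment(sim$promoters[zyg],
                     sim$promoters[names(lab)[lab == "maternal_down"]],
                     "CAGGTAB")
signif(c(p = en$p, OR = en$oddsRatio), 3)
#>        p       OR
#> 7.63e-12     2.71
```

Reading the numbers: one RPG10K unit corresponds to ~11,000 transcripts
per embryo in this simulation, so the 0.01-RPG10K sensitivity floor is a
detection limit of ~109 transcripts per embryo. The per-embryo mRNA
mass shows the hallmark MZT shape — a deep dip at 2 h and a rebound at
3 h. 255 genes are called zygotic-early (undetected through 2 h,
detected later), and their promoters are strongly enriched for the
TAGteam motif relative to maternally degraded genes, because the
generator plants CAGGTAG sites into half of the zygotic promoters.

Interspecies mass comparison with the printed embryo volumes:

```r
volumeScaledMass(1.26, sourceVolume = 0.025, targetVolume = 0.268)$reported
#>  scaledMass volumeRatio
#>        13.5        10.7
```

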