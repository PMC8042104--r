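---
title: "Methods: spike-in calibrated absolute quantification of embryo time courses"
author: "embryoQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-in calibrated absolute quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryoQuant)
```

## The quantification model

Early embryos violate the central assumption of relative RNA-seq
normalisation — that total transcript content is comparable across
samples. During the maternal-to-zygotic transition the global poly(A)
pool can halve within an hour and rebound the next. embryoQuant
therefore calibrates each sample against ERCC-style spike-ins added in
proportion to the number of embryos pooled, yielding transcripts per
embryo.

**Relative abundance.** For feature $i$ in sample $j$ with aligned-read
count $c_{ij}$ and per-sample total $N_j$ (spike-in reads included),

$$\rho_{ij} = \frac{c_{ij}}{N_j} \times 10^4 \quad \text{(RPG10K)}.$$

$N_j$ includes spike-in reads deliberately: a single per-sample factor
converts all RPG10K values, so genes and spike-ins must share the
denominator. Column sums of $\rho$ equal $10^4$ by construction (to
machine precision; counts are multiplied by $10^4$ before the division
so the numerators are exact integers in doubles).

**Conversion factors.** With known molecules per embryo equivalent
$S_q$ for spike-in $q$ and its observed relative abundance $r_{qj}$, we
fit the intercept-only Poisson log-link model
$r_{qj} \sim \text{offset}(\log S_q)$. Its score equation
$\sum_q r_{qj} - e^{\beta} \sum_q S_q = 0$ has the closed-form root

$$\beta_j = \log\!\left(\frac{\sum_q r_{qj}}{\sum_q S_q}\right),$$

used directly — no iterative optimiser, hence no convergence tolerance,
sits in the pipeline. An independently coded Fisher-scoring IRLS fit
(and `stats::glm`) serve as oracles in the test suite and agree with
the closed form to below $10^{-8}$. Spike-ins with zero observed reads
remain in both sums: a zero count from a high-concentration spike is
informative. Absolute abundance and the detection limit follow as

$$m_{ij} = \rho_{ij}\, e^{-\beta_j}, \qquad
  \text{limit}_j = \theta\, e^{-\beta_j},$$

with $\theta$ the RPG10K sensitivity floor. The default
$\theta = 0.01$ corresponds to roughly 2 mapped reads at a depth of 2
million aligned reads; detection uses a closed boundary
($\rho \ge \theta$) so a value exactly at the floor counts as
detected. The reported detection limit is the unweighted mean of the
per-sample limits.

**Mass conversion.** Transcript copies convert to mass via the
single-stranded RNA convention $MW(L) = 320.5\,L + 159$ g/mol for a
transcript of spliced length $L$ nt (both constants are arguments of
`transcriptsToMass()`), and Avogadro's number. Masses of differently
sized embryos are compared after scaling by the embryo-volume ratio
(`volumeScaledMass()`), reported to 3 significant figures.

## Temporal classification

`classifyTemporal()` applies four rules in precedence order to the
per-gene trajectory $m_i(t)$ and its detection pattern:

1. **zygotic** — undetected at every sample before the onset index
   (first sample at $\ge 4$ h after egg laying by default) and detected
   somewhere from it onward. Detectability-based, so it outranks the
   magnitude-based rules.
2. **maternal_down** — detected at the first timepoint, trajectory
   maximum at the first *or third* timepoint (the global poly(A)
   rebound at 3 h can lift degraded maternal transcripts briefly above
   their 1 h level), and $m(t_1) \ge 2 \times m(t_{last})$.
3. **transient** — a unique maximum at least twice the mean of all
   other timepoints.
4. **persistent** — detected throughout with standard deviation of
   $\log_2(m+1)$ over the 3–5 h samples at most 0.25.

Anything else is `unclassified`; every gene receives exactly one label.
The folds (2.0) and the log-scale spread bound (0.25) are package
defaults chosen to separate the archetypes cleanly on noise-free
trajectories; they are exposed via `temporalClassParams()`.

**Clustering.** `clusterProfiles()` is a deliberately deterministic
stand-in for nonparametric trajectory clustering: rows are z-scores of
$\log_2(m+1)$, the distance is $1 - $ Pearson correlation, linkage is
average, and the tree is cut at $k$. Zero-variance rows go to a
dedicated flat cluster (labelled 0) because correlation is undefined
for them. Average linkage on noisy flat profiles chains aggressively:
on the default synthetic experiment the zygotic group isolates cleanly
but persistent genes — whose z-scored profiles are essentially noise —
scatter, capping agreement with the generating labels well below 1.
The tests assert the level the method actually achieves there
(adjusted Rand index above 0.15, against a permutation null of about
0), not an aspirational one.

**Stability ranking.** Candidate reference genes are ranked by a
log-scale coefficient of variation: the standard deviation of
$\log_2(m+1)$ across timepoints divided by its mean, ascending, ties
broken by gene ID, restricted to genes detected at every timepoint. A
literal "standard deviation of the row z-score" is 1 for every gene by
construction, so it cannot rank anything; the log-CV preserves the
intended meaning (low relative variability on the multiplicative scale
expression lives on).

## Zygotic-early genes and their corroboration

`identifyZygoticEarly()` includes a gene iff it is undetected at every
sample at $\le 2$ h and detected at $\ge 1$ later sample — the window
before zygotic genome activation in which everything detectable must be
maternal. The call depends only on the detection pattern, so it is
invariant to expression changes that do not cross the floor.

Two orthogonal signals corroborate the calls. Intron-read fractions
(`intronReadFraction()`) pool exonic and intronic counts over the
samples where a gene is detected; elevated fractions indicate nascent
transcripts, i.e. ongoing transcription. Single-exon genes are flagged
not-applicable, and genes with no reads report a missing fraction
rather than 0/0. Gene architecture (`architectureCompare()`) tests
whether zygotic-early genes have shorter representative transcripts and
fewer exons, with Mann–Whitney rank-sum tests: exact enumeration when
both groups have $\le 10$ tie-free observations, otherwise the normal
approximation with tie correction and continuity correction. For fully
tied inputs the approximation degenerates (zero variance with the
statistic at its null mean); the test then reports $p = 1$. Relative
agreement between the exact and approximate branches is excellent for
moderate $p$ but deteriorates in deep tails, as normal tail
approximations always do.

## Promoter motifs

Promoters are the `window` (default 1000) bases immediately upstream of
the strand-aware TSS of the representative transcript (the longest
isoform — gene-level quantification needs one length and one TSS per
gene, and no finer rule is defensible without expression-weighted
isoform calls). Sequences are oriented so position `window` abuts the
TSS, clipped at contig edges, and dropped below 50 bp.

`scanMotif()` matches IUPAC patterns (TAGteam CAGGTAG, degenerate
CAGGTAB) through Biostrings with ambiguity codes interpreted in the
pattern only, so `N` in the genome never matches; both strands are
scanned by default (motif function is generally orientation-free) and
overlapping hits are all reported. Set-level enrichment dichotomises
each promoter by presence of $\ge 1$ hit and uses the one-sided Fisher
exact (hypergeometric-tail) test; the odds ratio is the sample
cross-product with a Haldane $+0.5$ correction when a cell is zero.
Positional enrichment pools hit positions and tests the proximal count
(default: the 300 bp nearest the TSS) against the uniform binomial
null, $p_0 = 300/1000$; zero hits give $p = 1$ by convention. This is
a simplification of local-enrichment scanning: it tests concentration
near the TSS, not an arbitrary positional mode.

## The synthetic experiment generator

`simulateExperiment()` emulates the statistical structure of an hourly
1–6 h embryo series with 2000 genes and 92 spike-in species:

* baseline abundance $b_i \sim \log N(7, 1.5)$ transcripts per embryo;
* a global scale $g_j = (1.00, 0.49, 1.18, 1.05, 0.95, 0.74)$ applied
  to the non-zygotic pool — the per-embryo mRNA-mass profile (1.26,
  0.61, 1.49, … ng) rescaled to 1 at the first timepoint: a *stylised*
  dip/rebound, not a fitted curve;
* maternal trajectories $b_i\, g_j\, d_i^{\,t}$ with per-gene decay
  $d_i \in [0.6, 0.95]$; persistent $b_i\, g_j$; transient Gaussian
  bumps of amplitude 4–20 at a random timepoint ($\sigma = 0.5$ h);
  zygotic genes exactly zero before a per-gene onset in $\{4,5,6\}$ h,
  ramping linearly after;
* spike-in molecules log-uniform over $[10^2, 10^7]$, identical across
  samples (spiking was per embryo);
* counts $c_{ij} \sim \text{Poisson}(d_j\, m^{*}_{ij} / \sum_k
  m^{*}_{kj})$ at depth $d_j = 2\times 10^6$, the sum running over
  genes *and* spikes; no length bias (full-length reads are molecule
  counts);
* intronic reads $\sim \text{Binomial}(c_{ij}, \pi)$ with
  $\pi = 0.02$ for non-zygotic and $0.15$ for zygotic genes, forced to
  0 for single-exon genes;
* spliced lengths $\log N(\log 2000, 0.5)$ with zygotic lengths
  $\times 0.6$; exon counts $1+\text{Poisson}(5)$ vs
  $1+\text{Poisson}(1)$ (zygotic); genes laid out on one synthetic
  contig, alternating strands, with deterministic 100–500 bp introns;
* promoters: i.i.d. bases at GC 0.40, with one CAGGTAG planted at a
  uniform position within the 300 bp proximal window for half of the
  zygotic genes (configurable).

All randomness flows from one seed; promoters are drawn last, so
skipping them (`withPromoters = FALSE`) changes nothing else. Choices
the generator had to make beyond the stylised constants — zygotic
baselines from the same log-normal as other groups, transient peaks
uniform over all timepoints, equal intron rates for all non-zygotic
groups — were fixed once at values a practitioner would call
unremarkable and are not tuned.

**What the generator does not emulate.** Isoform structure, sequencing
error, length-biased sampling, batch effects, spike-in pipetting
variation (a per-sample jitter would break the per-embryo spiking
assumption the calibration relies on), and realistic promoter
composition (background is i.i.d.; real promoters carry other motifs
and CpG/GC structure). Passing benchmarks on these simulations
demonstrates the *statistical machinery* — calibration recovery,
detection behaviour, enrichment calibration — not performance on any
real genome.

**A regime worth knowing about.** Under the generator's default
conditions the spike-in pool ($\approx 8\times10^7$ molecules summed
over 92 species) is much larger than the scaled-down gene pool
($\approx 6\times10^6$), so spike-ins absorb most of the reads and a
median gene receives only a few dozen. Calibration is unaffected
(spike totals are huge; recovered scales sit within 0.1% of truth),
but gene-level trajectories are Poisson-noisy: the acceptance
benchmark measures roughly 70% temporal-label accuracy there, with the
persistent group hardest hit (its 3–5 h log-spread under that noise
level often exceeds the 0.25 bound) — while the same rules recover
noise-free rule-conforming trajectories perfectly. This is a faithful
picture of what threshold rules do at low coverage, and the benchmark
reports it rather than simulating an easier regime.

## Numerical choices

* **Closed-form MLE, not a GLM fitter**, for $\beta_j$ (exactness;
  no optimiser tolerance). Verified against IRLS to $10^{-8}$.
* **Exact inverse conversion.** Floating-point multiplication is not
  bitwise invertible — division returns a value one ulp off for a few
  percent of entries, and two adjacent doubles can collide onto one
  product. `absoluteToRelative()` therefore forward-verifies candidate
  preimages (the quotient and its ulp-neighbours, plus the
  count-derived relative value, which settles collisions) and returns
  the one whose product reproduces the stored absolute value exactly.
* **Counts are multiplied by $10^4$ before division** in RPG10K so the
  numerator is exact.
* **Ties.** Rank-sum uses average ranks; stability ranking and
  clustering break ties by gene ID / input order; `max.col` with
  "first" makes the trajectory argmax deterministic.
* **Degenerate inputs.** Zero-depth samples, empty count tables,
  all-zero spike signal, constant columns in Spearman QC, empty groups
  in rank-sum, windows exceeding promoter length — all raise immediate,
  named errors or documented missing values rather than propagating
  NaN.

## Problem sizes

The test suite and the acceptance script run entirely on simulated
data: 2000-gene experiments for end-to-end checks, 20–50 replicate
simulations for calibration recovery, 5–10 replicates for
classification benchmarks, 100–200 replicates for null calibration of
the enrichment test, and 100 random instances for the closed-form /
IRLS comparison. These sizes make the full suite run in about a minute
while keeping Monte-Carlo error well below the margins being asserted.

## Known limitations

* Detectability-based zygotic calls cannot distinguish true zygotic
  transcription from maternal transcripts that become polyadenylated
  (hence visible to poly(A) selection) after egg laying; the
  intron-read signal mitigates but does not eliminate this.
* The calibration assumes spike-in amounts scale exactly with embryos
  pooled; pipetting error maps directly onto $e^{-\beta_j}$.
* No uncertainty is attached to $\beta_j$ (single intercept per
  sample); replicate designs should bootstrap at the sample level.
* The clustering is a reproducible summary device, not a model-based
  clustering; groups with no shape signal will not separate.
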