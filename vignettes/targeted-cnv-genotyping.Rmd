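---
title: "Targeted CNV genotyping from BAF and LRR signals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted CNV genotyping from BAF and LRR signals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetedCNV)
```

# The problem

A biallelic CNV polymorphism — here the motivating case is a 129-kb
deletion/duplication at 12p13.31 containing *SLC2A3* — segregates in the
population as copy number 1 (heterozygous deletion), 2 (diploid) or 3
(duplication). Genome-wide HMM callers genotype such loci with appreciable
false-positive and false-negative rates, so association studies need a
locus-specific second opinion. Because the breakpoints are known, the
problem reduces to classifying one interval per sample from two SNP-array
signal channels:

* **LRR** (log R ratio), the log2 ratio of observed to expected total
  intensity: its mean shifts down for a deletion and up for a duplication;
* **BAF** (B-allele frequency), the fraction of intensity attributable to
  the B allele: with *k* total copies and *i* of them carrying B, BAF
  clusters at *i/k*.

# The calling model

## LRR channel: flanking-window *t*-tests

The diploid flanking sequence is the natural within-sample control for the
interval: it shares the sample's array chemistry, DNA quality and wave
background. We compare the non-missing LRR values of SNPs inside
`[start, end]` (breakpoints inclusive, 1-based array-manifest convention)
against each 350-kb flank with a two-sided Welch two-sample *t*-test, and
keep

* `min_p` — the minimum of the two per-flank P values, and
* `lrr_delta` — mean inside-LRR minus mean pooled-flank LRR.

Two deliberate choices:

* **Welch, not Student.** Interval and flank SNP counts and variances
  differ, and nothing is gained by assuming equal variances.
* **Separate per-flank tests summarised by their minimum**, rather than one
  pooled-flank test. A real breakpoint shifts the interval against *both*
  flanks; testing each separately is robust to one flank being atypical
  (e.g. a neighbouring variant), and the minimum is the natural screening
  summary. `min_p` is used only as a screening statistic against a cutoff —
  no multiplicity correction is applied and it should never be reported as
  an inferential P value.

Degenerate inputs are given conventions rather than errors: when both
groups have (numerically) zero variance, equal means give P = 1 and unequal
constant means give P = 0. This makes exactly noiseless simulations
callable.

## BAF channel: fit to expected cluster positions

For copy number *k* the expected cluster set is `{i/k : i = 0..k}`. The fit
of the inside-interval BAFs to model *k* is the **mean squared distance to
the nearest cluster center**. Any monotone measure of cluster agreement
would serve; mean squared distance was chosen because it is smooth,
parameter-free, invariant to permutation and duplication of the input, and
does not require a noise model (a likelihood fit would). Fits for the three
models are combined into ratios with the diploid misfit in the numerator,

\[
\mathrm{ratio}_{del} = \frac{f_2 + \varepsilon}{f_1 + \varepsilon},\qquad
\mathrm{ratio}_{dup} = \frac{f_2 + \varepsilon}{f_3 + \varepsilon},
\]

so a ratio above 1 favours the non-diploid model. The guard
`epsilon = 1e-6` only matters on noiseless data, where fits can be exactly
zero.

One structural fact shapes the whole caller: **the CN1 centers `{0, 1}` are
a subset of the CN2 centers**, so `f_2 <= f_1` always and `ratio_del` can
never exceed 1. BAF cannot positively *prove* a deletion; what it can do is
**veto** one. A true one-copy interval shows only homozygous BAFs, which
fit CN1 and CN2 identically (`ratio_del` ≈ 1), whereas heterozygous BAFs
near 0.5 are incompatible with a deletion and drive `ratio_del` toward 0.
The duplication side is different: the CN3-only clusters at 1/3 and 2/3
are genuinely separated from 1/2, so `ratio_dup` grows without bound for
real duplications.

## The decision rule

With thresholds `pCutoff`, `ratioCutoff`, `minSnps`, `lrrSdMax`,
`homBafTol`:

1. `lrr_sd > lrrSdMax` → flag `HIGH_LRR_SD`; the call proceeds (the flag
   replaces a manual-review trigger, it is not a hard filter).
2. fewer than `minSnps` non-missing LRR in the interval or either flank →
   no-call `INSUFFICIENT_SNPS`.
3. every inside BAF within `homBafTol` of 0 or 1 → flag
   `BAF_UNINFORMATIVE`; the fit-ratio requirement below is waived because
   homozygous-only data cannot separate the models (the call then rests on
   the LRR channel).
4. `min_p < pCutoff` and `lrr_delta < 0`: CN1 if
   `ratio_del >= ratioCutoff` *or* BAF is uninformative, else no-call
   `DISCORDANT_EVIDENCE`.
5. `min_p < pCutoff` and `lrr_delta > 0`: CN3 under the symmetric
   condition on `ratio_dup`, else `DISCORDANT_EVIDENCE`.
6. otherwise CN2.

Given the nesting argument above, rule 4 in practice fires through the
homozygous-only route: a deletion call requires a significant downward LRR
shift *and* the absence of heterozygous BAFs inside the interval. The
waiver is applied symmetrically in rule 5 for the rare all-homozygous
duplication. `DISCORDANT_EVIDENCE` no-calls are exactly the samples a
human should look at; `plotSample()` renders the three-panel
BAF / LRR / cumulative-LRR review figure for them. Copy numbers above 3
are not modelled separately; calls saturate at 3.

## Threshold defaults and their calibration

The method description fixes the *existence* of a P-value cutoff and a fit
ratio threshold, not their values, so the defaults are this package's own
calibration, done on the simulator at its default noise profile and
recorded here once:

| parameter     | default | rationale |
|---------------|---------|-----------|
| `pCutoff`     | 1e-4    | True CN1/CN3 shifts of −0.66/+0.40 at LRR SD 0.20 with ≥20 SNPs give *t*-statistics far beyond any reasonable cutoff (observed null→alternative separation is many orders of magnitude), so sensitivity is insensitive to this choice. Specificity is not: with two flank tests per sample, a cutoff of 1e-3 lets through ~2 null samples per 1,000 (which then become `DISCORDANT_EVIDENCE` no-calls); 1e-4 keeps the diploid no-call rate at ~0.2/1,000 while costing no sensitivity. |
| `ratioCutoff` | 2       | Requires the non-diploid model to fit at least twice as well as diploid. True duplications at default noise give `ratio_dup` an order of magnitude above 2; diploid flukes sit near or below 1. Any value in roughly [1.5, 5] behaves identically. |
| `minSnps`     | 10      | Below ~10 LRR observations per partition the Welch test loses meaningful power and the BAF pattern is too sparse to veto; such samples are honest no-calls. |
| `lrrSdMax`    | 0.30    | A conventional array-QC ceiling for sample-level LRR SD. Advisory only. |
| `homBafTol`   | 0.12    | 4× the default BAF noise SD (0.03). With 25 inside SNPs, a true deletion has all BAFs within 4σ of 0/1 with probability ≈ 0.998, so almost no deletion misses the homozygous-only route; at 3σ about 6–7% would be spuriously discordant. A diploid interval with uniformly drawn allele frequencies is all-homozygous with negligible probability at 20+ SNPs, so the waiver does not leak diploids through. |
| `epsilon`     | 1e-6    | Division guard; irrelevant once fits exceed ~1e-4, i.e. for any noisy data. |

# The simulator

`simulateSample()` generates the locus geometry (evenly spaced SNPs inside
the interval and both flanks), draws a per-SNP population B-allele
frequency `q ~ U(0.05, 0.95)`, the B-copy count as Binomial(*k*, *q*), and
adds Gaussian noise: BAF noise SD 0.03 clamped to [0,1] (array BAF
saturates at the homozygous rails, which the clamping reproduces), LRR
noise SD 0.20 around per-copy-number means −0.66 / 0.00 / +0.40 — widely
used expectations for one and three copies on Illumina-style arrays.
Noise SDs of exactly 0 are allowed and produce exact signals, which the
noiseless recovery tests rely on. Cohorts draw each sample's state as
deletion with probability 1% and duplication with 4% — the carrier
frequencies typical of this locus in European-ancestry cohorts — with
per-sample child seeds derived from one master seed so any sample can be
regenerated in isolation.

What the simulator deliberately does **not** model: genomic waves and GC
bias, batch and plate effects, platform differences, mosaicism, and — most
importantly — it generates only the ~830 kb around the locus, not a
genome-wide track. Two consequences for interpreting test results. First,
passing tests show the *decision logic* is sound under idealised
Gaussian-cluster signals; they do not certify performance on real arrays,
where wave artefacts can mimic shifts. Second, the sample-level LRR SD is
computed over a track where the CNV occupies a third of the SNPs, so true
carriers routinely exceed `lrrSdMax` and carry an advisory `HIGH_LRR_SD`
flag; on real genome-wide data the flag isolates noisy arrays instead.

# Association statistics

Carrier-level (dominant) coding throughout: a subject either carries ≥1
deletion allele or does not, and deletions and duplications are tested
separately — matching how carrier counts are reported per cohort.

* **Odds ratios** use the cross-product with a Woolf log-OR interval;
  zero cells get the Haldane–Anscombe 0.5 correction (applied to all four
  cells, reported via a message and a `corrected` field).
* **Tests** are Pearson chi-square without continuity correction (df = 1),
  and subgroup heterogeneity is the K×2 chi-square (df = K−1) of carrier
  vs non-carrier across subgroups.
* **Combination across cohorts** uses the Mantel–Haenszel common OR with
  the Robins–Breslow–Greenland interval and the CMH statistic. A
  fixed-effect inverse-variance meta-analysis would be the main
  alternative; MH was chosen because it remains stable with the sparse
  carrier counts typical here (carrier frequencies ~1–3%). With one
  stratum it reduces algebraically to the Woolf analysis.
* **Replication power** is Monte-Carlo: the case carrier probability is
  obtained from the control frequency and the alternative OR through the
  odds transform, carrier counts are drawn binomially, and the chi-square
  test is applied per replicate (vectorised closed form, identical to
  `chisq.test(correct = FALSE)`). Simulation was preferred over a
  closed-form power formula because it reproduces the actual test used at
  the actual (discrete, sparse) counts; the analytic two-proportion
  approximation is kept as a cross-check in the test suite and agrees
  within Monte-Carlo error at the study's scale. Degenerate replicates
  with no carriers in either arm count as non-rejections.

# Numerical and interface conventions

* Missing BAF/LRR (`NA`, `NaN`, empty field) are dropped per-statistic,
  never per-record; counts reported with each call are of non-missing
  values actually used.
* Signal I/O uses the PennCNV signal-intensity text dialect
  (`Name/Chr/Position` plus `<sample>.B Allele Freq` /
  `<sample>.Log R Ratio` column pairs); multi-sample exports are read by
  column prefix. Written values carry 6 decimals, and round-trips are
  lossless at that precision.
* A SNP exactly on a breakpoint is inside; the flanks are half-open on the
  breakpoint side so the three partitions are disjoint by construction.
* All calls are deterministic functions of their inputs; all simulation
  functions take explicit seeds.

# Problem sizes used in the test suite

The packaged tests run the caller-recovery study at 1,000 simulated
samples per copy-number state (plus 150 noiseless), the null-calibration
study at 2,000 replicates, power comparisons at 10,000 Monte-Carlo
replicates per configuration, and oracle-equivalence checks on 20
randomised cases per statistic. These sizes give Monte-Carlo standard
errors comfortably inside the asserted bands (e.g. ±0.7% on a 99%
accuracy at n = 1,000) while keeping the full suite fast enough to run on
every change.

# Known limitations

* Only integer copy numbers 1–3 are modelled: no homozygous deletions
  (CN0), no CN ≥ 4, no mosaicism fractions.
* The caller assumes breakpoints are known and correct; it does not
  discover or refine them, and a mis-specified interval dilutes both
  channels.
* BAF cannot distinguish CN1 from CN2 at loci that happen to be
  homozygous; such deletions rest entirely on LRR, as flagged.
* The association layer implements per-cohort tests and MH combination
  only — no covariate adjustment, relatedness correction or imputation.
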