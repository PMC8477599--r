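---
title: "Methods: factorial pool-seq allele-frequency analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: factorial pool-seq allele-frequency analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Replicated pooled sequencing of selection experiments on highly fecund
marine larvae (here, oyster cohorts from a selectively bred and a wild
broodstock, reared under ambient and acidified seawater and sampled
early and late in larval development) produces, per replicate pool, read
counts of nucleotides at thousands of restriction-tag loci. Because each
pool contains thousands of individuals, allele frequencies are estimated
directly from read proportions rather than from genotypes. The questions
are which loci change in frequency over development (viability
selection), which change with the seawater treatment, and whether those
changes interact — and then where those loci sit on the genetic map and
near which functional annotations.

`poolfactor` implements that analysis as a reusable pipeline: count
extraction and filtering, per-locus inference, pool-adapted population
genetics, linkage bridging, enrichment, and a synthetic-data generator
with ground truth so the whole chain can be validated without any
external download.

## The model

For each biallelic locus and group, allele-2 read counts $c_2$ out of
$D = c_1 + c_2$ reads per replicate pool are modelled with a logit-link
binomial GLM

$$\operatorname{logit} \Pr(\text{allele 2}) =
  \beta_0 + \beta_S x_S + \beta_T x_T + \beta_{ST} x_S x_T,$$

with sum-to-zero coding $x_S \in \{-1,+1\}$ (early/late stage) and
$x_T \in \{-1,+1\}$ (ambient/high treatment). Each term receives a
**type III** p-value: the likelihood-ratio test of the full model
against the model with only that term's column removed, so main effects
are tested with the interaction retained. We use likelihood-ratio rather
than Wald tests because the LR statistic is well defined near boundary
fits and matches deviance-based "type III analysis of deviance"
behaviour under sum-to-zero contrasts.

Benjamini–Hochberg adjustment is applied per term across loci (three
families per group; a pooled family is available as a sensitivity flag),
and loci are classified exclusively: `Stage*Trt` if the interaction
q-value clears $\alpha = 0.05$ (regardless of the mains, since the
cross-tabulated categories are exclusive and "additive" means main
effects only), else `Stage+Trt` if both mains clear, else `Stage` or
`Trt`, else `None`. Non-converged or degenerate fits (e.g. a locus fixed
in every cell) are excluded from the BH families, reported `NA`, and
counted in the audit trail.

The binomial model deliberately ignores overdispersion from finite
replicate pools (drift between biological replicates). This mirrors the
analysis the pipeline reproduces; the synthetic generator can create
drift so the consequence — anti-conservative p-values — is measurable
(see below) rather than hidden.

## Filters

The locus-retention cascade runs in a fixed order, and every step
records how many loci it removed (the audit trail sums exactly to input
minus output):

1. **Depth**: cells with total depth outside $[50, 1000]$ are set
   *missing* (not dropped), so the presence filter is the sole arbiter
   of testability; loci missing everywhere are dropped.
2. **Biallelic**: loci with more than two nucleotides observed (at
   $\ge$ 1 read summed over samples, configurable) are dropped; a single
   stray read therefore creates a third allele, matching a strict
   reading of the rule.
3. **One SNP per 36-bp tag**: highest total depth wins, ties go to the
   lower position. The source protocol states the rule but not the
   criterion; depth is the natural proxy for reliability and the tie
   break makes the filter deterministic.
4. **Replicate presence**: $\ge 3$ non-missing replicates in *every*
   stage × treatment cell of each group under analysis. By default both
   groups must be testable (the modelling panel is shared); per-group
   panels are available via the `groups` argument.
5. **Starting MAF**: the day-2, treatments-pooled, read-count-weighted
   minor-allele frequency must *strictly* exceed 1% in at least one
   group. Day-2 pools of both treatments are pooled because treatment
   pools were split from a common embryo pool hours after fertilization,
   so their day-2 composition estimates the same founder frequencies.

Minor-allele orientation (allele 2) is fixed once, at the day-2 baseline
with both groups combined and count weighting, and held constant so
frequency trajectories and coefficient signs are comparable across
cells, groups, and stages.

## Population-genetic statistics

* **Frequencies** are read-count-weighted at every aggregation level:
  pooling replicates sums counts, it never averages ratios.
* **Nucleotide diversity** per locus and pool is
  $\hat\pi = \frac{D}{D-1}\, 2\hat f(1-\hat f)$ — the expected
  heterozygosity of two reads drawn without replacement, the standard
  pool-seq finite-depth correction. The uncorrected $2\hat f(1-\hat f)$
  is available by flag. Cells with $D < 2$ are excluded.
* **$F_{ST}$** uses the Hudson/Wright heterozygosity form on pooled
  per-group frequencies: $H_S = 2f(1-f)$ within groups, $H_T$ from the
  unweighted mean frequency, $F_{ST} = (H_T - \bar H_S)/H_T$.
  Uninformative SNPs ($H_T = 0$) are `NA` and excluded from means;
  negative per-SNP values are retained, not clamped, to keep the mean
  unbiased.
* **Bootstrap CIs** are percentile intervals of the mean over loci,
  resampling loci with replacement (1000 draws by default).
* **Spectra** are folded to MAF before the two-sample K–S test.
* **PCA** centers (but does not scale) per-locus frequencies with
  samples as observations; missing cells are mean-imputed per locus and
  the number imputed is reported.

The choice of SNP panel for diversity/differentiation (the full
quality-filtered panel including rare alleles, versus the stricter
modelling panel) is genuinely ambiguous in the source analysis; both are
supported — the statistics take any `snp_panel` — and the pipeline
records the panel audit trail beside every summary so the choice is
always declared.

## Synthetic data: the stated world

`simulate_experiment()` emulates the design: 2 broodstock groups × 2
stages × 2 treatments × 5 replicate pools. Per locus: a category drawn
from `{none, stage, trt, additive, interaction}` (defaults
`0.66/0.12/0.06/0.06/0.10`, approximately the union margins of the
published cross-tabulation, with "no change" the majority); a founder
MAF from Beta(2, 8) (mean 0.2, right-skewed towards rare alleles as in
the real spectra) rejection-sampled into $(0, 0.5]$; logit shifts of
magnitude 1.5 with random sign for the affected terms. The true cell
frequency is the inverse-logit of the shifted founder logit.

Sampling is two-layered: a binomial draw of $2 \times$ `pool_size`
allele copies per replicate pool (drift between biological replicates),
then binomial read sampling at a depth drawn from a log-normal
(median 200, sdlog 0.5) truncated to the retention window $[50, 1000]$.
`pool_size = Inf` disables drift. The default `pool_size = 200` reflects
the ~200 individuals sampled per pool late in the experiment; the true
census sizes are not stated precisely, so this is a declared free
parameter, chosen once.

What the generator does **not** emulate: linkage disequilibrium between
loci (loci are independent), shared pools across stages (stage cells are
sampled independently rather than longitudinally), sequencing error and
mapping artifacts, and genuine tri-allelic sites. A green recovery test
therefore establishes that the inference machinery is correct under its
own assumptions — not that the binomial model is robust to drift. That
second point is tested separately and deliberately: with a finite pool
the replicate variance exceeds binomial variance by the predicted factor
($\mathrm{Var} \approx f(1-f)(1/2N + 1/D)$), and the GLM's null
calibration holds only in the `pool_size = Inf` regime. Calibration and
power acceptance runs therefore use `pool_size = Inf`; the default
drifted world demonstrates the documented anti-conservatism.

## Linkage bridging and enrichment

SNPs inherit linkage positions through shared genomic scaffolds with a
published map: one marker on the scaffold → all its SNPs take that
marker's position; several markers on one linkage group → bp-nearest
marker, equidistant ties to the lower-bp marker (an implementation
convention, documented and tested — the source is silent); scaffolds
absent from the map or spanning multiple linkage groups are omitted with
the reason recorded. Assigned plus omitted always equals input.

Enrichment uses gene score resampling: genes within a closed ±5 kb
window of a mapped locus are scored with the best (minimum) locus
p-value per effect; a GO term's mean $-\log_{10} p$ is compared to the
mean of random gene sets of equal size drawn without replacement from
the scored-gene universe; the empirical p is
$(1 + \#\{\text{null} \ge \text{obs}\})/(M+1)$ with $M = 10^4$ draws by
default. Null draws are shared across terms of equal size, which makes
identical-membership terms exactly identical in output and keeps runs
seed-reproducible. The multifunctionality score is a *simplified*
diagnostic — the normalized mid-rank of a gene's GO membership count,
scaled to $[0,1]$, averaged per term — not the optimization-based score
of dedicated tools; it annotates, and never filters.

## Numerical choices and degenerate inputs

* Tests of main effects keep the interaction column (type III); LR
  statistics are clamped at 0 against round-off.
* `glm.fit` non-convergence, missing design cells, or loci with all
  reads on one allele yield `NA` p-values and a convergence flag; such
  loci never enter BH families.
* Bootstrap and resampling functions take explicit seeds and are
  bit-reproducible; the pipeline derives all stage seeds from one
  configured seed.
* All serialized positions are 1-based inclusive; gene windows are
  closed intervals, so a gene ending exactly 5 kb away is a hit.
* FASTQ quality is assessed *after* truncation to 36 bp — only retained
  bases matter — and the low-quality rule is strict (`< 10` bases below
  Q20 retained; exactly 10 discards). Reference-matching bases for the
  alignment filter are counted from the MD tag (matches, not merely
  aligned positions), and the floor is inclusive (`>= 30`).

## Known limitations

* The binomial GLM underestimates replicate variance whenever pools are
  finite; a beta-binomial or quasi-likelihood variant is the obvious
  extension and deliberately out of scope here.
* Genotype likelihoods, imputation, LD-aware statistics, Watterson's
  $\theta$ and Tajima's $D$ are not provided.
* The enrichment module tests the gene→GO map as given, without
  propagation up the GO graph; term counts are database-version
  dependent.
* The chi-square comparison of category distributions treats the two
  groups' classifications as independent samples, which they are not
  (same loci); it is exposed with a configurable collapsing and should
  be read as descriptive.
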