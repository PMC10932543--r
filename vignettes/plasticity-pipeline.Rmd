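---
title: "Methods: expression plasticity across colonization stages"
author: "plastfirst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression plasticity across colonization stages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question and the three-stage design

When a lowland population colonizes a high-elevation environment, gene
expression can respond twice: first plastically, when individuals are
exposed to hypoxia, and later genetically, after generations of selection
in residents. `plastfirst` implements a comparison across three groups of
samples per tissue:

* **ancestral** — lowland individuals in their original environment,
* **plastic** — lowland individuals after experimental hypoxia
  acclimation,
* **colonized** — individuals from an established highland population.

For each gene the per-stage mean TPM triple
$(E_\mathrm{anc}, E_\mathrm{pla}, E_\mathrm{col})$ defines a plastic
change $PC = E_\mathrm{pla} - E_\mathrm{anc}$ and an evolved change
$EC = E_\mathrm{col} - E_\mathrm{pla}$. With a relative threshold
$\tau$ (default 0.5, i.e. 50% of the ancestral level), a gene shows an
*excess* plastic change when $|PC| > \tau E_\mathrm{anc}$ and an excess
evolved change when $|EC| > \tau E_\mathrm{anc}$. Genes with both
excesses in the same direction are **reinforcement** genes — evolution
pushed expression further along the plastic response; both excesses in
opposite directions mark **reversion** genes — evolution pulled the
plastic response back. Everything else is unclassified.

The headline statistic is the split of classified genes between the two
groups, tested with an exact two-tailed binomial test (minimum-likelihood
convention, `stats::binom.test`) against a null proportion of 0.5.

# Magnitude, categories and bins

The two changes of a classified gene can differ in size, and the analysis
needs a single magnitude per gene to stratify by. The classifier uses

$$M = \min(|PC|, |EC|) / E_\mathrm{anc},$$

the *binding* constraint: a gene in the ">150%" category is guaranteed to
have *both* changes above 150% of the ancestral level. Categories are the
disjoint half-open intervals $(0.5, 1]$, $(1, 1.5]$, $(1.5, 2]$ and
$(2, \infty)$ on $M$ — half-open at the bottom because the excess rule
itself is a strict inequality — so category gene sets are independent and
each can be tested (and passed to the divergence test) on its own. A
second, coarser stratification bins $M$ into consecutive windows of
width 0.2, 0.4 or 0.6 starting at $\tau$; stable reversion excess across
bin widths shows the result is not an artifact of the category edges.

# Parametric bootstrap

With 3–7 samples per stage, a gene can land in a class by sampling error
alone. For every gene, each bootstrap replicate draws one Gaussian value
per stage with mean equal to the observed stage mean and standard
deviation equal to the standard error of that mean, and reclassifies the
triple. A call is *supported* when at least 950 of 1000 replicates
reproduce it — a 5%-error guard in the same spirit as a p < 0.05 rule.
Two counting modes exist: support for the gene's specific point class
(default — the support certifies the class that is reported) and support
for "either classified outcome".

Numerical details decided here:

* Gaussian draws can be negative; they are used as-is except replicates
  whose *ancestral* draw is non-positive, which would make the relative
  threshold undefined. Such replicates are redrawn wholly, at most 50
  times, after which the offending replicate is dropped from the support
  denominator (with SEs small relative to the mean — the usual case —
  redraws are rare).
* Per-gene random substreams are derived by hashing the gene id together
  with the master seed, so support values do not depend on the order of
  genes in the matrix.
* A stage with a single sample has an undefined SE; it is reported as 0
  (the bootstrap then treats that stage mean as exact) and the summary is
  flagged degenerate.

# Expression QC: conserved genes

Batch differences between sequencing groups would masquerade as stage
effects. The QC step selects "conserved" genes — coefficient of variation
of $\log_2(\mathrm{TPM}+1)$ across all samples at most 0.3 and mean TPM
at least 1 — and compares their per-stage median expression between every
stage pair with the unpaired Wilcoxon rank-sum test. The unpaired test is
used deliberately: the stage groups have different sizes, so a
signed-rank (paired) comparison is not defined. Genes with zero mean
log-expression are dropped before the CV (division by zero). Stable
medians (all pairwise p above 0.05) indicate negligible batch structure.

# Co-expression: modules, eigengenes, hub genes

The pipeline needs stage-associated co-expressed gene sets and their
summary profiles, not a full weighted-network analysis, so module
detection is a deliberately simple correlation clustering:

* adjacency $= |r|^\beta$ (Pearson, soft power $\beta$, default 6),
* average-linkage hierarchical clustering of $1 - |r|^\beta$,
* fixed-height cut (default 0.25), clusters below the minimum size
  (default 30) left unassigned.

Scale-free-fit calibration of $\beta$, topological-overlap smoothing and
dynamic tree cutting are intentionally out of scope; on data with clear
block structure the fixed cut recovers the blocks exactly, which is the
property the downstream logic relies on.

A module's **eigengene** is the first principal component (via SVD) of
its per-gene z-scored submatrix, one value per sample, with the sign
fixed so the eigengene correlates positively with the module's mean
standardized profile. Modules whose eigengenes correlate at p < 0.1 are
merged iteratively (most significant pair first, eigengene recomputed
after each merge); merged modules whose eigengene tracks the stage coding
(ancestral 0, plastic 1, colonized 2) at p < 0.01 are *stage-associated*.

**Gene significance** (GS) is the absolute Pearson correlation between a
gene's expression and the stage code. **Hub genes** are members of
stage-associated modules with GS strictly above the first quartile of GS
and correlation p < 0.05. Two conventions are fixed here because the
verbal rule leaves them open: the quartile is the type-7 (linearly
interpolated) quantile, computed over the genes of the stage-associated
modules (not all genes — configurable), and ties at the quartile are
excluded by the strict inequality.

A note on trend shapes: with only three stage levels, polynomial
regression beyond degree 2 is not identifiable, so monotone
(reinforcement-like) versus reversing trends are distinguished by the
sign structure of the two stage-to-stage changes rather than by
higher-order curve fits.

# Regulators and adaptive versus maladaptive plasticity

Phenotypes (e.g. capillary per fiber, fiber area, perimeter for flight
muscle) are measured in the field populations — ancestral and colonized
individuals — so gene–phenotype Pearson correlations are computed over
those samples only. A gene with correlation p < alpha (default 0.05, raw;
a Benjamini–Hochberg option exists but is off by default, matching the
raw-p convention of this analysis type) is a **positive** or **negative
regulator** according to the sign of r. Genes significant for several
phenotypes with conflicting signs are reported per phenotype and flagged;
the gene-level call keeps the smallest-p phenotype.

For regulator genes with an excess plastic change, plasticity is
**adaptive** when its direction matches the regulator's sign (positive
regulator up, negative regulator down at the plastic stage) and
**maladaptive** when it opposes it. Flipping the sign of a phenotype
flips every regulator sign and swaps every adaptive/maladaptive label — a
property the test suite checks.

# Genetic divergence: WC84 FST and the permutation test

If selection acted on the regulatory plasticity of a gene set, divergence
between the ancestral and colonized populations should be elevated in and
around those genes. Per-SNP divergence is the Weir–Cockerham (1984)
estimator with its three variance components — $a$ (among populations),
$b$ (among individuals within populations), $c$ (within individuals) —
and $\theta = a/(a+b+c)$, computed from allele frequencies, observed
heterozygosities and per-site called sample sizes (missing genotypes are
excluded per site; pooled-monomorphic sites are undefined and excluded).
The average over a SNP set is the ratio of sums
$\sum a / \sum (a+b+c)$ (the "weighted" FST of vcftools); the per-site
mean is available for comparison. Site filters mirror resequencing
practice: biallelic SNPs, QUAL ≥ 30, INFO/MQ ≥ 20 when present, adjacent
SNPs at least 5 bp apart (first of a closer pair kept).

SNPs are assigned to the **genic** body, the 2 kb **upstream** and the
2 kb **downstream** flank of every gene (strand-aware, truncated at
chromosome edges); a SNP overlapping several genes counts for each, and
the union of all three region sets — deduplicated — is the *genic
background*. For a candidate gene set and each region type separately,
the empirical weighted FST of its SNPs is compared with 100 resamplings
from the background: each replicate draws $N'$ SNPs without replacement,
$N'$ uniform within ±5% of the candidate count $N$. The flag is
*significant* when the empirical value exceeds the 95th percentile of the
resampled values; the reported p-value uses the add-one convention
$(1 + \#\{\mathrm{perm} \ge \mathrm{emp}\})/(n_\mathrm{perm}+1)$, which
cannot reach 0 with 100 permutations. Candidate SNPs are excluded from
the background pool by default (an inclusive mode exists).

A scaling property worth knowing: permutation draws are made *without
replacement* from a finite background, so their spread is smaller than
the candidate set's own sampling variability by roughly
$\sqrt{1 - n/N}$. When candidates are a large share of the background the
null is anti-conservative. In the intended regime — candidate sets of a
few hundred genes against a genic background of tens of thousands — the
ratio is negligible; the calibration checks in the test suite therefore
keep candidate genes a small fraction (~5%) of all genes, and users
applying the test to small backgrounds should expect the same effect.

# The synthetic-data generator

Every stage of the pipeline is testable without external downloads
because the generator plants known truth:

* **Expression.** Baseline means are log-uniform over 2–512 TPM. A
  reinforcement gene with magnitude $m$ gets stage means
  $(\mu, \mu(1+m), \mu(1+2m))$; a reversion gene
  $(\mu, \mu(1+m), \mu(1+m) - 1.5m\mu)$, the 1.5 overshoot putting both
  changes past the threshold; null genes stay at $\mu$. Per-sample values
  multiply the stage mean by log-normal noise with mean 1 and a
  configurable CV — TPM is positive and right-skewed, so multiplicative
  log-normal noise is the natural choice; the zero-noise limit reproduces
  the stage means exactly, which anchors the exact-recovery tests.
  Defaults: 1000 genes, 5 samples per stage, planted fractions 0.10
  reinforcement / 0.30 reversion, magnitude 0.8, noise CV 0.1.
* **Phenotypes.** A fraction of genes are regulators with random signs,
  partitioned round-robin across phenotypes; each phenotype is the sum of
  sign × coupling × z-scored regulator expression over the ancestral and
  colonized samples, plus Gaussian noise. With several independent
  regulators per phenotype each individual correlation is diluted by
  $1/\sqrt{k}$, so sign *recovery* at p < 0.05 with ten phenotype samples
  is only achievable when one or two regulators dominate a trait; the
  recovery tests plant one dominant regulator per phenotype.
* **Genotypes.** Genes are laid head-to-tail on one pseudo-chromosome
  (3 kb bodies, 2 kb flanks, never overlapping); SNPs fall uniformly over
  the union of bodies and flanks. Allele frequencies follow the
  Balding–Nichols model: ancestral $p \sim U(0.05, 0.95)$, population
  frequencies $\sim \mathrm{Beta}(p(1-F)/F, (1-p)(1-F)/F)$, genotypes
  $\mathrm{Binomial}(2, \cdot)$, with $F$ elevated in the flanks of the
  planted candidate genes. Population sizes default to 12 lowland and 11
  highland diploids, a realistic two-population resequencing design.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: linkage disequilibrium between SNPs,
count-based overdispersion of RNA-seq (no gene-length or library-size
structure), shared regulatory covariance beyond the planted modules,
individual-level pairing between expression and genotype data, and any
demography richer than the Balding–Nichols island model.

# Problem sizes and reproducibility

The default test-suite runs use 150–1000 genes, 1200–10,000 SNPs and
50–1000 bootstrap/permutation replicates; the parameter-recovery run uses
the full default generator (1000 genes, 1000 bootstrap replicates) and
the calibration run 200 replicate data sets of 3000 SNPs. All randomness
flows from explicit integer seeds: the generator uses one global stream,
the bootstrap per-gene substreams hashed from the master seed, the
permutation test one stream per region. `runPipeline()` writes no
timestamps, so a rerun with the same config and seed is byte-identical —
itself one of the checks in the suite.

# Known limitations

* The classifier works on stage means; it does not model within-stage
  variance beyond the bootstrap guard, and applies no multiple-testing
  correction across genes (by design, matching the analysis it
  implements).
* The magnitude $M$ of a classified gene is a summary choice; other
  summaries (e.g. $|PC|/E_\mathrm{anc}$ alone, used for adaptive /
  maladaptive stratification) shift genes between categories.
* Module detection is a fixed-height correlation clustering, not a full
  weighted-network pipeline; on weakly modular data the fixed cut is
  sensitive to `cutHeight`.
* The FST permutation test inherits the finite-background caveat above
  and assumes exchangeable SNPs (no LD-aware block resampling).
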