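---
title: "Detecting inversion-like LD blocks and partitioning population differentiation"
author: "invLD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting inversion-like LD blocks and partitioning population differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invLD)
```

## The problem

Chromosomal inversions suppress recombination between the inverted and
standard arrangements of a chromosome segment. In population samples this
produces a characteristic signature: a megabase-scale block of SNPs in
strong mutual linkage disequilibrium (a "supergene"), inherited as a unit,
often with arrangement frequencies that differ among populations. Marine
fish such as Atlantic cod carry several such blocks, which concentrate
nearly all of the genome's population differentiation while the remainder
of the genome behaves as one large outbreeding population.

invLD detects these blocks de novo from a multi-sample VCF and then uses
the called block coordinates to partition every downstream statistic into
in-block and out-of-block components.

## The detection procedure

1. **Site filtering.** Biallelic SNPs only; site quality `QUAL > 30`;
   complete genotyping across all samples; minor allele frequency
   `>= 0.05` computed from called genotypes (`apply_site_filters()`).
   Thresholds are parameters; these defaults are the conventional
   FreeBayes-downstream choices. `Q > 30` is read as the *site* QUAL
   field: variant callers report it for every record, whereas per-genotype
   GQ is not always emitted. Ties at MAF exactly 0.05 are retained (a
   "minimum" is inclusive).
2. **Stride subsampling.** Every 250th SNP per chromosome in 1-based
   counting (`subsample_snps()`), so a chromosome with $N$ retained SNPs
   contributes $\lfloor N/250 \rfloor$ subset SNPs. All-pairs LD on
   millions of SNPs is quadratic; the stride makes it tractable while
   sampling the chromosome evenly.
3. **Pairwise LD.** For subset SNPs $i, j$, $r^2_{ij}$ is the squared
   Pearson correlation of the diploid dosage vectors (0/1/2 copies of the
   alternate allele) across samples (`pairwise_r2()`). This is composite
   LD on unphased genotypes — with ~30 unrelated diploids no phasing is
   available, and the genotype correlation is the estimator that wording
   such as "correlation between the paired genotypes" describes. It is
   invariant under allele relabeling ($d \mapsto 2 - d$), and squaring
   removes the arbitrary sign.
4. **Mean-r² profile.** Each subset SNP gets the mean of its $r^2$ with
   every other subset SNP on the chromosome (`mean_r2_profile()`).
   Monomorphic-in-sample SNPs have undefined correlations; these are
   excluded from the mean rather than coded 0, which would deflate
   in-block means. For $n$ samples and independent loci the null
   expectation of $r^2$ is $1/(n-1)$ — about 0.033 at $n = 31$ — so an
   in-block SNP correlated with many partners stands far above the
   background.
5. **Block calling.** The block is delimited by the first and last subset
   SNP with mean $r^2 > 0.1$ (strict), and the edges are placed on the
   SNPs *adjacent to* those outermost high-LD SNPs (`call_blocks()`).

### The edge-placement ambiguity

"Adjacent" can mean two things, and both are implemented:

* `adjacent-subset` (default): the neighboring *subset* SNP, one stride
  away. Rationale: the ~250 untested SNPs between a high-LD subset SNP
  and its subset neighbor may themselves be linked, so the conservative
  block includes that interval.
* `adjacent-snp`: the literal neighboring SNP in the full list, one
  position outside the outermost high-LD subset SNP.

The two differ by at most one stride on each side. When no neighbor
exists (the high-LD SNP is first or last on the chromosome) the edge
falls on the high-LD SNP itself.

### Single span versus `max_gap`

By default one block per chromosome spans *all* high-LD subset SNPs, even
across internal runs of sub-threshold SNPs. Real inversion blocks can
contain internal "linkage gaps" — segments of SNPs unlinked to the
arrangement (e.g. recent mutations, or a gap of a couple of megabases as
observed on cod linkage group 2) — and splitting on them would fragment
one biological unit. For general scans `max_gap = k` emits separate
blocks when more than `k` consecutive sub-threshold subset SNPs intervene.

## Block-partitioned differentiation

* **Weir–Cockerham $F_{ST}$** (`wc_fst()`): the two-level
  (population/individual) moment estimator computed from per-population
  allele frequencies and observed heterozygosity, giving per-SNP variance
  components $a$ (among populations), $b$ (among individuals within
  populations), $c$ (within individuals) and
  $\theta = a/(a+b+c)$. Multi-locus means are **ratio-of-sums**,
  $\sum a / \sum(a+b+c)$ — the convention of the classical `wc`
  implementations; an unweighted per-SNP mean is also reported. $\theta$
  can be negative in small samples (that is information, not an error),
  and is undefined when $a+b+c = 0$ (monomorphic across the populations
  compared), in which case the SNP is flagged and excluded from means.
  Exonic SNP subsets follow the block partition: on block chromosomes all
  exonic SNPs, split in/out of block; elsewhere every 10th exonic SNP
  (`exonic_snp_subsets()`).
* **KS contrast** (`fst_distribution_test()`): two-sample two-sided
  Kolmogorov–Smirnov test of in-block versus out-of-block per-SNP
  $\theta$, with undefined values removed first. P-values are reported as
  computed (asymptotic); published bounds like $p < 10^{-10}$ are treated
  as bounds.
* **PCA** (`pca_genotypes()`): samples as observations, dosages as
  variables, centered but not scaled (the `prcomp` default, which the
  dosage scale shares across SNPs). Inside a real inversion block PC1
  separates samples into three clusters — the two arrangement homozygotes
  and the heterozygotes in between.
* **Block genotypes** (`assign_block_genotypes()`): one-dimensional
  3-means clustering of the in-block PC1 scores, clusters ordered by
  center and labeled AA/AB/BB with AB in the middle. The A/B orientation
  is arbitrary (PCA sign indeterminacy). The k-means initialization is
  deterministic (min/median/max of the scores). If the scores do not
  support three distinguishable clusters (relative center separation
  below $10^{-6}$ of the score range, or fewer than three distinct
  values), every sample is flagged `unassigned` rather than forced into a
  cluster.

## Annotation statistics

SNPs are classified exon > intron > intergenic by interval overlap
(`classify_snps()`; exon status wins across overlapping genes); the three
classes always partition the SNP set. Density (`snp_density()`) is SNPs
per base over a 1-based inclusive span; enrichment
(`enrichment_ratio()`) is the percent change of an in-block proportion or
density over its genome-wide baseline, rounded to integer percent for
reporting. Gene membership in a block defaults to any-overlap (≥ 1 base);
containment is a flag, since "within the boundaries" does not define
partial overlap.

GO enrichment (`go_fisher_enrichment()`) is a per-term one-sided Fisher
exact test over the background gene set with Benjamini–Hochberg
correction. This is a deliberate simplification relative to
ontology-graph algorithms (such as topGO's weight01): terms are taken as
given from a flat two-column gene-to-term map, with no DAG propagation or
decorrelation, so nested terms share genes and produce correlated
p-values. Published tables produced with graph-aware algorithms are
therefore a structural template for the output, not a numeric target.

## The synthetic-data generator

`simulate_dataset()` emits VCF + GFF3 + population map + truth file for a
single chromosome carrying one inversion-like block:

* each diploid receives two arrangement haplotypes, Bernoulli in the
  per-population arrangement-B frequency;
* *arrangement-linked* in-block SNPs (fraction `linked_fraction`,
  default 0.9) are fully determined by the arrangement — fixed allelic
  differences, complete mutual LD;
* *in-block unlinked* SNPs get independent draws at MAF just above the
  floor (`U(0.05, 0.10)`), emulating recent mutations inside an old
  inversion; at 20–31 samples a fair share of these fall below the MAF
  filter, as recent rare variants do;
* *background* SNPs come from a haplotype-copying chain over a founder
  pool (20 founders, per-SNP switch probability 0.1): short-range LD that
  decays to independence at stride spacing, and a realized population
  frequency equal to the founder-pool frequency (recorded as the truth).
  A copying chain was chosen over a coalescent simulator because it is
  seconds-fast, seed-deterministic, dependency-free, and produces exactly
  the two LD regimes the method distinguishes;
* SNP density inside the block is `density_multiplier_block` (default
  1.4, the order of in-block density elevation seen in real supergenes)
  times the background density; genes are non-overlapping with exon
  sub-intervals, and in-block genes get a higher exonic fraction (0.45 vs
  0.30) to plant the exonic-proportion enrichment;
* output is byte-deterministic given the seed.

Defaults mirror the motivating study design: three populations of
11/10/10 diploids (31 samples), arrangement frequencies 0.5/0.85/0.15,
block spanning ~9% of a 1 Mb chromosome (~12% of SNPs after the density
multiplier).

What the generator does **not** emulate: demography (migration, growth,
admixture), selection dynamics, linked selection outside the inversion,
genotyping error and missingness structure, multi-allelic sites, and
LD decay profiles calibrated to a real recombination map. Passing
parameter-recovery tests therefore demonstrates correctness of the
statistical machinery under the model's assumptions, not performance on
any particular real dataset.

## Operating characteristics and problem sizes

The block-calling threshold 0.1 must be read against the null mean
$r^2 \approx 1/(n-1)$:

* at $n = 31$ the threshold is ~3× the null and calling is robust across
  a wide range of block sizes;
* at $n = 20$ the null is 0.053 and the threshold is only ~2× the null.
  Two failure modes then bound the geometry: if the arrangement-linked
  subset SNPs are too few, their mean $r^2$ (≈ their share of subset
  partners) hovers at the threshold; if they are too many, a background
  SNP that correlates with the arrangement by chance (null
  $r^2 \sim \mathrm{Beta}(\tfrac12, \tfrac{n-2}{2})$) can drag its mean
  over the threshold and extend an edge. With ~200 subset SNPs the
  stable operating point is ~15 linked subset SNPs; the two-population
  validation datasets are sized accordingly (50k SNPs, block = 6.1% of
  the chromosome), and even there a few-percent chance of a marginal
  miscall per dataset remains — an honest property of the method at 20
  samples, not of the implementation.

Validation problem sizes (chosen to exercise each property at sufficient
statistical resolution while keeping the whole suite in the order of a
minute): null-LD level at 31 samples with ~270 background subset SNPs;
planted-block recovery over 5 seeds at 50k SNPs and 20 samples;
Weir–Cockerham oracle equivalence on 1,000 random tables; parameter
recovery over 300 replicate datasets (per-dataset $\theta$ at
$n = 10+10$ has sampling sd ≈ 0.17 — an inversion gives one effective
arrangement table per dataset — so ~300 replicates are needed to pin the
mean within ±0.01); KS contrast at ~2,400 SNPs per group.

## Numerical choices

* $r^2$ is clamped into $[0, 1]$ against floating-point excursions;
  diagonal fixed at 1.
* Mean $\theta$ ratio-of-sums excludes SNPs with undefined components.
* Undefined KS inputs are removed before testing; empty groups are fatal
  with context rather than silently returning NA.
* BED output converts 1-based inclusive spans to 0-based half-open;
  re-reading and converting back is exact.
* All simulation randomness flows from one `set.seed(seed)` call per
  dataset; identical configs produce byte-identical files.

## Limitations

* Composite (dosage) $r^2$, not haplotype $r^2$: with unphased data the
  two differ, especially under inbreeding or strong HWE departures.
* The mean-$r^2$ edge rule resolves block edges to about one stride
  (~250 SNPs); sub-stride resolution would require densifying the scan
  near candidate edges.
* Threshold 0.1 is calibrated for ~30 samples; smaller cohorts need a
  larger threshold-to-null ratio (or more subset SNPs) for stable edges.
* Flat Fisher/BH GO enrichment inherits term correlation from the
  ontology; strongly nested significant terms should be interpreted as
  one signal.
* The three-cluster genotype assignment presumes an inversion-like block;
  applied to a region without arrangement structure it returns
  `unassigned` or meaningless clusters by design.
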