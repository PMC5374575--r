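# invLD

Detection of inversion-like linkage disequilibrium (LD) blocks —
"supergenes" — from multi-sample SNP genotypes, and block-partitioned
analysis of population differentiation.

## The problem

Chromosomal inversions suppress recombination between their two
arrangements, so the SNPs inside the inverted segment travel together as a
megabase-scale block of strong mutual LD. In species such as Atlantic cod
these blocks carry essentially all of the genome's population
differentiation: arrangement frequencies differ among spawning
populations while the rest of the genome looks like one outbreeding pool.
Finding the blocks — with base-pair coordinates rather than genetic-map
units — and then splitting every statistic into in-block and
out-of-block parts is the analysis this package implements, for
population geneticists working from a VCF, gene models (GFF3) and a
sample-to-population map.

## Method at its core

* **Scan**: every 250th SNP per chromosome; pairwise
  *r*² = squared Pearson correlation of diploid dosage vectors; per-SNP
  mean *r*² over all other subset SNPs. Independent loci give mean
  *r*² ≈ 1/(*n*−1) (≈ 0.033 at *n* = 31), so a non-recombining block
  stands out sharply above the background.
* **Call**: block edges on the SNPs adjacent to the first and last subset
  SNP with mean *r*² > 0.1 (both readings of "adjacent" implemented;
  default: the neighboring subset SNP).
* **Partition**: Weir–Cockerham *F*<sub>ST</sub> (variance components
  *a*, *b*, *c*; θ = *a*/(*a*+*b*+*c*); multi-locus means as
  Σ*a*/Σ(*a*+*b*+*c*)), Kolmogorov–Smirnov contrasts of in- versus
  out-of-block θ distributions, PCA of dosages, 3-means block-genotype
  assignment (AA/AB/BB along PC1), SNP class (exon/intron/intergenic) and
  density enrichment, in-block gene content, Fisher + Benjamini–Hochberg
  GO enrichment.
* **Simulate**: a seed-deterministic generator of inversion-polymorphism
  datasets (VCF + GFF3 + popmap + machine-readable truth) used by the
  test suite for parameter recovery.

See `vignettes/inversion-ld-blocks.Rmd` for the full model description,
parameter rationale and limitations.

## Worked example

Simulate a study-sized dataset (3 populations, 31 diploids, one planted
block at 455,001–544,000 on a 1 Mb chromosome) and run the core scan:

```r
library(invLD)

cfg <- sim_config(seed = 1)
ds  <- simulate_dataset(cfg, "demo")

gm   <- apply_site_filters(read_vcf_genotypes(ds$vcf))
#> apply_site_filters: 0 failed QUAL > 30; 0 incomplete; 395 below MAF 0.05;
#>   retained 4152/4547
prof <- ld_profile(gm, "LG_sim1", stride = 25)
#> ld_profile: LG_sim1 - 166 subset SNPs (stride 25) of 4152 SNPs
#>   mean r2: median 0.0333  max 0.144

blocks <- call_blocks(prof)
blocks[, c("start", "end", "n_strongly_linked", "n_subset_in_block")]
#>    start    end n_strongly_linked n_subset_in_block
#> 1 452346 541699                19                22
```

The background mean *r*² sits at the 1/(*n*−1) = 0.033 null, and the
called block (452,346–541,699) recovers the planted span to within one
stride. Differentiation then splits cleanly at the block boundary:

```r
pm   <- read_population_map(ds$popmap)
inb  <- which(gm$snps$pos >= blocks$start & gm$snps$pos <= blocks$end)
f_in  <- wc_fst(gm, pm, pair = c("winter", "georges"), snp_set = inb)
#> mean theta (ratio of sums): 0.1702
f_out <- wc_fst(gm, pm, pair = c("winter", "georges"),
                snp_set = setdiff(seq_len(nrow(gm$snps)), inb))
#> mean theta (ratio of sums): -0.0008709
fst_distribution_test(f_in$per_snp$theta, f_out$per_snp$theta)
#> KS two-sided: D = 0.8811 , p = 0 (n = 526 vs 3625)

table(assign_block_genotypes(gm, blocks[1, ], prof)$class)
#>  AA  AB  BB unassigned
#>   6  16   9          0
```

In-block θ ≈ 0.17 against a background indistinguishable from zero
(slightly negative θ is legal small-sample output of the estimator), and
the three PC1 clusters recover every individual's arrangement genotype.

`run_pipeline(run_config(...))` chains all stages and writes TSV tables
plus a JSON manifest; `inst/cli/invld` exposes the same stages as shell
subcommands (`simulate`, `scan-ld`, `fst`, `annotate`, `run-all`).

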