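# Weir-Cockerham F_ST, KS contrasts, PCA, block-genotype assignment

test_that("vectorized WC components match the scalar oracle", {
  set.seed(31)
  pf2 <- factor(rep(c("a", "b"), times = c(8, 12)))
  pf3 <- factor(rep(c("a", "b", "c"), times = c(7, 6, 9)))
  for (i in 1:200) {
    d2 <- matrix(rbinom(20, 2, runif(1, 0.05, 0.95)), 1)
    d3 <- matrix(rbinom(22, 2, runif(1, 0.05, 0.95)), 1)
    expect_equal(wc_components(d2, pf2)$theta,
                 oracle_wc_theta(d2[1, ], as.character(pf2)),
                 tolerance = 1e-12)
    expect_equal(wc_components(d3, pf3)$theta,
                 oracle_wc_theta(d3[1, ], as.character(pf3)),
                 tolerance = 1e-12)
  }
})

test_that("theta hits the boundary cases of differentiation", {
  pf <- factor(rep(c("a", "b"), each = 10))
  # fixed for alternative alleles -> complete differentiation
  expect_equal(wc_components(matrix(rep(c(0, 2), each = 10), 1), pf)$theta, 1)
  # identical genotype tables in the two populations -> estimator at or
  # below zero
  g <- c(0, 1, 2, 1, 0, 2, 1, 1, 0, 2)
  expect_lte(wc_components(matrix(c(g, g), 1), pf)$theta, 1e-12)
  # monomorphic across both populations -> undefined, flagged
  expect_true(is.na(wc_components(matrix(0, 1, 20), pf)$theta))
})

test_that("theta is invariant under allele relabeling", {
  set.seed(5)
  pf <- factor(rep(c("a", "b"), each = 10))
  d <- matrix(rbinom(50 * 20, 2, 0.4), 50, 20)
  expect_equal(wc_components(d, pf)$theta, wc_components(2 - d, pf)$theta)
})

test_that("wc_fst aggregates by ratio of sums and flags undefined sites", {
  set.seed(17)
  d <- rbind(matrix(rbinom(5 * 20, 2, 0.5), 5, 20), rep(0L, 20))
  gm <- make_gm(d)
  pm <- make_popmap(gm)
  ft <- wc_fst(gm, pm)
  expect_equal(ft$n_snps, 6)
  expect_equal(ft$n_defined, 5)
  ok <- !is.na(ft$per_snp$theta)
  expect_equal(ft$mean_theta,
               sum(ft$per_snp$a[ok]) /
                 sum(ft$per_snp$a[ok] + ft$per_snp$b[ok] + ft$per_snp$c[ok]))
  # negative mean theta is legal small-sample output
  expect_true(is.finite(ft$mean_theta))
  expect_error(wc_fst(gm, pm, pair = c("p1", "nope")), "absent")
})

test_that("in-block theta is recovered and the background stays at zero", {
  # across-seed mean of per-dataset ratio-of-sums theta vs the MC oracle
  ths <- outs <- numeric(40)
  for (s in seq_len(40)) {
    ds <- micro_sim(seed = s)
    gm <- suppressMessages(apply_site_filters(truth_genotype_matrix(ds)))
    pm <- read_population_map(ds$popmap)
    tr <- ds$truth$snp
    lnk <- which(gm$snps$pos %in% tr$pos[tr$class == "linked"])
    bgs <- which(gm$snps$pos %in% tr$pos[tr$class == "background"])
    ths[s] <- wc_fst(gm, pm, snp_set = lnk)$mean_theta
    outs[s] <- wc_fst(gm, pm, snp_set = bgs)$mean_theta
  }
  # oracle evaluated at the planted per-population linked-SNP frequencies
  e <- oracle_at_planted(micro_sim(seed = 1), seed = 1)
  # per-dataset theta has sd ~0.17 (one arrangement table per dataset), so
  # 40 seeds bound the mean to +-0.08 at ~3 se
  expect_lt(abs(mean(ths) - as.numeric(e)), 0.08)
  expect_lt(abs(mean(outs)), 0.01)
})

test_that("equal arrangement frequencies leave no in-block differentiation", {
  ths <- sapply(1:5, function(s) {
    ds <- micro_sim(seed = 100 + s,
                    arrangement_freq = c(p1 = 0.5, p2 = 0.5))
    gm <- suppressMessages(apply_site_filters(truth_genotype_matrix(ds)))
    pm <- read_population_map(ds$popmap)
    tr <- ds$truth$snp
    lnk <- which(gm$snps$pos %in% tr$pos[tr$class == "linked"])
    wc_fst(gm, pm, snp_set = lnk)$mean_theta
  })
  expect_lt(abs(mean(ths)), 0.05)
})

test_that("KS comparison handles identity, disjoint supports and filtering", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  same <- fst_distribution_test(x, x)
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  disj <- fst_distribution_test(rep(0.9, 50), rep(0, 50))
  expect_equal(disj$D, 1)
  with_na <- fst_distribution_test(c(x, NA), x)
  expect_equal(with_na$n_in, 4)
  expect_error(fst_distribution_test(NA_real_, x), "empty")
})

test_that("genotype PCA centers dosages and orders variance", {
  set.seed(23)
  gm <- make_gm(matrix(rbinom(40 * 12, 2, 0.5), 40, 12))
  p <- pca_genotypes(gm)
  expect_equal(colMeans(p$scores), rep(0, ncol(p$scores)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  # identical samples -> all scores zero
  gm0 <- make_gm(matrix(rep(c(0L, 1L, 2L), each = 8), 3, 8, byrow = TRUE))
  expect_equal(max(abs(pca_genotypes(gm0)$scores)), 0)
  # sample reordering permutes scores (up to component sign)
  perm <- sample(12)
  p2 <- pca_genotypes(subset_genotypes(gm, samples = gm$samples[perm]))
  for (k in 1:3)
    expect_equal(abs(p2$scores[gm$samples, k]), abs(p$scores[, k]))
})

test_that("in-block PCA separates the three arrangement genotypes;
           out-of-block SNPs do not", {
  ds <- small_sim(seed = 2)
  gm <- suppressMessages(apply_site_filters(read_vcf_genotypes(ds$vcf)))
  cfg <- ds$config
  inb <- which(gm$snps$pos >= cfg$block_start & gm$snps$pos <= cfg$block_end)
  outb <- setdiff(seq_len(nrow(gm$snps)), inb)
  arr <- ds$truth$arrangement_dosage[gm$samples]
  sep <- function(sc) {       # between-cluster gap minus within-cluster spread
    ctr <- tapply(sc, arr, mean)
    within <- max(tapply(sc, arr, function(x) diff(range(x))))
    min(diff(sort(ctr))) - within
  }
  pc1_in <- pca_genotypes(gm, inb)$scores[, 1]
  pc1_out <- pca_genotypes(gm, outb)$scores[, 1]
  expect_gt(sep(pc1_in), 0)            # clean three-cluster separation
  expect_lt(sep(pc1_out), 0)           # no arrangement signal outside
  # heterozygotes sit between the homozygote clusters on PC1
  ctr <- tapply(pc1_in, arr, mean)
  expect_true(ctr["1"] > min(ctr[c("0", "2")]) &&
                ctr["1"] < max(ctr[c("0", "2")]))
})

test_that("block genotypes are assigned by 3-means on PC1 with AB middle", {
  ds <- small_sim(seed = 4)
  gm <- suppressMessages(apply_site_filters(read_vcf_genotypes(ds$vcf)))
  prof <- ld_profile(gm, ds$config$chrom, stride = 25, keep_r2 = FALSE)
  blk <- call_blocks(prof)
  out <- assign_block_genotypes(gm, blk[1, ], prof)
  expect_s3_class(out, "block_genotypes")
  expect_equal(assignment_accuracy(out, ds$truth$arrangement_dosage), 1)
  # AB is the middle cluster on PC1
  med <- tapply(out$pc1, out$class, mean)
  expect_true(med["AB"] > min(med[c("AA", "BB")]) &&
                med["AB"] < max(med[c("AA", "BB")]))
})

test_that("degenerate score distributions leave samples unassigned", {
  # all samples identical inside the "block": PCA scores all zero
  d <- matrix(rep(c(0L, 1L, 2L, 1L), each = 10), 4, 10, byrow = TRUE)
  gm <- make_gm(d, pos = c(100L, 200L, 300L, 400L))
  blk <- list(chrom = "chrA", start = 50, end = 450)
  out <- assign_block_genotypes(gm, blk)
  expect_true(all(out$class == "unassigned"))
})

test_that("exonic subsets split block chromosomes and stride the rest", {
  d <- matrix(rbinom(12 * 6, 2, 0.5), 12, 6)
  gm <- make_gm(d, pos = rep(c(10L, 20L, 30L, 40L, 50L, 60L), 2),
                chrom = rep(c("c1", "c2"), each = 6))
  classes <- factor(rep("exon", 12), levels = c("exon", "intron",
                                                "intergenic"))
  blocks <- data.frame(chrom = "c1", start = 15, end = 45)
  ss <- exonic_snp_subsets(gm, classes, blocks, stride_genome = 2)
  expect_equal(gm$snps$pos[ss$in_block$c1], c(20L, 30L, 40L))
  expect_equal(gm$snps$pos[ss$out_block$c1], c(10L, 50L, 60L))
  # every 2nd exonic SNP on the non-block chromosome
  expect_equal(gm$snps$pos[ss$genome], c(20L, 40L, 60L))
})

test_that("the MC oracle behaves at its own boundary cases", {
  e0 <- expected_wc_fst_oracle(c(0.4, 0.4), c(10, 10), reps = 3000, seed = 2)
  expect_lt(abs(as.numeric(e0)), 3 * attr(e0, "se") + 0.01)
  e1 <- expected_wc_fst_oracle(c(0, 1), c(10, 10), reps = 100, seed = 2)
  expect_equal(as.numeric(e1), 1)
  # self-consistency across seeds, within Monte-Carlo error
  ea <- expected_wc_fst_oracle(c(0.9, 0.1), c(10, 10), reps = 8000, seed = 3)
  eb <- expected_wc_fst_oracle(c(0.9, 0.1), c(10, 10), reps = 8000, seed = 4)
  se <- sqrt(attr(ea, "se")^2 + attr(eb, "se")^2)
  expect_lt(abs(as.numeric(ea) - as.numeric(eb)), 4 * se)
  expect_error(expected_wc_fst_oracle(c(0.5, 0.5), c(10, 10), reps = 0),
               "reps")
})
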