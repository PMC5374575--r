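# In-code fixtures shared across test files.

# small genotype matrix built directly from a dosage matrix
make_gm <- function(dosage, pos = NULL, chrom = "chrA", qual = 60) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage)
  if (is.null(pos)) pos <- seq_len(n) * 10L
  snps <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "C",
                     qual = qual, stringsAsFactors = FALSE)
  samples <- sprintf("s%02d", seq_len(ncol(dosage)))
  genotype_matrix(snps, samples, dosage)
}

# popmap data.frame for a gm whose samples split into equal halves
make_popmap <- function(gm, labels = c("p1", "p2")) {
  n <- length(gm$samples)
  data.frame(sample_id = gm$samples,
             population = rep(labels, length.out = n,
                              each = ceiling(n / length(labels)))[seq_len(n)],
             stringsAsFactors = FALSE)
}

# ld_profile object built from a given mean_r2 vector (for call_blocks tests)
make_profile <- function(mean_r2, stride = 10, chrom = "chrA") {
  m <- length(mean_r2)
  all_pos <- seq_len(m * stride) * 100L     # dense, evenly spaced
  subset_pos <- all_pos[seq_len(m) * stride]
  structure(list(chrom = chrom, stride = stride,
                 subset_idx = seq_len(m) * stride - 1L,
                 subset_pos = subset_pos, mean_r2 = mean_r2, r2 = NULL,
                 n_chrom_snps = length(all_pos), all_pos = all_pos),
            class = "ld_profile")
}

# default study conditions (3 populations, 31 diploids, ~4500 SNPs;
# stable block calling at stride 25)
small_sim <- function(seed = 1, dir = tempfile(), ...) {
  simulate_dataset(sim_config(seed = seed, ...), dir)
}

# micro simulation for statistical replicate studies (no block calling)
micro_sim <- function(seed = 1, dir = tempfile(),
                      arrangement_freq = c(p1 = 0.3, p2 = 0.7), ...) {
  cfg <- sim_config(seed = seed, pops = c(p1 = 10L, p2 = 10L),
                    arrangement_freq = arrangement_freq,
                    chrom_length = 2e5, block = c(94001, 107000),
                    n_snps_background = 900, gene_count = 20, ...)
  simulate_dataset(cfg, dir)
}

# MC-oracle expectation evaluated at the mean planted frequencies of the
# arrangement-linked SNPs of a dataset
oracle_at_planted <- function(ds, reps = 20000, seed = 77) {
  lnk <- ds$truth$snp$class == "linked"
  f <- colMeans(ds$truth$freq_by_pop[lnk, , drop = FALSE])
  expected_wc_fst_oracle(f, unname(ds$config$pops), reps = reps,
                         seed = seed)
}

# the planted-block recovery conditions: 2 pops x 10, ~50k SNPs, one block
# spanning 6.1% of the chromosome (~15 arrangement-linked subset SNPs at
# stride 250, the stable operating point for 20 samples)
recovery_sim <- function(seed, dir = tempfile()) {
  cfg <- sim_config(seed = seed, pops = c(p1 = 10L, p2 = 10L),
                    arrangement_freq = c(p1 = 0.3, p2 = 0.7),
                    chrom_length = 5e6, block = c(2347501, 2652500),
                    n_snps_background = 45900)
  simulate_dataset(cfg, dir)
}

# index (rank in the filtered SNP list) of the SNP nearest a position
snp_index_of <- function(gm, p) which.min(abs(gm$snps$pos - p))

# accuracy of AA/AB/BB calls against 0/1/2 arrangement dosages, allowing
# the arbitrary A/B orientation flip
assignment_accuracy <- function(assign, truth_dosage) {
  cls <- match(as.character(assign$class), c("AA", "AB", "BB")) - 1L
  truth <- truth_dosage[assign$sample_id]
  if (anyNA(cls)) return(0)
  max(mean(cls == truth), mean((2L - cls) == truth))
}
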