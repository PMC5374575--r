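# Independent scalar oracles, kept free of any R/ code path they check.

# Weir-Cockerham theta for one biallelic locus, brute-force transcription of
# the two-level variance-component formulas from per-population genotype
# counts.  `dosage`: vector of 0/1/2; `pop`: parallel vector of labels.
oracle_wc_theta <- function(dosage, pop) {
  labs <- unique(pop)
  r <- length(labs)
  n <- p <- h <- numeric(r)
  for (i in seq_len(r)) {
    d <- dosage[pop == labs[i]]
    n[i] <- length(d)
    p[i] <- sum(d) / (2 * length(d))
    h[i] <- sum(d == 1) / length(d)
  }
  nbar <- sum(n) / r
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  hbar <- sum(n * h) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  a <- (nbar / nc) *
    (s2 - 1 / (nbar - 1) *
       (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# naive linear-scan SNP classifier: checks every exon, then every gene
oracle_classify <- function(pos, chrom, genes) {
  vapply(seq_along(pos), function(i) {
    e <- genes$exons
    for (j in seq_len(nrow(e)))
      if (e$chrom[j] == chrom[i] && pos[i] >= e$start[j] &&
          pos[i] <= e$end[j]) return("exon")
    g <- genes$genes
    for (j in seq_len(nrow(g)))
      if (g$chrom[j] == chrom[i] && pos[i] >= g$start[j] &&
          pos[i] <= g$end[j]) return("intron")
    "intergenic"
  }, character(1))
}
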