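#' Configuration for the inversion-polymorphism simulator
#'
#' Defines one chromosome carrying a single non-recombining block (the
#' inversion) embedded in a recombining neutral background.  Each diploid
#' individual receives two arrangement haplotypes (A = standard,
#' B = inverted), Bernoulli in the per-population arrangement frequency.
#' SNP classes:
#'
#' * *arrangement-linked* in-block SNPs: the haplotype allele is fully
#'   determined by the arrangement (fixed allelic differences between the
#'   two arrangement classes), so linked SNPs are in complete mutual LD;
#' * *in-block unlinked* SNPs: independent low-MAF draws, the signature of
#'   recent mutations inside an old inversion;
#' * *background* SNPs: a haplotype-copying chain over a founder haplotype
#'   pool with per-SNP switch probability `background_ld_decay`, giving
#'   short-range LD that decays to independence at stride spacing.
#'
#' @param seed RNG seed; output is byte-deterministic given the seed.
#' @param pops named integer vector, individuals per population (default
#'   the 31-sample, three-population study design: 11/10/10).
#' @param chrom chromosome name in the emitted files.
#' @param chrom_length chromosome length in bases.
#' @param n_snps_background number of background SNPs (outside the block).
#' @param block length-2 vector `c(start, end)`, 1-based inclusive planted
#'   block span.
#' @param n_snps_block number of in-block SNPs; `NULL` (default) derives it
#'   from `density_multiplier_block` times the background density.
#' @param density_multiplier_block in-block SNP density relative to
#'   background (default 1.4, the order of in-block density elevation seen
#'   in real inversion supergenes).
#' @param arrangement_freq named per-population frequency of arrangement B.
#' @param linked_fraction fraction of in-block SNPs fully linked to the
#'   arrangement (default 0.9: inside a non-recombining inversion all but
#'   the recent mutations are in complete association with the
#'   arrangement).
#' @param background_ld_decay per-SNP probability that a background
#'   haplotype switches its founder template (default 0.1).
#' @param n_founders founder haplotypes in the background copying pool.
#' @param maf_floor minimum planted minor allele frequency (default 0.05).
#' @param qual constant site QUAL written to the VCF (default 60, passing
#'   the default `Q > 30` filter; lower it to exercise the filter).
#' @param gene_count number of non-overlapping genes in the toy GFF.
#' @param exon_fraction fraction of a gene's span covered by exons outside
#'   the block (default 0.3).
#' @param exon_fraction_block exon fraction for genes inside the block
#'   (default 0.45, planting the elevated in-block exonic proportion).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       pops = c(spring = 11L, winter = 10L, georges = 10L),
                       chrom = "LG_sim1",
                       chrom_length = 1e6,
                       n_snps_background = 4000,
                       block = c(455001, 544000),
                       n_snps_block = NULL,
                       density_multiplier_block = 1.4,
                       arrangement_freq = c(spring = 0.5, winter = 0.85,
                                            georges = 0.15),
                       linked_fraction = 0.9,
                       background_ld_decay = 0.1,
                       n_founders = 20,
                       maf_floor = 0.05,
                       qual = 60,
                       gene_count = 60,
                       exon_fraction = 0.3,
                       exon_fraction_block = 0.45) {
  cfg <- list(seed = as.integer(seed), pops = pops, chrom = chrom,
              chrom_length = as.integer(chrom_length),
              n_snps_background = as.integer(n_snps_background),
              block_start = as.integer(block[1]),
              block_end = as.integer(block[2]),
              density_multiplier_block = density_multiplier_block,
              arrangement_freq = arrangement_freq,
              linked_fraction = linked_fraction,
              background_ld_decay = background_ld_decay,
              n_founders = as.integer(n_founders),
              maf_floor = maf_floor, qual = qual,
              gene_count = as.integer(gene_count),
              exon_fraction = exon_fraction,
              exon_fraction_block = exon_fraction_block)
  if (is.null(n_snps_block)) {
    blen <- cfg$block_end - cfg$block_start + 1
    dens <- n_snps_background / (chrom_length - blen)
    n_snps_block <- round(density_multiplier_block * dens * blen)
  }
  cfg$n_snps_block <- as.integer(n_snps_block)
  with(cfg, {
    stopifnot(block_start >= 1, block_start < block_end,
              block_end <= chrom_length,
              all(arrangement_freq >= 0), all(arrangement_freq <= 1),
              linked_fraction >= 0, linked_fraction <= 1,
              maf_floor > 0, maf_floor < 0.5,
              all(names(pops) %in% names(arrangement_freq)))
  })
  if (cfg$n_snps_block > cfg$block_end - cfg$block_start + 1)
    stop("infeasible config: more in-block SNPs than block bases")
  if (cfg$n_snps_background > cfg$chrom_length -
      (cfg$block_end - cfg$block_start + 1))
    stop("infeasible config: more background SNPs than background bases")
  structure(cfg, class = "sim_config")
}

#' Simulate an inversion-polymorphism dataset
#'
#' Generates a VCF 4.2 (biallelic SNP genotypes for all individuals), a toy
#' GFF3 of non-overlapping genes with exon sub-intervals, a two-column
#' population map, and a machine-readable truth file recording the planted
#' block coordinates, per-sample arrangement genotypes, per-SNP truth class
#' and planted per-population allele frequencies, and per-SNP genomic class.
#' Output is deterministic given `cfg$seed`: the same configuration always
#' produces byte-identical files.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix (default `"sim"`).
#' @return list of class `sim_dataset`: file paths (`vcf`, `gff`, `popmap`,
#'   `truth_json`, `manifest`) plus the in-memory `truth` (class
#'   `sim_truth`) and the `config`.
#' @export
simulate_dataset <- function(cfg, dir, prefix = "sim") {
  stopifnot(inherits(cfg, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(cfg$seed)

  n_ind <- sum(cfg$pops)
  pop_of <- rep(names(cfg$pops), cfg$pops)
  sample_ids <- sprintf("%s_%02d", pop_of,
                        unlist(lapply(cfg$pops, seq_len)))

  ## --- SNP positions -----------------------------------------------------
  blen <- cfg$block_end - cfg$block_start + 1L
  # background: uniform without replacement over the block complement
  out_len <- cfg$chrom_length - blen
  pos_bg <- sort(sample.int(out_len, cfg$n_snps_background))
  shift <- pos_bg >= cfg$block_start
  pos_bg[shift] <- pos_bg[shift] + blen
  pos_blk <- sort(sample.int(blen, cfg$n_snps_block)) + cfg$block_start - 1L

  n_linked <- round(cfg$linked_fraction * cfg$n_snps_block)
  blk_class <- rep("inblock_unlinked", cfg$n_snps_block)
  blk_class[sample.int(cfg$n_snps_block, n_linked)] <- "linked"

  pos <- c(pos_bg, pos_blk)
  class <- c(rep("background", cfg$n_snps_background), blk_class)
  ord <- order(pos)
  pos <- pos[ord]; class <- class[ord]
  S <- length(pos)

  ## --- arrangement genotypes --------------------------------------------
  fB <- cfg$arrangement_freq[pop_of]
  hapB1 <- stats::rbinom(n_ind, 1, fB)
  hapB2 <- stats::rbinom(n_ind, 1, fB)
  arr_dosage <- hapB1 + hapB2   # copies of arrangement B per individual

  ## --- per-SNP planted allele frequencies -------------------------------
  is_lnk <- class == "linked"
  is_ubk <- class == "inblock_unlinked"
  is_bg <- class == "background"
  # linked SNPs are fully correlated with the arrangement: fixed allelic
  # differences between the two arrangement haplotype classes
  pA <- pB <- p_neutral <- rep(NA_real_, S)
  pA[is_lnk] <- 0
  pB[is_lnk] <- 1
  p_neutral[is_ubk] <- stats::runif(sum(is_ubk), cfg$maf_floor,
                                    2 * cfg$maf_floor)
  p_neutral[is_bg] <- stats::runif(sum(is_bg), cfg$maf_floor,
                                   1 - cfg$maf_floor)

  ## --- haplotype alleles -------------------------------------------------
  # one shared founder haplotype pool for the background copying chain
  nb <- sum(is_bg)
  founders <- if (nb > 0)
    matrix(stats::rbinom(nb * cfg$n_founders, 1, p_neutral[is_bg]),
           nb, cfg$n_founders)
  hap_alleles <- function(arrB) {   # arrB: 0/1 per individual, one haplotype
    a <- matrix(0L, S, n_ind)
    if (any(is_lnk)) {
      pm <- matrix(ifelse(rep(arrB, each = sum(is_lnk)) == 1,
                          pB[is_lnk], pA[is_lnk]), sum(is_lnk), n_ind)
      a[is_lnk, ] <- stats::rbinom(length(pm), 1, pm)
    }
    if (any(is_ubk))
      a[is_ubk, ] <- stats::rbinom(sum(is_ubk) * n_ind, 1,
                                   p_neutral[is_ubk])
    if (nb > 0) {
      # copying chain: founder index per SNP, switching with prob decay
      for (j in seq_len(n_ind)) {
        sw <- stats::runif(nb) < cfg$background_ld_decay
        sw[1] <- TRUE
        picks <- sample.int(cfg$n_founders, sum(sw), replace = TRUE)
        f <- picks[cumsum(sw)]
        a[is_bg, j] <- founders[cbind(seq_len(nb), f)]
      }
    }
    a
  }
  dosage <- hap_alleles(hapB1) + hap_alleles(hapB2)

  ## planted per-population allele frequencies; background SNPs segregate
  ## at the founder-pool frequency (the realized population frequency the
  ## copying chain samples from), identical across populations
  p_realized <- p_neutral
  if (nb > 0) p_realized[is_bg] <- rowMeans(founders)
  pop_names <- names(cfg$pops)
  freq_pop <- matrix(NA_real_, S, length(pop_names),
                     dimnames = list(NULL, pop_names))
  for (pn in pop_names) {
    f <- cfg$arrangement_freq[[pn]]
    freq_pop[, pn] <- ifelse(is_lnk, (1 - f) * pA + f * pB, p_realized)
  }

  ## --- toy gene models ---------------------------------------------------
  genes <- sim_gene_models(cfg)

  ## genomic truth class via plain interval arithmetic (findInterval),
  ## independent of the package's GenomicRanges-based classifier
  gclass <- rep("intergenic", S)
  gs <- genes$genes
  gi <- findInterval(pos, gs$start)
  in_gene <- gi >= 1 & pos <= gs$end[pmax(gi, 1)]
  gclass[in_gene] <- "intron"
  ex <- genes$exons[order(genes$exons$start), , drop = FALSE]
  ei <- findInterval(pos, ex$start)
  in_exon <- ei >= 1 & pos <= ex$end[pmax(ei, 1)]
  gclass[in_exon] <- "exon"

  ## --- alleles ------------------------------------------------------------
  nuc <- c("A", "C", "G", "T")
  ref <- nuc[sample.int(4, S, replace = TRUE)]
  alt <- vapply(ref, function(r) sample(setdiff(nuc, r), 1), character(1))

  ## --- write files --------------------------------------------------------
  paths <- list(vcf = file.path(dir, paste0(prefix, ".vcf")),
                gff = file.path(dir, paste0(prefix, ".gff3")),
                popmap = file.path(dir, paste0(prefix, ".popmap.tsv")),
                truth_json = file.path(dir, paste0(prefix, ".truth.json")),
                manifest = file.path(dir, paste0(prefix, ".manifest.json")))

  gt_str <- c("0/0", "0/1", "1/1")[dosage + 1L]
  gt <- matrix(gt_str, S, n_ind)
  body <- do.call(paste, c(list(cfg$chrom, pos, ".", ref, alt,
                                format(cfg$qual), "PASS", ".", "GT"),
                           lapply(seq_len(n_ind), function(j) gt[, j]),
                           list(sep = "\t")))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=invLD_simulate_dataset",
               sprintf("##contig=<ID=%s,length=%d>", cfg$chrom,
                       cfg$chrom_length),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sample_ids), collapse = "\t"),
               body), paths$vcf)

  write_sim_gff(genes, cfg, paths$gff)
  writeLines(paste(sample_ids, pop_of, sep = "\t"), paths$popmap)

  truth <- structure(list(
    block = c(start = cfg$block_start, end = cfg$block_end),
    sample_ids = sample_ids,
    population = pop_of,
    arrangement_dosage = stats::setNames(arr_dosage, sample_ids),
    snp = data.frame(chrom = cfg$chrom, pos = pos, class = class,
                     genomic_class = gclass, stringsAsFactors = FALSE),
    freq_by_pop = freq_pop,
    dosage = dosage,
    genes = genes,
    config = unclass(cfg)), class = "sim_truth")

  jsonlite::write_json(list(
    block = as.list(truth$block),
    sample_ids = sample_ids, population = pop_of,
    arrangement_dosage = arr_dosage,
    snp = truth$snp,
    freq_by_pop = as.data.frame(freq_pop),
    config = unclass(cfg)), paths$truth_json, auto_unbox = TRUE, digits = NA)

  jsonlite::write_json(list(seed = cfg$seed, files = paths,
                            n_snps = S, n_samples = n_ind,
                            generated = "invLD simulate_dataset"),
                       paths$manifest, auto_unbox = TRUE)

  structure(c(paths, list(truth = truth, config = cfg)),
            class = "sim_dataset")
}

#' Genotype matrix straight from simulator truth
#'
#' Builds the [genotype_matrix()] the emitted VCF encodes, directly from
#' the truth dosages — convenient for statistical replicate studies where
#' the (separately tested) VCF round trip would dominate the runtime.
#'
#' @param ds a `sim_dataset` from [simulate_dataset()].
#' @return A `genotype_matrix` with the same coordinates, samples and
#'   dosages as `read_vcf_genotypes(ds$vcf)` (allele letters are
#'   placeholders).
#' @export
truth_genotype_matrix <- function(ds) {
  tr <- ds$truth
  snps <- data.frame(chrom = tr$snp$chrom, pos = tr$snp$pos,
                     ref = "N", alt = "N", qual = ds$config$qual,
                     stringsAsFactors = FALSE)
  genotype_matrix(snps, tr$sample_ids, tr$dosage)
}

# non-overlapping genes: one per equal-width bin, exon sub-intervals
# covering ~exon_fraction of the gene span (higher inside the block)
sim_gene_models <- function(cfg) {
  bin <- floor(cfg$chrom_length / cfg$gene_count)
  gene_rows <- vector("list", cfg$gene_count)
  exon_rows <- vector("list", cfg$gene_count)
  for (i in seq_len(cfg$gene_count)) {
    b0 <- (i - 1L) * bin + 1L
    glen <- max(20L, round(bin * stats::runif(1, 0.2, 0.6)))
    gstart <- b0 + sample.int(max(bin - glen, 1L), 1) - 1L
    gend <- min(gstart + glen - 1L, cfg$chrom_length)
    mid <- (gstart + gend) / 2
    efrac <- if (mid >= cfg$block_start && mid <= cfg$block_end)
      cfg$exon_fraction_block else cfg$exon_fraction
    k <- sample.int(3L, 1)
    # k exons, one per equal sub-bin of the gene, total length ~ efrac*glen
    sub <- floor((gend - gstart + 1L) / k)
    elen <- max(1L, floor(efrac * sub))
    es <- gstart + (seq_len(k) - 1L) * sub +
      vapply(seq_len(k), function(x)
        sample.int(max(sub - elen, 1L), 1) - 1L, integer(1))
    ee <- pmin(es + elen - 1L, gend)
    gid <- sprintf("gene%04d", i)
    gene_rows[[i]] <- data.frame(gene_id = gid, chrom = cfg$chrom,
                                 start = gstart, end = gend,
                                 stringsAsFactors = FALSE)
    exon_rows[[i]] <- data.frame(gene_id = gid, chrom = cfg$chrom,
                                 start = es, end = ee,
                                 stringsAsFactors = FALSE)
  }
  structure(list(genes = do.call(rbind, gene_rows),
                 exons = do.call(rbind, exon_rows)),
            class = "gene_models")
}

write_sim_gff <- function(genes, cfg, path) {
  g <- genes$genes
  e <- genes$exons
  glines <- sprintf("%s\tinvLD_sim\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                    g$chrom, g$start, g$end, g$gene_id)
  elines <- sprintf("%s\tinvLD_sim\texon\t%d\t%d\t.\t+\t.\tID=%s.e%d;Parent=%s",
                    e$chrom, e$start, e$end, e$gene_id,
                    stats::ave(seq_len(nrow(e)), e$gene_id,
                               FUN = seq_along),
                    e$gene_id)
  feats <- c(glines, elines)
  starts <- c(g$start, e$start)
  writeLines(c("##gff-version 3",
               sprintf("##sequence-region %s 1 %d", cfg$chrom,
                       cfg$chrom_length),
               feats[order(starts)]), path)
}

#' Monte-Carlo expectation of the Weir-Cockerham estimator
#'
#' Independent oracle for parameter-recovery checks: repeatedly draws
#' genotype tables by binomial sampling at the given per-population allele
#' frequencies (dosage ~ Binomial(2, p), i.e. Hardy-Weinberg within
#' populations), evaluates a scalar transcription of the Weir-Cockerham
#' variance-component formulas on each table, and averages theta over the
#' replicates (undefined replicates are skipped).
#'
#' @param freq_by_pop numeric vector of per-population allele frequencies.
#' @param n_by_pop integer vector of per-population sample sizes
#'   (individuals).
#' @param reps number of Monte-Carlo replicates (default 5000).
#' @param seed RNG seed.
#' @return expected theta (numeric scalar), with attribute `"se"` giving
#'   the Monte-Carlo standard error.
#' @export
expected_wc_fst_oracle <- function(freq_by_pop, n_by_pop, reps = 5000,
                                   seed = 1) {
  stopifnot(length(freq_by_pop) >= 2,
            length(freq_by_pop) == length(n_by_pop))
  if (reps < 1) stop("reps must be >= 1")
  set.seed(seed)
  r <- length(freq_by_pop)
  thetas <- rep(NA_real_, reps)
  for (it in seq_len(reps)) {
    p_i <- h_i <- numeric(r)
    for (k in seq_len(r)) {
      d <- stats::rbinom(n_by_pop[k], 1, freq_by_pop[k]) +
        stats::rbinom(n_by_pop[k], 1, freq_by_pop[k])
      p_i[k] <- mean(d) / 2
      h_i[k] <- mean(d == 1)
    }
    thetas[it] <- wc_theta_scalar(p_i, h_i, n_by_pop)
  }
  ok <- !is.na(thetas)
  structure(mean(thetas[ok]),
            se = stats::sd(thetas[ok]) / sqrt(sum(ok)))
}

# scalar Weir-Cockerham theta from per-population allele frequencies,
# heterozygote proportions and sample sizes (one locus)
wc_theta_scalar <- function(p_i, h_i, n_i) {
  r <- length(n_i)
  n_bar <- mean(n_i)
  n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
  p_bar <- sum(n_i * p_i) / (r * n_bar)
  h_bar <- sum(n_i * h_i) / (r * n_bar)
  s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
       (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}
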