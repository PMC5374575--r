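#' Weir-Cockerham F_ST variance components, vectorized over SNPs
#'
#' Two-level (population / individual) moment estimator for diploid
#' biallelic data, computed from allele frequencies and observed
#' heterozygosity.  For each SNP the components are
#' `a` (among populations), `b` (among individuals within populations) and
#' `c` (within individuals), with `theta = a / (a + b + c)`.  `theta` is
#' undefined (`NA`) when `a + b + c = 0` (e.g. a SNP monomorphic across all
#' populations considered) and may legitimately be negative in small
#' samples.  The estimator is invariant under allele relabeling
#' (`d -> 2 - d`).
#'
#' @param dosage sites x samples matrix of dosages, no missing values.
#' @param pops factor of population labels, one per sample (>= 2 levels,
#'   each with >= 2 individuals).
#' @return data.frame with columns `a`, `b`, `c`, `theta`, one row per SNP.
#' @export
wc_components <- function(dosage, pops) {
  dosage <- as.matrix(dosage)
  pops <- droplevels(as.factor(pops))
  r <- nlevels(pops)
  if (r < 2) stop("need >= 2 populations")
  if (anyNA(dosage)) stop("wc_components requires complete genotypes")
  n_i <- as.vector(table(pops))
  if (any(n_i < 2)) stop("each population needs >= 2 individuals")

  # per-population allele frequency and observed heterozygosity, per SNP
  S <- nrow(dosage)
  p_mat <- matrix(0, S, r)   # p_i
  h_mat <- matrix(0, S, r)   # proportion of heterozygotes
  lev <- levels(pops)
  for (k in seq_len(r)) {
    d <- dosage[, pops == lev[k], drop = FALSE]
    p_mat[, k] <- rowMeans(d) / 2
    h_mat[, k] <- rowMeans(d == 1)
  }

  n_bar <- mean(n_i)
  n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
  w <- n_i / (r * n_bar)
  p_bar <- as.vector(p_mat %*% w)
  h_bar <- as.vector(h_mat %*% w)
  s2 <- as.vector((p_mat - p_bar)^2 %*% n_i) / ((r - 1) * n_bar)

  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
       (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  denom <- a + b + cc
  theta <- ifelse(denom == 0, NA_real_, a / denom)
  data.frame(a = a, b = b, c = cc, theta = theta)
}

#' Per-SNP and mean Weir-Cockerham F_ST between populations
#'
#' Computes the per-SNP variance components and theta for the requested
#' populations (a pair for pairwise tables, or all populations for a global
#' profile), plus the ratio-of-sums mean over the SNP set,
#' `Sum(a) / Sum(a + b + c)` — the conventional multi-locus combination.
#' An unweighted per-SNP average of theta is also reported.
#'
#' @param gm a filtered [genotype_matrix()].
#' @param popmap data.frame from [read_population_map()].
#' @param pair character vector of >= 2 population labels; `NULL` (default)
#'   uses every population in the map.
#' @param snp_set optional integer (1-based row) or logical selection of
#'   SNPs; `NULL` uses all.
#' @return An object of class `fst_table`: list with `pair`, `per_snp`
#'   (data.frame `chrom`, `pos`, `a`, `b`, `c`, `theta`), `mean_theta`
#'   (ratio of sums), `mean_theta_per_snp`, `n_snps`, `n_defined`.
#' @export
wc_fst <- function(gm, popmap, pair = NULL, snp_set = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  pf <- pop_factor(gm, popmap)
  if (is.null(pair)) pair <- levels(pf)
  miss <- setdiff(pair, levels(pf))
  if (length(miss))
    stop("population(s) absent from map: ", paste(miss, collapse = ", "))
  cols <- which(pf %in% pair)
  rows <- if (is.null(snp_set)) seq_len(nrow(gm$snps)) else
    (if (is.logical(snp_set)) which(snp_set) else snp_set)
  if (!length(rows)) stop("empty SNP set")

  comp <- wc_components(gm$dosage[rows, cols, drop = FALSE],
                        droplevels(pf[cols]))
  per_snp <- cbind(gm$snps[rows, c("chrom", "pos")], comp)
  rownames(per_snp) <- NULL
  ok <- !is.na(comp$theta)
  structure(list(pair = pair,
                 per_snp = per_snp,
                 mean_theta = if (any(ok))
                   sum(comp$a[ok]) / sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
                 else NA_real_,
                 mean_theta_per_snp = if (any(ok)) mean(comp$theta[ok])
                 else NA_real_,
                 n_snps = length(rows), n_defined = sum(ok)),
            class = "fst_table")
}

#' @export
print.fst_table <- function(x, ...) {
  cat("fst_table:", paste(x$pair, collapse = " vs "), "-", x$n_snps, "SNPs (",
      x$n_defined, "defined )\n  mean theta (ratio of sums):",
      signif(x$mean_theta, 4), "\n")
  invisible(x)
}

#' Kolmogorov-Smirnov comparison of two F_ST distributions
#'
#' Two-sample, two-sided KS test of the in-block versus out-of-block
#' per-SNP theta distributions.  Undefined (`NA`) values are removed before
#' testing; p-values are reported exactly as computed.
#'
#' @param fst_in,fst_out numeric vectors of per-SNP theta values.
#' @return list of class `ks_comparison`: `D`, `p`, `n_in`, `n_out`.
#' @export
fst_distribution_test <- function(fst_in, fst_out) {
  fst_in <- fst_in[!is.na(fst_in)]
  fst_out <- fst_out[!is.na(fst_out)]
  if (!length(fst_in) || !length(fst_out))
    stop("fst_distribution_test: empty sample after removing undefined values")
  k <- suppressWarnings(stats::ks.test(fst_in, fst_out,
                                       alternative = "two.sided"))
  structure(list(D = unname(k$statistic), p = unname(k$p.value),
                 n_in = length(fst_in), n_out = length(fst_out)),
            class = "ks_comparison")
}

#' @export
print.ks_comparison <- function(x, ...) {
  cat("KS two-sided: D =", signif(x$D, 4), ", p =", format(x$p, digits = 3),
      sprintf("(n = %d vs %d)\n", x$n_in, x$n_out))
  invisible(x)
}

#' PCA of genotype dosages
#'
#' Samples are observations and SNP dosages variables; variables are
#' centered but not scaled (the `prcomp` default).  Constant (zero
#' variance) SNPs contribute nothing after centering and are retained.
#'
#' @param gm a filtered [genotype_matrix()].
#' @param snp_set optional SNP row selection (integer or logical).
#' @return list of class `pca_result`: `scores` (samples x components,
#'   rownames = sample ids), `explained_variance` (proportions,
#'   non-increasing), `sdev`, and `rotation` (SNP loadings).
#' @export
pca_genotypes <- function(gm, snp_set = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (length(gm$samples) < 2) stop("PCA requires >= 2 samples")
  rows <- if (is.null(snp_set)) seq_len(nrow(gm$snps)) else
    (if (is.logical(snp_set)) which(snp_set) else snp_set)
  if (!length(rows)) stop("empty SNP set")
  x <- t(gm$dosage[rows, , drop = FALSE])
  if (anyNA(x)) stop("PCA requires complete genotypes")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2 / sum(p$sdev^2)
  rownames(p$x) <- gm$samples
  structure(list(scores = p$x, explained_variance = ev, sdev = p$sdev,
                 rotation = p$rotation),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", nrow(x$scores), "samples,",
      length(x$explained_variance), "components; PC1",
      sprintf("%.1f%%", 100 * x$explained_variance[1]), "variance\n")
  invisible(x)
}

#' Assign per-sample block genotypes by 3-means clustering of PC1
#'
#' Inside an inversion-like LD block the in-block PCA separates samples into
#' three clusters along component 1, corresponding to the three arrangement
#' genotypes (AA, AB, BB).  This operation performs one-dimensional 3-means
#' clustering of the PC1 scores of the in-block PCA, orders the clusters by
#' center, and labels them AA / AB / BB with AB the middle cluster.  The
#' A/B orientation is arbitrary (PCA sign indeterminacy): AA is the cluster
#' with the lowest PC1 center.
#'
#' When the scores do not support three distinguishable clusters (all
#' samples in one cluster, or fewer than three distinct score values) every
#' sample is flagged `unassigned`.
#'
#' @param gm a filtered [genotype_matrix()].
#' @param block one row of an `ld_blocks` data.frame (needs `chrom`,
#'   `start`, `end`).
#' @param profile optional [ld_profile()] used to check that the block
#'   contains at least 3 strongly linked subset SNPs (precondition of a
#'   meaningful assignment); checked with threshold 0.1 when supplied.
#' @return data.frame of class `block_genotypes`: `sample_id`, `class`
#'   (factor AA/AB/BB/unassigned), `pc1`, `dist_AA`, `dist_AB`, `dist_BB`.
#' @export
assign_block_genotypes <- function(gm, block, profile = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!is.null(profile)) {
    cnt <- count_strongly_linked(profile, block)
    if (cnt[["n_strongly_linked"]] < 3)
      warning("fewer than 3 strongly linked subset SNPs in block; ",
              "assignment may be unreliable")
  }
  inb <- which(gm$snps$chrom == block$chrom &
                 gm$snps$pos >= block$start & gm$snps$pos <= block$end)
  if (!length(inb)) stop("no SNPs inside block span")
  pca <- pca_genotypes(gm, snp_set = inb)
  s <- pca$scores[, 1]

  unassigned <- function() {
    data.frame(sample_id = gm$samples,
               class = factor(rep("unassigned", length(s)),
                              levels = c("AA", "AB", "BB", "unassigned")),
               pc1 = s, dist_AA = NA_real_, dist_AB = NA_real_,
               dist_BB = NA_real_, stringsAsFactors = FALSE)
  }
  if (length(unique(s)) < 3 || stats::sd(s) < sqrt(.Machine$double.eps)) {
    out <- unassigned()
    class(out) <- c("block_genotypes", "data.frame")
    return(out)
  }
  centers <- matrix(c(min(s), stats::median(s), max(s)), ncol = 1)
  km <- stats::kmeans(s, centers = centers)
  ord <- order(km$centers[, 1])
  ctr <- km$centers[ord, 1]
  # degenerate when two cluster centers coincide relative to total spread
  spread <- diff(range(s))
  if (min(diff(ctr)) < 1e-6 * spread) {
    out <- unassigned()
  } else {
    lab <- c("AA", "AB", "BB")[match(km$cluster, ord)]
    d <- abs(outer(s, ctr, "-"))
    out <- data.frame(sample_id = gm$samples,
                      class = factor(lab,
                                     levels = c("AA", "AB", "BB",
                                                "unassigned")),
                      pc1 = s, dist_AA = d[, 1], dist_AB = d[, 2],
                      dist_BB = d[, 3], stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("block_genotypes", "data.frame")
  out
}

#' Select exonic SNP subsets for differentiation analyses
#'
#' Follows the block-partitioned subsetting scheme: on chromosomes carrying
#' a called block, *all* exonic SNPs are used, split into in-block and
#' out-of-block groups; on the remaining chromosomes, every
#' `stride_genome`-th exonic SNP is retained as the genome-wide background.
#'
#' @param gm a filtered [genotype_matrix()].
#' @param classes factor from [classify_snps()] aligned to `gm$snps`.
#' @param blocks an `ld_blocks` data.frame.
#' @param stride_genome stride for off-block-chromosome exonic SNPs
#'   (default 10).
#' @return list with integer row-index vectors: `in_block` (named by
#'   chromosome, a list), `out_block` (list by chromosome), `genome`.
#' @export
exonic_snp_subsets <- function(gm, classes, blocks, stride_genome = 10) {
  stopifnot(length(classes) == nrow(gm$snps))
  exonic <- classes == "exon"
  block_chroms <- unique(blocks$chrom)
  in_block <- list(); out_block <- list()
  for (ch in block_chroms) {
    on_ch <- gm$snps$chrom == ch
    b <- blocks[blocks$chrom == ch, , drop = FALSE]
    inb <- rep(FALSE, nrow(gm$snps))
    for (j in seq_len(nrow(b)))
      inb <- inb | (on_ch & gm$snps$pos >= b$start[j] & gm$snps$pos <= b$end[j])
    in_block[[ch]] <- which(exonic & inb)
    out_block[[ch]] <- which(exonic & on_ch & !inb)
  }
  elsewhere <- which(exonic & !(gm$snps$chrom %in% block_chroms))
  genome <- elsewhere[subsample_snps(length(elsewhere), stride_genome)]
  list(in_block = in_block, out_block = out_block, genome = genome)
}
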