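#' Stride-subsample SNP indices along a chromosome
#'
#' Returns the 1-based row indices of every `stride`-th SNP in 1-based
#' counting, i.e. the `stride`-th, `2*stride`-th, ... SNP.  The result has
#' exactly `floor(n_snps / stride)` elements; a stride larger than the SNP
#' count yields an empty selection.
#'
#' @param n_snps number of SNPs on the chromosome.
#' @param stride subsampling stride (default 250).
#' @return integer vector of 1-based indices into the chromosome's SNP list.
#' @export
subsample_snps <- function(n_snps, stride = 250) {
  stopifnot(n_snps >= 0, stride >= 1)
  if (stride > n_snps) return(integer(0))
  seq.int(stride, n_snps, by = stride)
}

#' Pairwise genotype-dosage r2 among a set of SNPs
#'
#' Composite linkage disequilibrium: entry (i, j) is the squared Pearson
#' correlation of the dosage vectors of SNPs i and j across samples.  The
#' diagonal is 1.  SNPs that are monomorphic in the sample (zero dosage
#' variance) have undefined correlations; their off-diagonal entries are
#' `NA` and are excluded from all downstream means.  r2 is invariant under
#' allele relabeling (dosage `d -> 2 - d`).
#'
#' @param dosage sites x samples numeric matrix with no missing entries.
#' @return symmetric sites x sites matrix of r2 values in `[0, 1]` (or
#'   `NA`), unit diagonal.
#' @export
pairwise_r2 <- function(dosage) {
  dosage <- as.matrix(dosage)
  if (ncol(dosage) < 2) stop("pairwise_r2 requires >= 2 samples")
  if (anyNA(dosage)) stop("pairwise_r2 requires complete genotypes")
  r <- suppressWarnings(stats::cor(t(dosage)))
  r2 <- r * r
  # numerical guard: clamp tiny excursions beyond [0, 1]
  r2[!is.na(r2) & r2 > 1] <- 1
  diag(r2) <- 1
  r2
}

#' Per-SNP mean r2 over all other subset SNPs
#'
#' Row means of the pairwise r2 matrix excluding the diagonal (self) and
#' undefined (`NA`) pairs.  A SNP whose every pairing is undefined gets
#' `NA`.
#'
#' @param r2 symmetric r2 matrix from [pairwise_r2()].
#' @return numeric vector of per-SNP mean r2.
#' @export
mean_r2_profile <- function(r2) {
  stopifnot(is.matrix(r2), nrow(r2) == ncol(r2))
  if (nrow(r2) < 2) return(rep(NA_real_, nrow(r2)))
  m <- r2
  diag(m) <- NA
  rowMeans(m, na.rm = TRUE) -> out
  out[!is.finite(out)] <- NA
  out
}

#' Compute the LD profile of one chromosome
#'
#' Subsamples every `stride`-th SNP, computes the pairwise dosage r2 among
#' the subset, and the per-subset-SNP mean r2.  This is the input to
#' [call_blocks()].
#'
#' @param gm a filtered [genotype_matrix()] (no missing genotypes).
#' @param chrom chromosome to profile.
#' @param stride subsampling stride (default 250).
#' @param keep_r2 keep the full r2 matrix on the result (default `TRUE`;
#'   set `FALSE` to save memory on large subsets).
#' @return An object of class `ld_profile`: list with `chrom`,
#'   `subset_idx` (0-based indices into the chromosome's retained SNP
#'   list), `subset_pos` (1-based positions), `mean_r2`, and optionally
#'   `r2`.
#' @export
ld_profile <- function(gm, chrom, stride = 250, keep_r2 = TRUE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  rows <- which(gm$snps$chrom == chrom)
  if (!length(rows)) stop("no SNPs on chromosome ", chrom)
  sel <- subsample_snps(length(rows), stride)
  if (!length(sel))
    return(structure(list(chrom = chrom, stride = stride,
                          subset_idx = integer(0), subset_pos = integer(0),
                          mean_r2 = numeric(0), r2 = NULL,
                          n_chrom_snps = length(rows),
                          all_pos = gm$snps$pos[rows]),
                     class = "ld_profile"))
  rsel <- rows[sel]
  r2 <- pairwise_r2(gm$dosage[rsel, , drop = FALSE])
  structure(list(chrom = chrom, stride = stride,
                 subset_idx = sel - 1L,
                 subset_pos = gm$snps$pos[rsel],
                 mean_r2 = mean_r2_profile(r2),
                 r2 = if (keep_r2) r2 else NULL,
                 n_chrom_snps = length(rows),
                 all_pos = gm$snps$pos[rows]),
            class = "ld_profile")
}

#' @export
print.ld_profile <- function(x, ...) {
  cat("ld_profile:", x$chrom, "-", length(x$subset_idx), "subset SNPs",
      "(stride", paste0(x$stride, ")"), "of", x$n_chrom_snps, "SNPs\n")
  if (length(x$mean_r2))
    cat("  mean r2: median", signif(stats::median(x$mean_r2, na.rm = TRUE), 3),
        " max", signif(max(x$mean_r2, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Call LD blocks from a mean-r2 profile
#'
#' Identifies subset SNPs with `mean_r2 > threshold` ("high-LD" SNPs) and
#' places block edges on the SNPs adjacent to the first and last high-LD
#' SNP, on the rationale that untested linked loci lie between a high-LD
#' subset SNP and its neighbors:
#'
#' * `edge_rule = "adjacent-subset"` (default): the edge is the neighboring
#'   *subset* SNP, one stride outside the first/last high-LD subset SNP.
#' * `edge_rule = "adjacent-snp"`: the edge is the literal neighboring SNP
#'   in the chromosome's full SNP list.
#'
#' When no neighbor exists (the high-LD SNP is the chromosome's first or
#' last subset/full SNP) the edge falls on the high-LD SNP itself.
#'
#' By default a single span per chromosome is returned, covering all
#' high-LD subset SNPs even when sub-threshold SNPs interrupt them (an
#' inversion block can contain internal unlinked SNPs — a "linkage gap").
#' With `max_gap` set, runs of high-LD SNPs separated by more than
#' `max_gap` consecutive sub-threshold subset SNPs are emitted as separate
#' blocks.
#'
#' @param profile an [ld_profile()].
#' @param threshold mean-r2 threshold, strict inequality (default 0.1).
#' @param edge_rule `"adjacent-subset"` or `"adjacent-snp"`.
#' @param max_gap optional maximum run of consecutive sub-threshold subset
#'   SNPs bridged within one block; `NULL` (default) bridges everything.
#' @return An `ld_blocks` data.frame with one row per block: `chrom`,
#'   `start`, `end` (1-based inclusive), `length`, `first_high`,
#'   `last_high` (0-based subset indices), `n_subset_in_block`,
#'   `n_strongly_linked`, `mean_r2_in_block`.  Zero rows if no subset SNP
#'   exceeds the threshold.
#' @export
call_blocks <- function(profile, threshold = 0.1,
                        edge_rule = c("adjacent-subset", "adjacent-snp"),
                        max_gap = NULL) {
  stopifnot(inherits(profile, "ld_profile"),
            threshold > 0, threshold < 1)
  edge_rule <- match.arg(edge_rule)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      first_high = integer(0), last_high = integer(0),
                      n_subset_in_block = integer(0),
                      n_strongly_linked = integer(0),
                      mean_r2_in_block = numeric(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("ld_blocks", "data.frame")
  high <- which(!is.na(profile$mean_r2) & profile$mean_r2 > threshold)
  if (!length(high)) return(empty)

  # group high-LD subset SNPs into runs
  if (is.null(max_gap)) {
    groups <- list(c(high[1], high[length(high)]))
  } else {
    brk <- which(diff(high) > max_gap + 1L)
    starts <- c(1L, brk + 1L)
    ends <- c(brk, length(high))
    groups <- Map(function(s, e) c(high[s], high[e]), starts, ends)
  }

  rows <- lapply(groups, function(g) {
    i_first <- g[1]; i_last <- g[2]   # 1-based into subset vectors
    if (edge_rule == "adjacent-subset") {
      start <- profile$subset_pos[max(i_first - 1L, 1L)]
      end <- profile$subset_pos[min(i_last + 1L, length(profile$subset_pos))]
    } else {
      # full-list neighbors of the first/last high-LD subset SNP
      full_first <- profile$subset_idx[i_first] + 1L  # 1-based into all_pos
      full_last <- profile$subset_idx[i_last] + 1L
      start <- profile$all_pos[max(full_first - 1L, 1L)]
      end <- profile$all_pos[min(full_last + 1L, length(profile$all_pos))]
    }
    inb <- profile$subset_pos >= start & profile$subset_pos <= end
    strong <- inb & !is.na(profile$mean_r2) & profile$mean_r2 > threshold
    data.frame(chrom = profile$chrom, start = start, end = end,
               length = end - start + 1L,
               first_high = profile$subset_idx[i_first],
               last_high = profile$subset_idx[i_last],
               n_subset_in_block = sum(inb),
               n_strongly_linked = sum(strong),
               mean_r2_in_block = mean(profile$mean_r2[inb], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ld_blocks", "data.frame")
  out
}

#' Count strongly linked subset SNPs within a block
#'
#' Over the subset SNPs whose positions fall inside `[start, end]` of the
#' block, counts how many have `mean_r2 > threshold`.
#'
#' @param profile the [ld_profile()] the block was called from.
#' @param block one row of an `ld_blocks` data.frame (or a list with
#'   `start` and `end`).
#' @param threshold mean-r2 threshold (default 0.1).
#' @return named integer vector `c(n_strongly_linked, n_subset_in_block)`.
#' @export
count_strongly_linked <- function(profile, block, threshold = 0.1) {
  stopifnot(inherits(profile, "ld_profile"))
  inb <- profile$subset_pos >= block$start & profile$subset_pos <= block$end
  strong <- inb & !is.na(profile$mean_r2) & profile$mean_r2 > threshold
  c(n_strongly_linked = sum(strong), n_subset_in_block = sum(inb))
}

#' Export a per-subset-SNP LD profile as a data.frame
#'
#' @param profile an [ld_profile()].
#' @return data.frame with columns `chrom`, `pos`, `mean_r2`.
#' @export
profile_table <- function(profile) {
  data.frame(chrom = profile$chrom, pos = profile$subset_pos,
             mean_r2 = profile$mean_r2, stringsAsFactors = FALSE)
}
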