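#' Construct a genotype matrix object
#'
#' The central data container of the package: a sites x samples matrix of
#' diploid allele dosages (0, 1, 2 copies of the alternate allele; `NA` for
#' missing genotypes) together with the per-SNP metadata needed downstream.
#'
#' @param snps data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `qual`.  Rows must be sorted by (`chrom`, `pos`) with strictly
#'   increasing `pos` within each chromosome; a 0-based `idx` column
#'   (ordinal among retained SNPs on the chromosome) is recomputed here.
#' @param samples character vector of sample identifiers (matrix columns).
#' @param dosage integer matrix, `nrow(snps)` x `length(samples)`, entries
#'   in `{0, 1, 2, NA}`.
#' @param n_dropped number of input records dropped before construction
#'   (multi-allelic / non-SNP records), carried for logging.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `snps`, `samples`, `dosage`, `n_dropped`.
#' @export
genotype_matrix <- function(snps, samples, dosage, n_dropped = 0L) {
  stopifnot(is.data.frame(snps),
            all(c("chrom", "pos", "ref", "alt", "qual") %in% names(snps)))
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != nrow(snps))
    stop("dosage has ", nrow(dosage), " rows but snps has ", nrow(snps))
  if (ncol(dosage) != length(samples))
    stop("dosage has ", ncol(dosage), " columns but ", length(samples),
         " samples given")
  if (nrow(snps) > 0) {
    ord <- order(snps$chrom, snps$pos)
    snps <- snps[ord, , drop = FALSE]
    dosage <- dosage[ord, , drop = FALSE]
    if (any(unlist(tapply(snps$pos, snps$chrom, function(p) diff(p) <= 0))))
      stop("positions must be strictly increasing within each chromosome")
    if (any(snps$pos < 1)) stop("positions must be >= 1")
    bad <- dosage[!is.na(dosage)]
    if (length(bad) && (any(bad < 0) || any(bad > 2)))
      stop("dosage entries must be in {0, 1, 2, NA}")
    snps$idx <- stats::ave(seq_len(nrow(snps)), snps$chrom,
                           FUN = function(i) seq_along(i) - 1L)
  } else {
    snps$idx <- integer(0)
  }
  rownames(snps) <- NULL
  dimnames(dosage) <- list(NULL, samples)
  structure(list(snps = snps, samples = as.character(samples),
                 dosage = dosage, n_dropped = as.integer(n_dropped)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$snps), "SNPs x", length(x$samples),
      "samples on", length(unique(x$snps$chrom)), "chromosome(s)\n")
  nm <- sum(is.na(x$dosage))
  cat("  missing genotypes:", nm,
      if (x$n_dropped > 0) paste0("; records dropped at read: ", x$n_dropped),
      "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by SNP rows and/or samples
#'
#' @param gm a `genotype_matrix`.
#' @param snp_set integer vector of row indices (1-based into `gm$snps`) or
#'   logical vector; `NULL` keeps all rows.
#' @param samples character vector of sample names or indices; `NULL` keeps
#'   all samples.
#' @return A `genotype_matrix` restricted to the selection, with per-chromosome
#'   `idx` recomputed over the retained SNPs.
#' @export
subset_genotypes <- function(gm, snp_set = NULL, samples = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  rows <- if (is.null(snp_set)) seq_len(nrow(gm$snps)) else snp_set
  cols <- if (is.null(samples)) seq_along(gm$samples) else samples
  if (is.character(cols)) {
    miss <- setdiff(cols, gm$samples)
    if (length(miss)) stop("samples not present: ", paste(miss, collapse = ", "))
    cols <- match(cols, gm$samples)
  }
  genotype_matrix(gm$snps[rows, c("chrom", "pos", "ref", "alt", "qual"),
                          drop = FALSE],
                  gm$samples[cols],
                  gm$dosage[rows, cols, drop = FALSE],
                  n_dropped = gm$n_dropped)
}
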