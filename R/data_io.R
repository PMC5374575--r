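#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses a multi-sample VCF (via \pkg{vcfR}), retains biallelic SNP records
#' only, and codes each genotype as the count of alternate alleles (dosage
#' 0/1/2).  Missing or partial GT calls become `NA`.  Multi-allelic records
#' and records whose REF or ALT is not a single nucleotide are dropped and
#' counted; the count is reported in a message and stored on the returned
#' object.
#'
#' @param path path to a VCF 4.x file (plain or bgzipped).
#' @param samples optional character vector restricting to a sample subset;
#'   an error lists any requested sample absent from the file.
#' @return A [genotype_matrix()] sorted by (chrom, pos).
#' @export
read_vcf_genotypes <- function(path, samples = NULL) {
  if (!file.exists(path)) stop("cannot read VCF file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n_in <- nrow(fix)
  if (n_in == 0) stop("VCF contains no records: ", path)

  nuc <- c("A", "C", "G", "T")
  keep <- !is.na(fix$ALT) & fix$REF %in% nuc & fix$ALT %in% nuc
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message("read_vcf_genotypes: dropped ", n_dropped,
            " multi-allelic or non-SNP record(s)")

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  if (!is.null(samples)) {
    miss <- setdiff(samples, colnames(gt))
    if (length(miss))
      stop("sample(s) not found in VCF: ", paste(miss, collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
  }

  dosage <- gt_to_dosage(gt)
  snps <- data.frame(chrom = fix$CHROM,
                     pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT,
                     qual = suppressWarnings(as.numeric(fix$QUAL)),
                     stringsAsFactors = FALSE)
  genotype_matrix(snps, colnames(gt), dosage, n_dropped = n_dropped)
}

# GT strings ("0/0", "0|1", "./.", "1", ...) -> alt-allele dosage with NA
# for any call containing a missing allele.
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  conv <- vapply(u, function(g) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (length(al) != 2 || any(al == ".")) return(NA_integer_)
    sum(al == "1")
  }, integer(1))
  out <- conv[match(as.vector(gt), u)]
  matrix(out, nrow = nrow(gt), dimnames = dimnames(gt))
}

#' Apply per-site quality, completeness and allele-frequency filters
#'
#' Retains sites with QUAL strictly greater than `min_qual`, with no missing
#' genotypes (when `require_complete`), and with minor allele frequency
#' `min(p, 1 - p) >= maf_min`, where `p = mean(dosage) / 2` over called
#' genotypes (missing entries are excluded from both numerator and
#' denominator).  Retention counts per filter are reported via `message()`.
#'
#' The operation is idempotent: applying it twice with the same settings
#' yields the same matrix as applying it once.
#'
#' @param gm a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency, inclusive (default 0.05).
#' @param min_qual sites must have `qual > min_qual` (default 30); sites
#'   with missing QUAL fail this filter.
#' @param require_complete drop sites with any missing genotype (default
#'   `TRUE`).
#' @return A filtered `genotype_matrix`; if every site is removed an empty
#'   matrix is returned with a warning.
#' @export
apply_site_filters <- function(gm, maf_min = 0.05, min_qual = 30,
                               require_complete = TRUE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (nrow(gm$snps) == 0) stop("empty genotype matrix")

  ok_qual <- !is.na(gm$snps$qual) & gm$snps$qual > min_qual
  n_called <- rowSums(!is.na(gm$dosage))
  ok_complete <- if (require_complete) n_called == ncol(gm$dosage)
                 else rep(TRUE, nrow(gm$dosage))
  p <- rowSums(gm$dosage, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  maf <- pmin(p, 1 - p)
  ok_maf <- n_called > 0 & maf >= maf_min

  keep <- ok_qual & ok_complete & ok_maf
  message("apply_site_filters: ", sum(!ok_qual), " failed QUAL > ", min_qual,
          "; ", sum(!ok_complete), " incomplete; ",
          sum(!ok_maf), " below MAF ", maf_min,
          "; retained ", sum(keep), "/", length(keep))
  if (!any(keep)) warning("all sites removed by filters")
  subset_genotypes(gm, snp_set = which(keep))
}

#' Read a sample-to-population map
#'
#' Two-column tab-separated file: sample identifier, population label.
#' Lines starting with `#` are ignored; an optional header line whose first
#' field is `sample` or `sample_id` is skipped.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `sample_id`, `population`.
#' @export
read_population_map <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         comment.char = "#", stringsAsFactors = FALSE,
                         col.names = c("sample_id", "population"))
  if (nrow(d) && d$sample_id[1] %in% c("sample", "sample_id"))
    d <- d[-1, , drop = FALSE]
  if (anyDuplicated(d$sample_id))
    stop("duplicate sample identifiers in population map")
  rownames(d) <- NULL
  d
}

# population factor aligned to gm$samples; errors on unmapped samples
pop_factor <- function(gm, popmap) {
  i <- match(gm$samples, popmap$sample_id)
  if (anyNA(i))
    stop("samples missing from population map: ",
         paste(gm$samples[is.na(i)], collapse = ", "))
  factor(popmap$population[i])
}

#' Read gene models from a GFF3 file
#'
#' Imports `gene` and `exon` features (via \pkg{rtracklayer}), links exons
#' to genes through their `Parent` attribute (transitively, so exons whose
#' parent is an mRNA are resolved to the grandparent gene), and merges
#' overlapping exon intervals within each gene.  Exons whose parent cannot
#' be resolved to a gene are skipped with a warning.
#'
#' @param path path to a GFF3 file.
#' @return An object of class `gene_models`: a list with `genes`
#'   (data.frame `gene_id`, `chrom`, `start`, `end`; 1-based inclusive) and
#'   `exons` (data.frame `gene_id`, `chrom`, `start`, `end`, merged).
#' @export
read_gene_models <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  types <- as.character(g$type)
  ids <- as.character(g$ID)
  parents <- vapply(as.list(g$Parent), function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))

  is_gene <- types == "gene"
  if (!any(is_gene)) stop("no gene features in GFF: ", path)
  gene_ids <- ids[is_gene]
  genes <- data.frame(gene_id = gene_ids,
                      chrom = as.character(GenomicRanges::seqnames(g))[is_gene],
                      start = GenomicRanges::start(g)[is_gene],
                      end = GenomicRanges::end(g)[is_gene],
                      stringsAsFactors = FALSE)

  # resolve each feature id to its ancestral gene id
  id2parent <- stats::setNames(parents, ids)
  resolve <- function(p) {
    seen <- 0L
    while (!is.na(p) && !(p %in% gene_ids) && seen < 10L) {
      p <- id2parent[p]
      seen <- seen + 1L
    }
    if (is.na(p) || !(p %in% gene_ids)) NA_character_ else p
  }

  is_exon <- types == "exon"
  exons <- data.frame(gene_id = vapply(parents[is_exon], resolve, character(1)),
                      chrom = as.character(GenomicRanges::seqnames(g))[is_exon],
                      start = GenomicRanges::start(g)[is_exon],
                      end = GenomicRanges::end(g)[is_exon],
                      stringsAsFactors = FALSE)
  n_orphan <- sum(is.na(exons$gene_id))
  if (n_orphan > 0) {
    warning(n_orphan, " exon(s) with unresolvable parent skipped")
    exons <- exons[!is.na(exons$gene_id), , drop = FALSE]
  }

  # merge overlapping exon intervals per gene
  if (nrow(exons)) {
    merged <- lapply(split(exons, exons$gene_id), function(e) {
      r <- IRanges::reduce(IRanges::IRanges(e$start, e$end))
      data.frame(gene_id = e$gene_id[1], chrom = e$chrom[1],
                 start = IRanges::start(r), end = IRanges::end(r),
                 stringsAsFactors = FALSE)
    })
    exons <- do.call(rbind, merged)
  }
  bad <- merge(exons, genes, by = "gene_id", suffixes = c("", ".g"))
  if (nrow(bad) && any(bad$start < bad$start.g | bad$end > bad$end.g))
    warning("exon interval(s) extend outside their gene span")
  rownames(genes) <- rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$exons),
      "merged exon intervals on", length(unique(x$genes$chrom)),
      "chromosome(s)\n")
  invisible(x)
}

#' Write called LD blocks to a BED file
#'
#' Converts the 1-based inclusive block spans to BED's 0-based half-open
#' convention (`start - 1`, `end`).  Columns: chrom, start, end, name,
#' score (mean in-block r2, 4 decimal places).
#'
#' @param blocks an `ld_blocks` data.frame from [call_blocks()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_block_bed <- function(blocks, path) {
  lines <- "#chrom\tstart\tend\tname\tscore"
  if (nrow(blocks) > 0) {
    stopifnot(all(blocks$start >= 1), all(blocks$start < blocks$end))
    nm <- sprintf("%s_block%d", blocks$chrom, seq_len(nrow(blocks)))
    sc <- ifelse(is.na(blocks$mean_r2_in_block), ".",
                 sprintf("%.4f", blocks$mean_r2_in_block))
    lines <- c(lines, sprintf("%s\t%d\t%d\t%s\t%s", blocks$chrom,
                              blocks$start - 1L, blocks$end, nm, sc))
  }
  writeLines(lines, path)
  invisible(path)
}

# TSV writer used throughout the pipeline: deterministic, tab-separated,
# header, no quoting/rownames.
write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
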