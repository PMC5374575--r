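#' Classify SNPs as exonic, intronic or intergenic
#'
#' A SNP falling inside any (merged) exon interval is `exon`; otherwise a
#' SNP inside any gene span is `intron`; all remaining SNPs are
#' `intergenic`.  Exon status takes precedence across genes, so a SNP in
#' the exon of one gene and the intron of an overlapping gene is `exon`.
#' The three classes partition the SNP set.  Interval overlap uses
#' \pkg{GenomicRanges}; all coordinates are 1-based inclusive.
#'
#' @param snps data.frame with columns `chrom` and `pos` (e.g. `gm$snps`).
#' @param genes a `gene_models` object from [read_gene_models()].
#' @return factor with levels `exon`, `intron`, `intergenic`, one per SNP.
#' @export
classify_snps <- function(snps, genes) {
  stopifnot(inherits(genes, "gene_models"))
  out <- rep("intergenic", nrow(snps))
  if (nrow(snps)) {
    q <- GenomicRanges::GRanges(snps$chrom,
                                IRanges::IRanges(snps$pos, snps$pos))
    if (nrow(genes$genes)) {
      gr <- GenomicRanges::GRanges(genes$genes$chrom,
                                   IRanges::IRanges(genes$genes$start,
                                                    genes$genes$end))
      in_gene <- IRanges::overlapsAny(q, gr)
      out[in_gene] <- "intron"
    }
    if (nrow(genes$exons)) {
      er <- GenomicRanges::GRanges(genes$exons$chrom,
                                   IRanges::IRanges(genes$exons$start,
                                                    genes$exons$end))
      out[IRanges::overlapsAny(q, er)] <- "exon"
    }
  }
  factor(out, levels = c("exon", "intron", "intergenic"))
}

#' SNP density within a genomic region
#'
#' Count of SNPs with positions inside the 1-based inclusive span, divided
#' by the span length in bases.
#'
#' @param snps data.frame with columns `chrom`, `pos`.
#' @param chrom chromosome of the region.
#' @param start,end 1-based inclusive region span.
#' @return SNPs per base (numeric scalar).
#' @export
snp_density <- function(snps, chrom, start, end) {
  stopifnot(end >= start)
  n <- sum(snps$chrom == chrom & snps$pos >= start & snps$pos <= end)
  n / (end - start + 1)
}

#' Percent enrichment of an in-block quantity over a baseline
#'
#' `100 * (inblock / baseline - 1)`, rounded to the nearest integer percent
#' for reporting (e.g. exonic proportion 0.065 -> 0.089 is a 37% increase).
#'
#' @param baseline baseline proportion or density (> 0).
#' @param inblock the corresponding in-block value.
#' @return integer percent change; `NA` when `baseline` is 0.
#' @export
enrichment_ratio <- function(baseline, inblock) {
  if (is.na(baseline) || baseline == 0) return(NA_real_)
  round(100 * (inblock / baseline - 1))
}

#' Genes overlapping a called block
#'
#' By default a gene is in the block when its span overlaps the block by at
#' least one base; `mode = "contain"` requires the full gene span inside
#' the block.
#'
#' @param genes a `gene_models` object.
#' @param block one row of an `ld_blocks` data.frame (`chrom`, `start`,
#'   `end`).
#' @param mode `"overlap"` (default) or `"contain"`.
#' @return data.frame of the in-block genes (`gene_id`, `chrom`, `start`,
#'   `end`); the count is `nrow()` of the result.
#' @export
genes_in_block <- function(genes, block, mode = c("overlap", "contain")) {
  stopifnot(inherits(genes, "gene_models"), block$start <= block$end)
  mode <- match.arg(mode)
  g <- genes$genes
  on_ch <- g$chrom == block$chrom
  keep <- if (mode == "overlap")
    on_ch & g$start <= block$end & g$end >= block$start
  else
    on_ch & g$start >= block$start & g$end <= block$end
  out <- g[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a gene-to-GO-term annotation map
#'
#' Tab-separated file with columns `gene_id`, `go_id` and optionally
#' `term`; one row per (gene, term) pair.  Lines starting with `#` are
#' ignored.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `gene_id`, `go_id`, `term`.
#' @export
read_go_map <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         comment.char = "#", stringsAsFactors = FALSE,
                         fill = TRUE)
  names(d) <- c("gene_id", "go_id", "term")[seq_len(ncol(d))]
  if (!"term" %in% names(d)) d$term <- d$go_id
  if (nrow(d) && d$gene_id[1] %in% c("gene_id", "gene"))
    d <- d[-1, , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' GO-term enrichment of in-block genes by Fisher exact test
#'
#' For every GO term carried by at least one in-block gene, a one-sided
#' (greater) Fisher exact test on the 2x2 table of in-block / not-in-block
#' versus term / no-term over the background gene set, followed by
#' Benjamini-Hochberg adjustment across the tested terms.  Terms taken as
#' given: no ontology-graph propagation or decorrelation is performed, so
#' nested terms share genes and their p-values are correlated.
#'
#' @param block_genes character vector of in-block gene ids (must be a
#'   subset of `background_genes`).
#' @param background_genes character vector of all genes in the background.
#' @param go_map data.frame from [read_go_map()] (`gene_id`, `go_id`,
#'   optional `term`).
#' @return data.frame with columns `go_id`, `term`, `annotated` (background
#'   genes with the term), `significant` (in-block genes with the term),
#'   `fisher_p`, `p_adj`, sorted by `p_adj` then `fisher_p`.
#' @export
go_fisher_enrichment <- function(block_genes, background_genes, go_map) {
  if (!nrow(go_map)) stop("empty GO annotation")
  if (!all(block_genes %in% background_genes))
    stop("block_genes must be a subset of background_genes")
  block_genes <- unique(block_genes)
  background_genes <- unique(background_genes)
  m <- go_map[go_map$gene_id %in% background_genes, , drop = FALSE]
  m <- unique(m[, c("gene_id", "go_id")])
  terms <- if ("term" %in% names(go_map))
    stats::setNames(go_map$term, go_map$go_id) else NULL

  n_bg <- length(background_genes)
  n_blk <- length(block_genes)
  by_term <- split(m$gene_id, m$go_id)
  rows <- lapply(names(by_term), function(id) {
    genes <- by_term[[id]]
    k <- sum(genes %in% block_genes)
    if (k == 0) return(NULL)
    K <- length(genes)
    tab <- matrix(c(k, K - k, n_blk - k, n_bg - K - (n_blk - k)), 2, 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(go_id = id,
               term = if (!is.null(terms)) unname(terms[id]) else id,
               annotated = K, significant = k, fisher_p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(go_id = character(0), term = character(0),
                      annotated = integer(0), significant = integer(0),
                      fisher_p = numeric(0), p_adj = numeric(0)))
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$fisher_p, method = "BH")
  out <- out[order(out$p_adj, out$fisher_p, out$go_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
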