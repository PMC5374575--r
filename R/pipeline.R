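#' Configuration for an end-to-end pipeline run
#'
#' Defaults are the analysis parameters of the block-partitioned scan:
#' every 250th SNP for the LD profile, mean-r2 block threshold 0.1, minimum
#' minor allele frequency 0.05, site quality > 30, every 10th exonic SNP
#' for the genome-wide background.
#'
#' @param vcf,gff,popmap input file paths (VCF genotypes, GFF3 gene models,
#'   two-column population map).
#' @param go_map optional gene-to-GO TSV for enrichment.
#' @param out_dir output directory.
#' @param stride_ld LD subsampling stride (default 250).
#' @param stride_exonic_genome stride for off-block-chromosome exonic SNPs
#'   (default 10).
#' @param ld_threshold mean-r2 block threshold (default 0.1).
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param min_qual site QUAL must exceed this (default 30).
#' @param edge_rule block edge placement, `"adjacent-subset"` (default) or
#'   `"adjacent-snp"` (see [call_blocks()]).
#' @param chrom_whitelist optional chromosomes to scan for blocks; empty or
#'   `NULL` scans all chromosomes.
#' @param max_gap optional block-splitting gap (see [call_blocks()]).
#' @param seed RNG seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed feeds the kmeans-based genotype assignment).
#' @return validated list of class `run_config`.
#' @export
run_config <- function(vcf, gff, popmap, out_dir, go_map = NULL,
                       stride_ld = 250, stride_exonic_genome = 10,
                       ld_threshold = 0.1, maf_min = 0.05, min_qual = 30,
                       edge_rule = "adjacent-subset",
                       chrom_whitelist = NULL, max_gap = NULL, seed = 1) {
  stopifnot(stride_ld >= 1, stride_exonic_genome >= 1,
            ld_threshold > 0, ld_threshold < 1)
  structure(list(vcf = vcf, gff = gff, popmap = popmap, go_map = go_map,
                 out_dir = out_dir, stride_ld = stride_ld,
                 stride_exonic_genome = stride_exonic_genome,
                 ld_threshold = ld_threshold, maf_min = maf_min,
                 min_qual = min_qual, edge_rule = edge_rule,
                 chrom_whitelist = chrom_whitelist, max_gap = max_gap,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full block-partitioned analysis
#'
#' Stages, in order: read + filter genotypes; classify SNPs against the
#' gene models; per-chromosome LD scan and block calling; exonic SNP
#' subsetting (all exonic SNPs in/out of block on block chromosomes, every
#' `stride_exonic_genome`-th exonic SNP elsewhere); pairwise and global
#' Weir-Cockerham F_ST; KS tests of in- versus out-of-block F_ST per block
#' and population pair; PCA in/out of each block; block-genotype
#' assignment; gene lists, density and class-proportion enrichment, and
#' (when a GO map is supplied) Fisher/FDR GO enrichment.  Every table is
#' written as TSV under `cfg$out_dir`; `manifest.json` records the
#' configuration, package version, input checksums and per-stage row
#' counts.  A failing stage aborts with the stage name; tables already
#' written are preserved.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) list with the key in-memory results: `gm`, `blocks`,
#'   `profiles`, `fst_summary`, `ks_tests`, `enrichment`, `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  set.seed(cfg$seed)
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(stage, ...) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    stage, paste0(...))
    message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  stage <- "init"
  counts <- list()
  res <- list()
  tryCatch({
    stage <- "read"
    gm_raw <- read_vcf_genotypes(cfg$vcf)
    popmap <- read_population_map(cfg$popmap)
    genes <- read_gene_models(cfg$gff)
    counts$snps_read <- nrow(gm_raw$snps)
    counts$records_dropped <- gm_raw$n_dropped
    counts$samples <- length(gm_raw$samples)
    counts$genes <- nrow(genes$genes)
    logf(stage, counts$snps_read, " SNPs, ", counts$samples, " samples, ",
         counts$genes, " genes")

    stage <- "filter"
    gm <- apply_site_filters(gm_raw, maf_min = cfg$maf_min,
                             min_qual = cfg$min_qual,
                             require_complete = TRUE)
    counts$snps_filtered <- nrow(gm$snps)
    logf(stage, counts$snps_filtered, " SNPs retained")

    stage <- "classify"
    classes <- classify_snps(gm$snps, genes)
    counts$class_exon <- sum(classes == "exon")
    counts$class_intron <- sum(classes == "intron")
    counts$class_intergenic <- sum(classes == "intergenic")
    logf(stage, counts$class_exon, " exon / ", counts$class_intron,
         " intron / ", counts$class_intergenic, " intergenic")

    stage <- "ld_scan"
    chroms <- unique(gm$snps$chrom)
    if (length(cfg$chrom_whitelist))
      chroms <- intersect(chroms, cfg$chrom_whitelist)
    profiles <- lapply(chroms, function(ch)
      ld_profile(gm, ch, stride = cfg$stride_ld, keep_r2 = FALSE))
    names(profiles) <- chroms
    prof_tab <- do.call(rbind, lapply(profiles, profile_table))
    write_tsv(prof_tab, file.path(cfg$out_dir, "ld_profile.tsv"))
    counts$subset_snps <- nrow(prof_tab)
    logf(stage, counts$subset_snps, " subset SNPs across ",
         length(chroms), " chromosome(s)")

    stage <- "call_blocks"
    blocks <- do.call(rbind, lapply(profiles, function(p)
      call_blocks(p, threshold = cfg$ld_threshold,
                  edge_rule = cfg$edge_rule, max_gap = cfg$max_gap)))
    rownames(blocks) <- NULL
    write_tsv(as.data.frame(blocks),
              file.path(cfg$out_dir, "blocks.tsv"))
    write_block_bed(blocks, file.path(cfg$out_dir, "blocks.bed"))
    counts$blocks <- nrow(blocks)
    logf(stage, counts$blocks, " block(s) called")

    stage <- "exonic_subsets"
    subsets <- exonic_snp_subsets(gm, classes, blocks,
                                  stride_genome = cfg$stride_exonic_genome)
    counts$exonic_in_block <- sum(lengths(subsets$in_block))
    counts$exonic_out_block <- sum(lengths(subsets$out_block))
    counts$exonic_genome <- length(subsets$genome)
    logf(stage, counts$exonic_in_block, " in-block / ",
         counts$exonic_out_block, " out-of-block / ",
         counts$exonic_genome, " genome exonic SNPs")

    stage <- "fst"
    pops <- sort(unique(popmap$population))
    pairs <- if (length(pops) >= 2) utils::combn(pops, 2, simplify = FALSE)
             else list()
    fst_rows <- list(); per_snp_rows <- list(); ks_rows <- list()
    for (pr in pairs) {
      pname <- paste(pr, collapse = "_vs_")
      for (ch in names(subsets$in_block)) {
        fin <- fout <- NULL
        if (length(subsets$in_block[[ch]]) > 0) {
          fin <- wc_fst(gm, popmap, pair = pr,
                        snp_set = subsets$in_block[[ch]])
          fst_rows[[paste(ch, "in_block", pname)]] <-
            data.frame(group = paste0(ch, "_in_block"), pair = pname,
                       mean_theta = fin$mean_theta, n_snps = fin$n_snps)
          per_snp_rows[[paste(ch, "in", pname)]] <-
            cbind(fin$per_snp, pair = pname, group = paste0(ch, "_in_block"))
        }
        if (length(subsets$out_block[[ch]]) > 0) {
          fout <- wc_fst(gm, popmap, pair = pr,
                         snp_set = subsets$out_block[[ch]])
          fst_rows[[paste(ch, "out_block", pname)]] <-
            data.frame(group = paste0(ch, "_out_block"), pair = pname,
                       mean_theta = fout$mean_theta, n_snps = fout$n_snps)
          per_snp_rows[[paste(ch, "out", pname)]] <-
            cbind(fout$per_snp, pair = pname,
                  group = paste0(ch, "_out_block"))
        }
        if (!is.null(fin) && !is.null(fout) &&
            fin$n_defined > 0 && fout$n_defined > 0) {
          ks <- fst_distribution_test(fin$per_snp$theta, fout$per_snp$theta)
          ks_rows[[paste(ch, pname)]] <-
            data.frame(chrom = ch, pair = pname, D = ks$D, p = ks$p,
                       n_in = ks$n_in, n_out = ks$n_out)
        }
      }
      if (length(subsets$genome) > 0) {
        fg <- wc_fst(gm, popmap, pair = pr, snp_set = subsets$genome)
        fst_rows[[paste("genome", pname)]] <-
          data.frame(group = "genome", pair = pname,
                     mean_theta = fg$mean_theta, n_snps = fg$n_snps)
      }
    }
    fst_summary <- if (length(fst_rows)) do.call(rbind, fst_rows)
                   else data.frame()
    rownames(fst_summary) <- NULL
    write_tsv(fst_summary, file.path(cfg$out_dir, "fst_summary.tsv"))
    if (length(per_snp_rows))
      write_tsv(do.call(rbind, per_snp_rows),
                file.path(cfg$out_dir, "fst_per_snp.tsv"))
    ks_tests <- if (length(ks_rows)) do.call(rbind, ks_rows)
                else data.frame()
    rownames(ks_tests) <- NULL
    write_tsv(ks_tests, file.path(cfg$out_dir, "ks_tests.tsv"))
    counts$fst_comparisons <- nrow(fst_summary)
    logf(stage, counts$fst_comparisons, " mean-Fst comparisons, ",
         nrow(ks_tests), " KS tests")

    stage <- "pca_assignment"
    assign_rows <- list(); score_rows <- list()
    for (bi in seq_len(nrow(blocks))) {
      blk <- blocks[bi, ]
      ch <- blk$chrom
      inb <- subsets$in_block[[ch]]
      outb <- subsets$out_block[[ch]]
      if (length(inb) >= 2) {
        p_in <- pca_genotypes(gm, snp_set = inb)
        score_rows[[paste(ch, "in")]] <-
          data.frame(chrom = ch, set = "in_block",
                     sample_id = rownames(p_in$scores),
                     PC1 = p_in$scores[, 1], PC2 = p_in$scores[, 2])
      }
      if (length(outb) >= 2) {
        p_out <- pca_genotypes(gm, snp_set = outb)
        score_rows[[paste(ch, "out")]] <-
          data.frame(chrom = ch, set = "out_block",
                     sample_id = rownames(p_out$scores),
                     PC1 = p_out$scores[, 1], PC2 = p_out$scores[, 2])
      }
      bg <- assign_block_genotypes(gm, blk)
      assign_rows[[ch]] <- cbind(chrom = ch, bg)
    }
    if (length(score_rows))
      write_tsv(do.call(rbind, score_rows),
                file.path(cfg$out_dir, "pca_scores.tsv"))
    assignments <- if (length(assign_rows)) do.call(rbind, assign_rows)
                   else data.frame()
    rownames(assignments) <- NULL
    write_tsv(assignments, file.path(cfg$out_dir, "block_genotypes.tsv"))
    logf(stage, nrow(assignments), " block-genotype assignments")

    stage <- "annotation"
    enr_rows <- list(); gene_rows <- list(); go_tables <- list()
    genome_span <- sum(tapply(gm$snps$pos, gm$snps$chrom, max))
    dens_genome <- nrow(gm$snps) / genome_span
    prop_exon_genome <- mean(classes == "exon")
    go <- if (!is.null(cfg$go_map)) read_go_map(cfg$go_map) else NULL
    for (bi in seq_len(nrow(blocks))) {
      blk <- blocks[bi, ]
      gin <- genes_in_block(genes, blk)
      gene_rows[[bi]] <- cbind(block = sprintf("%s_block%d", blk$chrom, bi),
                               gin)
      inb <- gm$snps$chrom == blk$chrom & gm$snps$pos >= blk$start &
        gm$snps$pos <= blk$end
      dens_in <- snp_density(gm$snps, blk$chrom, blk$start, blk$end)
      prop_exon_in <- if (any(inb)) mean(classes[inb] == "exon") else NA
      enr_rows[[bi]] <- data.frame(
        chrom = blk$chrom, start = blk$start, end = blk$end,
        n_genes = nrow(gin),
        snp_density_block = dens_in, snp_density_genome = dens_genome,
        density_enrichment_pct = enrichment_ratio(dens_genome, dens_in),
        prop_exonic_block = prop_exon_in,
        prop_exonic_genome = prop_exon_genome,
        exonic_enrichment_pct = enrichment_ratio(prop_exon_genome,
                                                 prop_exon_in))
      if (!is.null(go) && nrow(gin)) {
        got <- go_fisher_enrichment(gin$gene_id, genes$genes$gene_id, go)
        if (nrow(got))
          go_tables[[bi]] <- cbind(block = sprintf("%s_block%d",
                                                   blk$chrom, bi), got)
      }
    }
    enrichment <- if (length(enr_rows)) do.call(rbind, enr_rows)
                  else data.frame()
    write_tsv(enrichment, file.path(cfg$out_dir, "block_enrichment.tsv"))
    if (length(gene_rows))
      write_tsv(do.call(rbind, gene_rows),
                file.path(cfg$out_dir, "block_genes.tsv"))
    if (length(go_tables))
      write_tsv(do.call(rbind, go_tables),
                file.path(cfg$out_dir, "go_enrichment.tsv"))
    counts$blocks_annotated <- nrow(enrichment)
    logf(stage, "annotated ", counts$blocks_annotated, " block(s)")

    stage <- "manifest"
    inputs <- c(vcf = cfg$vcf, gff = cfg$gff, popmap = cfg$popmap,
                go_map = if (!is.null(cfg$go_map)) cfg$go_map)
    manifest <- list(config = unclass(cfg),
                     package_version =
                       as.character(utils::packageVersion("invLD")),
                     input_md5 = as.list(tools::md5sum(inputs)),
                     stage_counts = counts)
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    logf(stage, "written")

    res <- list(gm = gm, classes = classes, blocks = blocks,
                profiles = profiles, subsets = subsets,
                fst_summary = fst_summary, ks_tests = ks_tests,
                assignments = assignments, enrichment = enrichment,
                manifest = manifest)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
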