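# VCF/GFF/popmap ingestion, site filters, BED output

write_test_vcf <- function(path, records, samples = c("s1", "s2", "s3")) {
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chrA,length=100000>",
               paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                      "Description=\"Genotype\">"),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t"),
               records), path)
  path
}

test_that("GT fields become alt-allele dosages, non-biallelic records drop", {
  p <- write_test_vcf(tempfile(fileext = ".vcf"), c(
    "chrA\t100\t.\tA\tC\t60\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chrA\t200\t.\tG\tA,T\t60\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chrA\t300\t.\tAT\tA\t60\tPASS\t.\tGT\t0/0\t0/0\t0/0",
    "chrA\t400\t.\tT\tG\t55\tPASS\t.\tGT\t./.\t0|1\t1/1"))
  gm <- suppressMessages(read_vcf_genotypes(p))
  expect_equal(nrow(gm$snps), 2)          # multi-allelic + indel dropped
  expect_equal(gm$n_dropped, 2L)
  expect_equal(unname(gm$dosage[1, ]), c(0L, 1L, 2L))
  expect_equal(unname(gm$dosage[2, ]), c(NA_integer_, 1L, 2L))
  expect_equal(gm$snps$qual, c(60, 55))
  expect_equal(gm$snps$idx, c(0L, 1L))
})

test_that("sample subsetting errors on unknown names, honors the subset", {
  p <- write_test_vcf(tempfile(fileext = ".vcf"),
                      "chrA\t100\t.\tA\tC\t60\tPASS\t.\tGT\t0/0\t0/1\t1/1")
  expect_error(read_vcf_genotypes(p, samples = c("s1", "nope")), "nope")
  gm <- read_vcf_genotypes(p, samples = c("s3", "s1"))
  expect_equal(gm$samples, c("s3", "s1"))
  expect_equal(unname(gm$dosage[1, ]), c(2L, 0L))
})

test_that("simulator VCF round-trips to the truth dosage matrix", {
  ds <- small_sim(seed = 11)
  gm <- read_vcf_genotypes(ds$vcf)
  expect_equal(nrow(gm$snps), nrow(ds$truth$snp))
  expect_equal(gm$n_dropped, 0L)
  expect_equal(sum(is.na(gm$dosage)), 0L)
  expect_equal(gm$snps$pos, ds$truth$snp$pos)
  expect_identical(unname(gm$dosage), unname(ds$truth$dosage))
  expect_identical(unname(gm$dosage),
                   unname(truth_genotype_matrix(ds)$dosage))
})

test_that("site filters enforce MAF, completeness and QUAL, idempotently", {
  # 31 samples; site 1: single heterozygote (MAF 1/62 < 0.05); site 2:
  # common variant; site 3: one missing genotype; site 4: low QUAL
  d <- rbind(c(1L, rep(0L, 30)),
             rep(c(0L, 1L, 2L), length.out = 31),
             rep(c(0L, 1L), length.out = 31),
             rep(c(0L, 2L), length.out = 31))
  d[3, 5] <- NA
  gm <- make_gm(d, qual = c(60, 60, 60, 25))
  out <- suppressMessages(apply_site_filters(gm))
  expect_equal(out$snps$pos, gm$snps$pos[2])
  # idempotence
  again <- suppressMessages(apply_site_filters(out))
  expect_identical(out$snps, again$snps)
  expect_identical(out$dosage, again$dosage)
  # relaxing completeness keeps the site with a missing call (MAF from
  # called genotypes only)
  kept <- suppressMessages(apply_site_filters(gm, require_complete = FALSE))
  expect_true(gm$snps$pos[3] %in% kept$snps$pos)
  # MAF exactly at the floor is retained (inclusive minimum)
  d6 <- matrix(rep(c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L),
                   length.out = 30), nrow = 1)       # p = 3/60 = 0.05
  gm6 <- make_gm(d6)
  expect_equal(nrow(suppressMessages(apply_site_filters(gm6))$snps), 1)
  # everything removed -> warning, empty matrix
  gm_bad <- make_gm(matrix(0L, 2, 31))
  expect_warning(suppressMessages(apply_site_filters(gm_bad)), "all sites")
})

test_that("retention matches MAF recomputed from simulator truth", {
  ds <- small_sim(seed = 3)
  gm <- read_vcf_genotypes(ds$vcf)
  p <- rowMeans(gm$dosage) / 2
  expected <- which(pmin(p, 1 - p) >= 0.05)
  out <- suppressMessages(apply_site_filters(gm))
  expect_equal(out$snps$pos, gm$snps$pos[expected])
})

test_that("gene models parse, merge overlapping exons, resolve parents", {
  p <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
    "chrA\tsrc\tgene\t100\t500\t.\t+\t.\tID=g1",
    "chrA\tsrc\texon\t100\t199\t.\t+\t.\tID=g1.e1;Parent=g1",
    "chrA\tsrc\texon\t300\t399\t.\t+\t.\tID=g1.e2;Parent=g1",
    "chrA\tsrc\tgene\t1000\t2000\t.\t+\t.\tID=g2",
    "chrA\tsrc\tmRNA\t1000\t2000\t.\t+\t.\tID=g2.t1;Parent=g2",
    "chrA\tsrc\texon\t1000\t1250\t.\t+\t.\tID=g2.e1;Parent=g2.t1",
    "chrA\tsrc\texon\t1200\t1300\t.\t+\t.\tID=g2.e2;Parent=g2.t1"), p)
  gmod <- read_gene_models(p)
  expect_equal(nrow(gmod$genes), 2)
  e1 <- gmod$exons[gmod$exons$gene_id == "g1", ]
  expect_equal(nrow(e1), 2)             # disjoint exons stay separate
  e2 <- gmod$exons[gmod$exons$gene_id == "g2", ]
  expect_equal(nrow(e2), 1)             # overlapping exons merged
  expect_equal(c(e2$start, e2$end), c(1000, 1300))
})

test_that("orphan exons are skipped with a warning", {
  p <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
    "chrA\tsrc\tgene\t100\t500\t.\t+\t.\tID=g1",
    "chrA\tsrc\texon\t100\t199\t.\t+\t.\tID=e1;Parent=g1",
    "chrA\tsrc\texon\t900\t950\t.\t+\t.\tID=e2;Parent=ghost"), p)
  expect_warning(gmod <- read_gene_models(p), "unresolvable")
  expect_equal(nrow(gmod$exons), 1)
})

test_that("simulator GFF round-trips gene spans", {
  ds <- small_sim(seed = 5)
  gmod <- read_gene_models(ds$gff)
  truth <- ds$truth$genes$genes
  expect_equal(nrow(gmod$genes), nrow(truth))
  m <- merge(gmod$genes, truth, by = "gene_id")
  expect_equal(m$start.x, m$start.y)
  expect_equal(m$end.x, m$end.y)
})

test_that("population map reads and rejects duplicates", {
  p <- tempfile()
  writeLines(c("# samples", "s1\tspring", "s2\twinter"), p)
  pm <- read_population_map(p)
  expect_equal(pm$population, c("spring", "winter"))
  writeLines(c("s1\ta", "s1\tb"), p)
  expect_error(read_population_map(p), "duplicate")
})

test_that("BED output is 0-based half-open and round-trips exactly", {
  blocks <- data.frame(chrom = "LG02", start = 18442392L, end = 24053701L,
                       length = 24053701L - 18442392L + 1L,
                       first_high = 10L, last_high = 20L,
                       n_subset_in_block = 11L, n_strongly_linked = 11L,
                       mean_r2_in_block = 0.25)
  p <- tempfile(fileext = ".bed")
  write_block_bed(blocks, p)
  lines <- readLines(p)
  f <- strsplit(lines[2], "\t")[[1]]
  expect_equal(f[1:3], c("LG02", "18442391", "24053701"))
  # re-read, convert back to 1-based inclusive
  expect_equal(as.integer(f[2]) + 1L, blocks$start)
  expect_equal(as.integer(f[3]), blocks$end)
  # empty list -> header-only file
  write_block_bed(blocks[0, ], p)
  expect_equal(length(readLines(p)), 1)
  expect_match(readLines(p)[1], "^#")
})

test_that("called blocks survive the BED round trip on simulated data", {
  ds <- small_sim(seed = 21)
  gm <- suppressMessages(apply_site_filters(read_vcf_genotypes(ds$vcf)))
  prof <- ld_profile(gm, ds$config$chrom, stride = 25, keep_r2 = FALSE)
  blocks <- call_blocks(prof)
  expect_equal(nrow(blocks), 1)
  p <- tempfile(fileext = ".bed")
  write_block_bed(blocks, p)
  f <- read.table(p, sep = "\t", comment.char = "#")
  expect_equal(f$V2 + 1L, blocks$start)
  expect_equal(f$V3, blocks$end)
})
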