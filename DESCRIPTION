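Package: invLD
Title: Detection of Inversion-Like Linkage Disequilibrium Blocks and
    Block-Partitioned Population Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: De novo detection of chromosome-scale linkage disequilibrium
    (LD) blocks -- the genomic signature of inversion supergenes -- from
    multi-sample SNP genotypes, and downstream analysis of the detected
    blocks: stride-subsampled pairwise genotype-dosage r2 profiles,
    threshold-based block-edge calling, Weir-Cockerham F_ST inside and
    outside blocks, Kolmogorov-Smirnov comparison of F_ST distributions,
    principal component analysis and three-cluster block-genotype
    assignment, SNP functional-class and density enrichment, in-block gene
    content, and Fisher/FDR Gene Ontology enrichment.  Includes a
    seed-deterministic simulator of inversion-polymorphism datasets
    (VCF + GFF3 + population map + truth file) for validation and
    parameter-recovery testing, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
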