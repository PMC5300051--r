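test_that("expression tables are parsed, validated and round-tripped", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "GeneA\t1\t2", "GeneB\t0\t0", "GeneC\t5.5\t1"), p)
  m <- read_expression_table(p)
  expect_equal(dim(m), c(3L, 3L))
  expect_equal(m$gene_id, c("GeneA", "GeneB", "GeneC"))
  expect_equal(m$s1, c(1, 0, 5.5))
  expect_equal(m$s2, c(2, 0, 1))

  # duplicated gene row is a hard error naming the gene
  writeLines(c("gene\ts1", "GeneA\t1", "GeneA\t2"), p)
  expect_error(read_expression_table(p), "GeneA")

  # negative value is a hard error naming gene and sample
  writeLines(c("gene\ts1\ts2", "GeneA\t1\t2", "GeneB\t-3\t0"), p)
  expect_error(read_expression_table(p), "GeneB.*s1")

  # round trip is the identity on a random matrix (>= 12 significant digits)
  set.seed(42)
  m0 <- random_expr(30, 4)
  m0$s1 <- m0$s1 + pi * 1e-3 # non-terminating decimals
  q <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(m0, q)
  m1 <- read_expression_table(q)
  expect_equal(m1, m0, tolerance = 1e-12)
})

test_that("cuffdiff-style tables map tracking ids and *_FPKM columns", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tracking_id\tlocus\tcondA_FPKM\tcondB_FPKM",
               "g1\tchr1:1-2\t3.5\t0", "g2\tchr2:5-9\t1\t2"), p)
  m <- read_expression_table(p, dialect = "cuffdiff_fpkm")
  expect_equal(names(m), c("gene_id", "condA", "condB"))
  expect_equal(m$condA, c(3.5, 1))
})

test_that("gene annotations classify chromosomes and apply exclusion rules", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  lines <- c(
    'chrX\tens\tgene\t100\t200\t.\t+\t.\tgene_id "gx1"; gene_biotype "protein_coding";',
    'chrX\tens\tgene\t300\t400\t.\t-\t.\tgene_id "gx2"; gene_biotype "protein_coding";',
    'chr1\tens\tgene\t1\t50\t.\t+\t.\tgene_id "ga1"; gene_biotype "protein_coding";',
    'chr2\tens\tgene\t1\t50\t.\t+\t.\tgene_id "ga2"; gene_biotype "protein_coding";',
    'chr12\tens\tgene\t1\t50\t.\t+\t.\tgene_id "ga3"; gene_biotype "protein_coding";',
    'chrM\tens\tgene\t1\t50\t.\t+\t.\tgene_id "gm1"; gene_biotype "protein_coding";'
  )
  writeLines(lines, gtf)
  ann <- read_gene_annotation(gtf, format = "gtf")
  expect_equal(sort(ann$gene_id[ann$chrom_class == "X"]), c("gx1", "gx2"))
  expect_equal(sum(ann$chrom_class == "AUTOSOME"), 3L)
  expect_equal(ann$chrom_class[ann$gene_id == "gm1"], "EXCLUDED")

  # an rRNA gene on an ordinary autosome is excluded by biotype
  bed <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tgene_id\tbiotype",
               "chr12\t0\t100\tgr1\trRNA",
               "chr12\t0\t100\tga1\tprotein_coding",
               "chrY\t0\t100\tgy1\tprotein_coding"), bed)
  ann2 <- read_gene_annotation(bed, format = "bed_like_tsv")
  expect_equal(ann2$chrom_class[ann2$gene_id == "gr1"], "EXCLUDED")
  expect_equal(ann2$chrom_class[ann2$gene_id == "ga1"], "AUTOSOME")
  expect_equal(ann2$chrom_class[ann2$gene_id == "gy1"], "Y")
  # BED starts converted to 1-based inclusive
  expect_equal(ann2$start[1], 1L)

  # missing chromosome: EXCLUDED with a warning, not an error
  writeLines(c("chrom\tstart\tend\tgene_id", "\t0\t10\tgn1", "chr3\t0\t10\tgn2"),
             bed)
  expect_warning(ann3 <- read_gene_annotation(bed, format = "bed_like_tsv"),
                 "without a chromosome")
  expect_equal(ann3$chrom_class[ann3$gene_id == "gn1"], "EXCLUDED")
})

test_that("replicate pooling matches a brute-force per-gene group mean", {
  set.seed(7)
  m <- random_expr(10, 6, zeros = 0)
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:6),
    condition_id = rep(c("c1", "c2", "c3"), each = 2),
    genotype = "XY", stage = "E14.5", cell_type = "GERM", replicate = rep(1:2, 3)
  )
  pooled <- pool_replicates(m, meta)
  expect_equal(names(pooled), c("gene_id", "c1", "c2", "c3"))
  for (g in seq_len(10)) {
    for (cc in c("c1", "c2", "c3")) {
      cols <- meta$sample_id[meta$condition_id == cc]
      expect_equal(pooled[[cc]][g], mean(c(m[[cols[1]]][g], m[[cols[2]]][g])))
    }
  }
  # median pooling, and a single-replicate condition passes through unchanged
  meta1 <- meta
  meta1$condition_id[6] <- "c4"
  pooled_med <- pool_replicates(m, meta1, method = "median")
  expect_equal(pooled_med$c4, m$s6)

  # pooling commutes with gene (row) permutation
  perm <- sample(nrow(m))
  pooled_perm <- pool_replicates(m[perm, ], meta)
  expect_equal(pooled_perm, pooled[perm, ])

  # unknown sample and empty condition are errors
  expect_error(pool_replicates(m, meta[-1, ]), "without metadata")
  meta_extra <- dplyr::bind_rows(meta, tibble::tibble(
    sample_id = "ghost", condition_id = "c9", genotype = "XX",
    stage = "E9.5", cell_type = "GERM", replicate = 1L))
  expect_error(pool_replicates(m, meta_extra), "zero samples")
})
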