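retro_fixture <- function() {
  ann <- toy_annotation(
    c("px1", "px2", "px3", "ra1", "ra2", "ra3", "ra4", "ga1", "ga2"),
    c("X", "X", "X", rep("AUTOSOME", 4), "AUTOSOME", "AUTOSOME"))
  records <- tibble::tibble(
    retro_gene_id =    c("ra1", "ra2", "ra3", "ra4", "ra1", "ghost"),
    parent_gene_id =   c("px1", "px2", "px1", "px3", "ga1", "zzz"),
    retro_chromosome = c("chr5", "chr7", "chrX", "chr2", "chr5", "chr1"),
    intron_count =     c(0L, 0L, 0L, 1L, 0L, 0L),
    coding_status =    c("protein_coding", "protein_coding", "protein_coding",
                         "protein_coding", "protein_coding", "protein_coding"),
    percent_identity = c(92, 85.5, 99, 95, 91, 90)
  )
  list(ann = ann, records = records)
}

test_that("retrogene candidates are filtered on all published criteria", {
  f <- retro_fixture()
  ubiq_x <- c("px1", "px2", "px3")
  expect_warning(
    expect_message(
      acc <- filter_retrogene_candidates(f$records, f$ann, ubiq_x),
      "2 distinct X parent"),
    "unannotated")
  # ra3 rejected (retro on chrX), ra4 rejected (intron), ra1/ga1 rejected
  # (parent not X-linked), ghost dropped (unannotated)
  expect_setequal(acc$retro_gene_id, c("ra1", "ra2"))
  expect_equal(attr(acc, "n_parents"), 2L)

  # identity exactly 80 is rejected (strict > 80)
  rec80 <- f$records[1, ]
  rec80$percent_identity <- 80
  expect_message(acc80 <- filter_retrogene_candidates(rec80, f$ann, ubiq_x))
  expect_equal(nrow(acc80), 0L)

  # parent outside the ubiquitous X set is rejected
  expect_message(accx <- filter_retrogene_candidates(f$records[1, ], f$ann,
                                                     c("px2", "px3")))
  expect_equal(nrow(accx), 0L)
})

test_that("parent augmentation equals brute-force per-condition sums", {
  f <- retro_fixture()
  set.seed(88)
  vals <- matrix(rlnorm(9 * 3, 2, 1), nrow = 9)
  m <- toy_expr(vals, gene_ids = f$ann$gene_id,
                sample_ids = c("c1", "c2", "c3"))
  acc <- tibble::tibble(retro_gene_id = c("ra1", "ra2"),
                        parent_gene_id = c("px1", "px1"))
  aug <- augment_parent_expression(m, acc)
  for (cc in c("c1", "c2", "c3")) {
    expect_equal(aug[[cc]][aug$gene_id == "px1"],
                 m[[cc]][m$gene_id == "px1"] +
                   m[[cc]][m$gene_id == "ra1"] + m[[cc]][m$gene_id == "ra2"])
    # retro rows retained unchanged, other genes untouched
    expect_equal(aug[[cc]][aug$gene_id != "px1"], m[[cc]][m$gene_id != "px1"])
    # augmentation never decreases a parent
    expect_gte(aug[[cc]][aug$gene_id == "px1"], m[[cc]][m$gene_id == "px1"])
  }
  # empty accepted set: identity
  aug0 <- augment_parent_expression(m, acc[0, ])
  expect_equal(aug0, m, ignore_attr = TRUE)
})

test_that("augmented comparison: zero retro FPKM is a no-op, strong retros shift X up", {
  f <- retro_fixture()
  set.seed(31)
  n_extra_a <- 40; n_extra_x <- 20
  ann <- dplyr::bind_rows(
    f$ann,
    toy_annotation(paste0("bg_a", seq_len(n_extra_a)), rep("AUTOSOME", n_extra_a)),
    toy_annotation(paste0("bg_x", seq_len(n_extra_x)), rep("X", n_extra_x)))
  vals <- matrix(2^rnorm(nrow(ann) * 2, 3, 1), ncol = 2)
  m <- toy_expr(vals, gene_ids = ann$gene_id, sample_ids = c("c1", "c2"))
  acc <- tibble::tibble(retro_gene_id = c("ra1", "ra2"),
                        parent_gene_id = c("px1", "px2"))

  # retro FPKM all zero -> augmented equals raw exactly
  m0 <- m
  m0$c1[m0$gene_id %in% acc$retro_gene_id] <- 0
  m0$c2[m0$gene_id %in% acc$retro_gene_id] <- 0
  cmp0 <- augmented_xa_comparison(m0, ann, m0$gene_id, acc, n_boot = 500,
                                  seed = 3)
  expect_equal(cmp0$point.raw, cmp0$point.augmented)
  expect_equal(cmp0$ci_low.raw, cmp0$ci_low.augmented)
  expect_true(all(cmp0$delta_point == 0))

  # retros at 1% of parent expression: states unchanged
  m1 <- m
  for (cc in c("c1", "c2")) {
    m1[[cc]][match(acc$retro_gene_id, m1$gene_id)] <-
      0.01 * m1[[cc]][match(acc$parent_gene_id, m1$gene_id)]
  }
  cmp1 <- augmented_xa_comparison(m1, ann, m1$gene_id, acc, n_boot = 500,
                                  seed = 3)
  expect_equal(cmp1$state.raw, cmp1$state.augmented)

  # strongly expressed retros on weak parents: the X median must move upward
  # (parents sit at the bottom of the X distribution, augmentation lifts them
  # to the top, so the median order statistic strictly increases)
  m2 <- m
  for (cc in c("c1", "c2")) {
    m2[[cc]][match(acc$parent_gene_id, m2$gene_id)] <- c(0.011, 0.012)
    m2[[cc]][match(acc$retro_gene_id, m2$gene_id)] <- c(900.5, 901.5)
  }
  cmp2 <- augmented_xa_comparison(m2, ann, m2$gene_id, acc, n_boot = 500,
                                  seed = 3)
  expect_true(all(cmp2$delta_point > 0))

  # no double counting: accepted retros sit outside the autosomal background
  # of both arms of the comparison
  n_autosomes_total <- sum(ann$chrom_class == "AUTOSOME")
  expect_equal(unique(cmp2$n_a.augmented), n_autosomes_total - nrow(acc))
  expect_equal(unique(cmp2$n_a.raw), n_autosomes_total - nrow(acc))
})
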