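test_that("median ratio matches an independent sort-and-pick oracle", {
  expect_equal(median_xa_ratio(c(3, 1, 2), c(3, 1, 2)), 1)
  expect_equal(median_xa_ratio(c(2, 2, 2), c(1, 1, 1)), 2)
  set.seed(9)
  for (i in 1:20) {
    x <- rlnorm(51); a <- rlnorm(51)
    expect_equal(median_xa_ratio(x, a), oracle_median(x) / oracle_median(a))
    # even-length vectors too
    xe <- rlnorm(40); ae <- rlnorm(26)
    expect_equal(median_xa_ratio(xe, ae), oracle_median(xe) / oracle_median(ae))
  }
  expect_error(median_xa_ratio(c(1, 2), c(0, 0, 0)), "median is zero")
  expect_error(median_xa_ratio(numeric(0), 1), "non-empty")
})

test_that("degenerate constant vectors give an exact point CI", {
  est <- bootstrap_xa_ci(c(2, 2, 2), c(1, 1, 1), n_boot = 500, seed = 1)
  expect_equal(est$point, 2)
  expect_equal(est$ci_low, 2)
  expect_equal(est$ci_high, 2)
})

test_that("bootstrap replicate distribution equals brute-force index resampling", {
  # the order-statistic sampler must be distributionally identical to
  # resampling indices and taking medians, for odd and even sizes
  set.seed(21)
  for (n in c(5, 6)) {
    x <- rlnorm(n)
    fast <- withr::with_seed(1, xadose:::boot_median_sample(sort(x), 40000))
    brute <- replicate(40000, median(x[sample.int(n, n, replace = TRUE)]))
    expect_gt(suppressWarnings(ks.test(fast, brute)$p.value), 1e-4)
    # supports agree exactly (both draw from data order statistics)
    expect_true(all(unique(fast) %in% unique(brute)))
  }
})

test_that("Monte-Carlo percentile CI agrees with exhaustive 27x27 enumeration", {
  set.seed(33)
  x <- rlnorm(3); a <- rlnorm(3)
  grid <- oracle_boot_ratio_enumeration(x, a) # all 729 equally likely ratios
  est <- bootstrap_xa_ci(x, a, n_boot = 2e5, seed = 4)
  for (b in c(est$ci_low, est$ci_high)) {
    p <- if (b == est$ci_low) 0.025 else 0.975
    exact <- quantile(grid, p, type = 7, names = FALSE)
    # within one grid step of the enumerated distribution
    steps <- sort(unique(grid))
    i <- findInterval(exact, steps)
    lo <- steps[max(1, i - 1)]; hi <- steps[min(length(steps), i + 1)]
    expect_gte(b, lo)
    expect_lte(b, hi)
  }
})

test_that("seeded bootstrap is reproducible and scale invariant", {
  set.seed(12)
  x <- rlnorm(30); a <- rlnorm(80)
  e1 <- bootstrap_xa_ci(x, a, n_boot = 5000, seed = 99)
  e2 <- bootstrap_xa_ci(x, a, n_boot = 5000, seed = 99)
  expect_identical(tidy(e1), tidy(e2))
  # multiplying all FPKM by c > 0 leaves ratio, CI and state unchanged
  e3 <- bootstrap_xa_ci(7.3 * x, 7.3 * a, n_boot = 5000, seed = 99)
  expect_equal(e3$point, e1$point)
  expect_equal(e3$ci_low, e1$ci_low)
  expect_equal(e3$ci_high, e1$ci_high)
})

test_that("CI width shrinks stochastically with more genes", {
  set.seed(77)
  width <- function(n) {
    mean(replicate(10, {
      e <- bootstrap_xa_ci(rlnorm(n), rlnorm(n), n_boot = 2000)
      log(e$ci_high / e$ci_low)
    }))
  }
  expect_gt(width(10), width(160))
})

test_that("dosage states classify by CI position relative to 1", {
  df <- tibble::tibble(ci_low = c(0.95, 1.10, 0.70), ci_high = c(1.05, 1.30, 0.90))
  out <- classify_state(df)
  expect_equal(out$state, c("COMPENSATED", "EXCESS", "DECOMPENSATED"))
  # secondary flags
  df2 <- tibble::tibble(ci_low = c(0.4, 1.9), ci_high = c(0.6, 2.2))
  out2 <- classify_state(df2)
  expect_equal(out2$crosses_half, c(TRUE, FALSE))
  expect_equal(out2$crosses_two, c(FALSE, TRUE))
  expect_error(classify_state(tibble::tibble(ci_low = 2, ci_high = 1)),
               "ci_low")
})

test_that("threshold_sweep on one condition matches a direct bootstrap call", {
  set.seed(5)
  m <- toy_expr(matrix(rlnorm(60, 2, 1), ncol = 1))
  ann <- toy_annotation(m$gene_id, rep(c("X", rep("AUTOSOME", 4)), 12))
  sw <- threshold_sweep(m, ann, lower_thresholds = 1, n_boot = 3000, seed = 8)
  gs <- expressed_genes(m, "s1", 1)
  direct <- xa_ratio_table(m, ann, gs, n_boot = 3000, seed = 8,
                           gene_set_tag = "all_expressed")
  expect_equal(sw$point, direct$point)
  expect_equal(sw$ci_low, direct$ci_low)
  expect_equal(sw$ci_high, direct$ci_high)
})

test_that("per-condition estimates do not depend on condition processing order", {
  set.seed(6)
  m <- toy_expr(matrix(rlnorm(120, 2, 1), ncol = 2))
  ann <- toy_annotation(m$gene_id, rep(c("X", rep("AUTOSOME", 3)), 15))
  both <- xa_ratio_table(m, ann, m$gene_id, conditions = c("s1", "s2"),
                         n_boot = 2000, seed = 31)
  only_s2 <- xa_ratio_table(m, ann, m$gene_id, conditions = "s2",
                            n_boot = 2000, seed = 31)
  expect_equal(both[both$condition_id == "s2", ], only_s2)
})

test_that("Y-linked and excluded genes never enter the autosomal background", {
  m <- toy_expr(matrix(c(10, 10, 1, 1, 500, 500), ncol = 1))
  ann <- toy_annotation(m$gene_id, c("X", "X", "AUTOSOME", "AUTOSOME", "Y",
                                     "EXCLUDED"))
  est <- bootstrap_xa_ci_from <- xa_ratio_table(m, ann, m$gene_id,
                                                n_boot = 100, seed = 1)
  expect_equal(est$n_a, 2L) # the Y and EXCLUDED genes are not autosomes
  expect_equal(est$point, 10)
})
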