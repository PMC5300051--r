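# Shared fixtures and independent brute-force oracles.

toy_expr <- function(values, gene_ids = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  colnames(values) <- sample_ids
  dplyr::bind_cols(tibble::tibble(gene_id = gene_ids),
                   tibble::as_tibble(values))
}

toy_annotation <- function(gene_ids, chrom_class) {
  tibble::tibble(
    gene_id = gene_ids,
    chromosome = dplyr::case_when(
      chrom_class == "X" ~ "chrX",
      chrom_class == "Y" ~ "chrY",
      chrom_class == "EXCLUDED" ~ "chrM",
      TRUE ~ "chr1"
    ),
    chrom_class = chrom_class,
    biotype = "protein_coding",
    start = 1L, end = 1000L
  )
}

random_expr <- function(n_genes, n_samples, zeros = 0.1) {
  vals <- matrix(round(rlnorm(n_genes * n_samples, 1, 1), 4),
                 n_genes, n_samples)
  vals[runif(length(vals)) < zeros] <- 0
  toy_expr(vals)
}

# oracle: median by explicit sort-and-pick
oracle_median <- function(v) {
  s <- sort(v)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# oracle: the full discrete bootstrap distribution of the median ratio for
# small vectors, by exhaustive enumeration of all n^n x m^m resample pairs
oracle_boot_ratio_enumeration <- function(x, a) {
  n <- length(x); m <- length(a)
  x_res <- expand.grid(rep(list(seq_len(n)), n))
  a_res <- expand.grid(rep(list(seq_len(m)), m))
  med_x <- apply(x_res, 1, function(i) oracle_median(x[as.integer(i)]))
  med_a <- apply(a_res, 1, function(i) oracle_median(a[as.integer(i)]))
  sort(as.vector(outer(med_x, med_a, "/")))
}

# oracle: ubiquitous set by explicit nested-loop intersection
oracle_ubiquitous <- function(expr, samples, thr) {
  keep <- character(0)
  for (g in expr$gene_id) {
    all_ok <- TRUE
    for (s in samples) {
      if (expr[[s]][expr$gene_id == g] < thr) all_ok <- FALSE
    }
    if (all_ok) keep <- c(keep, g)
  }
  keep
}

# oracle: two-sample KS statistic by explicit ECDF sweep
oracle_ks_stat <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  fx <- vapply(grid, function(t) mean(x <= t), numeric(1))
  fy <- vapply(grid, function(t) mean(y <= t), numeric(1))
  max(abs(fx - fy))
}

# oracle: Wilcoxon rank-sum statistic by O(n*m) pair counting (ties = 1/2)
oracle_rank_sum <- function(x, y) {
  w <- 0
  for (xi in x) for (yj in y) {
    w <- w + (xi > yj) + 0.5 * (xi == yj)
  }
  w
}

# oracle: Spearman rho as Pearson correlation of midranks
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

truth_implied_state <- function(r) {
  ifelse(r > 1, "EXCESS", ifelse(r < 1, "DECOMPENSATED", "COMPENSATED"))
}
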