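# Distribution comparisons: pairwise log2 expression ratios between two
# conditions (X vs autosomes, KS test) and X-linked expression between
# genotypes (Wilcoxon).

#' Per-gene log2 expression ratios between two conditions
#'
#' Computes `log2(FPKM_a / FPKM_b)` per gene over a gene set; genes with zero
#' FPKM in either condition are dropped (count reported via the `n_dropped`
#' attribute and a message).
#'
#' @param expr Expression matrix tibble.
#' @param annotation Gene annotation.
#' @param cond_a,cond_b Condition columns (numerator, denominator).
#' @param gene_set Character vector of gene ids (or a `ubiquitous_set`).
#' @return A tibble with `gene_id`, `chrom_class`, `log2_ratio`.
#' @export
pairwise_log2_ratios <- function(expr, annotation, cond_a, cond_b, gene_set) {
  validate_expression(expr)
  validate_annotation(annotation)
  if (inherits(gene_set, "ubiquitous_set")) gene_set <- gene_set$gene_ids
  for (cc in c(cond_a, cond_b)) {
    if (!cc %in% sample_ids(expr)) abort(sprintf("unknown condition: %s", cc))
  }
  rows <- expr$gene_id %in% gene_set
  if (!any(rows)) abort("gene set has empty intersection with the matrix")
  tbl <- tibble(
    gene_id = expr$gene_id[rows],
    chrom_class = annotation$chrom_class[match(expr$gene_id[rows],
                                               annotation$gene_id)],
    a = expr[[cond_a]][rows],
    b = expr[[cond_b]][rows]
  )
  ok <- tbl$a > 0 & tbl$b > 0
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    inform(sprintf("%d gene(s) with zero FPKM in '%s' or '%s' dropped",
                   n_dropped, cond_a, cond_b))
  }
  out <- tbl[ok, ]
  out <- tibble(gene_id = out$gene_id, chrom_class = out$chrom_class,
                log2_ratio = log2(out$a / out$b))
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Kolmogorov-Smirnov test: X vs autosomal log-ratio distributions
#'
#' Two-sample KS test comparing the X-linked log2-ratio distribution with the
#' autosomal one; the statistic is the maximal ECDF gap.
#'
#' @param ratios A tibble from [pairwise_log2_ratios()].
#' @return A one-row tibble: `statistic`, `p_value`, `n_x`, `n_a`.
#' @export
ks_x_vs_autosomes <- function(ratios) {
  stopifnot(all(c("chrom_class", "log2_ratio") %in% names(ratios)))
  xs <- ratios$log2_ratio[ratios$chrom_class == "X"]
  as <- ratios$log2_ratio[ratios$chrom_class == "AUTOSOME"]
  if (length(xs) < 1 || length(as) < 1) {
    abort("need at least one X and one autosomal ratio")
  }
  kt <- suppressWarnings(ks.test(xs, as))
  tibble(statistic = unname(kt$statistic), p_value = kt$p.value,
         n_x = length(xs), n_a = length(as))
}

#' Wilcoxon comparison of X-linked expression between two conditions
#'
#' Compares the X-linked members of a gene set between two conditions, by
#' default as an unpaired rank-sum test on log2 FPKM. In paired mode, genes
#' (matched across conditions by id) are compared by signed ranks. Ties are
#' midranked; for larger samples the normal approximation with continuity
#' correction is used, exact enumeration below (`stats::wilcox.test`
#' semantics). A fully degenerate paired comparison (all differences zero) is
#' reported as not significant with `degenerate = TRUE`.
#'
#' @param expr Expression matrix tibble.
#' @param annotation Gene annotation.
#' @param cond_a,cond_b Condition columns.
#' @param gene_set Character vector of gene ids (or a `ubiquitous_set`).
#' @param mode `"unpaired_rank_sum"` or `"paired_signed_rank"`.
#' @param log2_transform Compare log2 FPKM (zeros dropped) rather than raw
#'   FPKM? Default `TRUE`.
#' @return A one-row tibble: `mode`, `statistic`, `p_value`, `n_a_cond`,
#'   `n_b_cond`, `degenerate`.
#' @export
wilcoxon_x_between_conditions <- function(expr, annotation, cond_a, cond_b,
                                          gene_set,
                                          mode = c("unpaired_rank_sum",
                                                   "paired_signed_rank"),
                                          log2_transform = TRUE) {
  mode <- arg_match(mode)
  validate_expression(expr)
  validate_annotation(annotation)
  if (inherits(gene_set, "ubiquitous_set")) gene_set <- gene_set$gene_ids
  rows <- expr$gene_id %in% gene_set
  ids <- expr$gene_id[rows]
  cls <- annotation$chrom_class[match(ids, annotation$gene_id)]
  xa <- expr[[cond_a]][rows][cls == "X" & !is.na(cls)]
  xb <- expr[[cond_b]][rows][cls == "X" & !is.na(cls)]
  if (mode == "paired_signed_rank") {
    if (log2_transform) {
      ok <- xa > 0 & xb > 0
      xa <- log2(xa[ok]); xb <- log2(xb[ok])
    }
    if (length(xa) < 2) abort("need >= 2 X-linked genes")
    if (all(xa == xb)) {
      return(tibble(mode = mode, statistic = NA_real_, p_value = 1,
                    n_a_cond = length(xa), n_b_cond = length(xb),
                    degenerate = TRUE))
    }
    wt <- suppressWarnings(wilcox.test(xa, xb, paired = TRUE, correct = TRUE))
  } else {
    if (log2_transform) {
      xa <- log2(xa[xa > 0]); xb <- log2(xb[xb > 0])
    }
    if (length(xa) < 2 || length(xb) < 2) abort("need >= 2 X-linked genes")
    wt <- suppressWarnings(wilcox.test(xa, xb, paired = FALSE, correct = TRUE))
  }
  tibble(mode = mode, statistic = unname(wt$statistic), p_value = wt$p.value,
         n_a_cond = length(xa), n_b_cond = length(xb), degenerate = FALSE)
}
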