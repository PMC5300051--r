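# X:A ratio estimation: ratio of medians, bootstrap percentile confidence
# intervals, dosage-state classification, threshold sweeps.

#' Ratio of medians
#'
#' Median FPKM of X-linked genes divided by median FPKM of autosomal genes.
#' Even-length medians are the mean of the two central order statistics.
#'
#' @param x_values,a_values Non-empty numeric FPKM vectors.
#' @return A single number.
#' @export
#' @examples
#' median_xa_ratio(c(2, 2, 2), c(1, 1, 1)) # 2
median_xa_ratio <- function(x_values, a_values) {
  if (length(x_values) == 0 || length(a_values) == 0) {
    abort("gene value vectors must be non-empty")
  }
  ma <- median(a_values)
  if (ma == 0) abort("autosomal median is zero; X:A ratio undefined")
  median(x_values) / ma
}

# --- bootstrap core ----------------------------------------------------------
# The nonparametric bootstrap of the median admits an exact O(1)-per-replicate
# sampler: the m-th order statistic of a with-replacement resample of size n
# from sorted data x equals x[ceiling(n * U_(m))], where U_(m) is the m-th
# order statistic of n iid uniforms, i.e. Beta(m, n - m + 1). For even n the
# median is the mean of the two central order statistics; U_(m+1) given
# U_(m) = u is u + (1 - u) * Beta(1, n - m). Sampling these Beta variates
# reproduces the resample-median distribution exactly (ties included, since
# only sorted-data indices are drawn) without materializing resamples.

# B draws from the bootstrap distribution of median(resample(x))
boot_median_sample <- function(x_sorted, B) {
  n <- length(x_sorted)
  if (n == 1L) return(rep(x_sorted, B))
  m <- (n + 1L) %/% 2L
  u1 <- rbeta(B, m, n - m + 1)
  lo <- pmax(1L, as.integer(ceiling(n * u1)))
  if (n %% 2L == 1L) {
    x_sorted[lo]
  } else {
    u2 <- u1 + (1 - u1) * rbeta(B, 1, n - m)
    hi <- pmax(lo, pmin(n, as.integer(ceiling(n * u2))))
    (x_sorted[lo] + x_sorted[hi]) / 2
  }
}

# B bootstrap replicates of median(x*)/median(a*), X and autosomes resampled
# independently at their own sizes; zero autosomal medians redrawn.
boot_ratio_replicates <- function(x, a, B) {
  xs <- sort(x)
  as <- sort(a)
  mx <- boot_median_sample(xs, B)
  ma <- boot_median_sample(as, B)
  n_redrawn <- 0L
  guard <- 0L
  while (any(ma == 0)) {
    idx <- which(ma == 0)
    n_redrawn <- n_redrawn + length(idx)
    ma[idx] <- boot_median_sample(as, length(idx))
    guard <- guard + 1L
    if (guard > 1000L) abort("autosomal resample median persistently zero")
  }
  list(ratios = mx / ma, n_redrawn = n_redrawn)
}

#' Bootstrap X:A ratio with percentile confidence interval
#'
#' Resamples the X and autosomal gene sets independently with replacement at
#' their own sizes, computes the median ratio per replicate, and returns the
#' percentile interval at levels `alpha/2` and `1 - alpha/2`. Replicates with
#' an all-zero autosomal resample are redrawn (counted in `n_redrawn`).
#' Deterministic for a fixed seed.
#'
#' @param x_values,a_values FPKM vectors for X-linked and autosomal genes.
#' @param n_boot Number of bootstrap replications (default 1e6).
#' @param alpha Two-sided error level (default 0.05, i.e. a 95% CI).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param keep_replicates Keep the replicate ratios in the result?
#' @param condition_id,gene_set_tag Labels carried into the result.
#' @return An object of class `xa_boot` with elements `point`, `ci_low`,
#'   `ci_high`, `n_x`, `n_a`, `n_boot`, `alpha`, `n_redrawn`, plus labels;
#'   see [tidy.xa_boot()].
#' @export
#' @examples
#' est <- bootstrap_xa_ci(rlnorm(50), rlnorm(200), n_boot = 1000, seed = 1)
#' tidy(est)
bootstrap_xa_ci <- function(x_values, a_values, n_boot = 1e6, alpha = 0.05,
                            seed = NULL, keep_replicates = FALSE,
                            condition_id = NA_character_,
                            gene_set_tag = NA_character_) {
  if (length(x_values) == 0 || length(a_values) == 0) {
    abort("gene value vectors must be non-empty")
  }
  stopifnot(n_boot >= 1, alpha > 0, alpha < 1)
  point <- median_xa_ratio(x_values, a_values)
  res <- with_seed(seed, boot_ratio_replicates(x_values, a_values, n_boot))
  if (res$n_redrawn > 0) {
    warn(sprintf("%d bootstrap replicate(s) with zero autosomal median redrawn",
                 res$n_redrawn))
  }
  ci <- quantile(res$ratios, c(alpha / 2, 1 - alpha / 2), type = 7,
                 names = FALSE)
  structure(
    list(point = point, ci_low = ci[1], ci_high = ci[2],
         n_x = length(x_values), n_a = length(a_values),
         n_boot = as.integer(n_boot), alpha = alpha,
         n_redrawn = res$n_redrawn,
         condition_id = condition_id, gene_set_tag = gene_set_tag,
         replicates = if (keep_replicates) res$ratios else NULL),
    class = "xa_boot"
  )
}

#' @export
print.xa_boot <- function(x, ...) {
  cat(sprintf(
    "X:A ratio %.4f, %g%% CI [%.4f, %.4f] (n_x=%d, n_a=%d, %d bootstrap reps)\n",
    x$point, 100 * (1 - x$alpha), x$ci_low, x$ci_high, x$n_x, x$n_a, x$n_boot))
  invisible(x)
}

#' Tidy an X:A bootstrap estimate
#'
#' @param x An `xa_boot` object.
#' @param ... Unused.
#' @return A one-row tibble: `condition_id`, `gene_set_tag`, `point`,
#'   `ci_low`, `ci_high`, `n_x`, `n_a`, `n_boot`, `alpha`, `state`,
#'   `crosses_half`, `crosses_two`.
#' @method tidy xa_boot
#' @export
tidy.xa_boot <- function(x, ...) {
  classify_state(tibble(
    condition_id = x$condition_id, gene_set_tag = x$gene_set_tag,
    point = x$point, ci_low = x$ci_low, ci_high = x$ci_high,
    n_x = x$n_x, n_a = x$n_a, n_boot = x$n_boot, alpha = x$alpha
  ))
}

#' @rdname tidy.xa_boot
#' @method glance xa_boot
#' @export
glance.xa_boot <- function(x, ...) tidy.xa_boot(x)

#' Classify dosage states from X:A confidence intervals
#'
#' Primary state per estimate: `EXCESS` if `ci_low > 1`, `DECOMPENSATED` if
#' `ci_high < 1`, otherwise `COMPENSATED` (the interval crosses 1). Secondary
#' flags record whether the interval crosses 0.5 (a single un-upregulated X)
#' or 2.
#'
#' @param x A data frame with `ci_low` and `ci_high` columns (e.g. from
#'   [threshold_sweep()]), or an `xa_boot` object.
#' @param ... Passed between methods.
#' @return For data frames: the input with `state`, `crosses_half`,
#'   `crosses_two` columns added. For `xa_boot`: a one-row tibble.
#' @export
classify_state <- function(x, ...) UseMethod("classify_state")

#' @export
classify_state.data.frame <- function(x, ...) {
  stopifnot(all(c("ci_low", "ci_high") %in% names(x)))
  if (any(x$ci_low > x$ci_high, na.rm = TRUE)) abort("ci_low > ci_high")
  x$state <- dplyr::case_when(
    x$ci_low > 1 ~ "EXCESS",
    x$ci_high < 1 ~ "DECOMPENSATED",
    TRUE ~ "COMPENSATED"
  )
  x$crosses_half <- x$ci_low <= 0.5 & x$ci_high >= 0.5
  x$crosses_two <- x$ci_low <= 2 & x$ci_high >= 2
  x
}

#' @export
classify_state.xa_boot <- function(x, ...) tidy.xa_boot(x)

# --- condition-level estimation ---------------------------------------------

# X and autosomal FPKM vectors for one condition restricted to a gene set;
# Y-linked and EXCLUDED genes never enter the autosomal background.
xa_gene_values <- function(expr, annotation, condition, gene_set) {
  validate_annotation(annotation)
  rows <- expr$gene_id %in% gene_set
  ids <- expr$gene_id[rows]
  cls <- annotation$chrom_class[match(ids, annotation$gene_id)]
  if (anyNA(cls)) {
    abort(paste0("gene(s) without annotation: ",
                 paste(head(ids[is.na(cls)], 5), collapse = ", ")))
  }
  v <- expr[[condition]][rows]
  list(x = v[cls == "X"], a = v[cls == "AUTOSOME"])
}

#' Per-condition X:A ratio estimates for a fixed gene set
#'
#' @param expr Expression matrix tibble (typically pooled conditions).
#' @param annotation Gene annotation tibble.
#' @param gene_set Character vector of gene ids (or a `ubiquitous_set`).
#' @param conditions Condition columns (default all).
#' @param n_boot,alpha Bootstrap parameters.
#' @param seed Base seed; each condition uses [derive_seed()] on its id so
#'   estimates do not depend on processing order.
#' @param gene_set_tag Label recorded in the output.
#' @return A tibble with one classified estimate per condition.
#' @export
xa_ratio_table <- function(expr, annotation, gene_set, conditions = NULL,
                           n_boot = 1e6, alpha = 0.05, seed = NULL,
                           gene_set_tag = "custom") {
  validate_expression(expr)
  if (inherits(gene_set, "ubiquitous_set")) gene_set <- gene_set$gene_ids
  if (is.null(conditions)) conditions <- sample_ids(expr)
  purrr::map_dfr(conditions, function(cid) {
    gv <- xa_gene_values(expr, annotation, cid, gene_set)
    if (length(gv$x) == 0 || length(gv$a) == 0) {
      warn(sprintf("condition '%s': no %s genes in set; estimate omitted",
                   cid, if (length(gv$x) == 0) "X" else "autosomal"))
      return(NULL)
    }
    s <- if (is.null(seed)) NULL else derive_seed(seed, cid)
    tidy(bootstrap_xa_ci(gv$x, gv$a, n_boot = n_boot, alpha = alpha, seed = s,
                         condition_id = cid, gene_set_tag = gene_set_tag))
  })
}

#' Sweep lower FPKM thresholds and estimate X:A ratios per condition
#'
#' For each (condition, threshold) cell the gene vectors are drawn according
#' to `gene_set_mode`:
#' * `all_expressed` — genes with FPKM >= threshold in that condition;
#' * `ubiquitous` — genes with FPKM >= threshold in **all** analysed
#'   conditions;
#' * `ubiquitous_upper` — the ubiquitous set after the upper-centile
#'   exclusion ([apply_upper_threshold()]).
#'
#' @param expr Expression matrix tibble.
#' @param annotation Gene annotation.
#' @param conditions Condition columns (default all).
#' @param lower_thresholds Ascending FPKM thresholds; default
#'   `c(0, 0.25, 0.5, 1)`.
#' @param gene_set_mode See above.
#' @param upper_centile Centile for `ubiquitous_upper` (default 99).
#' @param n_boot,alpha,seed As in [xa_ratio_table()].
#' @return A tibble of classified estimates with `lower_fpkm` column; cells
#'   with zero X (or autosomal) genes are omitted with a warning.
#' @export
threshold_sweep <- function(expr, annotation, conditions = NULL,
                            lower_thresholds = c(0, 0.25, 0.5, 1),
                            gene_set_mode = c("all_expressed", "ubiquitous",
                                              "ubiquitous_upper"),
                            upper_centile = 99,
                            n_boot = 1e6, alpha = 0.05, seed = NULL) {
  gene_set_mode <- arg_match(gene_set_mode)
  validate_expression(expr)
  if (is.unsorted(lower_thresholds)) {
    abort("`lower_thresholds` must be sorted ascending")
  }
  if (is.null(conditions)) conditions <- sample_ids(expr)
  purrr::map_dfr(lower_thresholds, function(thr) {
    if (gene_set_mode == "all_expressed") {
      out <- purrr::map_dfr(conditions, function(cid) {
        gs <- expressed_genes(expr, cid, thr)
        if (length(gs) == 0) {
          warn(sprintf("condition '%s', threshold %g: empty gene set", cid, thr))
          return(NULL)
        }
        xa_ratio_table(expr, annotation, gs, conditions = cid,
                       n_boot = n_boot, alpha = alpha, seed = seed,
                       gene_set_tag = "all_expressed")
      })
    } else {
      gset <- build_ubiquitous_set(expr, order = conditions, lower_fpkm = thr,
                                   annotation = NULL)
      if (gene_set_mode == "ubiquitous_upper") {
        gset <- apply_upper_threshold(gset, expr, conditions = conditions,
                                      centile = upper_centile)
      }
      out <- xa_ratio_table(expr, annotation, gset, conditions = conditions,
                            n_boot = n_boot, alpha = alpha, seed = seed,
                            gene_set_tag = gene_set_mode)
    }
    if (nrow(out) > 0) out$lower_fpkm <- thr
    out
  })
}
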