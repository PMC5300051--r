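# ggplot2 visualisations for the main result types.

#' @describeIn build_ubiquitous_set Plot the stepwise sample-addition
#'   trajectory (surviving gene count vs samples included).
#' @param object A `ubiquitous_set`.
#' @method autoplot ubiquitous_set
#' @export
autoplot.ubiquitous_set <- function(object, ...) {
  ggplot2::ggplot(object$trajectory,
                  ggplot2::aes(x = .data$samples_included,
                               y = .data$genes_surviving)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "samples included",
                  y = sprintf("genes with FPKM >= %g in all samples",
                              object$lower_fpkm),
                  title = "Ubiquitous gene-set construction") +
    ggplot2::theme_minimal()
}

#' @describeIn bootstrap_xa_ci Histogram of bootstrap replicate ratios with
#'   the point estimate and CI marked (requires `keep_replicates = TRUE`).
#' @param object An `xa_boot` object.
#' @param ... Unused.
#' @method autoplot xa_boot
#' @export
autoplot.xa_boot <- function(object, ...) {
  if (is.null(object$replicates)) {
    abort("no replicates stored; rerun with keep_replicates = TRUE")
  }
  df <- tibble(ratio = object$replicates)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$point, colour = "black") +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$ci_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "bootstrap median X:A ratio", y = "replicates",
                  title = "Bootstrap distribution of the X:A ratio") +
    ggplot2::theme_minimal()
}

#' Plot per-condition X:A ratio estimates with confidence intervals
#'
#' Points with CI error bars across conditions, reference lines at 0.5, 1 and
#' 2, coloured by dosage state, faceted by gene-set tag when several are
#' present.
#'
#' @param estimates A tibble of classified estimates (e.g. from
#'   [threshold_sweep()] or [xa_ratio_table()]).
#' @return A ggplot object.
#' @export
plot_xa_ratios <- function(estimates) {
  stopifnot(all(c("condition_id", "point", "ci_low", "ci_high") %in%
                  names(estimates)))
  if (!"state" %in% names(estimates)) estimates <- classify_state(estimates)
  p <- ggplot2::ggplot(estimates,
                       ggplot2::aes(x = .data$condition_id, y = .data$point,
                                    colour = .data$state)) +
    ggplot2::geom_hline(yintercept = 1, colour = "grey30") +
    ggplot2::geom_hline(yintercept = c(0.5, 2), colour = "grey70",
                        linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::labs(x = NULL, y = "X:A ratio (log2 scale)", colour = "state") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  if ("gene_set_tag" %in% names(estimates) &&
      dplyr::n_distinct(estimates$gene_set_tag) > 1) {
    p <- p + ggplot2::facet_wrap(~gene_set_tag)
  }
  p
}

#' Density plot of pairwise log2 expression ratios, X vs autosomes
#'
#' @param ratios A tibble from [pairwise_log2_ratios()].
#' @return A ggplot object.
#' @export
plot_ratio_density <- function(ratios) {
  stopifnot(all(c("chrom_class", "log2_ratio") %in% names(ratios)))
  df <- ratios[ratios$chrom_class %in% c("X", "AUTOSOME"), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_ratio,
                                   colour = .data$chrom_class)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "log2 FPKM ratio", y = "density",
                  colour = "chromosome class") +
    ggplot2::theme_minimal()
}
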