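# X-derived autosomal retrogenes: candidate filtering and parent-expression
# augmentation for recomputed X:A ratios.

#' Filter candidate retrogenes of X-linked parents
#'
#' Accepts records that are (i) autosomally encoded, (ii) intronless,
#' (iii) putatively protein coding, (iv) share strictly more than 80%
#' nucleotide identity with their X-linked parent, and (v) whose parent gene
#' is X-annotated and a member of the supplied ubiquitous X set. Records
#' referencing unannotated genes are dropped with a warning.
#'
#' @param records Tibble with columns `retro_gene_id`, `parent_gene_id`,
#'   `retro_chromosome`, `intron_count`, `coding_status`, `percent_identity`.
#' @param annotation Gene annotation (used to check the parent's class).
#' @param ubiquitous_x Character vector of ubiquitous X-linked gene ids (or a
#'   `ubiquitous_set`, from which X members are taken via `annotation`).
#' @param min_identity Identity threshold, exclusive (default 80).
#' @return The accepted records, with attribute `n_parents` (distinct parent
#'   count, also reported via a message).
#' @export
filter_retrogene_candidates <- function(records, annotation, ubiquitous_x,
                                        min_identity = 80) {
  need <- c("retro_gene_id", "parent_gene_id", "retro_chromosome",
            "intron_count", "coding_status", "percent_identity")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    abort(paste0("records lack column(s): ", paste(miss, collapse = ", ")))
  }
  validate_annotation(annotation)
  if (inherits(ubiquitous_x, "ubiquitous_set")) {
    ids <- ubiquitous_x$gene_ids
    cls <- annotation$chrom_class[match(ids, annotation$gene_id)]
    ubiquitous_x <- ids[!is.na(cls) & cls == "X"]
  }
  parent_cls <- annotation$chrom_class[match(records$parent_gene_id,
                                             annotation$gene_id)]
  unann <- is.na(parent_cls)
  if (any(unann)) {
    warn(sprintf("%d record(s) referencing unannotated parent genes dropped",
                 sum(unann)))
  }
  # classify the retro's own chromosome label (annotation row not required)
  retro_chr <- sub("^chr", "", records$retro_chromosome, ignore.case = TRUE)
  retro_autosomal <- grepl("^[0-9]+$", retro_chr)
  keep <- !unann &
    parent_cls == "X" &
    records$parent_gene_id %in% ubiquitous_x &
    retro_autosomal &
    records$intron_count == 0 &
    records$coding_status == "protein_coding" &
    records$percent_identity > min_identity
  out <- records[keep, ]
  n_parents <- dplyr::n_distinct(out$parent_gene_id)
  inform(sprintf("%d accepted retrogene record(s) for %d distinct X parent(s)",
                 nrow(out), n_parents))
  attr(out, "n_parents") <- n_parents
  out
}

#' Add accepted retrogene FPKM onto the parental X-linked loci
#'
#' Per condition, each parent's FPKM becomes its own FPKM plus the sum of the
#' FPKMs of its accepted retrogenes. Retro rows are retained unchanged; their
#' ids are recorded in the `retro_gene_ids` attribute so downstream ratio
#' calls can exclude them from the autosomal background (no transcription is
#' counted twice).
#'
#' @param expr Expression matrix tibble containing both parents and retros.
#' @param accepted Accepted records from [filter_retrogene_candidates()].
#' @return The augmented expression matrix.
#' @export
augment_parent_expression <- function(expr, accepted) {
  validate_expression(expr)
  if (nrow(accepted) == 0) {
    attr(expr, "retro_gene_ids") <- character(0)
    return(expr)
  }
  missing <- setdiff(unique(c(accepted$parent_gene_id, accepted$retro_gene_id)),
                     expr$gene_id)
  if (length(missing) > 0) {
    abort(paste0("gene(s) absent from the matrix: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  samp <- sample_ids(expr)
  out <- expr
  for (p in unique(accepted$parent_gene_id)) {
    retros <- accepted$retro_gene_id[accepted$parent_gene_id == p]
    prow <- which(out$gene_id == p)
    rrows <- which(out$gene_id %in% retros)
    for (s in samp) {
      out[[s]][prow] <- out[[s]][prow] + sum(out[[s]][rrows])
    }
  }
  attr(out, "retro_gene_ids") <- unique(accepted$retro_gene_id)
  out
}

# annotation variant in which accepted retro rows are EXCLUDED, so they never
# enter the autosomal background of augmented ratios
mark_retro_excluded <- function(annotation, accepted) {
  annotation$chrom_class[annotation$gene_id %in% accepted$retro_gene_id] <-
    "EXCLUDED"
  annotation
}

#' Raw vs retrogene-augmented X:A ratios, side by side
#'
#' Estimates each condition's X:A ratio twice under identical seeds and gene
#' sets: once from the raw matrix and once after [augment_parent_expression()],
#' and reports the paired estimates plus their difference. Accepted retro rows
#' are excluded from the autosomal background of *both* estimates, so the
#' comparison isolates the effect of the added expression (and transcription
#' is never counted twice); with all retro FPKMs zero the two columns are
#' identical.
#'
#' @param expr Expression matrix tibble.
#' @param annotation Gene annotation.
#' @param gene_set Gene ids (or `ubiquitous_set`) used for both estimates.
#' @param accepted Accepted retrogene records.
#' @param conditions Condition columns (default all).
#' @param n_boot,alpha,seed Bootstrap parameters (see [xa_ratio_table()]).
#' @return A tibble with one row per condition and `.raw` / `.augmented`
#'   suffixed estimate columns plus `delta_point`.
#' @export
augmented_xa_comparison <- function(expr, annotation, gene_set, accepted,
                                    conditions = NULL, n_boot = 1e4,
                                    alpha = 0.05, seed = 1) {
  ann_noretro <- mark_retro_excluded(annotation, accepted)
  raw <- xa_ratio_table(expr, ann_noretro, gene_set, conditions = conditions,
                        n_boot = n_boot, alpha = alpha, seed = seed,
                        gene_set_tag = "raw")
  aug_expr <- augment_parent_expression(expr, accepted)
  aug <- xa_ratio_table(aug_expr, ann_noretro, gene_set, conditions = conditions,
                        n_boot = n_boot, alpha = alpha, seed = seed,
                        gene_set_tag = "augmented")
  keep <- c("condition_id", "point", "ci_low", "ci_high", "n_x", "n_a", "state")
  out <- left_join(raw[, keep], aug[, keep], by = "condition_id",
                   suffix = c(".raw", ".augmented"))
  out$delta_point <- out$point.augmented - out$point.raw
  out
}
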