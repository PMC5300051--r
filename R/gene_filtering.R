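# Expressed / ubiquitous gene-set construction under lower FPKM thresholds,
# and the upper-centile expression exclusion.

#' Genes expressed in one sample at a lower FPKM threshold
#'
#' Inclusive comparison: a gene with FPKM exactly equal to `lower_fpkm` is
#' expressed. `lower_fpkm = 0` therefore returns all genes.
#'
#' @param expr Expression matrix tibble.
#' @param sample Sample/condition column name.
#' @param lower_fpkm Non-negative threshold (default 1).
#' @return Character vector of gene ids.
#' @export
expressed_genes <- function(expr, sample, lower_fpkm = 1) {
  validate_expression(expr)
  stopifnot(lower_fpkm >= 0)
  if (!sample %in% sample_ids(expr)) {
    abort(sprintf("unknown sample: %s", sample))
  }
  expr$gene_id[expr[[sample]] >= lower_fpkm]
}

#' Build the ubiquitous (housekeeping-proxy) gene set
#'
#' Adds samples stepwise, on each addition retaining only genes expressed
#' (FPKM >= `lower_fpkm`) in every sample so far; the final set is the
#' intersection over all samples and is independent of the addition order.
#' The recorded trajectory (running intersection size) reproduces the familiar
#' drop-then-plateau curve as samples accumulate.
#'
#' @param expr Expression matrix tibble (samples or pooled conditions).
#' @param order Character vector of sample columns in addition order; default
#'   all columns in matrix order.
#' @param lower_fpkm Inclusive lower FPKM threshold (default 1).
#' @param annotation Optional gene annotation; when supplied, genes annotated
#'   `EXCLUDED` (rRNA, mitochondrial, very highly abundant) are ignored from
#'   the universe before construction, and per-class member counts are
#'   tallied.
#' @return An object of class `ubiquitous_set`: a list with `gene_ids`,
#'   `lower_fpkm`, `trajectory` (tibble: `sample_id`, `samples_included`,
#'   `genes_surviving`), `counts_by_class`, `universe` (the set before any
#'   upper-threshold exclusion), `upper_centile`, `upper_threshold`.
#' @export
#' @examples
#' expr <- tibble::tibble(gene_id = paste0("g", 1:3),
#'                        a = c(2, 1, 0), b = c(5, 0, 2))
#' build_ubiquitous_set(expr, lower_fpkm = 1)
build_ubiquitous_set <- function(expr, order = NULL, lower_fpkm = 1,
                                 annotation = NULL) {
  validate_expression(expr)
  if (is.null(order)) order <- sample_ids(expr)
  if (length(order) == 0) abort("`order` must name at least one sample")
  bad <- setdiff(order, sample_ids(expr))
  if (length(bad) > 0) {
    abort(paste0("unknown sample(s) in `order`: ", paste(bad, collapse = ", ")))
  }
  if (!is.null(annotation)) {
    validate_annotation(annotation)
    excl <- annotation$gene_id[annotation$chrom_class == "EXCLUDED"]
    expr <- expr[!expr$gene_id %in% excl, ]
  }
  keep <- rep(TRUE, nrow(expr))
  sizes <- integer(length(order))
  for (i in seq_along(order)) {
    keep <- keep & (expr[[order[i]]] >= lower_fpkm)
    sizes[i] <- sum(keep)
  }
  ids <- expr$gene_id[keep]
  out <- structure(
    list(
      gene_ids = ids,
      lower_fpkm = lower_fpkm,
      trajectory = tibble(sample_id = order,
                          samples_included = seq_along(order),
                          genes_surviving = sizes),
      counts_by_class = count_by_class(ids, annotation),
      universe = ids,
      upper_centile = NA_real_,
      upper_threshold = NA_real_
    ),
    class = "ubiquitous_set"
  )
  out
}

count_by_class <- function(ids, annotation) {
  if (is.null(annotation)) return(NULL)
  validate_annotation(annotation)
  cls <- annotation$chrom_class[match(ids, annotation$gene_id)]
  tab <- table(factor(cls, levels = chrom_classes))
  setNames(as.integer(tab), names(tab))
}

#' Upper FPKM threshold: the lowest per-condition top centile
#'
#' For each condition, the `centile`-th percentile of FPKM over the gene
#' universe in use is computed (linear interpolation between order statistics,
#' R quantile type 7); the threshold is the minimum across conditions.
#'
#' @param expr Expression matrix tibble.
#' @param conditions Condition columns (default all).
#' @param centile Percentile in (0, 100]; default 99.
#' @param genes Gene universe (default all genes in `expr`).
#' @return A single FPKM value.
#' @export
upper_threshold_value <- function(expr, conditions = NULL, centile = 99,
                                  genes = NULL) {
  validate_expression(expr)
  stopifnot(centile > 0, centile <= 100)
  if (is.null(conditions)) conditions <- sample_ids(expr)
  if (is.null(genes)) genes <- expr$gene_id
  rows <- expr$gene_id %in% genes
  if (!any(rows)) abort("empty gene universe")
  per_cond <- vapply(conditions, function(cid) {
    quantile(expr[[cid]][rows], probs = centile / 100, type = 7, names = FALSE)
  }, numeric(1))
  min(per_cond)
}

#' Apply the upper-centile exclusion to a ubiquitous gene set
#'
#' Removes any gene whose FPKM strictly exceeds [upper_threshold_value()] in
#' any listed condition; the exclusion is global (one fixed reduced set).
#' The centile is always computed over the set's original (pre-exclusion)
#' universe, so the operation is idempotent.
#'
#' @param gset A `ubiquitous_set`.
#' @param expr The expression matrix the set was built from.
#' @param conditions Condition columns (default all).
#' @param centile Percentile in (0, 100]; default 99.
#' @param annotation Optional annotation for per-class counts.
#' @return The reduced `ubiquitous_set`, with `upper_centile` and
#'   `upper_threshold` recorded.
#' @export
apply_upper_threshold <- function(gset, expr, conditions = NULL, centile = 99,
                                  annotation = NULL) {
  stopifnot(inherits(gset, "ubiquitous_set"))
  validate_expression(expr)
  if (is.null(conditions)) conditions <- sample_ids(expr)
  if (length(gset$universe) == 0) {
    gset$upper_centile <- centile
    return(gset) # nothing to exclude from an empty set
  }
  thr <- upper_threshold_value(expr, conditions, centile, genes = gset$universe)
  rows <- expr$gene_id %in% gset$gene_ids
  vals <- expr_values(expr[rows, c("gene_id", conditions)])
  over <- rownames(vals)[apply(vals > thr, 1, any)]
  gset$gene_ids <- setdiff(gset$gene_ids, over)
  gset$upper_centile <- centile
  gset$upper_threshold <- thr
  gset$counts_by_class <- count_by_class(gset$gene_ids, annotation)
  gset
}

#' @export
print.ubiquitous_set <- function(x, ...) {
  cat(sprintf("Ubiquitous gene set: %d genes (FPKM >= %g in all %d samples)\n",
              length(x$gene_ids), x$lower_fpkm, nrow(x$trajectory)))
  if (!is.na(x$upper_centile)) {
    cat(sprintf("  upper exclusion: centile %g, threshold FPKM %.6g\n",
                x$upper_centile, x$upper_threshold))
  }
  if (!is.null(x$counts_by_class)) {
    cb <- x$counts_by_class
    cat(sprintf("  by class: %s\n",
                paste(sprintf("%s=%d", names(cb), cb), collapse = ", ")))
  }
  invisible(x)
}

#' @rdname build_ubiquitous_set
#' @param x A `ubiquitous_set`.
#' @param ... Unused.
#' @method tidy ubiquitous_set
#' @export
tidy.ubiquitous_set <- function(x, ...) {
  x$trajectory
}

#' @rdname build_ubiquitous_set
#' @method glance ubiquitous_set
#' @export
glance.ubiquitous_set <- function(x, ...) {
  cb <- x$counts_by_class
  tibble(
    n_genes = length(x$gene_ids),
    lower_fpkm = x$lower_fpkm,
    upper_centile = x$upper_centile,
    upper_threshold = x$upper_threshold,
    n_autosomal = if (is.null(cb)) NA_integer_ else cb[["AUTOSOME"]],
    n_x = if (is.null(cb)) NA_integer_ else cb[["X"]]
  )
}

#' Serialize / read a gene set as one-gene-per-line text with a JSON sidecar
#'
#' @param gset A `ubiquitous_set`.
#' @param path Output path for the gene list; the sidecar is `<path>.json` and
#'   the trajectory is written to `<path>.trajectory.tsv`.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(gset, path) {
  stopifnot(inherits(gset, "ubiquitous_set"))
  writeLines(gset$gene_ids, path)
  side <- list(lower_fpkm = gset$lower_fpkm,
               upper_centile = gset$upper_centile,
               upper_threshold = gset$upper_threshold,
               counts_by_class = as.list(gset$counts_by_class))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  readr::write_tsv(gset$trajectory, paste0(path, ".trajectory.tsv"),
                   progress = FALSE)
  invisible(path)
}
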