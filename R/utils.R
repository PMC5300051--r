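# Shared internal helpers: validation, seed derivation, formatting.

chrom_classes <- c("AUTOSOME", "X", "Y", "EXCLUDED")

#' Derive a reproducible sub-seed from a base seed and a string key
#'
#' Used so that per-condition bootstrap estimates are independent of the order
#' in which conditions are processed: each condition gets its own seed, a
#' deterministic function of the base seed and the condition identifier.
#'
#' @param seed Integer base seed.
#' @param key Character scalar (e.g. a condition id).
#' @return An integer in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1, "XX.germ.E14.5")
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  codes <- utf8ToInt(as.character(key))
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647)
}

# Evaluate `expr` with the RNG seeded by `seed` (NULL = leave RNG state alone),
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# --- expression-matrix helpers -----------------------------------------------
# An expression matrix is a tibble whose first column is `gene_id` (character,
# unique) and whose remaining columns are numeric, non-negative, finite FPKM
# values, one column per sample/condition.

validate_expression <- function(expr, arg = "expr") {
  if (!is.data.frame(expr)) abort(sprintf("`%s` must be a data frame", arg))
  if (!"gene_id" %in% names(expr)) {
    abort(sprintf("`%s` must have a `gene_id` column", arg))
  }
  ids <- expr$gene_id
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf("duplicated gene id(s): %s",
                  paste(head(dup, 5), collapse = ", ")))
  }
  samp <- setdiff(names(expr), "gene_id")
  if (length(samp) == 0) abort(sprintf("`%s` has no sample columns", arg))
  if (anyDuplicated(samp)) abort("duplicated sample id(s)")
  for (s in samp) {
    v <- expr[[s]]
    if (!is.numeric(v)) abort(sprintf("column '%s' is not numeric", s))
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad) > 0) {
      abort(sprintf("negative or non-finite FPKM at gene '%s', sample '%s'",
                    ids[bad[1]], s))
    }
  }
  invisible(expr)
}

sample_ids <- function(expr) setdiff(names(expr), "gene_id")

# numeric matrix (genes x samples) view of an expression tibble
expr_values <- function(expr) {
  m <- as.matrix(expr[, sample_ids(expr), drop = FALSE])
  rownames(m) <- expr$gene_id
  m
}

validate_annotation <- function(ann) {
  if (!is.data.frame(ann)) abort("`annotation` must be a data frame")
  need <- c("gene_id", "chrom_class")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0) {
    abort(paste0("annotation lacks column(s): ", paste(miss, collapse = ", ")))
  }
  bad <- setdiff(unique(ann$chrom_class), chrom_classes)
  if (length(bad) > 0) {
    abort(paste0("unknown chrom_class value(s): ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(ann$gene_id)) abort("annotation has duplicated gene ids")
  invisible(ann)
}

validate_metadata <- function(meta) {
  if (!is.data.frame(meta)) abort("`metadata` must be a data frame")
  need <- c("sample_id", "condition_id", "genotype", "stage", "cell_type",
            "replicate")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0) {
    abort(paste0("metadata lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(meta$sample_id)) abort("metadata has duplicated sample ids")
  invisible(meta)
}

# fixed 6-significant-digit formatting for report files (stable diffs)
signif6 <- function(x) {
  if (is.numeric(x)) signif(x, 6) else x
}
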