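# Compendium quality control: replicate Spearman correlation, Jensen-Shannon
# distances between conditions, hierarchical clustering with Newick export.

#' Pairwise Spearman correlation between samples
#'
#' Spearman rho on the gene-set rows, ties midranked. Pairs involving a
#' constant expression vector have undefined rho and are reported as `NA`
#' (with a warning).
#'
#' @param expr Expression matrix tibble (>= 2 samples).
#' @param gene_set Optional gene ids to restrict to (or a `ubiquitous_set`).
#' @return A symmetric correlation matrix with sample ids as dimnames.
#' @export
spearman_matrix <- function(expr, gene_set = NULL) {
  validate_expression(expr)
  if (inherits(gene_set, "ubiquitous_set")) gene_set <- gene_set$gene_ids
  if (length(sample_ids(expr)) < 2) abort("need >= 2 samples")
  vals <- expr_values(expr)
  if (!is.null(gene_set)) vals <- vals[rownames(vals) %in% gene_set, , drop = FALSE]
  const <- apply(vals, 2, function(v) length(unique(v)) == 1)
  if (any(const)) {
    warn(paste0("constant expression vector(s), rho undefined: ",
                paste(colnames(vals)[const], collapse = ", ")))
  }
  suppressWarnings(cor(vals, method = "spearman"))
}

#' Jensen-Shannon distance between two expression vectors
#'
#' Each vector is normalized to a probability distribution; the distance is
#' the square root of the Jensen-Shannon divergence with base-2 logarithms
#' (`0 * log 0 = 0`), hence bounded by 1 and a metric.
#'
#' @param p_expr,q_expr Non-negative vectors of equal length, each with a
#'   positive sum.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' js_distance(c(1, 0), c(0, 1)) # 1: disjoint supports
js_distance <- function(p_expr, q_expr) {
  if (length(p_expr) != length(q_expr)) abort("vectors must have equal length")
  if (any(p_expr < 0) || any(q_expr < 0)) abort("vectors must be non-negative")
  sp <- sum(p_expr); sq <- sum(q_expr)
  if (sp <= 0 || sq <= 0) abort("each vector must have a positive sum")
  p <- p_expr / sp
  q <- q_expr / sq
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  jsd <- 0.5 * kl(p, m) + 0.5 * kl(q, m)
  sqrt(max(0, min(1, jsd))) # clamp tiny floating-point overshoot
}

#' Pairwise Jensen-Shannon distance matrix between conditions
#'
#' @param expr Expression matrix tibble.
#' @param gene_set Optional gene ids to restrict to (or a `ubiquitous_set`).
#' @return A symmetric distance matrix (zero diagonal, values in `[0, 1]`).
#' @export
js_distance_matrix <- function(expr, gene_set = NULL) {
  validate_expression(expr)
  if (inherits(gene_set, "ubiquitous_set")) gene_set <- gene_set$gene_ids
  vals <- expr_values(expr)
  if (!is.null(gene_set)) vals <- vals[rownames(vals) %in% gene_set, , drop = FALSE]
  n <- ncol(vals)
  d <- matrix(0, n, n, dimnames = list(colnames(vals), colnames(vals)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- js_distance(vals[, i], vals[, j])
    }
  }
  d
}

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' Ids are ordered lexicographically before clustering so tie-breaking is
#' deterministic; the result is a standard `hclust` object.
#'
#' @param d Symmetric distance matrix with dimnames (e.g. from
#'   [js_distance_matrix()]).
#' @param linkage `"average"` (UPGMA, default) or `"complete"`.
#' @return An `hclust` object.
#' @export
hierarchical_cluster <- function(d, linkage = c("average", "complete")) {
  linkage <- arg_match(linkage)
  if (!is.matrix(d) || nrow(d) != ncol(d)) abort("`d` must be a square matrix")
  if (nrow(d) < 2) abort("need >= 2 items to cluster")
  if (max(abs(d - t(d))) > 1e-12) abort("`d` must be symmetric")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  hclust(as.dist(d), method = linkage)
}

#' Export a dendrogram in Newick format
#'
#' @param hc An `hclust` object.
#' @param path Optional file path; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
export_newick <- function(hc, path = NULL) {
  stopifnot(inherits(hc, "hclust"))
  tr <- ape::as.phylo(hc)
  if (is.null(path)) {
    ape::write.tree(tr)
  } else {
    ape::write.tree(tr, file = path)
    invisible(ape::write.tree(tr))
  }
}

#' Cut a dendrogram into k groups
#'
#' Convenience wrapper around `stats::cutree` returning a tibble.
#'
#' @param hc An `hclust` object.
#' @param k Number of groups.
#' @return A tibble with `id` and `cluster`.
#' @export
cut_clusters <- function(hc, k) {
  cl <- stats::cutree(hc, k = k)
  tibble(id = names(cl), cluster = unname(cl))
}
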