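# Reading, validating and joining expression matrices, gene annotations and
# sample metadata into an analysis-ready compendium.

#' Read a genes-by-samples FPKM expression table
#'
#' Reads a tab-separated expression matrix whose header row names the samples
#' and whose first column names the genes. Values must be non-negative, finite
#' FPKM. Parsing is locale-independent (decimal point only).
#'
#' @param path Path to a TSV file.
#' @param dialect `"generic_tsv"` (first column = gene ids, remaining columns =
#'   samples) or `"cuffdiff_fpkm"` (a Cuffdiff-style table with a
#'   `tracking_id` column and per-sample `<sample>_FPKM` columns; the suffix is
#'   stripped from sample names).
#' @return A tibble with a `gene_id` column followed by one numeric column per
#'   sample (an *expression matrix* in the sense used throughout this package).
#' @export
#' @examples
#' p <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\t0\t0.5"), p)
#' read_expression_table(p)
read_expression_table <- function(path, dialect = c("generic_tsv", "cuffdiff_fpkm")) {
  dialect <- arg_match(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         locale = readr::locale(decimal_mark = "."))
  if (ncol(tbl) < 2) abort("expression table needs >= 2 columns")
  if (dialect == "cuffdiff_fpkm") {
    idcol <- intersect(c("tracking_id", "gene_id"), names(tbl))[1]
    if (is.na(idcol)) abort("cuffdiff table lacks a tracking_id/gene_id column")
    fpkm <- grep("_FPKM$", names(tbl), value = TRUE)
    if (length(fpkm) == 0) abort("cuffdiff table has no *_FPKM columns")
    tbl <- tbl[, c(idcol, fpkm)]
    names(tbl) <- c("gene_id", sub("_FPKM$", "", fpkm))
  } else {
    names(tbl)[1] <- "gene_id"
  }
  tbl$gene_id <- as.character(tbl$gene_id)
  # non-numeric columns indicate unparseable values; report the column
  for (s in setdiff(names(tbl), "gene_id")) {
    if (!is.numeric(tbl[[s]])) {
      abort(sprintf("non-numeric value(s) in sample column '%s'", s))
    }
  }
  validate_expression(tbl)
  tbl
}

#' Write an expression matrix as TSV
#'
#' Values round-trip through [read_expression_table()] exactly (shortest
#' round-trippable decimal representation).
#'
#' @param expr Expression matrix tibble (see [read_expression_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path) {
  validate_expression(expr)
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

#' Read and classify a gene annotation
#'
#' Maps every gene to exactly one chromosome class: `AUTOSOME`, `X`, `Y` or
#' `EXCLUDED`. Genes on the mitochondrial chromosome, genes whose biotype
#' matches one of `exclusion_rules` (by default rRNA-like biotypes, i.e.
#' annotated highly abundant structural RNAs), genes without a chromosome and
#' genes on unplaced scaffolds are marked `EXCLUDED`; Y-linked genes are never
#' counted among autosomes.
#'
#' @param path Annotation file.
#' @param format `"gtf"` (Ensembl/UCSC dialect, parsed with
#'   `rtracklayer::readGFF()`) or `"bed_like_tsv"` (tab-separated with columns
#'   `chrom`, `start`, `end`, `gene_id` and optionally `biotype`; BED
#'   half-open 0-based starts are converted to 1-based inclusive).
#' @param exclusion_rules Character vector of regular expressions matched
#'   (case-insensitively) against the biotype; matching genes are `EXCLUDED`.
#' @return A tibble with columns `gene_id`, `chromosome`, `chrom_class`,
#'   `biotype`, `start`, `end`.
#' @export
read_gene_annotation <- function(path,
                                 format = c("gtf", "bed_like_tsv"),
                                 exclusion_rules = c("rRNA", "Mt_tRNA")) {
  format <- arg_match(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "gtf") {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      abort("reading GTF requires the rtracklayer package")
    }
    g <- as.data.frame(rtracklayer::readGFF(path))
    if ("type" %in% names(g) && any(g$type == "gene")) g <- g[g$type == "gene", ]
    bio_col <- intersect(c("gene_biotype", "gene_type", "biotype"), names(g))[1]
    ann <- tibble(
      gene_id = as.character(g$gene_id),
      chromosome = as.character(g$seqid),
      biotype = if (!is.na(bio_col)) as.character(g[[bio_col]]) else NA_character_,
      start = as.integer(g$start),
      end = as.integer(g$end)
    )
    ann <- distinct(ann, .data$gene_id, .keep_all = TRUE)
  } else {
    b <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    need <- c("chrom", "start", "end", "gene_id")
    miss <- setdiff(need, names(b))
    if (length(miss) > 0) {
      abort(paste0("bed-like annotation lacks column(s): ",
                   paste(miss, collapse = ", ")))
    }
    ann <- tibble(
      gene_id = as.character(b$gene_id),
      chromosome = as.character(b$chrom),
      biotype = if ("biotype" %in% names(b)) as.character(b$biotype) else NA_character_,
      start = as.integer(b$start) + 1L, # BED 0-based half-open -> 1-based
      end = as.integer(b$end)
    )
  }
  classify_chromosome(ann, exclusion_rules)
}

# assign chrom_class from chromosome label + biotype exclusion rules
classify_chromosome <- function(ann, exclusion_rules) {
  chr <- sub("^chr", "", ann$chromosome, ignore.case = TRUE)
  cls <- rep("EXCLUDED", nrow(ann))
  cls[grepl("^[0-9]+$", chr)] <- "AUTOSOME"
  cls[toupper(chr) == "X"] <- "X"
  cls[toupper(chr) == "Y"] <- "Y"
  cls[toupper(chr) %in% c("M", "MT")] <- "EXCLUDED"
  no_chr <- is.na(ann$chromosome) | ann$chromosome == ""
  if (any(no_chr)) {
    warn(sprintf("%d gene(s) without a chromosome marked EXCLUDED",
                 sum(no_chr)))
    cls[no_chr] <- "EXCLUDED"
  }
  if (length(exclusion_rules) > 0 && any(!is.na(ann$biotype))) {
    pat <- paste(exclusion_rules, collapse = "|")
    hit <- !is.na(ann$biotype) & grepl(pat, ann$biotype, ignore.case = TRUE)
    cls[hit] <- "EXCLUDED"
  }
  ann$chrom_class <- cls
  validate_annotation(ann)
  ann[, c("gene_id", "chromosome", "chrom_class", "biotype", "start", "end")]
}

#' Read a sample metadata table
#'
#' Mandatory columns: `sample_id`, `condition_id`, `genotype` (XX, XY, XO,
#' XX_SRY), `stage`, `cell_type`, `replicate`.
#'
#' @param path TSV file.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_metadata(meta)
  meta$sample_id <- as.character(meta$sample_id)
  meta$condition_id <- as.character(meta$condition_id)
  meta
}

#' Pool replicate samples into per-condition columns
#'
#' The analysis unit downstream is the condition; replicate FPKMs are pooled
#' per gene by mean (default) or median. Column order follows the first
#' appearance of each condition in `metadata`.
#'
#' @param expr Expression matrix tibble.
#' @param metadata Sample metadata with `sample_id` and `condition_id`; every
#'   sample column of `expr` must have exactly one metadata record.
#' @param method `"mean"` or `"median"`.
#' @return An expression matrix keyed by `condition_id`.
#' @export
#' @examples
#' expr <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(2, 0), s2 = c(4, 1))
#' meta <- tibble::tibble(sample_id = c("s1", "s2"), condition_id = "c1",
#'                        genotype = "XY", stage = "E14.5",
#'                        cell_type = "GERM", replicate = 1:2)
#' pool_replicates(expr, meta)
pool_replicates <- function(expr, metadata, method = c("mean", "median")) {
  method <- arg_match(method)
  validate_expression(expr)
  validate_metadata(metadata)
  samp <- sample_ids(expr)
  missing_meta <- setdiff(samp, metadata$sample_id)
  if (length(missing_meta) > 0) {
    abort(paste0("sample(s) without metadata: ",
                 paste(head(missing_meta, 5), collapse = ", ")))
  }
  meta <- metadata[metadata$sample_id %in% samp, ]
  conds <- unique(meta$condition_id)
  empty <- setdiff(unique(metadata$condition_id), meta$condition_id)
  if (length(empty) > 0) {
    abort(paste0("condition(s) with zero samples in the matrix: ",
                 paste(empty, collapse = ", ")))
  }
  f <- if (method == "mean") rowMeans else function(m) apply(m, 1, median)
  vals <- expr_values(expr)
  pooled <- vapply(conds, function(cid) {
    cols <- meta$sample_id[meta$condition_id == cid]
    f(vals[, cols, drop = FALSE])
  }, numeric(nrow(vals)))
  if (!is.matrix(pooled)) {
    pooled <- matrix(pooled, nrow = nrow(vals), dimnames = list(NULL, conds))
  }
  out <- as_tibble(pooled)
  names(out) <- conds
  dplyr::bind_cols(tibble(gene_id = expr$gene_id), out)
}
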