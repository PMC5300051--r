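# End-to-end orchestration: config validation, full analysis report bundle,
# simulation writer. A thin command-line wrapper lives in inst/cli/xadose.

#' Pipeline configuration
#'
#' @param expression,annotation,metadata Paths to the expression TSV,
#'   annotation (GTF or bed-like TSV) and metadata TSV.
#' @param retrogenes Optional path to a retrogene candidate TSV (columns as in
#'   [filter_retrogene_candidates()]).
#' @param annotation_format `"gtf"` or `"bed_like_tsv"`.
#' @param lower_fpkm,upper_centile Threshold configuration.
#' @param n_boot,alpha Bootstrap parameters.
#' @param seed Integer seed (mandatory: every report must be reproducible).
#' @param contrasts Optional tibble with `cond_a`, `cond_b`, `test`
#'   (`"ks"` or `"wilcoxon"`) naming condition pairs to compare.
#' @param pool `TRUE` (default) to pool replicates into conditions by mean;
#'   `FALSE` analyses per-sample columns.
#' @param out_dir Output directory.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, annotation, metadata,
                            retrogenes = NULL,
                            annotation_format = c("bed_like_tsv", "gtf"),
                            lower_fpkm = 1, upper_centile = 99,
                            n_boot = 1e6, alpha = 0.05, seed,
                            contrasts = NULL, pool = TRUE, out_dir = ".") {
  annotation_format <- arg_match(annotation_format)
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory")
  for (field in c("expression", "annotation", "metadata")) {
    p <- get(field)
    if (is.null(p)) abort(sprintf("config field '%s' is missing", field))
    if (!file.exists(p)) {
      abort(sprintf("config field '%s': file not found: %s", field, p))
    }
  }
  if (!is.null(retrogenes) && !file.exists(retrogenes)) {
    abort(sprintf("config field 'retrogenes': file not found: %s", retrogenes))
  }
  if (!is.null(contrasts)) {
    stopifnot(all(c("cond_a", "cond_b", "test") %in% names(contrasts)))
  }
  structure(
    list(expression = expression, annotation = annotation, metadata = metadata,
         retrogenes = retrogenes, annotation_format = annotation_format,
         lower_fpkm = lower_fpkm, upper_centile = upper_centile,
         n_boot = n_boot, alpha = alpha, seed = as.integer(seed),
         contrasts = contrasts, pool = pool, out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' File keys mirror the arguments of [pipeline_config()]; `contrasts` is a
#' list of `{cond_a, cond_b, test}` records. Relative paths are resolved
#' against the config file's directory.
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @param out_dir Optional output-directory override.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  contrasts <- if (!is.null(raw$contrasts)) {
    as_tibble(do.call(rbind.data.frame, lapply(raw$contrasts, as.list)))
  } else NULL
  pipeline_config(
    expression = resolve(raw$expression),
    annotation = resolve(raw$annotation),
    metadata = resolve(raw$metadata),
    retrogenes = resolve(raw$retrogenes),
    annotation_format = raw$annotation_format %||% "bed_like_tsv",
    lower_fpkm = raw$lower_fpkm %||% 1,
    upper_centile = raw$upper_centile %||% 99,
    n_boot = raw$n_boot %||% 1e6,
    alpha = raw$alpha %||% 0.05,
    seed = raw$seed,
    contrasts = contrasts,
    pool = raw$pool %||% TRUE,
    out_dir = out_dir %||% raw$out_dir %||% "."
  )
}

write_report_tsv <- function(tbl, path) {
  tbl[] <- lapply(tbl, signif6)
  readr::write_tsv(tbl, path, progress = FALSE)
}

#' Run the full X:A dosage-compensation analysis
#'
#' Sequences the pipeline: read + validate inputs, pool replicates, build the
#' ubiquitous gene set (with stepwise trajectory), apply the upper-centile
#' exclusion, estimate per-condition X:A ratios for the three gene-set modes,
#' classify dosage states, run requested distribution contrasts, optionally
#' run the retrogene comparison, compute QC matrices and the condition
#' dendrogram, and write a JSON manifest capturing versions, seed, config and
#' input checksums. Any stage failure aborts with a stage-named error and a
#' `FAILED` marker in the output directory (partial outputs retained).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the main in-memory results (`gene_set`,
#'   `gene_set_upper`, `ratios`, `contrasts`, `retrogene`, `manifest`).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  counts_log <- list()
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      writeLines(sprintf("stage %s: %s", name, conditionMessage(e)),
                 file.path(out, "FAILED"))
      abort(sprintf("stage %s: %s", name, conditionMessage(e)))
    })
  }

  inputs <- stage("read_inputs", {
    expr <- read_expression_table(config$expression)
    ann <- read_gene_annotation(config$annotation,
                                format = config$annotation_format)
    meta <- read_sample_metadata(config$metadata)
    list(expr = expr, ann = ann, meta = meta)
  })
  counts_log$n_genes_input <- nrow(inputs$expr)
  counts_log$n_samples <- length(sample_ids(inputs$expr))

  expr <- stage("pool_replicates", {
    if (config$pool) pool_replicates(inputs$expr, inputs$meta) else inputs$expr
  })
  counts_log$n_conditions <- length(sample_ids(expr))

  gset <- stage("ubiquitous_set", {
    g <- build_ubiquitous_set(expr, lower_fpkm = config$lower_fpkm,
                              annotation = inputs$ann)
    write_gene_set(g, file.path(out, "ubiquitous_set.txt"))
    g
  })
  counts_log$n_ubiquitous <- length(gset$gene_ids)

  gset_up <- stage("upper_threshold", {
    g <- apply_upper_threshold(gset, expr, centile = config$upper_centile,
                               annotation = inputs$ann)
    write_gene_set(g, file.path(out, "ubiquitous_upper_set.txt"))
    g
  })
  counts_log$n_ubiquitous_upper <- length(gset_up$gene_ids)

  ratios <- stage("xa_ratios", {
    tabs <- purrr::map_dfr(
      c("all_expressed", "ubiquitous", "ubiquitous_upper"),
      function(mode) {
        threshold_sweep(expr, inputs$ann,
                        lower_thresholds = config$lower_fpkm,
                        gene_set_mode = mode,
                        upper_centile = config$upper_centile,
                        n_boot = config$n_boot, alpha = config$alpha,
                        seed = config$seed)
      })
    write_report_tsv(tabs, file.path(out, "xa_ratios.tsv"))
    tabs
  })

  contrast_res <- if (is.null(config$contrasts)) NULL else stage("contrasts", {
    res <- purrr::map(seq_len(nrow(config$contrasts)), function(i) {
      ct <- config$contrasts[i, ]
      if (ct$test == "ks") {
        rt <- pairwise_log2_ratios(expr, inputs$ann, ct$cond_a, ct$cond_b,
                                   gset$gene_ids)
        r <- ks_x_vs_autosomes(rt)
        c(list(test = "ks", cond_a = ct$cond_a, cond_b = ct$cond_b),
          as.list(r))
      } else {
        r <- wilcoxon_x_between_conditions(expr, inputs$ann, ct$cond_a,
                                           ct$cond_b, gset$gene_ids)
        c(list(test = "wilcoxon", cond_a = ct$cond_a, cond_b = ct$cond_b),
          as.list(r))
      }
    })
    jsonlite::write_json(res, file.path(out, "contrasts.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res
  })

  retro_res <- if (is.null(config$retrogenes)) NULL else stage("retrogene", {
    recs <- readr::read_tsv(config$retrogenes, show_col_types = FALSE,
                            progress = FALSE)
    acc <- filter_retrogene_candidates(recs, inputs$ann, gset)
    cmp <- augmented_xa_comparison(expr, inputs$ann, gset$gene_ids, acc,
                                   n_boot = config$n_boot,
                                   alpha = config$alpha, seed = config$seed)
    write_report_tsv(cmp, file.path(out, "retrogene_comparison.tsv"))
    cmp
  })

  stage("qc", {
    sp <- spearman_matrix(inputs$expr, gset$gene_ids)
    readr::write_tsv(as_tibble(signif(sp, 6), rownames = "sample_id"),
                     file.path(out, "spearman.tsv"), progress = FALSE)
    jd <- js_distance_matrix(expr, gset$gene_ids)
    readr::write_tsv(as_tibble(signif(jd, 6), rownames = "condition_id"),
                     file.path(out, "jsd.tsv"), progress = FALSE)
    hc <- hierarchical_cluster(jd)
    export_newick(hc, file.path(out, "dendrogram.nwk"))
    NULL
  })

  manifest <- stage("manifest", {
    m <- list(
      package = "xadose",
      version = as.character(utils::packageVersion("xadose")),
      seed = config$seed,
      config = config[setdiff(names(config), "contrasts")],
      input_checksums = as.list(tools::md5sum(
        unlist(config[c("expression", "annotation", "metadata", "retrogenes")],
               use.names = TRUE))),
      gene_counts = counts_log
    )
    jsonlite::write_json(m, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", force = TRUE)
    m
  })

  invisible(list(gene_set = gset, gene_set_upper = gset_up, ratios = ratios,
                 contrasts = contrast_res, retrogene = retro_res,
                 manifest = manifest))
}

#' Write a simulated compendium in pipeline-consumable formats
#'
#' Emits `expression.tsv`, `annotation.tsv` (bed-like), `metadata.tsv` and
#' `truth.json` under `out_dir`; the files are directly readable by
#' [run_full_analysis()].
#'
#' @param cfg A [simulation_config()].
#' @param out_dir Output directory.
#' @return Invisibly, the simulated `xa_compendium`.
#' @export
run_simulation <- function(cfg, out_dir) {
  sim <- simulate_compendium(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_table(sim$expression, file.path(out_dir, "expression.tsv"))
  ann <- sim$annotation
  bed <- tibble(chrom = ann$chromosome, start = ann$start - 1L, end = ann$end,
                gene_id = ann$gene_id, biotype = ann$biotype)
  readr::write_tsv(bed, file.path(out_dir, "annotation.tsv"), progress = FALSE)
  readr::write_tsv(sim$metadata, file.path(out_dir, "metadata.tsv"),
                   progress = FALSE)
  truth <- list(
    conditions = sim$truth$conditions,
    genes = sim$truth$genes,
    config = unclass(sim$truth$config)[setdiff(names(sim$truth$config),
                                               "trajectories")],
    trajectories = sim$truth$config$trajectories
  )
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(sim)
}
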