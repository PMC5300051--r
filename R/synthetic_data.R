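# Synthetic FPKM compendium generator with known per-condition true X:A
# ratios, emulating: log-scale expression with replicate noise, X enrichment
# of tissue-specific (germline) genes silent in the soma, a high-expression
# X tail in gonadal somatic conditions, and the four-genotype germline
# trajectory model (compensated -> excess/decompensated by X-chromosome
# number).

#' Default germline X:A trajectories for the four genotypes
#'
#' Qualitative model: all genotypes start dosage compensated (ratio 1).
#' During reprogramming the genotypes with two X chromosomes (XX females,
#' XX-Sry males) develop dosage excess (ratio > 1, here 1.4) as the inactive
#' X reactivates while upregulation of the active X persists. After
#' reprogramming, X upregulation is lost: genotypes with one X (XY males, XO
#' females) become decompensated (ratio < 1, here 0.6-0.8), while XX females
#' return to balance.
#'
#' @return A named list (genotype -> tibble with `stage`, `true_xa_ratio`).
#' @export
default_trajectories <- function() {
  list(
    XX = tibble(stage = c("E6.5", "E9.5", "E11.5", "E14.5", "E15.5", "E18.5"),
                true_xa_ratio = c(1, 1, 1.4, 1.4, 1, 1)),
    XO = tibble(stage = c("E9.5", "E14.5", "E15.5", "E18.5"),
                true_xa_ratio = c(1, 1, 0.7, 0.6)),
    XY = tibble(stage = c("E6.5", "E9.5", "E14.5", "E15.5", "E18.5", "P11"),
                true_xa_ratio = c(1, 1, 1, 0.8, 0.7, 0.7)),
    XX_SRY = tibble(stage = c("E9.5", "E11.5", "E12.5", "E14.5"),
                    true_xa_ratio = c(1, 1, 1, 1.4))
  )
}

#' Simulation configuration
#'
#' Validated parameter container for [simulate_compendium()].
#'
#' @param n_autosomal,n_x Gene counts (>= 10 each).
#' @param n_excluded Extra rRNA/mitochondrial-like genes (annotated EXCLUDED,
#'   drawn very highly abundant).
#' @param frac_tissue_specific_x,frac_tissue_specific_a Fractions of X and
#'   autosomal genes that are tissue-specific: each is assigned to one
#'   compartment (early germ, late germ or soma) and is a hard zero FPKM
#'   elsewhere. The X fraction exceeds the autosomal one in the default,
#'   emulating the X enrichment of tissue-specific genes whose silence in
#'   the soma depresses naive X:A estimates.
#' @param base_log2_mean,base_log2_sd Per-gene base expression is
#'   `2^N(base_log2_mean, base_log2_sd)` FPKM.
#' @param replicate_cv Coefficient of variation of multiplicative
#'   (median-preserving log-normal) replicate noise.
#' @param tail_frac,tail_multiplier Fraction of non-tissue-specific X genes
#'   given a `tail_multiplier`-fold boost in gonadal somatic conditions (the
#'   reproductive-tissue high-expression X tail).
#' @param trajectories Named list genotype -> tibble(`stage`,
#'   `true_xa_ratio`); see [default_trajectories()].
#' @param soma Include somatic conditions (E14.5 gonadal soma and liver for
#'   XX and XY, true ratio 1)?
#' @param n_replicates Biological replicates per condition (>= 1; the study
#'   design uses >= 2).
#' @param calibrate `"exact"`: rescale X per condition so the realized
#'   ubiquitous-gene median ratio equals the configured truth exactly;
#'   `"population"`: shift the X distribution by the ratio so the truth holds
#'   for population medians and sample medians vary (use for CI-coverage
#'   studies).
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_autosomal = 2000, n_x = 170, n_excluded = 20,
                              frac_tissue_specific_x = 0.4,
                              frac_tissue_specific_a = 0.1,
                              base_log2_mean = 3, base_log2_sd = 1,
                              replicate_cv = 0.2,
                              tail_frac = 0.25, tail_multiplier = 16,
                              trajectories = default_trajectories(),
                              soma = TRUE, n_replicates = 2,
                              calibrate = c("exact", "population"),
                              seed = 1) {
  calibrate <- arg_match(calibrate)
  fr <- c(frac_tissue_specific_x, frac_tissue_specific_a, tail_frac)
  if (any(fr < 0 | fr > 1)) abort("fractions must lie in [0, 1]")
  if (n_autosomal < 10 || n_x < 10) abort("gene counts must be >= 10")
  if (replicate_cv < 0) abort("replicate_cv must be >= 0")
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  if (!is.list(trajectories) || is.null(names(trajectories))) {
    abort("trajectories must be a named list of genotype tibbles")
  }
  for (g in names(trajectories)) {
    tr <- trajectories[[g]]
    if (!all(c("stage", "true_xa_ratio") %in% names(tr))) {
      abort(sprintf("trajectory '%s' needs columns stage, true_xa_ratio", g))
    }
    if (any(tr$true_xa_ratio <= 0)) abort("true ratios must be positive")
  }
  structure(
    list(n_autosomal = n_autosomal, n_x = n_x, n_excluded = n_excluded,
         frac_tissue_specific_x = frac_tissue_specific_x,
         frac_tissue_specific_a = frac_tissue_specific_a,
         base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
         replicate_cv = replicate_cv,
         tail_frac = tail_frac, tail_multiplier = tail_multiplier,
         trajectories = trajectories, soma = soma,
         n_replicates = n_replicates, calibrate = calibrate,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# condition table implied by a config
sim_conditions <- function(cfg) {
  germ <- purrr::map_dfr(names(cfg$trajectories), function(g) {
    tr <- cfg$trajectories[[g]]
    tibble(
      condition_id = paste(g, "germ", tr$stage, sep = "."),
      genotype = g, stage = tr$stage,
      cell_type = ifelse(tr$stage == "E6.5", "EPIBLAST", "GERM"),
      true_xa_ratio = tr$true_xa_ratio
    )
  })
  # early germ: stages up to E11.5 (and epiblast); late germ: E12.5 onwards
  early <- c("E6.5", "E9.5", "E11.5")
  germ$tissue <- ifelse(germ$stage %in% early, "early_germ", "late_germ")
  germ$gonadal <- FALSE
  if (!cfg$soma) return(germ)
  soma <- tibble(
    condition_id = c("XY.soma.gonad.E14.5", "XX.soma.gonad.E14.5",
                     "XY.soma.liver.E14.5", "XX.soma.liver.E14.5"),
    genotype = rep(c("XY", "XX"), 2),
    stage = "E14.5",
    cell_type = rep(c("GONADAL_SOMA", "NON_GONADAL_SOMA"), each = 2),
    true_xa_ratio = 1,
    tissue = "soma",
    gonadal = rep(c(TRUE, FALSE), each = 2)
  )
  bind_rows(germ, soma)
}

#' Simulate an FPKM compendium with known X:A ground truth
#'
#' Autosomal and X ubiquitous genes are drawn log-normal; per condition the X
#' chromosome is scaled so the median of ubiquitous X genes over the median of
#' ubiquitous autosomal genes equals the configured true ratio (exactly under
#' `calibrate = "exact"`, in population under `"population"`). Tissue-specific
#' genes are hard zeros outside their tissue; tail genes are boosted
#' `tail_multiplier`-fold in gonadal somatic conditions; replicates multiply
#' the condition value by median-preserving log-normal noise with coefficient
#' of variation `replicate_cv`.
#'
#' @param cfg A [simulation_config()].
#' @return A list of class `xa_compendium`: `expression` (genes x samples
#'   tibble), `annotation`, `metadata`, `truth` (list with `conditions`,
#'   `genes`, `config`).
#' @export
#' @examples
#' sim <- simulate_compendium(simulation_config(seed = 7))
#' dim(sim$expression)
simulate_compendium <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    conds <- sim_conditions(cfg)

    # --- gene table ---------------------------------------------------------
    a_ids <- sprintf("GA%04d", seq_len(cfg$n_autosomal))
    x_ids <- sprintf("GX%04d", seq_len(cfg$n_x))
    e_ids <- if (cfg$n_excluded > 0) sprintf("GE%04d", seq_len(cfg$n_excluded))
             else character(0)
    n_ts_a <- round(cfg$frac_tissue_specific_a * cfg$n_autosomal)
    n_ts_x <- round(cfg$frac_tissue_specific_x * cfg$n_x)
    ts_a <- sample(a_ids, n_ts_a)
    ts_x <- sample(x_ids, n_ts_x)
    tissues <- c("early_germ", "late_germ", if (cfg$soma) "soma")
    ts_tissue <- setNames(sample(tissues, n_ts_a + n_ts_x, replace = TRUE),
                          c(ts_a, ts_x))
    ubiq_x <- setdiff(x_ids, ts_x)
    tail_x <- sample(ubiq_x, round(cfg$tail_frac * length(ubiq_x)))
    genes <- tibble(
      gene_id = c(a_ids, x_ids, e_ids),
      chrom_class = c(rep("AUTOSOME", cfg$n_autosomal),
                      rep("X", cfg$n_x), rep("EXCLUDED", length(e_ids))),
      category = "ubiquitous"
    )
    genes$category[genes$gene_id %in% c(ts_a, ts_x)] <- "tissue_specific"
    genes$category[genes$gene_id %in% tail_x] <- "tail"
    genes$tissue <- ts_tissue[genes$gene_id]

    base_l2 <- rnorm(nrow(genes), cfg$base_log2_mean, cfg$base_log2_sd)
    # excluded genes emulate very highly abundant structural RNAs
    base_l2[genes$chrom_class == "EXCLUDED"] <-
      base_l2[genes$chrom_class == "EXCLUDED"] + 6
    base <- 2^base_l2

    is_x <- genes$chrom_class == "X"
    is_ubiq_a <- genes$chrom_class == "AUTOSOME" & genes$category == "ubiquitous"
    is_ubiq_x <- is_x & genes$category != "tissue_specific"
    is_ts <- genes$category == "tissue_specific"
    is_tail <- genes$category == "tail"

    # --- condition-level values --------------------------------------------
    cond_vals <- matrix(0, nrow(genes), nrow(conds),
                        dimnames = list(genes$gene_id, conds$condition_id))
    for (k in seq_len(nrow(conds))) {
      v <- base
      silent <- is_ts & genes$tissue != conds$tissue[k]
      v[silent] <- 0
      r <- conds$true_xa_ratio[k]
      x_factor <- if (cfg$calibrate == "exact") {
        r * median(v[is_ubiq_a]) / median(v[is_ubiq_x])
      } else {
        r
      }
      v[is_x] <- v[is_x] * x_factor
      if (conds$gonadal[k]) v[is_tail] <- v[is_tail] * cfg$tail_multiplier
      cond_vals[, k] <- v
    }

    # --- replicates ---------------------------------------------------------
    sdlog2 <- if (cfg$replicate_cv > 0) {
      sqrt(log(1 + cfg$replicate_cv^2)) / log(2)
    } else 0
    samples <- list()
    meta <- list()
    for (k in seq_len(nrow(conds))) {
      for (r in seq_len(cfg$n_replicates)) {
        sid <- sprintf("%s.r%d", conds$condition_id[k], r)
        noise <- if (sdlog2 > 0) 2^rnorm(nrow(genes), 0, sdlog2) else 1
        samples[[sid]] <- unname(cond_vals[, k] * noise)
        meta[[sid]] <- tibble(
          sample_id = sid, condition_id = conds$condition_id[k],
          genotype = conds$genotype[k], stage = conds$stage[k],
          cell_type = conds$cell_type[k], replicate = r
        )
      }
    }
    expression <- dplyr::bind_cols(tibble(gene_id = genes$gene_id),
                                   as_tibble(samples))
    metadata <- bind_rows(meta)

    # --- annotation ---------------------------------------------------------
    chrom <- character(nrow(genes))
    chrom[genes$chrom_class == "AUTOSOME"] <-
      paste0("chr", (seq_len(sum(genes$chrom_class == "AUTOSOME")) %% 19) + 1)
    chrom[genes$chrom_class == "X"] <- "chrX"
    chrom[genes$chrom_class == "EXCLUDED"] <- "chrM"
    annotation <- tibble(
      gene_id = genes$gene_id,
      chromosome = chrom,
      chrom_class = genes$chrom_class,
      biotype = ifelse(genes$chrom_class == "EXCLUDED", "rRNA",
                       "protein_coding"),
      start = 1000L + 2000L * seq_len(nrow(genes)),
      end = 2000L + 2000L * seq_len(nrow(genes))
    )

    structure(
      list(expression = expression,
           annotation = annotation,
           metadata = metadata,
           truth = list(conditions = conds, genes = genes, config = cfg)),
      class = "xa_compendium"
    )
  })
}

#' Simulate the tissue-specific-silence artifact variant
#'
#' A compendium in which the X carries a larger fraction of tissue-specific
#' (soma-silent) genes than the autosomes, so that in somatic conditions the
#' all-genes (FPKM >= 0) X:A estimate is depressed below the ubiquitous-gene
#' estimate by construction, and rising lower thresholds recover the true
#' ratio.
#'
#' @param cfg A [simulation_config()]; its tissue-specific fractions must
#'   satisfy `frac_tissue_specific_x > frac_tissue_specific_a` and somatic
#'   conditions must be enabled.
#' @return An `xa_compendium` (see [simulate_compendium()]).
#' @export
simulate_fig2_artifact <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$frac_tissue_specific_x <= cfg$frac_tissue_specific_a) {
    abort("artifact variant requires frac_tissue_specific_x > frac_tissue_specific_a")
  }
  if (!cfg$soma) abort("artifact variant requires somatic conditions")
  simulate_compendium(cfg)
}

#' Simulate bare X/autosome FPKM vectors with a known population median ratio
#'
#' Minimal generator for CI-coverage studies: autosomal FPKMs are
#' `2^N(base_log2_mean, base_log2_sd)` and X FPKMs are the same law shifted by
#' `log2(true_ratio)`, so the population median ratio is exactly
#' `true_ratio` while sample medians vary.
#'
#' @param n_x,n_a Gene counts.
#' @param true_ratio Target population median ratio.
#' @param base_log2_mean,base_log2_sd Log-normal parameters.
#' @return A list with vectors `x` and `a`.
#' @export
simulate_ratio_vectors <- function(n_x, n_a, true_ratio,
                                   base_log2_mean = 3, base_log2_sd = 1) {
  stopifnot(true_ratio > 0)
  list(
    x = 2^rnorm(n_x, base_log2_mean + log2(true_ratio), base_log2_sd),
    a = 2^rnorm(n_a, base_log2_mean, base_log2_sd)
  )
}

#' @export
print.xa_compendium <- function(x, ...) {
  cat(sprintf("Synthetic compendium: %d genes x %d samples, %d conditions\n",
              nrow(x$expression), length(sample_ids(x$expression)),
              nrow(x$truth$conditions)))
  invisible(x)
}
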