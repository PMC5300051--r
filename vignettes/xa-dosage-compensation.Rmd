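---
title: "Estimating X:A dosage compensation states from RNA-seq compendia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating X:A dosage compensation states from RNA-seq compendia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xadose)
```

## The problem

Mammalian males carry one X chromosome against a diploid autosomal
complement. Ohno's hypothesis holds that expression from the active X is
upregulated roughly two-fold so that the X-to-autosome output ratio (X:A)
is restored to 1; X inactivation then equalizes dosage between the sexes.
Whether a cell population is *compensated* (X:A ≈ 1), in *dosage excess*
(X:A > 1, e.g. when a silenced X reactivates while upregulation persists) or
*decompensated* (X:A < 1, when upregulation is lost from a single active X)
is an empirical question that can be read off bulk RNA-seq, provided the
estimator is protected from two well-known artifacts:

1. the X chromosome is enriched in tissue-specific genes that are silent in
   most cell types; including them (an FPKM ≥ 0 analysis) drags the X median
   toward zero and makes upregulation invisible;
2. reproductive tissues express a disproportionate number of highly
   expressed X genes, which inflate the X median in gonadal samples.

`xadose` packages the full inference chain: threshold-based construction of
a ubiquitously expressed (housekeeping-proxy) gene set, an upper-centile
exclusion against the high-expression tail, bootstrap median-ratio X:A
estimation with percentile confidence intervals, dosage-state
classification, distribution comparisons (Kolmogorov–Smirnov, Wilcoxon),
retrogene-augmented ratios, and compendium QC — together with a synthetic
compendium generator whose ground truth exercises every stage.

## The estimator

For one condition, let $x_1,\dots,x_{n_X}$ be the FPKM values of the
X-linked genes in the active gene set and $a_1,\dots,a_{n_A}$ those of the
autosomal genes (Y-linked, mitochondrial, rRNA-like and otherwise excluded
genes never enter the autosomal background). The point estimate is the
ratio of medians

$$\widehat{R} = \frac{\mathrm{med}(x)}{\mathrm{med}(a)},$$

with even-length medians the mean of the two central order statistics. The
confidence interval is a percentile bootstrap: X and autosomal gene sets are
resampled independently, with replacement, at their own sizes; the median
ratio is recomputed per replicate (default $10^6$ replications); the CI is
the $(\alpha/2, 1-\alpha/2)$ quantile pair of the replicate distribution.
A condition is classified `EXCESS` when the CI lies wholly above 1,
`DECOMPENSATED` when wholly below 1, and `COMPENSATED` otherwise; secondary
flags record whether the CI crosses 0.5 (a single un-upregulated X) or 2.

The bootstrap scheme is *independent* (not paired or stratified) gene
resampling within each chromosome class; with gene sets shared across
conditions this is the simplest scheme that can be verified exactly by
enumeration, and its percentile intervals are the documented default of the
median-ratio CI tools this estimator descends from.

### An exact O(1) sampler for the bootstrap median

Resampling $n$ genes and taking a median costs $O(n)$ per replicate, which
makes $10^6$ replications per condition (and coverage studies over hundreds
of datasets) expensive. `xadose` instead samples the resample-median
distribution exactly through uniform order statistics: for sorted data
$x_{(1)} \le \dots \le x_{(n)}$, the $m$-th order statistic of a
with-replacement resample equals $x_{(\lceil n U_{(m)} \rceil)}$, where
$U_{(m)} \sim \mathrm{Beta}(m,\, n-m+1)$ is the $m$-th order statistic of
$n$ i.i.d. uniforms. For odd $n$ the resample median is a single such draw;
for even $n$ it is the mean of the two central order statistics, drawn
jointly via $U_{(m+1)} = U_{(m)} + (1-U_{(m)})\,B$ with
$B \sim \mathrm{Beta}(1,\, n-m)$. Because only indices into the sorted data
are drawn, ties are handled identically to literal resampling. The test
suite checks this sampler against a brute-force index resampler
(distributional equality) and against exhaustive enumeration of all
$27 \times 27$ equally likely resample pairs at $n_X = n_A = 3$.

Replicates whose autosomal resample median is zero (possible only for
pathological inputs with ≥ half zeros) are redrawn and counted, never
propagated as infinities.

### Seeding

Every stochastic entry point takes an integer seed. Condition-level
estimation derives one sub-seed per condition id from the base seed via a
string hash (`derive_seed()`), so the estimate for a condition does not
depend on which other conditions are processed alongside it or in what
order. (R's global RNG is save/restored around seeded sections, so seeded
calls do not perturb a caller's RNG stream.)

## Gene-set construction

*Expressed* genes in a sample are those with FPKM ≥ `lower_fpkm`
(inclusive, so the threshold 0 keeps every gene). The *ubiquitous* set is
the intersection of expressed genes over all samples (or pooled
conditions), built stepwise so the drop-then-plateau trajectory can be
inspected; the final set is order-invariant and anti-monotone in the
threshold. The default threshold of FPKM ≥ 1 follows standard practice for
assaying X upregulation.

The *upper threshold* is the minimum, across conditions, of each
condition's 99th-centile FPKM over the ubiquitous set (percentiles use
linear interpolation between order statistics, R type 7 — the convention is
a documented choice, as is computing the centile over the ubiquitous set
rather than all expressed genes). A gene strictly exceeding the threshold
in *any* condition is removed globally, yielding one fixed reduced set; the
strict comparison means a degenerate constant matrix excludes nothing. The
centile is always computed over the set's original pre-exclusion universe,
which makes the operation idempotent. Both choices (centile universe,
replicate pooling vs per-library analysis) are switchable, since published
descriptions of this workflow leave them open.

The analysis unit is the **condition**: replicate libraries are pooled by
per-gene mean before set construction and estimation (a `pool = FALSE`
flag analyses raw libraries instead).

## The synthetic compendium generator

`simulate_compendium()` generates FPKM matrices in which every pipeline
claim has a known truth:

* **Expression model.** Per-gene base expression is
  $2^{N(\mu, \sigma)}$ FPKM with $\mu = 3$, $\sigma = 1$ by default — a
  housekeeping-like set spanning roughly FPKM 1–60, median 8.
* **Trajectories.** Each genotype (XX, XO, XY, XX-Sry) carries an ordered
  stage list with a true X:A ratio: balanced (1) before reprogramming;
  excess (1.4) in two-X genotypes during reprogramming; decompensated
  (0.6–0.8) in one-X genotypes afterwards; XX females return to 1. The
  magnitudes are desk-scale choices — the modelled biology fixes only the
  direction (> 1, < 1) — sized so that, at the default gene counts, the
  designed states are resolvable by their CIs, which is the defining
  property of the states being modelled.
* **Calibration.** Under `calibrate = "exact"` (default) the X chromosome
  is rescaled per condition so the realized median ratio over ubiquitous
  genes *equals* the configured truth — truth is exact by construction, not
  asymptotic, because the estimand is a ratio of medians. The alternative
  `calibrate = "population"` shifts the X distribution by the ratio so the
  truth holds in population and sample medians vary; CI *coverage* studies
  must use this mode (with exact calibration the observed statistic equals
  the truth, and a percentile interval nearly always contains its own
  center, so "coverage" would be trivially ~100%). The bare-vector helper
  `simulate_ratio_vectors()` exists for exactly this use.
* **Tissue-specific silence.** A fraction of genes (default 40% of X, 10%
  of autosomal — the X enrichment) is assigned to one compartment (early
  germ, late germ, soma) and is a hard zero elsewhere, mirroring the
  argument that these genes are silent in the soma. This produces the
  classic artifact: in somatic conditions the FPKM ≥ 0 estimate sits well
  below the ubiquitous-gene estimate, and rising lower thresholds recover
  the truth monotonically (up to the few borderline genes a threshold step
  removes, whose loss can wiggle the ratio by ~0.1%).
* **Gonadal tail.** In gonadal somatic conditions, 25% of the
  non-tissue-specific X genes are boosted 16-fold — a high-expression X
  tail that inflates the naive ubiquitous-set ratio (~1.36× expected) and
  shifts the X log-ratio distribution relative to autosomes (KS-detectable).
  The boost exceeds the 99th-centile exclusion threshold for most boosted
  genes, so applying the upper threshold returns the CI to crossing 1. The
  tail is applied to gonadal *soma* only: germ-cell conditions stay pure
  realizations of the trajectory model, keeping truth-recovery well defined.
* **Replicates.** Each library multiplies the condition value by
  median-preserving log-normal noise with CV 0.2 (a documented guess for
  FACS-purified libraries; the design guarantees ≥ 2 replicates per
  condition). Generation is fully reproducible from the config seed.

What the generator does **not** emulate: count-level (negative binomial)
sampling noise and its mean–variance relation, library-size and
gene-length biases, correlated gene modules, partial (soft) tissue
specificity, and allele-level X dynamics (an explicit two-allele mixture is
approximated by the single excess ratio). Passing recovery tests therefore
demonstrates the *estimator chain* is correct and calibrated under a clean
generative model — not that any particular real tissue satisfies that
model.

## Numerical and degenerate-input choices

* Inclusive lower threshold (≥), strict upper exclusion (>).
* Percentiles and CI quantiles: linear interpolation (type 7), stated in
  the docs because different conventions move the CI by one grid step at
  small $n$.
* A constant gene vector in Spearman QC yields `NA` with a warning rather
  than an error; an all-zero probability vector in Jensen–Shannon distance
  is an error.
* Jensen–Shannon distances use base-2 logarithms and the square-root
  (metric) form, so values are bounded by 1; FPKM vectors are normalized to
  probabilities over the chosen gene universe.
* Hierarchical clustering sorts ids lexicographically before `hclust`, so
  tie-breaking is deterministic; average linkage is the default (the
  published dendrogram's linkage is unstated).
* Paired Wilcoxon with all differences zero is reported as not significant
  with a `degenerate` flag instead of erroring; ties are midranked with the
  exact distribution at small $n$ and the continuity-corrected normal
  approximation otherwise (`stats::wilcox.test` semantics).
* Retrogene acceptance requires autosomal location, zero introns,
  protein-coding status, strictly > 80% identity, and a parent inside the
  ubiquitous X set. In augmented comparisons the accepted retro rows are
  excluded from the autosomal background of *both* arms, so the comparison
  isolates the added expression and no transcription is counted twice.

## Known limitations

* The global upper-centile exclusion preferentially removes X genes that
  exceed the threshold in high-ratio conditions, truncating the X
  distribution from above and biasing excess-state point estimates downward
  by several percent at desk scale. This is a property of the published
  procedure itself, visible here because truth is known; trajectory
  recovery is therefore assessed on the ubiquitous set without the upper
  exclusion, whose role is the gonadal-tail correction.
* FPKM is taken as given; no within-pipeline re-normalization is applied,
  and no count-level inference is attempted.
* The Wilcoxon contrast defaults to the unpaired rank-sum on log2 FPKM;
  whether published "Wilcoxon test" values were paired or logged is
  generally unstated, so the paired signed-rank is offered as an option.

## Problem sizes used in the validation suite

The packaged validation suite runs at desk scale, chosen to mirror the
proportions of a realistic reduced housekeeping set: 102 X vs 4,188
autosomal genes for coverage studies (200 datasets per true ratio at
10,000 bootstrap replications), 200 simulated compendia (~2,200 genes, 24
conditions, 2 replicates) for trajectory-state recovery at 1,000
replications, 2,000 null simulations for test calibration, and exhaustive
$27\times27$ enumeration for the bootstrap oracle. The package default of
$10^6$ replications is used where a single estimate is computed.

## A worked example

```{r example, eval = FALSE}
library(xadose)

sim <- simulate_compendium(simulation_config(seed = 11))
pooled <- pool_replicates(sim$expression, sim$metadata)

gset <- build_ubiquitous_set(pooled, lower_fpkm = 1,
                             annotation = sim$annotation)
autoplot(gset) # stepwise sample-addition trajectory

est <- xa_ratio_table(pooled, sim$annotation, gset,
                      n_boot = 1e4, seed = 11, gene_set_tag = "ubiquitous")
plot_xa_ratios(est)

# gonadal tail artifact and its correction
rt <- pairwise_log2_ratios(pooled, sim$annotation,
                           "XY.soma.gonad.E14.5", "XY.soma.liver.E14.5", gset)
ks_x_vs_autosomes(rt)
plot_ratio_density(rt)
```

The full pipeline, including report files and a reproducibility manifest,
is `run_full_analysis(pipeline_config(...))`; `run_simulation()` writes a
generated compendium in the same formats the readers consume.
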