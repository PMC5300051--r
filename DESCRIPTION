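Package: xadose
Title: X-to-Autosome Dosage Compensation Analysis from RNA-Seq Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring X-chromosome dosage compensation states from
    bulk RNA-seq expression compendia. Builds ubiquitously expressed
    (housekeeping-like) gene sets under lower FPKM thresholds with an optional
    upper-centile exclusion, estimates X:A ratios as bootstrap median-of-X over
    median-of-autosome ratios with percentile confidence intervals, classifies
    per-condition dosage states (compensated, excess, decompensated), compares
    expression distributions between chromosome classes and genotypes
    (Kolmogorov-Smirnov, Wilcoxon), aggregates X-derived autosomal retrogene
    expression onto parental loci, and provides compendium quality control
    (Spearman correlation, Jensen-Shannon distances, hierarchical clustering).
    Includes a synthetic compendium generator with known per-condition true
    X:A ratios for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
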