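Package: multistress
Title: Multi-Stress DEG Set Intersections, Monte-Carlo Overlap Nulls, and
    Seedling Phenotype Statistics
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Downstream inference for multi-stress transcriptomic experiments
    in which differentially expressed gene (DEG) sets from several stress
    treatments and tissues are compared against each other and against a
    co-expression network. Provides exclusive (UpSet-style) intersection
    accounting of DEG sets with directionality classification, a size-matched
    Monte-Carlo null for intersection sizes with two-tailed percentile
    p-values, a module-size-preserving simulated-network null for
    co-expression module membership with Benjamini-Hochberg correction,
    derived-phenotype computation (relative water content, organ mass
    fractions, leaf mass per area) with Kruskal-Wallis and pairwise Wilcoxon
    treatment tests plus compact letter displays and trait PCA with
    missing-value imputation, and a synthetic-data generator that constructs
    DEG tables with exactly specified intersection structure, module
    partitions with injected enrichment, and phenotype tables with treatment
    effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
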