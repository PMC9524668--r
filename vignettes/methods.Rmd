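---
title: "Methods: set-level and phenotype-level inference for multi-stress transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: set-level and phenotype-level inference for multi-stress transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multistress)
```

# The inference problem

A multi-stress experiment exposes seedlings to several stress treatments —
here four: repeated dry-down (D), salt (S), PEG-mediated osmotic challenge
(P) and nutrient limitation (N) — and calls differentially expressed genes
(DEGs) per stress and tissue against a common control. Three questions
follow the DEG calling, and they are what this package answers:

1. **Which genes respond to which combinations of stresses?** Answered by
   *exclusive* intersections: each gene belongs to exactly the subset of
   stresses that call it, so categories are disjoint and partition the DEG
   union. This is the UpSet-plot convention; it differs from "inclusive"
   overlap counts (|A ∩ B| regardless of other sets), which double-count
   genes across categories. Within each category, genes are split into
   consistently up, consistently down, and "differentially regulated"
   (mixed-sign) classes.
2. **Is the observed sharing more or less than chance?** The DEG sets have
   very different sizes, and large sets overlap substantially by chance
   alone, so raw intersection sizes are uninterpretable. The package uses a
   size-matched Monte-Carlo null (below).
3. **Do shared DEGs concentrate in particular co-expression modules?**
   Module sizes in real networks span orders of magnitude, so raw member
   counts are again uninterpretable; the package uses a
   module-size-preserving simulated-network null.

Alongside the transcriptomic inference, the package computes the derived
phenotypes of such experiments (relative water content, organ mass
fractions, leaf mass per area) and their treatment statistics.

# The Monte-Carlo overlap null

For each of `n_reps` replicates, every stress receives a pseudo-DEG set
drawn uniformly without replacement from that stress's expressed-gene
universe, with the size fixed at the observed DEG count. Exclusive
intersections are recomputed per replicate, giving each category a null
distribution of sizes. The default `n_reps = 1000` keeps the granularity of
the resulting p-values at 2/1001 ≈ 0.002, fine enough for calls at
alpha = 0.05 while cheap enough to run interactively at a ~40,000-gene
universe.

Sampling is from each stress's *own* universe by default
(`universe_mode = "per_stress"`): the expression filter that defines the
universe is applied per tissue/treatment group, so the sampling frame of
one stress need not equal another's. A `"shared"` mode (union of the
universes) is available for sensitivity analysis.

## The two-tailed percentile p-value

With `N` null samples and observed count `x`:

$$p_{up} = \frac{1 + \#\{s \ge x\}}{N+1},\qquad
  p_{low} = \frac{1 + \#\{s \le x\}}{N+1},\qquad
  p = \min(1,\; 2\min(p_{up}, p_{low})).$$

Three numerical choices are deliberate. The **add-one** (plus-one)
convention counts the observation as one more replicate, which is the
standard way to avoid reporting p = 0 from a finite simulation; the
smallest attainable p is 2/(N+1). **Ties count toward both tails** (both
inequalities are inclusive), so p never exceeds 1 after capping, at the
price of mild conservatism when the null distribution is coarse — visible
in the calibration test, where the empirical type-I rate sits slightly
below the nominal 0.05. **Doubling** the smaller tail (rather than
interpolating percentiles) keeps the test exact-valid under discreteness.
The identical procedure is shared by the overlap and module nulls (one
implementation, `two_tailed_percentile_p()`).

A direction (`more` / `fewer`) is attached only when p clears alpha *and*
the observation lies on the corresponding side of the null median; the raw
two-tailed p is the primary quantity for the overlap test (one test per
category), with a BH column provided for convenience. For the module test,
where hundreds of (set, module) pairs are tested jointly, BH adjustment
across all pairs in the call is the primary quantity and direction is
called at the adjusted alpha.

# The simulated-network module null

Each replicate draws one uniform random gene-to-module partition with
exactly the observed module sizes and asks, for every DEG set, how many of
its genes land in each module. Simulating whole partitions (rather than
independent per-pair hypergeometric draws) preserves the negative
correlation between module counts — a gene placed in one module cannot be
in another — and mirrors the simulation of whole networks. For a random
set of size $k$ in a universe of $N$ genes, the null mean count in a module
of size $m$ is the hypergeometric expectation $km/N$, which the test suite
checks.

The WGCNA convention puts all unclustered genes in a "grey" pseudo-module.
Grey participates in simulation — it occupies genes, and removing it would
distort the other modules' nulls — but results for it are flagged
(`is_grey`) and should not be interpreted biologically.

The BH family is *all (DEG set, module) pairs within one call* (typically
one tissue). This is the widest defensible family for the joint question
"which pairs are enriched", and the choice is configuration, not
hard-coded: callers testing tissues jointly can pass both tissues' sets in
one call.

# Phenotype statistics

Derived traits are pure arithmetic and validated as such: RWC is
(FM − DM)/(HM − DM) and may legitimately fall slightly outside [0, 1] by
measurement noise (warned, never clipped, since clipping would bias
treatment contrasts); mass fractions sum to one by construction; LMA is
dry mass over area (g/cm²).

Treatment testing is nonparametric throughout: a Kruskal–Wallis test (with
tie correction) per trait, and — only when the overall test is significant
at alpha — pairwise two-sided Wilcoxon rank-sum tests with BH adjustment,
summarised by a compact letter display. "Controlling for block effects"
inside a Kruskal–Wallis test is not a standard construct, so the package
tests treatment only as the primary analysis and reports per-block
stratified Kruskal–Wallis p-values alongside, letting the analyst flag
traits whose significance is block-dependent. Pairwise tests use exact
enumeration when both groups have fewer than 8 observations and no ties,
and the normal approximation with tie correction otherwise. The letter
display uses the insert-and-absorb algorithm with input-order
(alphabetical) tie-breaking; two treatments share a letter exactly when
their adjusted p is at or above alpha, a property the test suite checks
exhaustively on up to five treatments.

Trait PCA centers and unit-scales each trait, excludes zero-variance
traits with a warning, and imputes missing cells before decomposition. The
default imputation is iterative low-rank SVD reconstruction on the
standardized matrix (rank `min(3, p − 1)`, converged on the missing cells)
— a probabilistic-PCA-style EM scheme; `method = "mean"` is the fallback.
The estimator is a configuration flag because at the typical missingness
of such tables (tens of cells out of hundreds) the two differ negligibly.
Component signs are arbitrary; tests compare loadings up to a global sign
per component. The "size-independent" trait subset used for a second PCA
is user-supplied: which traits count as size-independent is a biological
judgement, not something the package should hard-code.

# The synthetic-data generator

The generator exists so every stage of the pipeline can be exercised,
calibrated and power-tested without sequencing data. Its design principle:
**set-level structure is constructed exactly; only nuisance quantities are
random.** Genes are *allocated* to intersection categories so the realized
exclusive sizes equal the configuration with zero tolerance; randomness
enters only in which genes land where, fold-change signs (per-category
up/down/mixed probabilities; mixed genes are guaranteed both signs),
magnitudes (log-normal, sdlog 0.5), and FDR values (uniform below the 0.05
threshold for DEGs). These distributional choices are arbitrary and
irrelevant to set-level inference, which depends only on membership.

Default scales emulate the motivating study conditions: a 39,042-gene
universe across five treatments and two tissues; 1000 replicates for both
nulls; module-size spectra spanning ~30 to ~18,500 genes; a
randomized-block phenotype design with two blocks and 11 individuals per
treatment, 21 traits, and a missing-cell rate of 11/630 when missingness
is wanted. Phenotype baselines and noise SDs are generic seedling-scale
values (e.g. RWC 0.92 ± 0.03, δ13C −30 ± 0.8 ‰) chosen once and
documented in the source; treatment effects default to zero and are
supplied per scenario.

What the generator does **not** emulate: count-level RNA-seq noise,
library-size and dispersion structure, the DE caller's behaviour near its
threshold, correlated co-expression (module partitions are structureless
except for injected enrichment), and correlated trait measurement error.
Passing tests therefore demonstrate that the *set-level and rank-level
inference* is correct and calibrated given upstream calls — not that any
particular upstream caller is reliable.

# Problem sizes in the test suite

Tests run at desk scale, chosen to keep the full suite under a minute
while leaving Monte-Carlo error well inside the asserted tolerances:
brute-force oracle comparison on 1000 random collections of up to 50
genes; calibration over 200 null scenarios of 500 replicates each on a
2000-gene universe (rejection rate compared to 0.05 within three binomial
standard errors); hypergeometric agreement at 10,000 replicates; module
recovery with 90/100 genes injected into a 200-gene module of a
10,000-gene, five-module partition at 500 simulations; phenotype recovery
over 100 replicates at 11 individuals per treatment with a four-SD shift
on one trait. The acceptance script uses the same scales.

# Known limitations

- The overlap null tests *exclusive* category sizes for all categories,
  including multi-stress ones. An inclusive-overlap statistic is a
  reasonable alternative for multi-stress keys; the building blocks
  (`sample_null_intersections()` returns full per-replicate category
  vectors) allow computing it, but it is not the reported default.
- Percentile p-values are discrete; at 1000 replicates the granularity is
  ~0.002, and BH-adjusted values inherit plateaus (e.g. many pairs sharing
  one adjusted value just above alpha). This is a property of the
  procedure, not special-cased.
- The letter display is a summary of the adjusted-p graph, not an
  inference procedure; with heavily tied adjusted p-values near alpha it
  can change letters under small data perturbations.
- Directionality classification requires a nonzero log2 fold change for
  every member call; a significant DEG with an exactly zero estimate is
  treated as invalid input rather than silently assigned a sign.
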