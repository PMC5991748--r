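---
title: "Module biomarkers from miRNA co-expression networks: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Module biomarkers from miRNA co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirmod)
```

`mirmod` identifies multi-miRNA diagnostic biomarkers as *activated
co-expression modules*: groups of miRNAs that co-express reproducibly in a
disease cohort but lose that wiring in healthy controls. This vignette
explains the models behind each stage, the parameters that matter, and the
design decisions taken where the methodology left genuine choices.

## The synthetic study and what it emulates

All development and testing run against a synthetic three-cohort study
produced by `synthetic_design()` / `generate_cohorts()`:

* a **disease (reference) cohort** of 90 samples,
* a **technical replicate** of the same 90 samples (same values plus
  measurement noise), and
* a **normal-control cohort** of 34 samples,

over 300 miRNA features arranged in 13 modules of sizes 3–120 (mean ≈ 21.6),
with the remaining features unassigned noise. These counts mirror a typical
clinical microarray design in this field: the two disrupted modules play the
role of disease-rewired ("activated") modules, and 18 features carry an
additive log-scale mean shift in the disease cohort (three of the four
members of the small disrupted module are up-shifted, emulating an
up-regulated biomarker module; the rest are scattered so the classifier
stage has a multi-module signal).

**The one-factor block model.** Inside module $m$ each feature is
$x = \sqrt{\rho_m}\, f + \sqrt{1-\rho_m}\, \varepsilon$ with a shared
per-sample factor $f \sim N(0,1)$ and independent unit noise. Its virtue is
analytic transparency: every within-module pair has correlation exactly
$\rho_m$ in expectation, so correlation calibration, disruption, and module
recovery can all be checked against closed-form targets. The default
$\rho = 0.7$ gives modules that are clearly detectable at $n = 90$ without
being degenerate.

**Technical replication.** The replicate is `ref + rep_noise_sd * noise`
with `rep_noise_sd = 0.3`: the same biological samples remeasured with
roughly 9% added noise variance, giving a per-feature test–retest
correlation of about 0.96 — the reproducibility a good same-RNA rehybridization
achieves. **Disruption** replaces the shared factor with an independent
per-feature factor in the control cohort only, destroying co-expression while
keeping each feature's marginal variance.

What the generator does *not* emulate: probe-level replicate structure,
batch effects, missing values, heavy-tailed intensity noise, and — most
importantly — a scale-free connectivity distribution (see below). Passing
tests therefore demonstrate correctness of the machinery and its behaviour
under a controlled block-correlation world, not performance on any
particular clinical dataset.

## Network construction

Correlation is Pearson on the (already normalized, log-scale) intensities;
adjacency is the unsigned soft threshold $|r|^\beta$.

**Scale-free fit and the choice of β.** The fit index bins the connectivity
vector into 10 equal-width bins, drops empty bins, and takes the $R^2$ of
log10 frequency against log10 mean connectivity. Equal-*width* binning is a
requirement, not a preference: equal-count bins have constant frequency by
construction, which makes the regression exactly flat and the index
meaningless. β is the smallest candidate with $R^2 \ge 0.8$; if no candidate
reaches the cut, the best-fitting power is returned with a flag.

The default candidate grid stops at 12. Block-correlated data are not
scale-free, so the $R^2$ criterion keeps improving as β grows — but at
β ≈ 19 a within-module correlation range of 0.55–0.85 maps to adjacencies
spanning four orders of magnitude, and the dendrogram loses its block
structure. A robustness scan (8 seeds × β ∈ 2…16 on a 10-module design)
showed perfect planted-module recovery for β ∈ [4, 12] and failures from
β ≥ 14; the grid cap encodes that. On real, approximately scale-free data
the criterion typically halts at β ≈ 4–8 well before the cap matters.

**Module detection.** Average-linkage clustering on $1 - \mathrm{TOM}$,
cut at a data-driven height: the cut is placed in the widest gap between
consecutive merge heights within the upper part of the tree (`deep_split`
moves the floor of that search window; higher values allow deeper cuts and
more, smaller modules). Branches below `min_module_size = 3` stay
unassigned (grey). This is a deliberate simplification of dynamic
branch decomposition — for block-structured similarity the between-module
merges concentrate near the top of the tree and the widest gap separates
them cleanly, which is exactly the regime the planted-recovery invariant
tests (adjusted Rand ≥ 0.9 at ρ = 0.7; in practice 1.0 across seeds).
Degenerate flat dendrograms (all dissimilarities equal) return a single
flagged module rather than an arbitrary split. Eigengene-based module
merging is off: whether to merge correlated modules is a dataset-level
judgement, and the planted modules are generated distinct.

**Edge lists.** The TOM graph is thresholded for export and for the SVM
Laplacian. An absolute cutoff is exposed, but the default rule keeps the
top 5% of off-diagonal TOM values: TOM's scale collapses as β grows, so a
fixed absolute default would silently produce empty graphs at higher
powers.

## Module comparison (MCR)

Each pair of modules from two partitions is tested with the upper-tail
hypergeometric probability $P(X \ge \text{overlap})$; unassigned features
are excluded from the module axes but count in the test universe (they were
clustered, they simply joined no module). The universe is the intersection
of the two cohorts' feature sets. The pairwise $p < 0.05$ rule is used
as-is, with no multiplicity correction — MCR is a descriptive consistency
ratio, not an inference.

## Preservation and activation (Z_summary)

Four density statistics are computed in the test cohort (mean member
correlation, mean adjacency, proportion of variance explained by the module
eigengene, mean kME) and three connectivity statistics between cohorts
(correlations of kIM vectors, kME vectors, and vectorized member
correlation matrices). Each is standardized against `n_perm` random
pseudo-modules of the same size drawn uniformly from all features —
the null hypothesis is "a random feature set of this size". The reference
cohort's β is reused for the test cohort so adjacencies are comparable.
`Z_summary` is the average of the density-median and connectivity-median.

Parameters: `n_perm` defaults to 200 (100 in the heavier recovery tests;
at these module counts one permutation pass costs a few seconds), and the
seed is mandatory — every draw is reproducible. Modules with fewer than 3
members are skipped with a warning: a correlation of length-≤2 vectors is
degenerate.

**Degenerate nulls.** When the permutation distribution has zero standard
deviation *and* the observed value equals the permutation mean, Z is
reported as 0 (flagged), not missing. This case is not hypothetical: with
the test cohort identical to the reference, every connectivity statistic —
observed and permuted — is exactly 1, and a strict missing value would
poison `Z_summary` for perfectly preserved modules. A zero-sd null with a
*different* observed value is reported as flagged missing, never ±Inf.

**A known limitation.** Against a high-quality technical replicate, the
permutation null for connectivity statistics is extremely tight (random
pseudo-modules also reproduce almost perfectly, because the two datasets
share everything but measurement noise). Large heterogeneous modules can
then score connectivity Z values far below zero even though their absolute
reproducibility is excellent: a near-constant kIM vector correlates less
stably across datasets than the strongly heterogeneous kIM of a random
cross-module feature set. The classification therefore rests on the
*joint* rule — activated means `Z_summary < 0` versus controls *and*
`Z_summary ≥ 0` versus the replicate — which in the synthetic study
recovers exactly the planted disrupted modules. Density Z values do not
suffer from this artifact.

## Network-constrained SVM

The objective is
$\frac{1}{n}\sum_i \mathrm{hinge}\!\left(y_i(w^\top x_i + b)\right) +
\lambda_{margin}\|w\|^2 + \lambda_{net}\, w^\top L w$,
with $L$ the symmetric normalized Laplacian of the co-expression graph
(isolated features contribute identity rows, i.e. plain ridge). The
Laplacian term pulls the weights of connected features together, so hubs of
class-associated sub-networks accumulate weight. Features are standardized
across all samples first, making a positive weight mean "higher in the
disease class".

**Solver.** Folding the two quadratic penalties into
$M = \lambda_{margin} I + \lambda_{net} L$ turns the problem into a
standard soft-margin SVM in the metric of $M$; its dual is a box-constrained
QP with one equality constraint, solved by a deterministic
maximal-violating-pair ascent with exact clipped line search (KKT tolerance
1e-8, iteration cap 1e5). Exact per-step maximization makes the dual
objective non-decreasing — asserted on the recorded trace — and the solution
matches an independent interior-point QP solution to ~1e-8 on toys, far
inside the 1e-4 agreement the test suite requires. A primal subgradient
scheme was rejected: at the hinge kink its convergence is too slow and too
step-size-sensitive to certify that agreement.

Defaults $\lambda_{margin} = \lambda_{net} = 0.01$ balance the margin and
smoothness terms at the standardized scale of these data; both are exposed,
and `evaluate_classifier()` accepts vectors to scan a grid. Performance is
reported as stratified 5-fold cross-validation (pooled held-out decision
values) *and* as apparent resubstitution metrics, labelled as such, because
published single-number sensitivities/specificities in this literature are
often resubstitution values.

## Diagnostics

Module scores are the member mean, or the weighted mean
$\sum_j w_j x_j / \sum_j |w_j|$ when SVM weights are supplied — normalizing
by $\sum |w|$ keeps mixed-sign weights from driving the denominator toward
zero. Both modes are first-class and every report labels which was used.
ROC thresholds sit at each distinct score; AUC uses the rank (concordance)
estimator with ties counted ½. Youden-optimal cutoffs are searched over
midpoints between consecutive distinct scores plus the infinite endpoints,
with ties broken toward higher specificity, then lower cutoff. Markers with
AUC < 0.5 are flagged as flipped rather than silently inverted. The subset
search enumerates all member subsets (capped at 12 members; the pipeline
pre-selects by |weight| beyond that) and orders by AUC, then
lexicographically, so output is deterministic.

## Annotation

Target predictions are consumed as three local export files; a consensus
target must appear in all three sources, and per-miRNA consensus sets are
unioned with attribution. The bundled files under `inst/extdata/` are
synthetic (as their names state), built only to exercise the set algebra and
the enrichment path. Enrichment is the same hypergeometric upper tail as
the module-overlap test (one shared implementation, asserted equal in the
tests), with Benjamini–Hochberg adjustment within each term category; both
raw and adjusted p-values are reported and the significance column can
threshold on either, since listing practice differs between the two.

## Problem sizes and determinism

The test suite exercises: oracle equivalences on ≤ 10-feature matrices
(TOM, hypergeometric tails, AUC, QP), module recovery and preservation on a
300-feature / 10-module cohort with 100 permutations, classifier properties
on 120-feature cohorts, and the full pipeline on an 80-feature
mini-study; the acceptance script runs the complete default study
(300 features, 200 permutations, 5-fold CV) in about a minute. Every
random stage takes an explicit seed, RNG state is restored after each call,
and permutation draws are made over a sorted feature universe so results do
not depend on input row or column order. `run_pipeline()` writes an MD5
manifest; identical configurations produce identical manifests.
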