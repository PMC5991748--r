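# mirmod

Discovery and evaluation of **miRNA co-expression module biomarkers** from
three expression cohorts: a disease group, a technical replicate of the same
samples, and a normal-control group.

Single-miRNA markers ignore the co-regulation structure of disease; `mirmod`
instead looks for *modules* — branches of a weighted co-expression network —
whose internal wiring is reproducible in the technical replicate but
*disrupted* ("activated") in healthy controls, and turns those modules into
multi-miRNA diagnostic scores.

## The method

1. **Co-expression networks and modules** (per cohort). Pairwise Pearson
   correlations are soft-thresholded into an unsigned adjacency
   `a_ij = |cor(x_i, x_j)|^β`, with β chosen as the smallest power whose
   connectivity distribution meets the scale-free fit criterion R² ≥ 0.8.
   The topological overlap measure

   `TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)`

   combines direct adjacency with shared neighbours; average-linkage
   clustering of `1 − TOM` is cut into branches of ≥ 3 features, each branch
   a module labelled by a colour.

2. **Module-based consensus ratio (MCR).** Partitions of two cohorts are
   cross-tabulated; each module pair is tested for overlap with a one-sided
   Fisher (hypergeometric) test, and

   `MCR_{a,b} = NM_overlap / (NM_a × NM_b) × 100%`

   summarizes how consistently the two cohorts agree at module level.

3. **Permutation Z_summary preservation.** For each reference module, four
   density statistics (mean correlation, mean adjacency, proportion of
   variance explained by the eigengene, mean kME) and three connectivity
   statistics (ref-vs-test correlations of kIM, kME and the member
   correlation matrices) are standardized against random same-size
   pseudo-modules:

   `Z_summary = ( median(Z_density terms) + median(Z_connectivity terms) ) / 2`

   `Z_summary ≥ 2` means preserved (≥ 10 strongly preserved); a negative
   value means disrupted. A module disrupted versus controls but intact
   versus the technical replicate is an **activated biomarker module**.

4. **Network-constrained SVM (hub ranking).** A linear SVM with an extra
   graph-smoothness penalty,

   `min_w,b  mean hinge(y(wᵀx + b)) + λ_margin‖w‖² + λ_net wᵀLw`,

   where `L` is the normalized Laplacian of the TOM graph, ranks miRNAs by
   signed weight; the induced sub-network of the top-k hubs is reported with
   stratified cross-validated sensitivity/specificity/AUC.

5. **Diagnostics.** Module members are combined into a per-sample score
   (mean, or SVM-weighted mean `Σ w_j x_j / Σ|w_j|`), evaluated by ROC AUC
   and the Youden-optimal cutoff (`J = Se + Sp − 1`), with an exhaustive
   member-subset search for the best-performing combination.

6. **Annotation.** Consensus target genes (predicted by all three local
   target-database exports) and hypergeometric term enrichment with
   Benjamini–Hochberg adjustment.

A synthetic three-cohort generator (`synthetic_design()`,
`generate_cohorts()`) with planted block-correlated modules, disrupted
modules, and differential features provides ground truth for every stage.

## Worked example

```r
library(mirmod)

co  <- generate_cohorts(synthetic_design(seed = 1))
det <- detect_modules(co$ref)
det$partition
#> Module partition: 13 modules over 300 features ( 19 unassigned )
#>   sizes: 120, 35, 25, 20, 18, 15, 12, 10, 8, 6, 5, 4, 3

compare_partitions(det$partition, detect_modules(co$rep)$partition)
#> Module overlap: 13 x 13 modules; 13 significant pairs (p < 0.05 )
#>   MCR: 7.69 % over universe of 300 features

pres <- module_preservation(co$ref, co$norm, det$partition, det$beta,
                            n_perm = 200, seed = 2)
glance(pres)
#> # A tibble: 1 × 7
#>   n_modules n_perm  beta n_strong n_preserved n_weak n_activated
#>       <int>  <int> <int>    <int>       <int>  <int>       <int>
#> 1        13    200    12        0           1      8           4
```

The 13 detected modules exactly match the planted partition (adjusted Rand
index 1.0), and the module-based consensus ratio is 7.69%. Four modules
score a negative `Z_summary` against controls; intersecting with the
replicate comparison (`classify_modules()`) keeps exactly the two planted
disrupted modules as activated-biomarker candidates. The full chain,
including the SVM hub ranking and the diagnostic subset search, runs from
one call:

```r
manifest <- run_pipeline(default_config(seed = 1))
```

which writes each stage's CSV/JSON/SIF artifacts plus an MD5 manifest. A
thin command-line wrapper with one subcommand per stage lives at
`inst/cli/mirmod-cli.R`.

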