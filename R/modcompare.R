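#' Cross-tabulate two module partitions
#'
#' Counts, for every pair of modules (one from each partition), the features
#' shared by both, over the common feature universe. Unassigned features
#' (label 0) are excluded from both axes.
#'
#' @param pa,pb `mirmod_partition` tibbles sharing at least one feature id.
#' @return An integer matrix; rows are `pa` modules (`Mod_1`, ...), columns
#'   `pb` modules.
#' @export
overlap_counts <- function(pa, pb) {
  common <- intersect(pa$feature_id, pb$feature_id)
  if (!length(common)) abort("partitions share no feature ids")
  la <- pa$module[match(common, pa$feature_id)]
  lb <- pb$module[match(common, pb$feature_id)]
  mods_a <- sort(unique(la[la > 0]))
  mods_b <- sort(unique(lb[lb > 0]))
  counts <- matrix(0L, length(mods_a), length(mods_b))
  dimnames(counts) <- list(if (length(mods_a)) paste0("Mod_", mods_a),
                           if (length(mods_b)) paste0("Mod_", mods_b))
  for (i in seq_along(mods_a)) {
    for (j in seq_along(mods_b)) {
      counts[i, j] <- sum(la == mods_a[i] & lb == mods_b[j])
    }
  }
  counts
}

#' One-sided Fisher (hypergeometric) overlap test for one module pair
#'
#' Upper-tail probability of observing at least `overlap` shared features
#' between a module of `size_a` and one of `size_b` drawn from a universe of
#' `n` features.
#'
#' @param overlap Observed intersection size.
#' @param size_a,size_b Module sizes within the universe.
#' @param n Universe size.
#' @return The enrichment p-value `P(X >= overlap)`.
#' @export
fisher_overlap_p <- function(overlap, size_a, size_b, n) {
  hyper_upper_p(overlap, size_a, size_b, n)
}

#' Module-based consensus ratio from an overlap p-value table
#'
#' The MCR between two partitions is the percentage of module pairs whose
#' overlap is significant: `NM_overlap / (NM_a * NM_b) * 100`, where
#' `NM_overlap` counts pairs with `p < alpha`.
#'
#' @param pvalues Matrix of pairwise overlap p-values.
#' @param alpha Significance level for a pair to count as overlapping.
#' @return A list with `nm_overlap` and `mcr_percent`.
#' @export
mcr <- function(pvalues, alpha = 0.05) {
  if (!length(pvalues)) abort("p-value table is empty")
  nm_overlap <- sum(pvalues < alpha)
  list(nm_overlap = nm_overlap,
       mcr_percent = nm_overlap / length(pvalues) * 100)
}

#' Compare two module partitions (counts, Fisher tests, MCR)
#'
#' Cross-tabulates the partitions over their common feature universe, tests
#' every module pair for overlap enrichment with a one-sided hypergeometric
#' test (no multiplicity correction; the pairwise `p < alpha` rule defines a
#' significant overlap), and summarizes with the module-based consensus
#' ratio.
#'
#' @inheritParams overlap_counts
#' @param alpha Per-pair significance level.
#' @param grey_in_universe Should unassigned (label 0) features count in the
#'   test universe? They are always excluded from the module axes.
#' @return A `mirmod_overlap` object: `counts`, `pvalues`, `nm_a`, `nm_b`,
#'   `nm_overlap`, `mcr_percent`, `alpha`, `n_universe`.
#' @export
compare_partitions <- function(pa, pb, alpha = 0.05,
                               grey_in_universe = TRUE) {
  common <- intersect(pa$feature_id, pb$feature_id)
  if (!length(common)) abort("partitions share no feature ids")
  la <- pa$module[match(common, pa$feature_id)]
  lb <- pb$module[match(common, pb$feature_id)]
  if (grey_in_universe) {
    n_universe <- length(common)
  } else {
    n_universe <- sum(la > 0 & lb > 0)
  }
  counts <- overlap_counts(pa, pb)
  if (!length(counts)) {
    return(structure(list(counts = counts, pvalues = counts + NA_real_,
                          nm_a = nrow(counts), nm_b = ncol(counts),
                          nm_overlap = 0L, mcr_percent = NA_real_,
                          alpha = alpha, n_universe = n_universe),
                     class = "mirmod_overlap"))
  }
  # module sizes within the common universe
  sizes_a <- sapply(sub("Mod_", "", rownames(counts)),
                    function(mod) sum(la == as.integer(mod)))
  sizes_b <- sapply(sub("Mod_", "", colnames(counts)),
                    function(mod) sum(lb == as.integer(mod)))
  pvalues <- counts * NA_real_
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      pvalues[i, j] <- fisher_overlap_p(counts[i, j], sizes_a[i],
                                        sizes_b[j], n_universe)
    }
  }
  s <- mcr(pvalues, alpha = alpha)
  structure(list(counts = counts, pvalues = pvalues,
                 nm_a = nrow(counts), nm_b = ncol(counts),
                 nm_overlap = s$nm_overlap, mcr_percent = s$mcr_percent,
                 alpha = alpha, n_universe = n_universe),
            class = "mirmod_overlap")
}

#' @export
print.mirmod_overlap <- function(x, ...) {
  cat("Module overlap:", x$nm_a, "x", x$nm_b, "modules;",
      x$nm_overlap, "significant pairs (p <", x$alpha, ")\n")
  cat("  MCR:", round(x$mcr_percent, 2), "% over universe of",
      x$n_universe, "features\n")
  invisible(x)
}
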