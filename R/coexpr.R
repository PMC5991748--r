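#' Pairwise feature correlation matrix
#'
#' Pearson correlation of every pair of features across samples.
#'
#' @param x An expression tibble (or feature-by-sample matrix).
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(x) {
  m <- expression_matrix(x)
  if (ncol(m) < 3) abort("need at least 3 samples for correlation")
  if (nrow(m) < 2) abort("need at least 2 features for correlation")
  if (!all(is.finite(m))) abort("expression values must all be finite")
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    abort(paste0("zero-variance feature(s): ",
                 paste(rownames(m)[sds == 0], collapse = ", ")))
  }
  cc <- cor(t(m))
  diag(cc) <- 1
  cc
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins the connectivity vector into equal-width bins spanning its range and
#' regresses the log10 frequency on the log10 mean connectivity per bin; the
#' R-squared of that line is the scale-free topology fit index used to pick
#' the soft power. (Equal-width binning is required: equal-count bins have
#' constant frequency by construction, which makes the regression
#' meaningless.)
#'
#' @param k Nonnegative connectivity vector (adjacency row sums).
#' @param n_bins Number of equal-width bins (empty bins are dropped).
#' @return A list with `r_squared` (in `[0, 1]`), `slope`, a `bins` tibble,
#'   and a `degenerate` flag (TRUE when all connectivities are equal, in
#'   which case `r_squared` is 0).
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  stopifnot(n_bins >= 4)
  if (any(k < 0)) abort("connectivity must be nonnegative")
  if (diff(range(k)) == 0) {
    return(list(r_squared = 0, slope = NA_real_,
                bins = tibble(), degenerate = TRUE))
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  cut_idx <- cut(k, breaks = breaks, include.lowest = TRUE)
  bins <- tibble(mean_k = tapply(k, cut_idx, mean),
                 freq = tapply(k, cut_idx, length) / length(k)) |>
    dplyr::filter(!is.na(.data$mean_k), .data$mean_k > 0, .data$freq > 0)
  if (nrow(bins) < 2) {
    return(list(r_squared = 0, slope = NA_real_,
                bins = bins, degenerate = TRUE))
  }
  fit <- stats::lm(log10(freq) ~ log10(mean_k), data = bins)
  r2 <- if (sd(log10(bins$freq)) == 0) 0 else {
    cor(log10(bins$freq), log10(bins$mean_k))^2
  }
  list(r_squared = r2, slope = unname(stats::coef(fit)[2]),
       bins = bins, degenerate = FALSE)
}

#' Select the soft-threshold power
#'
#' Scans candidate powers, forming the unsigned adjacency `|cor|^power` for
#' each and scoring its connectivity distribution with [scale_free_fit()].
#' The selected power is the smallest whose fit reaches `fit_cut`; if none
#' does, the power with the best fit is returned and `reached_cut` is FALSE.
#'
#' @param x An expression tibble or matrix.
#' @param powers Ascending candidate powers. The default grid stops at 12:
#'   for networks of a few hundred features, higher powers spread the
#'   within-module adjacencies over several orders of magnitude, which
#'   degrades downstream dendrogram cutting more than it improves the
#'   scale-free fit.
#' @param fit_cut Scale-free R-squared required to accept a power.
#' @param n_bins Passed to [scale_free_fit()].
#' @return A list with `beta`, the `scan` tibble (power, r_squared, slope,
#'   mean_k), and `reached_cut`.
#' @export
pick_power <- function(x, powers = 1:12, fit_cut = 0.8, n_bins = 10) {
  if (!length(powers) || is.unsorted(powers)) {
    abort("candidate powers must be nonempty and ascending")
  }
  cc <- abs(correlation_matrix(x))
  scan <- purrr::map_dfr(powers, function(p) {
    a <- cc^p
    diag(a) <- 0
    k <- rowSums(a)
    f <- scale_free_fit(k, n_bins = n_bins)
    tibble(power = p, r_squared = f$r_squared, slope = f$slope,
           mean_k = mean(k))
  })
  ok <- which(scan$r_squared >= fit_cut)
  if (length(ok)) {
    list(beta = powers[ok[1]], scan = scan, reached_cut = TRUE)
  } else {
    list(beta = powers[which.max(scan$r_squared)], scan = scan,
         reached_cut = FALSE)
  }
}

#' Topological overlap matrix
#'
#' For adjacency `a` (symmetric, values in `[0, 1]`, diagonal ignored),
#' `TOM[i, j] = (sum_u a[i,u] a[u,j] + a[i,j]) / (min(k_i, k_j) + 1 - a[i,j])`
#' for `i != j`, with the diagonal reported as 1. The dissimilarity
#' `1 - TOM` is the clustering input for module detection.
#'
#' @param adjacency Symmetric adjacency matrix in `[0, 1]`.
#' @return The TOM matrix, symmetric with values in `[0, 1]` and unit
#'   diagonal.
#' @export
tom_matrix <- function(adjacency) {
  check_symmetric(adjacency, "adjacency")
  a <- adjacency
  diag(a) <- 0
  if (any(a < 0) || any(a > 1)) abort("adjacency values must lie in [0, 1]")
  k <- rowSums(a)
  shared <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (shared + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

new_partition <- function(feature_id, module, ...) {
  out <- tibble(feature_id = as.character(feature_id),
                module = as.integer(module),
                color = label_colors(as.integer(module)))
  structure(out, class = c("mirmod_partition", class(out)), ...)
}

#' Detect modules by clustering the TOM dissimilarity
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, cut into branches
#' at a data-driven height: the cut is placed in the widest gap between
#' consecutive dendrogram merge heights within the upper part of the tree
#' (how deep the search window reaches is set by `deep_split`). Branches
#' smaller than `min_module_size` are left unassigned (label 0, grey).
#' Remaining branches become modules labeled 1, 2, ... by decreasing size.
#' A flat dendrogram (all merge heights equal) yields a single flagged
#' module spanning all features.
#'
#' @param tom A TOM matrix (or any symmetric similarity in `[0, 1]`).
#' @param min_module_size Smallest branch size kept as a module.
#' @param deep_split Integer 0-4; larger values let the cut search deeper
#'   into the tree, producing more, smaller modules.
#' @param cut_height Optional explicit dissimilarity cut height overriding
#'   the gap heuristic.
#' @return A `mirmod_partition` tibble (`feature_id`, `module`, `color`)
#'   with attributes `cut_height`, `degenerate` and the `hclust` tree.
#' @export
cluster_and_cut <- function(tom, min_module_size = 3, deep_split = 2,
                            cut_height = NULL) {
  check_symmetric(tom, "tom")
  ids <- rownames(tom) %||% as.character(seq_len(nrow(tom)))
  n <- nrow(tom)
  if (n < min_module_size) {
    warn("fewer features than min_module_size; all features unassigned")
    return(new_partition(ids, rep(0L, n),
                         cut_height = NA_real_, degenerate = TRUE))
  }
  diss <- 1 - tom
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  heights <- sort(hc$height)
  if (diff(range(heights)) < 1e-10) {
    warn("flat dendrogram: all dissimilarities equal; one module returned")
    return(new_partition(ids, rep(1L, n),
                         cut_height = NA_real_, degenerate = TRUE, tree = hc))
  }
  if (is.null(cut_height)) {
    stopifnot(deep_split %in% 0:4)
    lo <- quantile(heights, probs = max(0, 0.95 - 0.15 * (deep_split + 1)))
    cand <- heights[heights >= lo]
    if (length(cand) < 2) cand <- heights
    gaps <- diff(cand)
    g <- which.max(gaps)
    cut_height <- (cand[g] + cand[g + 1]) / 2
  }
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  keep <- keep[order(-sizes[keep], as.integer(keep))]
  relabel <- setNames(rep(0L, length(sizes)), names(sizes))
  relabel[keep] <- seq_along(keep)
  new_partition(ids, relabel[as.character(cl)],
                cut_height = cut_height, degenerate = FALSE, tree = hc)
}

#' Build the weighted co-expression network for one cohort
#'
#' @param x Expression tibble or matrix.
#' @param beta Soft-threshold power (see [pick_power()]).
#' @return A `mirmod_network` list: `corr`, `beta`, `adjacency`
#'   (`|corr|^beta`, unsigned), `tom`, and connectivity `k` (adjacency row
#'   sums excluding the diagonal).
#' @export
build_network <- function(x, beta) {
  stopifnot(length(beta) == 1, beta > 0)
  cc <- correlation_matrix(x)
  adj <- abs(cc)^beta
  diag(adj) <- 1
  a0 <- adj
  diag(a0) <- 0
  structure(list(corr = cc, beta = beta, adjacency = adj,
                 tom = tom_matrix(adj), k = rowSums(a0)),
            class = "mirmod_network")
}

#' One-call module detection for a cohort
#'
#' Picks the soft power, builds the network, and cuts the TOM dendrogram.
#'
#' @inheritParams pick_power
#' @inheritParams cluster_and_cut
#' @return A list with `network` (`mirmod_network`), `partition`
#'   (`mirmod_partition`), `beta`, `power_scan`, and `reached_cut`.
#' @export
detect_modules <- function(x, powers = 1:12, fit_cut = 0.8,
                           min_module_size = 3, deep_split = 2,
                           cut_height = NULL) {
  pw <- pick_power(x, powers = powers, fit_cut = fit_cut)
  net <- build_network(x, pw$beta)
  part <- cluster_and_cut(net$tom, min_module_size = min_module_size,
                          deep_split = deep_split, cut_height = cut_height)
  list(network = net, partition = part, beta = pw$beta,
       power_scan = pw$scan, reached_cut = pw$reached_cut)
}

# First principal component of the standardized member submatrix, oriented
# so the mean member correlation with it is positive. Returns the
# sample-length eigengene, propVarExpl (mean squared member correlation with
# the eigengene) and the member kME vector.
eigengene_of <- function(m) {
  if (nrow(m) == 1) {
    eg <- as.numeric(scale(m[1, ]))
    return(list(eigengene = eg, prop_var_expl = 1,
                kme = setNames(1, rownames(m))))
  }
  zs <- t(scale(t(m)))
  sv <- svd(zs, nu = 0, nv = 1)
  eg <- sv$v[, 1]
  kme <- as.numeric(cor(t(m), eg))
  if (mean(kme) < 0) {
    eg <- -eg
    kme <- -kme
  }
  list(eigengene = eg, prop_var_expl = mean(kme^2),
       kme = setNames(kme, rownames(m)))
}

#' Module eigengenes and proportion of variance explained
#'
#' The eigengene of a module is the first principal component of its
#' standardized member expression, sign-oriented so that the mean member
#' correlation with it is positive. `prop_var_expl` is the mean squared
#' member correlation with the eigengene.
#'
#' @param x Expression tibble or matrix.
#' @param partition A `mirmod_partition` over the same features.
#' @return A list with `eigengenes` (samples-by-modules matrix, columns
#'   `ME1`, `ME2`, ...) and a `prop_var_expl` tibble (module, prop_var_expl).
#' @export
module_eigengene <- function(x, partition) {
  m <- expression_matrix(x)
  stopifnot(all(partition$feature_id %in% rownames(m)))
  mods <- sort(unique(partition$module[partition$module > 0]))
  if (!length(mods)) abort("partition has no assigned modules")
  egs <- matrix(NA_real_, ncol(m), length(mods),
                dimnames = list(colnames(m), paste0("ME", mods)))
  pve <- numeric(length(mods))
  for (i in seq_along(mods)) {
    members <- partition$feature_id[partition$module == mods[i]]
    e <- eigengene_of(m[members, , drop = FALSE])
    egs[, i] <- e$eigengene
    pve[i] <- e$prop_var_expl
  }
  list(eigengenes = egs,
       prop_var_expl = tibble(module = mods, prop_var_expl = pve))
}

#' Module membership (kME) and intramodular connectivity (kIM)
#'
#' kME is the correlation of every feature with every module eigengene; kIM
#' is a feature's adjacency row sum restricted to its own module (excluding
#' itself), and 0 for unassigned features.
#'
#' @param x Expression tibble or matrix.
#' @param network A `mirmod_network` over the same features.
#' @param partition A `mirmod_partition` over the same features.
#' @return A list with the `kme` feature-by-module matrix and a `kim`
#'   tibble (feature_id, module, kim).
#' @export
kme_and_kim <- function(x, network, partition) {
  m <- expression_matrix(x)
  stopifnot(identical(rownames(network$adjacency), rownames(m)))
  me <- module_eigengene(x, partition)
  kme <- cor(t(m), me$eigengenes)
  rownames(kme) <- rownames(m)
  a <- network$adjacency
  diag(a) <- 0
  kim <- purrr::map2_dbl(partition$feature_id, partition$module,
    function(f, mod) {
      if (mod == 0) return(0)
      members <- setdiff(partition$feature_id[partition$module == mod], f)
      sum(a[f, members])
    })
  list(kme = kme,
       kim = tibble(feature_id = partition$feature_id,
                    module = partition$module, kim = kim))
}

#' Threshold a network's TOM into an edge list
#'
#' An edge is kept when its TOM reaches `cutoff`. Because the scale of TOM
#' values shrinks rapidly with the soft power, the cutoff can instead be set
#' adaptively as an upper `quantile` of the off-diagonal TOM distribution.
#'
#' @param network A `mirmod_network`.
#' @param cutoff Minimum TOM for an edge to be kept.
#' @param quantile If not `NULL`, overrides `cutoff` with
#'   `quantile(off-diagonal TOM, quantile)`.
#' @return A tibble of undirected edges (`from`, `to`, `weight` = TOM).
#' @export
network_edges <- function(network, cutoff = 0.1, quantile = NULL) {
  tom <- network$tom
  if (!is.null(quantile)) {
    cutoff <- stats::quantile(tom[upper.tri(tom)], quantile)
  }
  ids <- rownames(tom)
  idx <- which(upper.tri(tom) & tom >= cutoff, arr.ind = TRUE)
  tibble(from = ids[idx[, 1]], to = ids[idx[, 2]],
         weight = tom[idx])
}

#' @export
print.mirmod_network <- function(x, ...) {
  cat("Co-expression network:", nrow(x$adjacency), "features, beta =",
      x$beta, "\n")
  cat("  mean connectivity:", round(mean(x$k), 3), "\n")
  invisible(x)
}

#' @export
print.mirmod_partition <- function(x, ...) {
  sizes <- table(x$module[x$module > 0])
  cat("Module partition:", length(sizes), "modules over", nrow(x),
      "features (", sum(x$module == 0), "unassigned )\n")
  if (length(sizes)) {
    cat("  sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
  }
  invisible(x)
}
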