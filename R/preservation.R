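#' Observed module density statistics in a test dataset
#'
#' Four statistics describing how tightly a module's members co-express in
#' one dataset: mean off-diagonal member correlation (`mean_cor`), mean
#' off-diagonal unsigned adjacency at power `beta` (`mean_adj`), proportion
#' of member variance explained by the module eigengene (`prop_var_expl`),
#' and mean (sign-oriented) module membership (`mean_kme`).
#'
#' @param x_test Expression tibble or matrix in which to evaluate the module.
#' @param members Character vector of member feature ids (at least 3).
#' @param beta Soft-threshold power for the adjacency.
#' @return A named list of the four statistics.
#' @export
observed_density_stats <- function(x_test, members, beta) {
  m <- expression_matrix(x_test)
  missing <- setdiff(members, rownames(m))
  if (length(missing)) {
    abort(paste0("module members missing from the dataset: ",
                 paste(missing, collapse = ", ")))
  }
  if (length(members) < 3) abort("module must have at least 3 members")
  sub <- m[members, , drop = FALSE]
  cc <- cor(t(sub))
  off <- upper.tri(cc)
  e <- eigengene_of(sub)
  list(mean_cor = mean(cc[off]),
       mean_adj = mean(abs(cc[off])^beta),
       prop_var_expl = e$prop_var_expl,
       mean_kme = mean(e$kme))
}

#' Observed module connectivity statistics between reference and test data
#'
#' Three statistics describing whether a module's internal connectivity
#' pattern in the reference dataset persists in the test dataset:
#' `cor_kim` correlates the members' intramodular connectivities between the
#' two datasets, `cor_kme` their module memberships, and `cor_cor` the
#' vectorized upper triangles of the member correlation matrices.
#'
#' @param x_ref,x_test Expression tibbles or matrices containing all members.
#' @param members Character vector of member feature ids (at least 3).
#' @param beta Soft-threshold power for the adjacency.
#' @return A named list of the three statistics.
#' @export
observed_connectivity_stats <- function(x_ref, x_test, members, beta) {
  if (length(members) < 3) abort("module must have at least 3 members")
  one_side <- function(x) {
    m <- expression_matrix(x)
    missing <- setdiff(members, rownames(m))
    if (length(missing)) {
      abort(paste0("module members missing from the dataset: ",
                   paste(missing, collapse = ", ")))
    }
    sub <- m[members, , drop = FALSE]
    cc <- cor(t(sub))
    adj <- abs(cc)^beta
    diag(adj) <- 0
    list(cors = cc[upper.tri(cc)], kim = rowSums(adj),
         kme = eigengene_of(sub)$kme)
  }
  a <- one_side(x_ref)
  b <- one_side(x_test)
  safe_cor <- function(u, v) {
    if (sd(u) == 0 || sd(v) == 0) return(NA_real_)
    cor(u, v)
  }
  list(cor_kim = safe_cor(a$kim, b$kim),
       cor_kme = safe_cor(a$kme, b$kme),
       cor_cor = safe_cor(a$cors, b$cors))
}

#' Permutation null for one module statistic
#'
#' Draws `n_perm` pseudo-modules of the given size uniformly (without
#' replacement) from all features of the datasets, recomputes the statistic
#' for each, and standardizes an observed value against that null:
#' `Z = (observed - mean_perm) / sd_perm`. When the permutation distribution
#' is degenerate (`sd_perm == 0`), Z is 0 if the observed value equals the
#' permutation mean and flagged missing (`NA`) otherwise; it is never
#' infinite.
#'
#' @param x_ref,x_test Expression tibbles or matrices over the same features.
#' @param module_size Size of the pseudo-modules to draw.
#' @param statistic A function `(x_ref, x_test, members) -> scalar`.
#' @param observed The observed value of the statistic for the real module.
#' @param n_perm Number of permutations (at least 20).
#' @param seed Integer seed for the draws.
#' @return A list with `mean`, `sd`, `z`, `degenerate`, and the permutation
#'   values `perm`.
#' @export
permutation_null <- function(x_ref, x_test, module_size, statistic, observed,
                             n_perm = 200, seed = 1L) {
  stopifnot(n_perm >= 20)
  m_ref <- expression_matrix(x_ref)
  m_test <- expression_matrix(x_test)
  ids <- sort(rownames(m_test))
  if (module_size > length(ids)) {
    abort("module size exceeds the number of features")
  }
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      members <- sample(ids, module_size)
      statistic(m_ref, m_test, members)
    }, numeric(1))
  })
  mu <- mean(perm)
  s <- sd(perm)
  if (s == 0) {
    z <- if (isTRUE(all.equal(observed, mu))) 0 else NA_real_
    list(mean = mu, sd = s, z = z, degenerate = TRUE, perm = perm)
  } else {
    list(mean = mu, sd = s, z = (observed - mu) / s,
         degenerate = FALSE, perm = perm)
  }
}

#' Combine the seven permutation Z components into Z_summary
#'
#' `Z_density` is the median of the four density components, `Z_connectivity`
#' the median of the three connectivity components, and
#' `Z_summary = (Z_density + Z_connectivity) / 2`. A missing component
#' propagates as a missing (flagged) `Z_summary`.
#'
#' @param z Named numeric vector with elements `z_mean_cor`, `z_mean_adj`,
#'   `z_prop_var_expl`, `z_mean_kme` (density) and `z_cor_kim`, `z_cor_kme`,
#'   `z_cor_cor` (connectivity).
#' @return A list with `z_density`, `z_connectivity`, `z_summary`.
#' @export
zsummary <- function(z) {
  need <- c("z_mean_cor", "z_mean_adj", "z_prop_var_expl", "z_mean_kme",
            "z_cor_kim", "z_cor_kme", "z_cor_cor")
  stopifnot(all(need %in% names(z)))
  zd <- median(z[need[1:4]])
  zc <- median(z[need[5:7]])
  list(z_density = unname(zd), z_connectivity = unname(zc),
       z_summary = unname((zd + zc) / 2))
}

# All seven statistics from one pass over the member submatrices.
module_stats_all <- function(m_ref, m_test, members, beta) {
  sub_r <- m_ref[members, , drop = FALSE]
  sub_t <- m_test[members, , drop = FALSE]
  cc_r <- cor(t(sub_r))
  cc_t <- cor(t(sub_t))
  off <- upper.tri(cc_t)
  e_r <- eigengene_of(sub_r)
  e_t <- eigengene_of(sub_t)
  adj_r <- abs(cc_r)^beta
  adj_t <- abs(cc_t)^beta
  diag(adj_r) <- 0
  diag(adj_t) <- 0
  safe_cor <- function(u, v) {
    if (sd(u) == 0 || sd(v) == 0) return(NA_real_)
    cor(u, v)
  }
  c(mean_cor = mean(cc_t[off]),
    mean_adj = mean(adj_t[off]),
    prop_var_expl = e_t$prop_var_expl,
    mean_kme = mean(e_t$kme),
    cor_kim = safe_cor(rowSums(adj_r), rowSums(adj_t)),
    cor_kme = safe_cor(e_r$kme, e_t$kme),
    cor_cor = safe_cor(cc_r[off], cc_t[off]))
}

preservation_statistics <- function(beta) {
  list(
    mean_cor = function(r, t, mem)
      observed_density_stats(t, mem, beta)$mean_cor,
    mean_adj = function(r, t, mem)
      observed_density_stats(t, mem, beta)$mean_adj,
    prop_var_expl = function(r, t, mem)
      observed_density_stats(t, mem, beta)$prop_var_expl,
    mean_kme = function(r, t, mem)
      observed_density_stats(t, mem, beta)$mean_kme,
    cor_kim = function(r, t, mem)
      observed_connectivity_stats(r, t, mem, beta)$cor_kim,
    cor_kme = function(r, t, mem)
      observed_connectivity_stats(r, t, mem, beta)$cor_kme,
    cor_cor = function(r, t, mem)
      observed_connectivity_stats(r, t, mem, beta)$cor_cor
  )
}

#' Permutation Z_summary module preservation between two datasets
#'
#' For every reference module (size at least 3), computes the four density
#' statistics in the test dataset and the three reference-vs-test
#' connectivity statistics, standardizes each against a shared permutation
#' null of random same-size pseudo-modules, and combines them into
#' `Z_summary` (see [zsummary()]). A module is classed `strong`
#' (`Z_summary >= 10`), `preserved` (`>= 2`), `weak` (`[0, 2)`) or
#' `activated` (`< 0`, i.e. disrupted relative to the reference).
#'
#' All seven statistics are evaluated on the same pseudo-module draws, so one
#' permutation pass per module serves every component.
#'
#' @param x_ref Reference expression (the cohort whose modules are given).
#' @param x_test Test expression over the same features.
#' @param partition A `mirmod_partition` of the reference cohort.
#' @param beta Soft-threshold power fitted on the reference cohort (reused
#'   for the test data so the statistics are comparable).
#' @param n_perm Number of pseudo-module draws per module.
#' @param seed Integer seed.
#' @return A `mirmod_preservation` object whose `report` tibble has one row
#'   per scored module: size, the 7 observed statistics, the 7 Z components,
#'   `z_density`, `z_connectivity`, `z_summary`, and `class`.
#' @export
module_preservation <- function(x_ref, x_test, partition, beta,
                                n_perm = 200, seed = 1L) {
  stopifnot(n_perm >= 20)
  m_ref <- expression_matrix(x_ref)
  m_test <- expression_matrix(x_test)
  # sorted so the permutation draws do not depend on input feature order
  common <- sort(intersect(rownames(m_ref), rownames(m_test)))
  m_ref <- m_ref[common, , drop = FALSE]
  m_test <- m_test[common, , drop = FALSE]
  part <- partition[partition$feature_id %in% common, ]
  mods <- sort(unique(part$module[part$module > 0]))
  sizes <- vapply(mods, function(mm) sum(part$module == mm), integer(1))
  skip <- sizes < 3
  if (any(skip)) {
    warn(paste("skipping modules with fewer than 3 members:",
               paste(mods[skip], collapse = ", ")))
  }
  mods <- mods[!skip]
  stat_fns <- preservation_statistics(beta)
  stat_names <- names(stat_fns)

  rows <- with_seed(seed, {
    purrr::map_dfr(mods, function(mod) {
      members <- part$feature_id[part$module == mod]
      obs <- as.list(module_stats_all(m_ref, m_test, members, beta))
      perm <- matrix(NA_real_, n_perm, length(stat_fns),
                     dimnames = list(NULL, stat_names))
      for (p in seq_len(n_perm)) {
        pseudo <- sample(common, length(members))
        perm[p, ] <- module_stats_all(m_ref, m_test, pseudo,
                                      beta)[stat_names]
      }
      z <- vapply(stat_names, function(s) {
        mu <- mean(perm[, s])
        sdev <- sd(perm[, s])
        o <- obs[[s]]
        if (is.na(o) || any(is.na(perm[, s]))) return(NA_real_)
        if (sdev == 0) {
          if (isTRUE(all.equal(o, mu))) 0 else NA_real_
        } else {
          (o - mu) / sdev
        }
      }, numeric(1))
      names(z) <- paste0("z_", stat_names)
      zs <- zsummary(z)
      dplyr::bind_cols(
        tibble(module = mod, size = length(members)),
        as_tibble(as.list(unlist(obs))),
        as_tibble(as.list(z)),
        tibble(z_density = zs$z_density,
               z_connectivity = zs$z_connectivity,
               z_summary = zs$z_summary)
      )
    })
  })
  rows$class <- preservation_class(rows$z_summary)
  structure(list(report = rows, beta = beta, n_perm = n_perm, seed = seed),
            class = "mirmod_preservation")
}

preservation_class <- function(z) {
  dplyr::case_when(
    is.na(z) ~ NA_character_,
    z >= 10 ~ "strong",
    z >= 2 ~ "preserved",
    z >= 0 ~ "weak",
    TRUE ~ "activated"
  )
}

#' Classify modules across the replicate and normal comparisons
#'
#' Applies the activated-biomarker rule: a module is an activated biomarker
#' candidate when its `Z_summary` against the normal cohort is negative
#' (disrupted co-expression in controls) while its `Z_summary` against the
#' technical replicate is nonnegative (so the disruption is not a
#' reproducibility artifact).
#'
#' @param z_vs_rep,z_vs_norm Named (by module) or aligned numeric vectors of
#'   per-module `Z_summary` values from the two comparisons.
#' @param modules Optional module labels; defaults to the names of
#'   `z_vs_rep` or a sequence.
#' @return A tibble with `module`, `z_vs_rep`, `z_vs_norm`, the
#'   replicate-based `class`, and `activated_biomarker`.
#' @export
classify_modules <- function(z_vs_rep, z_vs_norm, modules = NULL) {
  stopifnot(length(z_vs_rep) == length(z_vs_norm))
  modules <- modules %||% names(z_vs_rep) %||% seq_along(z_vs_rep)
  tibble(
    module = modules,
    z_vs_rep = unname(z_vs_rep),
    z_vs_norm = unname(z_vs_norm),
    class = preservation_class(unname(z_vs_rep)),
    activated_biomarker = !is.na(z_vs_norm) & !is.na(z_vs_rep) &
      z_vs_norm < 0 & z_vs_rep >= 0
  )
}

#' @export
print.mirmod_preservation <- function(x, ...) {
  cat("Module preservation (", x$n_perm, "permutations, beta =", x$beta,
      ")\n")
  print(dplyr::select(x$report, "module", "size", "z_density",
                      "z_connectivity", "z_summary", "class"))
  invisible(x)
}
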