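#' Describe a synthetic three-cohort study design
#'
#' Defines the ground truth for a simulated miRNA expression study with a
#' disease (reference) cohort, a technical replicate of the same samples, and
#' a normal-control cohort. Features are arranged in block-correlated modules
#' generated from a one-factor Gaussian model, so the expected pairwise
#' correlation inside a module equals `rho_within`. A chosen set of modules is
#' "disrupted" in the normal cohort (each member gets its own latent factor,
#' destroying co-expression), and chosen features carry an additive mean shift
#' in the disease cohort, emulating differential expression on log-scale
#' intensities.
#'
#' The defaults emulate the study conditions this package targets: 90 disease
#' samples, a technical replicate of the same 90, 34 controls; a few hundred
#' features in modules of sizes 3-120 (mean about 20); two modules rewired in
#' controls, one of them a small four-member module whose members are mostly
#' up-shifted in disease, plus scattered up- and down-shifted features.
#'
#' @param n_features Total number of features.
#' @param module_sizes Integer sizes of the planted modules, in label order;
#'   features beyond `sum(module_sizes)` are unassigned independent noise.
#' @param rho_within Within-module correlation, a single value in `[0, 1)` or
#'   one per module.
#' @param n_ref,n_rep,n_norm Sample counts for the three cohorts.
#' @param disrupted_in_norm Integer labels of modules whose co-expression is
#'   destroyed in the normal cohort.
#' @param de_features Named numeric vector mapping feature id to the mean
#'   shift (log-units) added in the reference/replicate cohorts only. `NULL`
#'   uses the default design described above; use `numeric(0)` for none.
#' @param rep_noise_sd Standard deviation of the additive technical noise that
#'   turns the reference cohort into its replicate.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   design.
#' @return A `mirmod_design` list, validated against the design invariants.
#' @export
synthetic_design <- function(n_features = 300,
                             module_sizes = c(120, 35, 25, 20, 18, 15, 12,
                                              10, 8, 6, 5, 4, 3),
                             rho_within = 0.7,
                             n_ref = 90, n_rep = 90, n_norm = 34,
                             disrupted_in_norm = c(9, 12),
                             de_features = NULL,
                             rep_noise_sd = 0.3,
                             seed = 1L) {
  rho_within <- rep_len(rho_within, length(module_sizes))
  ids <- feature_ids(n_features)
  labels <- module_labels(n_features, module_sizes)
  if (is.null(de_features)) {
    de_features <- default_de_shifts(ids, labels, disrupted_in_norm)
  }
  design <- structure(
    list(n_features = as.integer(n_features),
         module_sizes = as.integer(module_sizes),
         rho_within = rho_within,
         n_ref = as.integer(n_ref), n_rep = as.integer(n_rep),
         n_norm = as.integer(n_norm),
         disrupted_in_norm = as.integer(disrupted_in_norm),
         de_features = de_features,
         rep_noise_sd = rep_noise_sd,
         seed = as.integer(seed)),
    class = "mirmod_design")
  validate_design(design)
  design
}

feature_ids <- function(n) sprintf("miR-%03d", seq_len(n))

module_labels <- function(n_features, module_sizes) {
  labels <- integer(n_features)
  pos <- 0L
  for (m in seq_along(module_sizes)) {
    labels[pos + seq_len(module_sizes[m])] <- m
    pos <- pos + module_sizes[m]
  }
  labels
}

# Default differential-expression design: the small disrupted module has
# three of its members up-shifted (a four-member biomarker-module analog),
# and further up/down shifts are scattered over the large modules and the
# unassigned tail so the classifier stage has a multi-module signal.
default_de_shifts <- function(ids, labels, disrupted) {
  shifts <- numeric(0)
  small_disrupted <- disrupted[which.min(tabulate(labels)[disrupted])]
  members <- ids[labels == small_disrupted]
  if (length(members) >= 4) {
    shifts <- c(shifts, setNames(c(1.0, 0.9, 0.8), members[1:3]))
  }
  take_from <- function(lab, k) {
    cand <- ids[labels == lab]
    cand <- setdiff(cand, names(shifts))
    utils::head(cand, k)
  }
  up <- c(take_from(1, 3), take_from(2, 2), take_from(11, 2))
  down <- c(take_from(1, 4)[4], take_from(3, 3), take_from(8, 2),
            utils::tail(ids[labels == 0], 2))
  down <- setdiff(down, c(up, names(shifts)))
  shifts <- c(shifts,
              setNames(rep(1.0, length(up)), up),
              setNames(rep(-1.0, length(down)), down))
  shifts
}

validate_design <- function(design) {
  d <- design
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  if (length(d$n_features) != 1 || is.na(d$n_features) || d$n_features < 1) {
    add("n_features must be a positive count")
  }
  if (any(d$module_sizes < 1)) add("all module sizes must be >= 1")
  if (sum(d$module_sizes) > d$n_features) {
    add("sum(module_sizes) must not exceed n_features")
  }
  if (any(d$rho_within < 0 | d$rho_within >= 1)) {
    add("all rho_within must lie in [0, 1)")
  }
  for (nm in c("n_ref", "n_rep", "n_norm")) {
    if (d[[nm]] < 1) add(sprintf("%s must be a positive count", nm))
  }
  if (length(d$disrupted_in_norm) &&
      (any(d$disrupted_in_norm < 1) ||
       any(d$disrupted_in_norm > length(d$module_sizes)))) {
    add("disrupted_in_norm must name existing module labels")
  }
  if (length(d$de_features)) {
    if (is.null(names(d$de_features)) || any(names(d$de_features) == "")) {
      add("de_features must be a named numeric vector")
    } else if (!all(names(d$de_features) %in% feature_ids(d$n_features))) {
      add("de_features names must be feature ids of the design")
    }
  }
  if (length(d$rep_noise_sd) != 1 || d$rep_noise_sd < 0) {
    add("rep_noise_sd must be a single nonnegative number")
  }
  if (length(d$seed) != 1 || is.na(d$seed)) add("seed must be an integer")
  if (length(problems)) {
    abort(paste0("invalid synthetic design:\n",
                 paste0("- ", problems, collapse = "\n")))
  }
  invisible(design)
}

#' Generate the three synthetic cohorts
#'
#' Draws the reference, replicate and normal expression matrices from the
#' design's one-factor block model. Inside module `m`, feature values are
#' `sqrt(rho_m) * f + sqrt(1 - rho_m) * e` with a per-sample module factor `f`
#' and independent unit noise `e`; unassigned features are pure noise. The
#' replicate cohort is the reference plus `rep_noise_sd` technical noise on
#' the same samples. In the normal cohort, disrupted modules draw an
#' independent factor per feature (co-expression destroyed, marginal variance
#' kept); differential features have their mean shift added in the reference
#' and replicate cohorts only.
#'
#' @param design A `mirmod_design` from [synthetic_design()].
#' @return A `mirmod_cohorts` list with expression tables `ref`, `rep`,
#'   `norm` (tibbles: `feature_id` plus one column per sample), the ground
#'   truth tibble `truth` (see [truth_table()]), and the `design`.
#' @export
generate_cohorts <- function(design) {
  validate_design(design)
  d <- design
  ids <- feature_ids(d$n_features)
  labels <- module_labels(d$n_features, d$module_sizes)
  n_mod <- length(d$module_sizes)

  with_seed(d$seed, {
    draw <- function(labels_use, n_samples, disrupted = integer(0)) {
      x <- matrix(0, d$n_features, n_samples)
      factors <- matrix(stats::rnorm(n_mod * n_samples), n_mod, n_samples)
      for (i in seq_len(d$n_features)) {
        m <- labels_use[i]
        eps <- stats::rnorm(n_samples)
        if (m == 0) {
          x[i, ] <- eps
        } else if (m %in% disrupted) {
          own_factor <- stats::rnorm(n_samples)
          x[i, ] <- sqrt(d$rho_within[m]) * own_factor +
            sqrt(1 - d$rho_within[m]) * eps
        } else {
          x[i, ] <- sqrt(d$rho_within[m]) * factors[m, ] +
            sqrt(1 - d$rho_within[m]) * eps
        }
      }
      x
    }
    ref <- draw(labels, d$n_ref)
    norm <- draw(labels, d$n_norm, disrupted = d$disrupted_in_norm)
    noise <- matrix(stats::rnorm(length(ref)), nrow(ref), ncol(ref))
    if (length(d$de_features)) {
      idx <- match(names(d$de_features), ids)
      ref[idx, ] <- ref[idx, ] + d$de_features
    }
    rep_mat <- ref + d$rep_noise_sd * noise
    dimnames(ref) <- list(ids, sprintf("GC_%02d", seq_len(d$n_ref)))
    dimnames(rep_mat) <- list(ids, sprintf("Rep_%02d", seq_len(d$n_rep)))
    dimnames(norm) <- list(ids, sprintf("Norm_%02d", seq_len(d$n_norm)))
    structure(
      list(ref = as_expression_tbl(ref),
           rep = as_expression_tbl(rep_mat),
           norm = as_expression_tbl(norm),
           truth = truth_table(design),
           design = design),
      class = "mirmod_cohorts")
  })
}

#' Ground-truth table for a synthetic design
#'
#' @param design A `mirmod_design`.
#' @return A tibble with one row per feature: `feature_id`, planted `module`
#'   label (0 = unassigned), `is_de`, and `module_disrupted_in_norm`.
#' @export
truth_table <- function(design) {
  validate_design(design)
  ids <- feature_ids(design$n_features)
  labels <- module_labels(design$n_features, design$module_sizes)
  tibble(
    feature_id = ids,
    module = labels,
    is_de = ids %in% names(design$de_features),
    module_disrupted_in_norm = labels %in% design$disrupted_in_norm
  )
}

#' @export
print.mirmod_cohorts <- function(x, ...) {
  d <- x$design
  cat("Synthetic miRNA cohorts:", d$n_features, "features;",
      d$n_ref, "ref /", d$n_rep, "rep /", d$n_norm, "norm samples\n")
  cat("  modules:", length(d$module_sizes),
      sprintf("(sizes %d-%d)", min(d$module_sizes), max(d$module_sizes)),
      "| disrupted in norm:",
      paste(d$disrupted_in_norm, collapse = ", "), "\n")
  cat("  differential features:", length(d$de_features), "\n")
  invisible(x)
}
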