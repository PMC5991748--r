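#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-feature weights of a network-constrained SVM fit
#'
#' @param x A `mirmod_netsvm` object.
#' @param ... Unused.
#' @return A tibble with `feature_id`, `weight`, `direction`, `rank` (by
#'   absolute weight).
#' @method tidy mirmod_netsvm
#' @export
tidy.mirmod_netsvm <- function(x, ...) {
  x$weights |>
    dplyr::arrange(dplyr::desc(abs(.data$weight)), .data$feature_id) |>
    dplyr::mutate(direction = ifelse(.data$weight >= 0, "up", "down"),
                  rank = dplyr::row_number())
}

#' @rdname tidy.mirmod_netsvm
#' @method glance mirmod_netsvm
#' @export
glance.mirmod_netsvm <- function(x, ...) {
  tibble(n_features = nrow(x$weights), bias = x$bias,
         lambda_margin = x$lambda_margin, lambda_net = x$lambda_net,
         iterations = x$iterations, converged = x$converged)
}

#' Tidy a module preservation report
#'
#' @param x A `mirmod_preservation` object.
#' @param ... Unused.
#' @return The per-module report tibble (observed statistics, Z components,
#'   `z_summary`, `class`).
#' @method tidy mirmod_preservation
#' @export
tidy.mirmod_preservation <- function(x, ...) x$report

#' @rdname tidy.mirmod_preservation
#' @method glance mirmod_preservation
#' @export
glance.mirmod_preservation <- function(x, ...) {
  tibble(n_modules = nrow(x$report), n_perm = x$n_perm, beta = x$beta,
         n_strong = sum(x$report$class == "strong", na.rm = TRUE),
         n_preserved = sum(x$report$class == "preserved", na.rm = TRUE),
         n_weak = sum(x$report$class == "weak", na.rm = TRUE),
         n_activated = sum(x$report$class == "activated", na.rm = TRUE))
}

#' Tidy an ROC result
#'
#' @param x A `mirmod_roc` object.
#' @param ... Unused.
#' @return The ROC points tibble.
#' @method tidy mirmod_roc
#' @export
tidy.mirmod_roc <- function(x, ...) x$points

#' @rdname tidy.mirmod_roc
#' @method glance mirmod_roc
#' @export
glance.mirmod_roc <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg,
         flipped = x$flipped)
}

#' Tidy a module-overlap comparison into one row per module pair
#'
#' @param x A `mirmod_overlap` object.
#' @param ... Unused.
#' @return A tibble with `module_a`, `module_b`, `overlap`, `p`,
#'   `significant`.
#' @method tidy mirmod_overlap
#' @export
tidy.mirmod_overlap <- function(x, ...) {
  if (!length(x$counts)) return(tibble())
  tibble(module_a = rep(rownames(x$counts), ncol(x$counts)),
         module_b = rep(colnames(x$counts), each = nrow(x$counts)),
         overlap = as.integer(x$counts),
         p = as.numeric(x$pvalues)) |>
    dplyr::mutate(significant = .data$p < x$alpha)
}

#' @rdname tidy.mirmod_overlap
#' @method glance mirmod_overlap
#' @export
glance.mirmod_overlap <- function(x, ...) {
  tibble(nm_a = x$nm_a, nm_b = x$nm_b, nm_overlap = x$nm_overlap,
         mcr_percent = x$mcr_percent, alpha = x$alpha,
         n_universe = x$n_universe)
}

#' Tidy a diagnostic marker result
#'
#' @param x A `mirmod_diagnostic` object.
#' @param ... Unused.
#' @return One row: `marker`, `n_members`, `weighted`, `auc`, `cutoff`,
#'   `sensitivity`, `specificity`, `youden_j`, `flipped`.
#' @method glance mirmod_diagnostic
#' @export
glance.mirmod_diagnostic <- function(x, ...) {
  dplyr::bind_cols(
    tibble(marker = x$name, n_members = length(x$members),
           weighted = !is.null(x$weights), auc = x$auc),
    x$optimal, tibble(flipped = x$flipped))
}
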