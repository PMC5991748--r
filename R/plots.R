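#' @import ggplot2
NULL

#' Plot an ROC curve
#'
#' @param object A `mirmod_roc` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mirmod_roc
#' @export
autoplot.mirmod_roc <- function(object, ...) {
  ggplot(object$points, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                color = "grey60") +
    geom_step(linewidth = 0.8, color = "firebrick") +
    labs(x = "1 - specificity", y = "Sensitivity",
         title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    coord_equal() +
    theme_minimal()
}

#' Plot Z_summary preservation against module size
#'
#' The classic preservation display: one point per module, horizontal
#' reference lines at Z = 0 (activation), 2 (preservation) and 10 (strong
#' preservation).
#'
#' @param object A `mirmod_preservation` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mirmod_preservation
#' @export
autoplot.mirmod_preservation <- function(object, ...) {
  ggplot(object$report,
         aes(x = .data$size, y = .data$z_summary, color = .data$class)) +
    geom_hline(yintercept = c(0, 2, 10),
               linetype = c("solid", "dashed", "dashed"),
               color = c("grey30", "blue", "darkgreen")) +
    geom_point(size = 2.5) +
    ggplot2::geom_text(aes(label = paste0("Mod_", .data$module)),
                       vjust = -0.8, size = 3, show.legend = FALSE) +
    scale_x_log10() +
    labs(x = "Module size", y = expression(Z[summary]),
         title = "Module preservation") +
    theme_minimal()
}

#' Heatmap of module-overlap significance between two partitions
#'
#' Tiles show -log10 of the Fisher overlap p-value, annotated with the
#' overlap counts.
#'
#' @param object A `mirmod_overlap` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mirmod_overlap
#' @export
autoplot.mirmod_overlap <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$module_b, y = .data$module_a,
                 fill = -log10(pmax(.data$p, 1e-300)))) +
    geom_tile(color = "white") +
    ggplot2::geom_text(aes(label = .data$overlap), size = 3) +
    scale_fill_gradient(low = "white", high = "red",
                        name = expression(-log[10](p))) +
    labs(x = "Partition B modules", y = "Partition A modules",
         title = sprintf("Module overlap (MCR = %.1f%%)",
                         object$mcr_percent)) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Bar chart of the top network-constrained SVM weights
#'
#' @param object A `mirmod_netsvm` object.
#' @param top_n How many features (by absolute weight) to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mirmod_netsvm
#' @export
autoplot.mirmod_netsvm <- function(object, top_n = 20, ...) {
  df <- tidy(object) |> utils::head(top_n)
  ggplot(df, aes(x = stats::reorder(.data$feature_id, .data$weight),
                 y = .data$weight, fill = .data$direction)) +
    geom_col() +
    coord_flip() +
    scale_fill_manual(values = c(up = "firebrick", down = "forestgreen")) +
    labs(x = NULL, y = "SVM weight",
         title = "Top network-constrained SVM weights") +
    theme_minimal()
}
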