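#' Per-sample (weighted) module score
#'
#' Summarizes a module's member expression into one score per sample: the
#' arithmetic mean of member values (unweighted mode), or
#' `sum(w_j * x_j) / sum(|w_j|)` when member weights are given. Normalizing
#' by the absolute weight sum keeps the denominator away from zero for
#' mixed-sign weights.
#'
#' @param x Expression tibble or matrix.
#' @param members Member feature ids, all present in `x`.
#' @param weights Optional numeric weights, one per member, not all zero.
#' @return A tibble with `sample_id` and `score`.
#' @export
module_score <- function(x, members, weights = NULL) {
  m <- expression_matrix(x)
  missing <- setdiff(members, rownames(m))
  if (length(missing)) {
    abort(paste0("members missing from expression data: ",
                 paste(missing, collapse = ", ")))
  }
  sub <- m[members, , drop = FALSE]
  if (is.null(weights)) {
    score <- colMeans(sub)
  } else {
    stopifnot(length(weights) == length(members))
    if (all(weights == 0)) abort("weights must not all be zero")
    score <- as.numeric(crossprod(weights, sub)) / sum(abs(weights))
  }
  tibble(sample_id = colnames(m), score = unname(score))
}

as_binary_labels <- function(labels, n) {
  if (is.factor(labels) || is.character(labels)) {
    f <- factor(labels)
    if (nlevels(f) != 2) abort("labels must have exactly two classes")
    labels <- as.integer(f) == 2
  } else if (is.numeric(labels)) {
    u <- sort(unique(labels))
    if (!length(u) %in% 1:2 ||
        !(all(u %in% c(0, 1)) || all(u %in% c(-1, 1)))) {
      abort("numeric labels must be 0/1 or -1/+1")
    }
    labels <- labels == max(u)
  }
  if (length(labels) != n) abort("one label per score is required")
  if (length(unique(labels)) < 2) abort("both classes must be present")
  as.logical(labels)
}

#' ROC curve and AUC for a score vector
#'
#' Thresholds at every distinct score (score >= cutoff calls a case), with
#' AUC computed by the pairwise concordance (rank) estimator, counting tied
#' case/control pairs as 1/2.
#'
#' @param scores Numeric scores, larger = more disease-like.
#' @param labels Case/control labels: logical, 0/1, -1/+1, or a two-level
#'   factor whose second level is the case class.
#' @return A `mirmod_roc` object: `points` tibble (`cutoff`, `fpr`, `tpr`,
#'   `sensitivity`, `specificity`), `auc`, `n_pos`, `n_neg`, a `flipped`
#'   flag (TRUE when AUC < 0.5, reported rather than silently inverting the
#'   orientation), and the input `scores`/`labels`.
#' @export
roc_and_auc <- function(scores, labels) {
  labels <- as_binary_labels(labels, length(scores))
  stopifnot(all(is.finite(scores)))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  cutoffs <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- purrr::map_dfr(cutoffs, function(ct) {
    pos_call <- scores >= ct
    tibble(cutoff = ct,
           tpr = sum(pos_call & labels) / n_pos,
           fpr = sum(pos_call & !labels) / n_neg)
  })
  pts$sensitivity <- pts$tpr
  pts$specificity <- 1 - pts$fpr
  r <- rank(scores)
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg,
                 flipped = auc < 0.5, scores = scores, labels = labels),
            class = "mirmod_roc")
}

#' Youden's index
#'
#' @param sensitivity,specificity Operating characteristics in `[0, 1]`.
#' @return `sensitivity + specificity - 1`.
#' @export
youden_index <- function(sensitivity, specificity) {
  sensitivity + specificity - 1
}

#' Youden-optimal operating cutoff of an ROC
#'
#' Candidate cutoffs are the midpoints between consecutive distinct scores
#' plus the two infinite endpoints; the cutoff maximizing Youden's J
#' (`sensitivity + specificity - 1`) is returned, breaking ties by higher
#' specificity, then lower cutoff.
#'
#' @param roc A `mirmod_roc` from [roc_and_auc()].
#' @return A one-row tibble: `cutoff`, `sensitivity`, `specificity`,
#'   `youden_j`.
#' @export
youden_optimal <- function(roc) {
  stopifnot(inherits(roc, "mirmod_roc"))
  s <- sort(unique(roc$scores))
  cand <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  labels <- roc$labels
  rows <- purrr::map_dfr(cand, function(ct) {
    pos_call <- roc$scores >= ct
    tibble(cutoff = ct,
           sensitivity = sum(pos_call & labels) / roc$n_pos,
           specificity = sum(!pos_call & !labels) / roc$n_neg)
  })
  rows$youden_j <- youden_index(rows$sensitivity, rows$specificity)
  rows |>
    dplyr::arrange(dplyr::desc(.data$youden_j),
                   dplyr::desc(.data$specificity), .data$cutoff) |>
    dplyr::slice(1)
}

#' Evaluate one module (or subset) as a diagnostic marker
#'
#' Scores samples with [module_score()], computes the ROC/AUC and the
#' Youden-optimal cutoff.
#'
#' @inheritParams module_score
#' @inheritParams roc_and_auc
#' @param name Marker name for reporting.
#' @return A `mirmod_diagnostic` object: `name`, `members`, `weights`,
#'   `scores` tibble, `roc`, `auc`, `optimal` (one-row tibble), `flipped`.
#' @export
evaluate_marker <- function(x, labels, members, weights = NULL,
                            name = paste(members, collapse = "+")) {
  sc <- module_score(x, members, weights)
  roc <- roc_and_auc(sc$score, labels)
  structure(list(name = name, members = members, weights = weights,
                 scores = sc, roc = roc, auc = roc$auc,
                 optimal = youden_optimal(roc), flipped = roc$flipped),
            class = "mirmod_diagnostic")
}

#' Exhaustive member-subset search for the best-performing marker
#'
#' Evaluates every subset of the module members with at least `min_size`
#' features (exhaustive enumeration; at most 12 members) and ranks the
#' subsets by AUC (descending), breaking ties lexicographically on the
#' subset.
#'
#' @inheritParams evaluate_marker
#' @param min_size Smallest subset size to evaluate.
#' @return A tibble with one row per subset: `subset`, `members` (list
#'   column), `size`, `auc`, `cutoff`, `sensitivity`, `specificity`,
#'   `youden_j`, `weighted`.
#' @export
evaluate_combinations <- function(x, labels, members, weights = NULL,
                                  min_size = 1) {
  if (length(members) > 12) {
    abort("exhaustive subset search is limited to 12 members")
  }
  if (!is.null(weights)) stopifnot(length(weights) == length(members))
  subsets <- unlist(lapply(seq(min_size, length(members)), function(k) {
    utils::combn(seq_along(members), k, simplify = FALSE)
  }), recursive = FALSE)
  rows <- purrr::map_dfr(subsets, function(idx) {
    mem <- members[idx]
    res <- evaluate_marker(x, labels, mem,
                           weights = if (!is.null(weights)) weights[idx])
    dplyr::bind_cols(tibble(subset = paste(mem, collapse = "+"),
                            members = list(mem), size = length(mem),
                            auc = res$auc),
                     res$optimal,
                     tibble(weighted = !is.null(weights)))
  })
  dplyr::arrange(rows, dplyr::desc(.data$auc), .data$subset)
}

#' @export
print.mirmod_roc <- function(x, ...) {
  cat("ROC:", x$n_pos, "cases vs", x$n_neg, "controls; AUC =",
      round(x$auc, 4), if (x$flipped) "(orientation flipped)" else "", "\n")
  invisible(x)
}

#' @export
print.mirmod_diagnostic <- function(x, ...) {
  cat("Diagnostic marker", x$name, "\n")
  cat("  AUC =", round(x$auc, 4), "| cutoff", round(x$optimal$cutoff, 4),
      "-> Se", round(x$optimal$sensitivity, 3),
      "Sp", round(x$optimal$specificity, 3),
      "J", round(x$optimal$youden_j, 3), "\n")
  invisible(x)
}
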