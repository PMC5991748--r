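#' Symmetric normalized Laplacian of a feature network
#'
#' `L = I - D^(-1/2) A D^(-1/2)` for the weighted adjacency `A` of the edge
#' list; isolated features get an identity row. Used as the smoothness
#' penalty of the network-constrained SVM, which pulls the weights of
#' connected features together.
#'
#' @param edges Tibble with columns `from`, `to` and optionally `weight`
#'   (nonnegative; defaults to 1).
#' @param features Character vector fixing node order; defaults to the nodes
#'   present in `edges`.
#' @return A symmetric positive semi-definite matrix over `features`.
#' @export
build_laplacian <- function(edges, features = NULL) {
  w <- edges[["weight"]] %||% rep(1, nrow(edges))
  if (any(w < 0)) abort("edge weights must be nonnegative")
  features <- features %||% unique(c(edges$from, edges$to))
  n <- length(features)
  a <- matrix(0, n, n, dimnames = list(features, features))
  if (nrow(edges)) {
    i <- match(edges$from, features)
    j <- match(edges$to, features)
    if (anyNA(i) || anyNA(j)) abort("edge endpoints missing from features")
    for (e in seq_along(i)) {
      a[i[e], j[e]] <- a[i[e], j[e]] + w[e]
      a[j[e], i[e]] <- a[j[e], i[e]] + w[e]
    }
  }
  d <- rowSums(a)
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  l <- diag(n) - (inv_sqrt %o% inv_sqrt) * a
  # rows of isolated nodes are identity rows already (d == 0 -> off-diag 0)
  dimnames(l) <- list(features, features)
  l
}

# Deterministic SMO solver for the dual of
#   min_w,b  mean(hinge(y * (w'x + b))) + w' M w,   M = lm*I + ln*L.
# Dual: max  sum(alpha) - 1/4 alpha' (yy' * K) alpha,  K = X' M^-1 X,
# subject to 0 <= alpha <= 1/n, sum(alpha * y) = 0.
# Maximal-violating-pair working-set selection; exact clipped line search,
# so the dual objective is non-decreasing across iterations.
smo_solve <- function(kmat, y, cbox, tol = 1e-8, max_iter = 100000L) {
  n <- length(y)
  q <- (y %o% y) * kmat / 2
  alpha <- numeric(n)
  grad <- rep(-1, n)          # gradient of 1/2 a'Qa - e'a at alpha = 0
  trace <- numeric(0)
  iter <- 0L
  converged <- FALSE
  eps_act <- 1e-12
  while (iter < max_iter) {
    iter <- iter + 1L
    minus_yg <- -y * grad
    up <- (y > 0 & alpha < cbox - eps_act) | (y < 0 & alpha > eps_act)
    low <- (y > 0 & alpha > eps_act) | (y < 0 & alpha < cbox - eps_act)
    if (!any(up) || !any(low)) break
    m_up <- max(minus_yg[up])
    m_low <- min(minus_yg[low])
    if (m_up - m_low < tol) {
      converged <- TRUE
      break
    }
    i <- which(up)[which.max(minus_yg[up])]
    j <- which(low)[which.min(minus_yg[low])]
    s <- y[i] * y[j]
    curv <- q[i, i] + q[j, j] - 2 * s * q[i, j]
    if (curv <= 1e-12) curv <- 1e-12
    step <- (-grad[i] + s * grad[j]) / curv
    # direction: alpha_i += t, alpha_j -= s * t; keep both in [0, cbox]
    t_max <- min(if (step > 0) cbox - alpha[i] else alpha[i],
                 if (s > 0) (if (step > 0) alpha[j] else cbox - alpha[j])
                 else (if (step > 0) cbox - alpha[j] else alpha[j]))
    tt <- sign(step) * min(abs(step), t_max)
    if (abs(tt) < 1e-15) {
      converged <- TRUE
      break
    }
    alpha[i] <- alpha[i] + tt
    alpha[j] <- alpha[j] - s * tt
    grad <- grad + tt * (q[, i] - s * q[, j])
    if (iter %% 10 == 0 || iter == 1) {
      trace <- c(trace, sum(alpha) - sum(alpha * (grad + 1)) / 2)
    }
  }
  minus_yg <- -y * grad
  interior <- alpha > eps_act & alpha < cbox - eps_act
  b <- if (any(interior)) {
    mean(minus_yg[interior])
  } else {
    up <- (y > 0 & alpha < cbox - eps_act) | (y < 0 & alpha > eps_act)
    low <- (y > 0 & alpha > eps_act) | (y < 0 & alpha < cbox - eps_act)
    (max(minus_yg[up]) + min(minus_yg[low])) / 2
  }
  dual <- sum(alpha) - sum(alpha * (grad + 1)) / 2
  list(alpha = alpha, b = b, iterations = iter, converged = converged,
       dual_objective = dual, trace = c(trace, dual))
}

#' Fit a network-constrained linear SVM
#'
#' Minimizes `mean(hinge(y * (w'x + b))) + lambda_margin * ||w||^2 +
#' lambda_net * w' L w` over weights `w` and bias `b`, where `L` is the
#' normalized Laplacian of the co-expression network. The Laplacian term
#' smooths the weights of connected features, so hub features of a
#' class-associated sub-network accumulate weight. Features are standardized
#' (mean 0, sd 1 across all samples) before fitting, so a positive weight
#' means higher standardized expression in the `+1` (disease) class. The
#' solver is a deterministic maximal-violating-pair dual ascent; given
#' identical inputs it returns identical weights.
#'
#' @param x Expression tibble or matrix (features x samples).
#' @param y Sample labels: numeric `+1`/`-1`, or a factor whose second level
#'   is the disease (`+1`) class.
#' @param laplacian Feature Laplacian from [build_laplacian()]; `NULL` (with
#'   `lambda_net = 0`) drops the network term.
#' @param lambda_margin Ridge penalty (must be positive).
#' @param lambda_net Network-smoothness penalty (nonnegative).
#' @param tol Dual KKT violation tolerance.
#' @param max_iter Iteration cap for the solver.
#' @return A `mirmod_netsvm` object: `weights` tibble (feature_id, weight),
#'   `bias`, `lambda_margin`, `lambda_net`, `iterations`, `converged`,
#'   `dual_trace`, plus the standardization used (`center`, `scale`).
#' @export
fit_netsvm <- function(x, y, laplacian = NULL, lambda_margin = 0.01,
                       lambda_net = 0.01, tol = 1e-8, max_iter = 100000L) {
  m <- expression_matrix(x)
  if (!all(is.finite(m))) abort("expression values must all be finite")
  y <- as_pm1(y, ncol(m))
  if (length(unique(y)) < 2) abort("both classes must be present in y")
  stopifnot(lambda_margin > 0, lambda_net >= 0)
  center <- rowMeans(m)
  scale_ <- apply(m, 1, sd)
  if (any(scale_ == 0)) abort("zero-variance feature; cannot standardize")
  z <- (m - center) / scale_
  d <- nrow(z)
  if (lambda_net > 0) {
    if (is.null(laplacian)) abort("lambda_net > 0 requires a laplacian")
    stopifnot(identical(rownames(laplacian), rownames(m)))
    mm <- lambda_margin * diag(d) + lambda_net * laplacian
  } else {
    mm <- lambda_margin * diag(d)
  }
  minv <- chol2inv(chol(mm))
  kmat <- t(z) %*% minv %*% z
  n <- ncol(z)
  fit <- smo_solve(kmat, y, cbox = 1 / n, tol = tol, max_iter = max_iter)
  w <- as.numeric(minv %*% (z %*% (fit$alpha * y))) / 2
  structure(
    list(weights = tibble(feature_id = rownames(m), weight = w),
         bias = fit$b,
         lambda_margin = lambda_margin, lambda_net = lambda_net,
         iterations = fit$iterations, converged = fit$converged,
         dual_trace = fit$trace,
         center = center, scale = scale_),
    class = "mirmod_netsvm")
}

as_pm1 <- function(y, n) {
  if (is.factor(y) || is.character(y)) {
    f <- factor(y)
    if (nlevels(f) != 2) abort("y must have exactly two classes")
    y <- ifelse(as.integer(f) == 2, 1, -1)
  }
  if (length(y) != n) abort("y must have one label per sample")
  if (!all(y %in% c(-1, 1))) abort("numeric y must be +1/-1")
  as.numeric(y)
}

#' Decision values of a fitted network-constrained SVM
#'
#' @param object A `mirmod_netsvm` fit.
#' @param x Expression tibble or matrix with the same features.
#' @param ... Unused.
#' @return Named numeric vector of `w'x + b` per sample (positive =
#'   predicted disease).
#' @export
predict.mirmod_netsvm <- function(object, x, ...) {
  m <- expression_matrix(x)
  m <- m[object$weights$feature_id, , drop = FALSE]
  z <- (m - object$center) / object$scale
  setNames(as.numeric(t(z) %*% object$weights$weight) + object$bias,
           colnames(m))
}

#' Rank features by their network-constrained SVM weight
#'
#' @param weights A `mirmod_netsvm` fit or its `weights` tibble.
#' @param k_up,k_down How many top positive / negative features to list.
#' @param k_overall Size of the merged top list by absolute weight
#'   (default `k_up`).
#' @return A list of tibbles `up` (most positive first), `down` (most
#'   negative first) and `overall` (largest `|weight|` first), each with
#'   `feature_id`, `weight`, `direction` and `rank`. Ties break by feature
#'   id.
#' @export
rank_nodes <- function(weights, k_up = 20, k_down = 20,
                       k_overall = k_up) {
  w <- if (inherits(weights, "mirmod_netsvm")) weights$weights else weights
  stopifnot(all(is.finite(w$weight)))
  w <- dplyr::mutate(w,
                     direction = ifelse(.data$weight >= 0, "up", "down"))
  up <- w |> dplyr::filter(.data$weight > 0) |>
    dplyr::arrange(dplyr::desc(.data$weight), .data$feature_id) |>
    utils::head(k_up) |> dplyr::mutate(rank = dplyr::row_number())
  down <- w |> dplyr::filter(.data$weight < 0) |>
    dplyr::arrange(.data$weight, .data$feature_id) |>
    utils::head(k_down) |> dplyr::mutate(rank = dplyr::row_number())
  overall <- w |>
    dplyr::arrange(dplyr::desc(abs(.data$weight)), .data$feature_id) |>
    utils::head(k_overall) |> dplyr::mutate(rank = dplyr::row_number())
  list(up = up, down = down, overall = overall)
}

#' Induced sub-network of the top-ranked features
#'
#' @param edges Network edge tibble (`from`, `to`, optional `weight`).
#' @param nodes Tibble of selected nodes with `feature_id` and `weight`
#'   (e.g. the `overall` table of [rank_nodes()]).
#' @param log2fc Optional named vector of log2 fold changes (disease vs
#'   control) used to annotate node direction for display; a sign
#'   disagreement with the SVM weight is flagged in `direction_conflict`.
#' @return A `mirmod_subnetwork` list with `nodes` and the induced `edges`.
#' @export
extract_subnetwork <- function(edges, nodes, log2fc = NULL) {
  sel <- nodes$feature_id
  keep <- edges$from %in% sel & edges$to %in% sel
  nodes <- dplyr::mutate(nodes,
                         direction = ifelse(.data$weight >= 0, "up", "down"))
  if (!is.null(log2fc)) {
    nodes$log2fc <- unname(log2fc[nodes$feature_id])
    nodes$direction_conflict <- !is.na(nodes$log2fc) &
      sign(nodes$log2fc) != sign(nodes$weight)
  }
  structure(list(nodes = nodes, edges = edges[keep, , drop = FALSE]),
            class = "mirmod_subnetwork")
}

#' Cross-validated performance of the network-constrained SVM
#'
#' Stratified k-fold cross-validation: per fold, the model is fitted on the
#' training samples and decision values of the held-out samples are pooled;
#' sensitivity, specificity (at decision threshold 0) and ROC AUC are
#' computed on the pooled held-out predictions. Apparent (resubstitution)
#' metrics from a fit on all samples are reported alongside, labeled as
#' such. With vector `lambda_margin`/`lambda_net`, every combination is
#' evaluated.
#'
#' @inheritParams fit_netsvm
#' @param folds Number of stratified folds (>= 2).
#' @param seed Integer seed for the fold assignment.
#' @return A tibble with one row per lambda combination: `lambda_margin`,
#'   `lambda_net`, `cv_sensitivity`, `cv_specificity`, `cv_auc`,
#'   `apparent_sensitivity`, `apparent_specificity`, `apparent_auc`.
#' @export
evaluate_classifier <- function(x, y, laplacian = NULL,
                                lambda_margin = 0.01, lambda_net = 0.01,
                                folds = 5, seed = 1L) {
  m <- expression_matrix(x)
  y <- as_pm1(y, ncol(m))
  stopifnot(folds >= 2)
  if (min(table(y)) < folds) {
    abort("each class needs at least `folds` samples for stratified CV")
  }
  fold_id <- with_seed(seed, {
    id <- integer(length(y))
    for (cls in c(-1, 1)) {
      idx <- sample(which(y == cls))
      id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    id
  })
  grid <- tidyr::expand_grid(lambda_margin = lambda_margin,
                             lambda_net = lambda_net)
  purrr::pmap_dfr(grid, function(lambda_margin, lambda_net) {
    scores <- numeric(length(y))
    for (f in seq_len(folds)) {
      train <- fold_id != f
      fit <- fit_netsvm(m[, train, drop = FALSE], y[train],
                        laplacian = laplacian,
                        lambda_margin = lambda_margin,
                        lambda_net = lambda_net)
      scores[!train] <- predict(fit, m[, !train, drop = FALSE])
    }
    fit_all <- fit_netsvm(m, y, laplacian = laplacian,
                          lambda_margin = lambda_margin,
                          lambda_net = lambda_net)
    app_scores <- predict(fit_all, m)
    metrics <- function(s) {
      c(sens = mean(s[y == 1] > 0), spec = mean(s[y == -1] <= 0),
        auc = roc_and_auc(s, y)$auc)
    }
    cv <- metrics(scores)
    ap <- metrics(app_scores)
    tibble(lambda_margin = lambda_margin, lambda_net = lambda_net,
           cv_sensitivity = unname(cv["sens"]),
           cv_specificity = unname(cv["spec"]),
           cv_auc = unname(cv["auc"]),
           apparent_sensitivity = unname(ap["sens"]),
           apparent_specificity = unname(ap["spec"]),
           apparent_auc = unname(ap["auc"]))
  })
}

#' @export
print.mirmod_netsvm <- function(x, ...) {
  cat("Network-constrained SVM:", nrow(x$weights), "features;",
      "lambda_margin =", x$lambda_margin, ", lambda_net =", x$lambda_net,
      "\n")
  cat("  iterations:", x$iterations,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' @export
print.mirmod_subnetwork <- function(x, ...) {
  cat("Sub-network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}
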