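#' @importFrom rlang abort warn %||%
#' @importFrom stats cor sd median quantile phyper p.adjust setNames prcomp
#' @import dplyr
#' @importFrom tibble tibble as_tibble is_tibble
NULL

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Convert an expression table to a feature-by-sample matrix
#'
#' Expression tables have one row per feature: a `feature_id` character column
#' followed by one numeric column per sample.
#'
#' @param x A data frame with a `feature_id` column and numeric sample columns.
#' @return A numeric matrix with feature ids as row names and sample ids as
#'   column names.
#' @export
expression_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  stopifnot(is.data.frame(x))
  if (!"feature_id" %in% names(x)) {
    abort("expression table must have a 'feature_id' column")
  }
  ids <- as.character(x$feature_id)
  if (anyDuplicated(ids)) abort("feature ids must be unique")
  m <- as.matrix(x[setdiff(names(x), "feature_id")])
  if (!is.numeric(m)) abort("sample columns must be numeric")
  rownames(m) <- ids
  m
}

# Inverse of expression_matrix().
as_expression_tbl <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  dplyr::bind_cols(tibble(feature_id = rownames(m)), as_tibble(m))
}

check_symmetric <- function(m, name = "matrix", tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort(sprintf("%s must be square", name))
  }
  if (max(abs(m - t(m))) > tol) abort(sprintf("%s must be symmetric", name))
  invisible(m)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items.
#' Used to compare detected modules against planted ground truth.
#'
#' @param a,b Integer or factor label vectors of equal length.
#' @return A single number, 1 for identical partitions (up to relabeling).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n_pairs <- comb2(length(a))
  expected <- sum_a * sum_b / n_pairs
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# Module color palette (grey is reserved for unassigned features).
module_palette <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue")
}

label_colors <- function(labels) {
  pal <- module_palette()
  lev <- sort(unique(labels[labels > 0]))
  cols <- c("0" = "grey",
            setNames(rep_len(pal, length(lev)), as.character(lev)))
  unname(cols[as.character(labels)])
}

# Shared upper-tail hypergeometric probability P(X >= overlap) for an
# overlap of two sets of sizes size_a and size_b drawn from a universe of
# size n. Used by both the module-overlap Fisher test and term enrichment.
hyper_upper_p <- function(overlap, size_a, size_b, n) {
  if (overlap > min(size_a, size_b) || size_a > n || size_b > n ||
      overlap < 0 || overlap < size_a + size_b - n) {
    abort("inconsistent counts for hypergeometric tail probability")
  }
  phyper(overlap - 1, size_a, n - size_a, size_b, lower.tail = FALSE)
}
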