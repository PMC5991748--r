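#' Read and write expression tables
#'
#' Expression CSVs have one row per feature: a first `feature_id` column and
#' one numeric column per sample, with a header row of sample ids.
#'
#' @param path File path.
#' @return `read_expression()` returns an expression tibble.
#' @export
read_expression <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "feature_id"
  x$feature_id <- as.character(x$feature_id)
  x
}

#' @rdname read_expression
#' @param x An expression tibble.
#' @export
write_expression <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' Write all cohorts and the truth table of a synthetic study
#'
#' Writes `ref.csv`, `rep.csv`, `norm.csv` and `truth.csv` under `dir`.
#'
#' @param cohorts A `mirmod_cohorts` object.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_cohorts <- function(cohorts, dir) {
  stopifnot(inherits(cohorts, "mirmod_cohorts"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("ref.csv", "rep.csv", "norm.csv", "truth.csv"))
  write_expression(cohorts$ref, paths[1])
  write_expression(cohorts$rep, paths[2])
  write_expression(cohorts$norm, paths[3])
  if (is.null(cohorts$truth)) return(invisible(paths[1:3]))
  readr::write_csv(cohorts$truth, paths[4])
  invisible(paths)
}

#' Read or write a module partition CSV (feature, label, color)
#'
#' @param path File path.
#' @return A `mirmod_partition` tibble.
#' @export
read_partition <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  new_partition(x$feature_id, x$module)
}

#' @rdname read_partition
#' @param partition A `mirmod_partition` tibble.
#' @export
write_partition <- function(partition, path) {
  readr::write_csv(as_tibble(partition), path)
  invisible(path)
}

#' Write an edge list in SIF format
#'
#' SIF rows are `source  interaction  target`, tab-separated.
#'
#' @param edges A tibble with columns `from`, `to` and optionally `weight`.
#' @param path Output path.
#' @param interaction Interaction type written in the middle column.
#' @return Invisibly, the path.
#' @export
write_sif <- function(edges, path, interaction = "coexp") {
  lines <- sprintf("%s\t%s\t%s", edges$from, interaction, edges$to)
  writeLines(lines, path)
  invisible(path)
}

#' Write an edge list as GraphML
#'
#' @param edges A tibble with columns `from`, `to` and optionally `weight`.
#' @param path Output path.
#' @param nodes Optional character vector of node names (to keep isolated
#'   nodes); defaults to the nodes present in `edges`.
#' @return Invisibly, the path.
#' @export
write_graphml <- function(edges, path, nodes = NULL) {
  vs <- nodes %||% unique(c(edges$from, edges$to))
  g <- igraph::graph_from_data_frame(as.data.frame(edges),
                                     directed = FALSE,
                                     vertices = data.frame(name = vs))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
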