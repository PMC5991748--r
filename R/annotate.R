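#' Read miRNA target predictions from local database export files
#'
#' Each export is a two-or-more-column delimited file (TSV or CSV by
#' extension) whose first two columns are the miRNA id and the target gene
#' symbol.
#'
#' @param paths Named character vector of exactly three file paths; the
#'   names identify the prediction sources.
#' @return A `mirmod_targetmap`: a named list of tibbles (`mirna`, `gene`).
#' @export
read_target_map <- function(paths) {
  if (length(paths) != 3 || is.null(names(paths))) {
    abort("exactly three named source files are required")
  }
  sources <- purrr::map(paths, function(p) {
    reader <- if (grepl("\\.csv$", p)) readr::read_csv else readr::read_tsv
    x <- reader(p, show_col_types = FALSE, progress = FALSE)
    tibble(mirna = as.character(x[[1]]), gene = as.character(x[[2]])) |>
      dplyr::filter(.data$gene != "") |>
      dplyr::distinct()
  })
  structure(sources, class = "mirmod_targetmap")
}

#' Three-way consensus target genes of a miRNA set
#'
#' A gene is a consensus target of a miRNA when all three prediction
#' sources list it; the module target set is the union of the per-miRNA
#' consensus sets with per-gene attribution. miRNAs absent from a source
#' are treated as having an empty prediction set there (and flagged), so
#' their consensus is empty.
#'
#' @param target_map A `mirmod_targetmap` (or named list of three tibbles
#'   with columns `mirna`, `gene`).
#' @param mirnas miRNA ids to query.
#' @return A list with `per_mirna` (named list of consensus gene sets),
#'   `table` (tibble `mirna`, `gene`), `union` (character vector), and
#'   `missing` (tibble `mirna`, `source` for flagged absences).
#' @export
consensus_targets <- function(target_map, mirnas) {
  stopifnot(length(target_map) == 3)
  per_source_sets <- function(mir) {
    purrr::map(target_map, function(src) src$gene[src$mirna == mir])
  }
  missing <- purrr::map_dfr(mirnas, function(mir) {
    absent <- names(target_map)[
      !purrr::map_lgl(target_map, function(src) mir %in% src$mirna)]
    if (length(absent)) tibble(mirna = mir, source = absent) else tibble()
  })
  per_mirna <- purrr::map(setNames(mirnas, mirnas), function(mir) {
    sets <- per_source_sets(mir)
    sort(purrr::reduce(sets, intersect))
  })
  tab <- purrr::imap_dfr(per_mirna, function(genes, mir) {
    if (length(genes)) tibble(mirna = mir, gene = genes) else tibble()
  })
  list(per_mirna = per_mirna, table = tab,
       union = sort(unique(tab$gene)), missing = missing)
}

#' Read a GMT gene-set file into a term annotation table
#'
#' GMT rows are `term_id <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#'
#' @param path GMT file path.
#' @param category Category label attached to every term (e.g. "GO",
#'   "pathway").
#' @return A tibble with `term_id`, `term_name`, `category`, `gene`.
#' @export
read_gmt <- function(path, category = "geneset") {
  lines <- readLines(path)
  purrr::map_dfr(lines[nzchar(lines)], function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) return(tibble())
    tibble(term_id = parts[1], term_name = parts[2], category = category,
           gene = unique(parts[-(1:2)]))
  })
}

#' Hypergeometric term enrichment with Benjamini-Hochberg adjustment
#'
#' One-sided hypergeometric (Fisher) enrichment of a query gene set against
#' every term of an annotation table, with BH adjustment applied across the
#' tested terms within each category. Both the raw and adjusted p-values are
#' reported; `significant` applies `alpha` to the column chosen by
#' `threshold_on`.
#'
#' @param query Character vector of query genes (must lie in the universe).
#' @param annotation Tibble with columns `term_id`, `gene`, and optionally
#'   `term_name` and `category`.
#' @param universe Background gene set; defaults to all genes in
#'   `annotation`.
#' @param alpha Significance level.
#' @param threshold_on `"p"` or `"p_adjusted"`: which column `significant`
#'   thresholds.
#' @param drop_zero_overlap Skip terms sharing no gene with the query.
#' @return A tibble with one row per tested term: `term_id`, `term_name`,
#'   `category`, `overlap`, `term_size`, `query_size`, `universe_size`,
#'   `p`, `p_adjusted`, `significant`, ordered by `p`.
#' @export
enrich <- function(query, annotation, universe = NULL, alpha = 0.05,
                   threshold_on = c("p", "p_adjusted"),
                   drop_zero_overlap = TRUE) {
  threshold_on <- match.arg(threshold_on)
  if (!"term_name" %in% names(annotation)) annotation$term_name <- annotation$term_id
  if (!"category" %in% names(annotation)) annotation$category <- "geneset"
  universe <- universe %||% sort(unique(annotation$gene))
  if (!length(universe)) abort("universe must not be empty")
  extra <- setdiff(query, universe)
  if (length(extra)) {
    abort(paste0("query genes outside the universe: ",
                 paste(extra, collapse = ", ")))
  }
  query <- unique(query)
  ann <- dplyr::filter(annotation, .data$gene %in% universe)
  rows <- ann |>
    dplyr::group_by(.data$term_id, .data$term_name, .data$category) |>
    dplyr::summarise(
      overlap = length(intersect(unique(.data$gene), query)),
      term_size = dplyr::n_distinct(.data$gene), .groups = "drop") |>
    dplyr::mutate(query_size = length(query),
                  universe_size = length(universe))
  if (drop_zero_overlap) rows <- dplyr::filter(rows, .data$overlap > 0)
  if (!nrow(rows)) return(dplyr::mutate(rows, p = numeric(0),
                                        p_adjusted = numeric(0),
                                        significant = logical(0)))
  rows$p <- purrr::pmap_dbl(
    rows[c("overlap", "term_size", "query_size", "universe_size")],
    function(overlap, term_size, query_size, universe_size) {
      hyper_upper_p(overlap, term_size, query_size, universe_size)
    })
  rows <- rows |>
    dplyr::group_by(.data$category) |>
    dplyr::mutate(p_adjusted = p.adjust(.data$p, method = "BH")) |>
    dplyr::ungroup()
  rows$significant <- rows[[threshold_on]] < alpha
  dplyr::arrange(rows, .data$p, .data$term_id)
}
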