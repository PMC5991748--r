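#' Default pipeline configuration for a synthetic study
#'
#' @param output_dir Directory for stage artifacts.
#' @param seed Master seed; stage seeds default to offsets of it.
#' @return A nested configuration list accepted by [validate_config()].
#' @export
default_config <- function(output_dir = tempfile("mirmod_run_"),
                           seed = 1L) {
  list(
    synthetic = list(seed = seed),
    coexpr = list(powers = 1:12, fit_cut = 0.8, min_module_size = 3,
                  deep_split = 2, tom_edge_quantile = 0.95),
    preservation = list(n_perm = 200L, seed = seed + 1L),
    netsvm = list(lambda_margin = 0.01, lambda_net = 0.01,
                  top_k = 20L, folds = 5L, seed = seed + 2L),
    diagnostics = list(weight_mode = "netsvm", min_subset_size = 1L),
    annotate = list(
      target_files = c(
        targetscan = system.file("extdata", "targets_sourceA_synthetic.tsv",
                                 package = "mirmod"),
        mirdb = system.file("extdata", "targets_sourceB_synthetic.tsv",
                            package = "mirmod"),
        mirtarbase = system.file("extdata", "targets_sourceC_synthetic.tsv",
                                 package = "mirmod")),
      annotation_file = system.file("extdata", "terms_synthetic.gmt",
                                    package = "mirmod")),
    output_dir = output_dir
  )
}

#' Validate a pipeline configuration
#'
#' Checks the full configuration document and returns every problem found
#' (not only the first). Every stage that draws random numbers must carry an
#' explicit seed.
#'
#' @param config A nested configuration list, or a path to a YAML/JSON file.
#' @return The validated config (classed `mirmod_config`); on failure an
#'   error listing all problems.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- read_config(config)
  }
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  need_num <- function(section, field, min = -Inf) {
    v <- config[[section]][[field]]
    if (is.null(v) || !is.numeric(v) || any(is.na(v))) {
      add(sprintf("%s$%s is required and must be numeric", section, field))
    } else if (any(v < min)) {
      add(sprintf("%s$%s must be >= %s", section, field, min))
    }
  }
  if (is.null(config$synthetic) && is.null(config$inputs)) {
    add("either a 'synthetic' design section or an 'inputs' section is required")
  }
  if (!is.null(config$synthetic)) {
    if (is.null(config$synthetic$seed)) {
      add("synthetic$seed is required")
    }
    design_try <- tryCatch({
      do.call(synthetic_design, config$synthetic)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(design_try)) add(design_try)
  }
  if (!is.null(config$inputs)) {
    for (f in c("ref", "rep", "norm")) {
      p <- config$inputs[[f]]
      if (is.null(p)) {
        add(sprintf("inputs$%s path is required", f))
      } else if (!file.exists(p)) {
        add(sprintf("inputs$%s does not exist: %s", f, p))
      }
    }
  }
  if (is.null(config$coexpr)) add("'coexpr' section is required")
  need_num("coexpr", "powers", min = 1)
  need_num("coexpr", "fit_cut", min = 0)
  need_num("coexpr", "min_module_size", min = 1)
  has_cut <- !is.null(config$coexpr$tom_edge_cutoff)
  has_q <- !is.null(config$coexpr$tom_edge_quantile)
  if (!has_cut && !has_q) {
    add("coexpr needs tom_edge_cutoff or tom_edge_quantile")
  }
  if (has_q) need_num("coexpr", "tom_edge_quantile", min = 0)
  if (is.null(config$preservation)) add("'preservation' section is required")
  need_num("preservation", "n_perm", min = 20)
  if (!is.null(config$preservation) && is.null(config$preservation$seed)) {
    add("preservation$seed is required")
  }
  if (is.null(config$netsvm)) add("'netsvm' section is required")
  need_num("netsvm", "lambda_margin", min = 1e-12)
  need_num("netsvm", "lambda_net", min = 0)
  need_num("netsvm", "folds", min = 2)
  need_num("netsvm", "top_k", min = 1)
  if (!is.null(config$netsvm) && is.null(config$netsvm$seed)) {
    add("netsvm$seed is required")
  }
  if (!is.null(config$annotate)) {
    for (p in c(config$annotate$target_files, config$annotate$annotation_file)) {
      if (!file.exists(p)) add(sprintf("annotate file does not exist: %s", p))
    }
  }
  if (is.null(config$output_dir)) add("output_dir is required")
  if (length(problems)) {
    abort(paste0("invalid pipeline config:\n",
                 paste0("- ", problems, collapse = "\n")))
  }
  structure(config, class = "mirmod_config")
}

read_config <- function(path) {
  if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

log_stage <- function(con, stage, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
}

#' Run the full module-biomarker pipeline
#'
#' Orchestrates all stages on one configuration: simulate (or load) the
#' three cohorts, detect co-expression modules per cohort, compare the
#' partitions (MCR), score module preservation/activation (Z_summary vs the
#' replicate and vs the normal cohort), rank miRNAs with the
#' network-constrained SVM, evaluate the activated biomarker module
#' diagnostically, and (when annotation files are configured) derive
#' consensus targets with term enrichment. Every stage writes plain-file
#' artifacts with stable names under `output_dir`, and the returned manifest
#' lists each artifact with its MD5 hash, so reruns with an identical
#' configuration are verifiably identical.
#'
#' @param config A configuration list or file path (see
#'   [validate_config()], [default_config()]).
#' @return A `mirmod_manifest` tibble (stage, file, md5) with attributes
#'   `results` (the in-memory stage results) and `elapsed` seconds.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  t0 <- Sys.time()
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(out, "pipeline_log.jsonl"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  manifest <- list()
  results <- list()
  record <- function(stage, files) {
    manifest[[stage]] <<- tibble(stage = stage, file = basename(files),
                                 md5 = unname(tools::md5sum(files)))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      rec <- list(stage = stage, error = conditionMessage(e))
      log_stage(log_con, stage, error = conditionMessage(e))
      abort(paste0("pipeline stage '", stage, "' failed: ",
                   conditionMessage(e)))
    })
  }

  # -- stage 1: cohorts ------------------------------------------------
  run_stage("simulate", {
    if (!is.null(config$synthetic)) {
      design <- do.call(synthetic_design, config$synthetic)
      cohorts <- generate_cohorts(design)
    } else {
      cohorts <- list(ref = read_expression(config$inputs$ref),
                      rep = read_expression(config$inputs$rep),
                      norm = read_expression(config$inputs$norm),
                      truth = NULL, design = NULL)
      class(cohorts) <- "mirmod_cohorts"
    }
    paths <- write_cohorts(cohorts, out)
    if (is.null(cohorts$truth)) paths <- paths[1:3]
    results$cohorts <- cohorts
    record("simulate", paths)
    log_stage(log_con, "simulate", n_features = nrow(cohorts$ref))
  })
  cohorts <- results$cohorts

  # -- stage 2: co-expression networks and modules per cohort ----------
  run_stage("coexpr", {
    cx <- config$coexpr
    files <- character(0)
    results$coexpr <- purrr::imap(
      list(ref = cohorts$ref, rep = cohorts$rep, norm = cohorts$norm),
      function(x, nm) {
        det <- detect_modules(x, powers = cx$powers, fit_cut = cx$fit_cut,
                              min_module_size = cx$min_module_size,
                              deep_split = cx$deep_split %||% 2)
        p1 <- file.path(out, paste0("modules_", nm, ".csv"))
        p2 <- file.path(out, paste0("power_scan_", nm, ".csv"))
        p3 <- file.path(out, paste0("network_", nm, ".sif"))
        p4 <- file.path(out, paste0("network_", nm, ".graphml"))
        write_partition(det$partition, p1)
        readr::write_csv(det$power_scan, p2)
        edges <- network_edges(det$network,
                               cutoff = cx$tom_edge_cutoff %||% 0.1,
                               quantile = cx$tom_edge_quantile)
        write_sif(edges, p3)
        write_graphml(edges, p4, nodes = det$partition$feature_id)
        files <<- c(files, p1, p2, p3, p4)
        log_stage(log_con, "coexpr", cohort = nm, beta = det$beta,
                  reached_cut = det$reached_cut,
                  n_modules = max(det$partition$module))
        det
      })
    record("coexpr", files)
  })

  # -- stage 3: module-overlap comparison (MCR) ------------------------
  run_stage("compare", {
    cmp <- list(
      ref_vs_rep = compare_partitions(results$coexpr$ref$partition,
                                      results$coexpr$rep$partition),
      ref_vs_norm = compare_partitions(results$coexpr$ref$partition,
                                       results$coexpr$norm$partition))
    files <- character(0)
    for (nm in names(cmp)) {
      p1 <- file.path(out, paste0("overlap_counts_", nm, ".csv"))
      p2 <- file.path(out, paste0("overlap_pvalues_", nm, ".csv"))
      utils::write.csv(cmp[[nm]]$counts, p1)
      utils::write.csv(cmp[[nm]]$pvalues, p2)
      files <- c(files, p1, p2)
    }
    p3 <- file.path(out, "mcr_summary.json")
    jsonlite::write_json(
      purrr::map(cmp, function(o) {
        list(nm_a = o$nm_a, nm_b = o$nm_b, nm_overlap = o$nm_overlap,
             mcr_percent = o$mcr_percent)
      }), p3, auto_unbox = TRUE, digits = NA)
    results$compare <- cmp
    record("compare", c(files, p3))
    log_stage(log_con, "compare",
              mcr_ref_vs_rep = cmp$ref_vs_rep$mcr_percent,
              mcr_ref_vs_norm = cmp$ref_vs_norm$mcr_percent)
  })

  # -- stage 4: Z_summary preservation and the activated module --------
  run_stage("preserve", {
    pv <- config$preservation
    beta <- results$coexpr$ref$beta
    part <- results$coexpr$ref$partition
    pres_rep <- module_preservation(cohorts$ref, cohorts$rep, part, beta,
                                    n_perm = pv$n_perm, seed = pv$seed)
    pres_norm <- module_preservation(cohorts$ref, cohorts$norm, part, beta,
                                     n_perm = pv$n_perm,
                                     seed = pv$seed + 1L)
    cls <- classify_modules(
      setNames(pres_rep$report$z_summary, pres_rep$report$module),
      setNames(pres_norm$report$z_summary, pres_norm$report$module))
    p1 <- file.path(out, "preservation_vs_rep.csv")
    p2 <- file.path(out, "preservation_vs_norm.csv")
    p3 <- file.path(out, "biomarker_modules.json")
    readr::write_csv(pres_rep$report, p1)
    readr::write_csv(pres_norm$report, p2)
    jsonlite::write_json(
      list(classification = cls,
           activated_biomarkers = cls$module[cls$activated_biomarker]),
      p3, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    results$preservation <- list(vs_rep = pres_rep, vs_norm = pres_norm,
                                  classification = cls)
    record("preserve", c(p1, p2, p3))
    log_stage(log_con, "preserve",
              activated = paste(cls$module[cls$activated_biomarker],
                                collapse = ","))
  })

  # -- stage 5: network-constrained SVM ranking ------------------------
  run_stage("netsvm", {
    nv <- config$netsvm
    x_all <- dplyr::inner_join(cohorts$ref, cohorts$norm, by = "feature_id")
    y <- c(rep(1, ncol(cohorts$ref) - 1), rep(-1, ncol(cohorts$norm) - 1))
    edges <- network_edges(results$coexpr$ref$network,
                           cutoff = config$coexpr$tom_edge_cutoff %||% 0.1,
                           quantile = config$coexpr$tom_edge_quantile)
    lap <- build_laplacian(edges, features = x_all$feature_id)
    fit <- fit_netsvm(x_all, y, laplacian = lap,
                      lambda_margin = nv$lambda_margin,
                      lambda_net = nv$lambda_net)
    ranks <- rank_nodes(fit, k_up = nv$top_k, k_down = nv$top_k,
                        k_overall = nv$top_k)
    m_ref <- expression_matrix(cohorts$ref)
    m_norm <- expression_matrix(cohorts$norm)
    lfc <- setNames(rowMeans(m_ref) - rowMeans(m_norm), rownames(m_ref))
    subnet <- extract_subnetwork(edges, ranks$overall, log2fc = lfc)
    part <- results$coexpr$ref$partition
    weights_out <- fit$weights |>
      dplyr::left_join(as_tibble(part)[c("feature_id", "module")],
                       by = "feature_id") |>
      dplyr::arrange(dplyr::desc(abs(.data$weight))) |>
      dplyr::mutate(rank = dplyr::row_number(),
                    direction = ifelse(.data$weight >= 0, "up", "down"))
    metrics <- evaluate_classifier(x_all, y, laplacian = lap,
                                   lambda_margin = nv$lambda_margin,
                                   lambda_net = nv$lambda_net,
                                   folds = nv$folds, seed = nv$seed)
    p1 <- file.path(out, "netsvm_weights.csv")
    p2 <- file.path(out, "subnetwork.sif")
    p3 <- file.path(out, "subnetwork.graphml")
    p4 <- file.path(out, "netsvm_metrics.json")
    readr::write_csv(weights_out, p1)
    write_sif(subnet$edges, p2)
    write_graphml(subnet$edges, p3, nodes = subnet$nodes$feature_id)
    jsonlite::write_json(as.list(metrics[1, ]), p4, auto_unbox = TRUE,
                         digits = NA)
    results$netsvm <- list(fit = fit, ranks = ranks, subnetwork = subnet,
                            metrics = metrics, laplacian_features = NULL)
    record("netsvm", c(p1, p2, p3, p4))
    log_stage(log_con, "netsvm", converged = fit$converged,
              cv_auc = metrics$cv_auc[1])
  })

  # -- stage 6: diagnostic evaluation of the biomarker module ----------
  run_stage("diagnose", {
    cls <- results$preservation$classification
    mods <- cls$module[cls$activated_biomarker]
    if (!length(mods)) {
      # fall back to the lowest-Z module so the stage always reports
      mods <- cls$module[which.min(cls$z_vs_norm)]
    }
    part <- results$coexpr$ref$partition
    x_all <- dplyr::inner_join(cohorts$ref, cohorts$norm, by = "feature_id")
    y <- c(rep(1, ncol(cohorts$ref) - 1), rep(-1, ncol(cohorts$norm) - 1))
    wtab <- results$netsvm$fit$weights
    files <- character(0)
    results$diagnostics <- purrr::map(setNames(mods, paste0("Mod_", mods)),
      function(mod) {
        members <- part$feature_id[part$module == as.integer(mod)]
        if (length(members) > 12) {
          keep <- wtab |>
            dplyr::filter(.data$feature_id %in% members) |>
            dplyr::arrange(dplyr::desc(abs(.data$weight)))
          members <- keep$feature_id[1:12]
        }
        w <- if (identical(config$diagnostics$weight_mode, "netsvm")) {
          wtab$weight[match(members, wtab$feature_id)]
        }
        marker <- evaluate_marker(x_all, y, members, weights = w,
                                  name = paste0("Mod_", mod))
        combos <- evaluate_combinations(
          x_all, y, members, weights = w,
          min_size = config$diagnostics$min_subset_size %||% 1)
        p1 <- file.path(out, sprintf("roc_mod_%s.csv", mod))
        p2 <- file.path(out, sprintf("diagnostics_mod_%s.csv", mod))
        readr::write_csv(marker$roc$points, p1)
        readr::write_csv(dplyr::select(combos, -"members"), p2)
        files <<- c(files, p1, p2)
        log_stage(log_con, "diagnose", module = mod, auc = marker$auc,
                  best_subset = combos$subset[1],
                  best_subset_auc = combos$auc[1])
        list(marker = marker, combinations = combos)
      })
    record("diagnose", files)
  })

  # -- stage 7: consensus targets and enrichment -----------------------
  run_stage("annotate", {
    if (is.null(config$annotate)) {
      log_stage(log_con, "annotate", skipped = TRUE)
    } else {
      tm <- read_target_map(config$annotate$target_files)
      mods <- names(results$diagnostics)
      part <- results$coexpr$ref$partition
      members <- unique(unlist(purrr::map(results$diagnostics,
                                          function(d) d$marker$members)))
      cons <- consensus_targets(tm, members)
      ann <- read_gmt(config$annotate$annotation_file)
      enr <- if (length(cons$union)) {
        enrich(intersect(cons$union, unique(ann$gene)), ann)
      } else {
        tibble()
      }
      p1 <- file.path(out, "consensus_targets.csv")
      p2 <- file.path(out, "target_network.sif")
      p3 <- file.path(out, "enrichment.csv")
      readr::write_csv(cons$table, p1)
      write_sif(tibble(from = cons$table$mirna, to = cons$table$gene), p2,
                interaction = "targets")
      readr::write_csv(enr, p3)
      results$annotate <- list(consensus = cons, enrichment = enr)
      record("annotate", c(p1, p2, p3))
      log_stage(log_con, "annotate", n_targets = length(cons$union),
                n_significant_terms = sum(enr$significant %||% logical(0)))
    }
  })

  manifest_tbl <- dplyr::bind_rows(manifest)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  p_manifest <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest_tbl, p_manifest, dataframe = "rows")
  structure(manifest_tbl, class = c("mirmod_manifest", class(manifest_tbl)),
            results = results, elapsed = elapsed, output_dir = out)
}
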