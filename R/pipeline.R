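# End-to-end orchestration: QC filter -> percent of total -> composition
# metrics -> cell means -> PLS-DA -> co-occurrence (-> DDCT), with CSV/JSON
# outputs and a reproducibility log.

#' Configuration of a pipeline run
#'
#' @param lipid_csv,meta_csv Input paths (wide signal CSV + metadata CSV);
#'   leave `NULL` to simulate instead.
#' @param ct_csv Optional CT-table CSV for the expression stage.
#' @param simulate A [sim_config()] used when no input paths are given.
#' @param out_dir Output directory (created if missing); `NULL` disables
#'   file output.
#' @param seed Master seed for the simulation stage.
#' @param lod,cov_max QC-filter thresholds.
#' @param rho_threshold Co-occurrence group threshold.
#' @param alpha Significance level.
#' @param vip_components,vip_top_k PLS-DA settings.
#' @param fold_call Expression fold-call threshold.
#' @return A `run_config` list.
#' @export
run_config <- function(lipid_csv = NULL, meta_csv = NULL, ct_csv = NULL,
                       simulate = sim_config(), out_dir = NULL, seed = 1,
                       lod = 0.00005, cov_max = 0.3, rho_threshold = 0.90,
                       alpha = 0.05, vip_components = 2, vip_top_k = 15,
                       fold_call = 1.5) {
  stopifnot(lod >= 0, cov_max > 0, rho_threshold > 0, rho_threshold <= 1,
            alpha > 0, alpha < 1, vip_components >= 1, vip_top_k >= 1,
            fold_call > 1)
  structure(
    list(lipid_csv = lipid_csv, meta_csv = meta_csv, ct_csv = ct_csv,
         simulate = simulate, out_dir = out_dir, seed = seed, lod = lod,
         cov_max = cov_max, rho_threshold = rho_threshold, alpha = alpha,
         vip_components = vip_components, vip_top_k = vip_top_k,
         fold_call = fold_call),
    class = "run_config"
  )
}

.write_stage <- function(out_dir, name, x) {
  if (is.null(out_dir)) return(invisible(NULL))
  readr::write_csv(x, file.path(out_dir, paste0(name, ".csv")))
}

#' Run the full analysis pipeline
#'
#' Stages: data input (or simulation) -> QC filtering -> percent-of-total
#' normalization -> class/species composition and unsaturation indices ->
#' per-genotype AT-vs-HT statistics -> PLS-DA with VIP ranking ->
#' co-occurrence grouping with Newick export -> (optionally) delta-delta-Ct
#' expression.  With an output directory, per-stage CSVs, the Newick tree, a
#' JSON summary, and a log (package version, configuration hash, seed) are
#' written; reruns with an identical configuration reproduce identical
#' outputs.
#'
#' @param config A [run_config()].
#' @return Invisible list with the per-stage results (`dataset`, `qc`,
#'   `percent`, `class_composition`, `species_composition`, `unsaturation`,
#'   `treatment_stats`, `plsda`, `vip_top`, `cooccurrence`, `expression`,
#'   `summary`).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  truth <- NULL
  ds <- stage("input", {
    if (!is.null(config$lipid_csv)) {
      if (!file.exists(config$lipid_csv)) {
        stop("lipid CSV not found: ", config$lipid_csv)
      }
      if (is.null(config$meta_csv) || !file.exists(config$meta_csv)) {
        stop("metadata CSV not found: ", config$meta_csv %||% "<missing>")
      }
      read_lipid_csv(config$lipid_csv, config$meta_csv)
    } else {
      sim <- simulate_study(config$simulate, seed = config$seed)
      truth <<- sim$truth
      sim$dataset
    }
  })
  qc <- stage("qc_filter",
              qc_filter(ds, lod = config$lod, cov_max = config$cov_max))
  .write_stage(out_dir, "qc_report", qc$report)
  pct <- stage("percent_of_total", percent_of_total(qc$dataset))
  classes_present <- unique(pct$analytes$class)
  comp <- stage("class_composition", class_composition(pct))
  .write_stage(out_dir, "class_composition", comp)
  spcomp <- stage("species_composition", species_composition(pct))
  .write_stage(out_dir, "species_composition", spcomp)
  unsat <- stage("unsaturation", {
    purrr::map_dfr(
      setdiff(classes_present, "SG"),
      ~ unsaturation_index_class(pct, .x)
    )
  })
  .write_stage(out_dir, "unsaturation_index", unsat)
  tstats <- stage("treatment_stats", {
    long <- tidy(pct)
    long <- long[!long$is_qc_pool, ]
    purrr::map_dfr(unique(long$analyte), function(a) {
      cm <- fit_cell_means(long[long$analyte == a, ], "value", config$alpha)
      dplyr::bind_cols(tibble::tibble(analyte = a), at_vs_ht_flags(cm))
    })
  })
  .write_stage(out_dir, "at_vs_ht_per_analyte", tstats)
  model <- stage("plsda",
                 fit_plsda(pct, n_components = config$vip_components))
  vip_top <- rank_top_k(model, config$vip_top_k)
  .write_stage(out_dir, "vip", tidy(model, "vip"))
  .write_stage(out_dir, "plsda_scores", tidy(model, "scores"))
  cooc <- stage("cooccurrence",
                cooccurrence(pct, threshold = config$rho_threshold,
                             alpha = config$alpha))
  .write_stage(out_dir, "cooccurrence_groups", tidy(cooc))
  if (!is.null(out_dir)) {
    export_newick(cooc$tree, file.path(out_dir, "cooccurrence.nwk"))
  }
  expression <- NULL
  if (!is.null(config$ct_csv)) {
    expression <- stage("expression_ddct", {
      if (!file.exists(config$ct_csv)) {
        stop("CT CSV not found: ", config$ct_csv)
      }
      ct <- readr::read_csv(config$ct_csv, show_col_types = FALSE)
      ddct_fold_change(ct, threshold = config$fold_call)
    })
    .write_stage(out_dir, "expression_folds", expression)
  }
  summary <- list(
    n_samples = sum(!pct$meta$is_qc_pool),
    n_analytes_input = ncol(ds$values),
    n_analytes_kept = ncol(pct$values),
    class_shares = comp,
    unsaturation = unsat,
    vip_top = vip_top,
    groups = cooc$groups,
    directions = table(cooc$directions$direction),
    expression = expression
  )
  if (!is.null(out_dir)) {
    cfg_for_hash <- config
    cfg_for_hash$out_dir <- NULL
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    writeLines(
      c(paste0("antherlipids version: ",
               as.character(utils::packageVersion("antherlipids"))),
        paste0("config hash: ", rlang::hash(cfg_for_hash)),
        paste0("seed: ", config$seed)),
      file.path(out_dir, "run_log.txt")
    )
  }
  invisible(list(dataset = ds, truth = truth, qc = qc, percent = pct,
                 class_composition = comp, species_composition = spcomp,
                 unsaturation = unsat, treatment_stats = tstats,
                 plsda = model, vip_top = vip_top, cooccurrence = cooc,
                 expression = expression, summary = summary))
}
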