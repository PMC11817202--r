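#' Subset a feature table by bands and parameters
#'
#' Keeps the metadata columns and the feature columns whose band and
#' Hjorth parameter fall in the requested sets, preserving canonical
#' column order.
#'
#' @param table Feature table.
#' @param bands Character vector of band labels (`NULL` keeps all).
#' @param parameters Character vector of parameter names (`NULL` keeps
#'   all).
#' @return Feature table with the reduced column set.
#' @export
subset_features <- function(table, bands = NULL, parameters = NULL) {
  fcols <- feature_columns(table)
  info <- parse_feature_names(fcols)
  keep <- rep(TRUE, length(fcols))
  if (!is.null(bands)) keep <- keep & info$band %in% bands
  if (!is.null(parameters)) keep <- keep & info$parameter %in% parameters
  if (!any(keep)) stop("no feature columns match the requested subset")
  table[, c("subject_id", "group", fcols[keep]), drop = FALSE]
}

# Build a simulation_config from a plain (e.g. YAML-decoded) list.
parse_sim_config <- function(x, seed) {
  args <- x[intersect(names(x),
                      c("n_per_group", "epochs_per_subject", "epoch_length",
                        "fs", "band_sd", "pink_background_sd", "pad_s"))]
  if (!is.null(x$effect)) {
    args$effect <- if (isFALSE(x$effect) ||
                       (!is.null(x$effect$factor) && x$effect$factor == 1)) {
      NULL
    } else {
      list(factor = x$effect$factor,
           channels = unlist(x$effect$channels),
           bands = unlist(x$effect$bands))
    }
  }
  args$seed <- if (!is.null(x$seed)) x$seed else seed
  do.call(simulation_config, args)
}

#' Run the full configured pipeline
#'
#' Executes simulate/load, preprocessing, feature extraction, and then
#' each experiment of the grid (a feature-column subset by bands and
#' parameters, evaluated with one or more classifiers), optionally
#' followed by LIME channel attribution and channel-wise Wilcoxon
#' statistics. All outputs are written under `output_dir`: the pooled
#' feature table, one JSON evaluation report per (experiment,
#' classifier), channel maps and statistics as CSV, a machine-readable
#' grid summary (CSV) plus an aligned text rendering, and a manifest
#' with the seeds used.
#'
#' The master seed is fanned out deterministically: the simulation uses
#' `seed`, classifier fits in experiment `e` use `seed + 100 * e`, and
#' LIME uses `seed + 10000 * e`, so any experiment can be re-run in
#' isolation and reproduce its results bit for bit.
#'
#' @param config Path to a YAML config file, or an equivalent nested
#'   list. Top-level fields: `seed`, `output_dir`, `input` (either
#'   `simulate: <simulation_config fields>` or `load: <EDF path list>`),
#'   `preprocessing` (`target_fs`, `broadband`, `epoch_length`), `grid`
#'   (list of experiments: `name`, `bands`, `parameters`, `classifiers`,
#'   optional `selection` (k/scheme/n_bins), optional `explain`,
#'   `stats`), `lime` (`n_samples`, `max_per_fold`), and `stats`
#'   (`unit`).
#' @param output_dir Overrides the config's output directory.
#' @return Invisibly, a `run_report` list: `features` (the pooled
#'   table), `experiments` (per-experiment list with `reports` per
#'   classifier, optional `explanations`, `maps`, `channel_stats`), and
#'   `summary` (the grid summary data.frame).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- if (!is.null(output_dir)) output_dir else {
    if (is.null(config$output_dir)) "." else config$output_dir
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message(sprintf("[hjortheeg] %s", sprintf(...)))

  # --- input ---------------------------------------------------------
  if (!is.null(config$input$simulate)) {
    sim <- parse_sim_config(config$input$simulate, seed)
    log_stage("simulate: %d + %d subjects, %d epochs x %g s @ %g Hz, seed %d",
              sim$n_per_group, sim$n_per_group, sim$epochs_per_subject,
              sim$epoch_length, sim$fs, sim$seed)
    cohort <- generate_cohort(sim)
  } else if (!is.null(config$input$load)) {
    paths <- unlist(config$input$load)
    log_stage("load: %d EDF file(s)", length(paths))
    cohort <- lapply(paths, read_edf)
  } else {
    stop("config$input needs either 'simulate' or 'load'")
  }

  # --- preprocess + features ----------------------------------------
  pp <- config$preprocessing
  target_fs <- if (is.null(pp$target_fs)) 250 else pp$target_fs
  broadband <- if (is.null(pp$broadband)) c(0.5, 45) else unlist(pp$broadband)
  epoch_length <- if (is.null(pp$epoch_length)) 4 else pp$epoch_length
  log_stage("preprocess: fs -> %g Hz, broadband %g-%g Hz, %g s epochs",
            target_fs, broadband[1], broadband[2], epoch_length)
  features <- cohort_features(cohort, target_fs = target_fs,
                              broadband = broadband,
                              epoch_length = epoch_length)
  write_feature_table(features, file.path(out_dir, "features.csv"))
  log_stage("features: %d epochs x %d feature columns", nrow(features),
            length(feature_columns(features)))
  run_pipeline_grid(config, features, out_dir)
}

# The experiment-grid half of the pipeline, entered either from
# run_pipeline() or from the staged CLI interface with a pre-computed
# feature table.
run_pipeline_grid <- function(config, features, out_dir) {
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  log_stage <- function(...) message(sprintf("[hjortheeg] %s", sprintf(...)))
  lime_cfg_raw <- config$lime
  stats_unit <- if (is.null(config$stats$unit)) "subject_mean" else config$stats$unit
  experiments <- list()
  summary_rows <- list()
  for (e in seq_along(config$grid)) {
    exp_cfg <- config$grid[[e]]
    name <- if (is.null(exp_cfg$name)) paste0("experiment", e) else exp_cfg$name
    tab <- subset_features(features, unlist(exp_cfg$bands),
                           unlist(exp_cfg$parameters))
    sel <- if (is.null(exp_cfg$selection)) selection_config() else {
      do.call(selection_config, exp_cfg$selection)
    }
    sel$k <- min(sel$k, length(feature_columns(tab)))
    clf_names <- unlist(exp_cfg$classifiers)
    if (is.null(clf_names)) clf_names <- "linear_svm"
    reports <- list()
    row <- list(experiment = name,
                bands = paste(unlist(exp_cfg$bands), collapse = "+"),
                parameters = paste(unlist(exp_cfg$parameters), collapse = "+"))
    for (ci in seq_along(clf_names)) {
      cn <- clf_names[ci]
      clf <- classifier_spec(cn, seed = seed + 100L * e)
      explain_this <- isTRUE(exp_cfg$explain) && ci == 1L
      log_stage("evaluate: %s / %s", name, cn)
      rep_ <- run_loso(tab, clf, sel, keep_models = explain_this)
      reports[[cn]] <- rep_
      write_evaluation_report(
        rep_, file.path(out_dir, sprintf("report_%s_%s.json", name, cn)))
      utils::write.csv(rep_$roc,
                       file.path(out_dir, sprintf("roc_%s_%s.csv", name, cn)),
                       row.names = FALSE)
      row[[paste0(cn, "_AC")]] <- rep_$accuracy
      row[[paste0(cn, "_SN")]] <- rep_$sensitivity
      row[[paste0(cn, "_SP")]] <- rep_$specificity
      row[[paste0(cn, "_AUC")]] <- rep_$auc
    }
    experiment <- list(name = name, reports = reports)

    if (isTRUE(exp_cfg$explain)) {
      lime_args <- lime_cfg_raw[intersect(names(lime_cfg_raw),
                                          c("n_samples", "kernel_width",
                                            "top_k", "ridge"))]
      lime_args$seed <- seed + 10000L * e
      lcfg <- do.call(lime_config, lime_args)
      mpf <- if (is.null(lime_cfg_raw$max_per_fold)) Inf else {
        lime_cfg_raw$max_per_fold
      }
      log_stage("explain: %s (LIME, %d samples/instance)", name,
                lcfg$n_samples)
      expl <- explain_evaluation(tab, reports[[1]], lcfg, max_per_fold = mpf)
      experiment$explanations <- expl
      experiment$maps <- lapply(unlist(exp_cfg$bands), function(b) {
        m <- aggregate_channel_importance(expl, b)
        write_channel_map(
          m, file.path(out_dir, sprintf("lime_map_%s_%s.csv", name, b)))
        m
      })
      names(experiment$maps) <- unlist(exp_cfg$bands)
    }
    if (!is.null(exp_cfg$stats) || isTRUE(exp_cfg$explain)) {
      params <- unlist(exp_cfg$parameters)
      experiment$channel_stats <- lapply(unlist(exp_cfg$bands), function(b) {
        cs <- wilcoxon_map(features, params[1], b, unit = stats_unit)
        utils::write.csv(
          cs, file.path(out_dir, sprintf("wilcoxon_%s_%s_%s.csv", name,
                                         params[1], b)),
          row.names = FALSE)
        cs
      })
      names(experiment$channel_stats) <- unlist(exp_cfg$bands)
    }
    experiments[[name]] <- experiment
    summary_rows[[name]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }

  # --- grid summary + manifest --------------------------------------
  summary <- if (length(summary_rows)) {
    do.call(rbind, lapply(summary_rows, function(r) {
      # pad missing columns so rbind works across heterogeneous grids
      all_cols <- unique(unlist(lapply(summary_rows, names)))
      r[setdiff(all_cols, names(r))] <- NA
      r[all_cols]
    }))
  } else data.frame()
  if (nrow(summary)) {
    utils::write.csv(summary, file.path(out_dir, "grid_summary.csv"),
                     row.names = FALSE)
    writeLines(format_grid_summary(summary),
               file.path(out_dir, "grid_summary.txt"))
  }
  manifest <- list(seed = seed,
                   generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   config = config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(structure(list(features = features, experiments = experiments,
                           summary = summary, output_dir = out_dir),
                      class = "run_report"))
}

# Aligned text rendering of the grid summary (one row per experiment,
# AC/SN/SP/AUC per classifier).
format_grid_summary <- function(summary) {
  num <- vapply(summary, is.numeric, logical(1))
  txt <- summary
  txt[num] <- lapply(summary[num], function(v) {
    ifelse(is.na(v), "", ifelse(abs(v) <= 1, sprintf("%.4f", v),
                                sprintf("%.2f", v)))
  })
  widths <- pmax(nchar(names(txt)),
                 vapply(txt, function(v) max(nchar(as.character(v)), 0L),
                        integer(1)))
  fmt_row <- function(vals) {
    paste(mapply(formatC, as.character(vals), width = widths), collapse = "  ")
  }
  c(fmt_row(names(txt)),
    paste(rep("-", sum(widths) + 2 * (length(widths) - 1)), collapse = ""),
    apply(txt, 1, fmt_row))
}
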