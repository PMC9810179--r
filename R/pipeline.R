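#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run: the cohort generator
#' settings, the preprocessing overrides, feature options, and the
#' classification setup. Fully serialisable: a run's config snapshot is
#' written beside its outputs and suffices to reproduce it.
#'
#' @param cohort A [cohort_config()].
#' @param window Smoothing window (samples) for hesitation detection.
#' @param threshold_deg Compass gate in degrees.
#' @param prominence_frac Peak-detection prominence floor.
#' @param stop_frac Hesitation stop threshold.
#' @param jerk_mode `"absolute"` or `"signed"` jerk aggregation.
#' @param correlation_filter Apply [filter_correlated()] to the feature
#'   tables (default off).
#' @param correlation_cutoff Cutoff for the correlation filter.
#' @param feature_sets,algorithms,k,nested,grid Classification setup; see
#'   [classify_trials()].
#' @param seed Master seed of the run.
#' @return A list of class `vrt_pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), window = 100,
                            threshold_deg = 80, prominence_frac = 0.05,
                            stop_frac = 0.10, jerk_mode = "absolute",
                            correlation_filter = FALSE,
                            correlation_cutoff = 0.95,
                            feature_sets = c("all", "no_end_error", "no_demographics"),
                            algorithms = c("rf", "svm", "mlp"),
                            k = 5, nested = TRUE, grid = hyper_grid(),
                            seed = 1L) {
  structure(
    list(
      cohort = cohort, window = window, threshold_deg = threshold_deg,
      prominence_frac = prominence_frac, stop_frac = stop_frac,
      jerk_mode = jerk_mode, correlation_filter = correlation_filter,
      correlation_cutoff = correlation_cutoff,
      feature_sets = feature_sets, algorithms = algorithms,
      k = k, nested = nested, grid = grid, seed = as.integer(seed)
    ),
    class = "vrt_pipeline_config"
  )
}

#' Read or write a pipeline config as YAML or JSON
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @param config A [pipeline_config()] (for writing).
#' @return `read_pipeline_config()` returns a `vrt_pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cohort <- do.call(cohort_config, c(
    raw$cohort[setdiff(names(raw$cohort), "phenotype")],
    list(phenotype = lapply(raw$cohort$phenotype %||% list(), unlist))
  ))
  grid <- do.call(hyper_grid, raw$grid %||% list())
  rest <- raw[setdiff(names(raw), c("cohort", "grid"))]
  do.call(pipeline_config, c(list(cohort = cohort, grid = grid), rest))
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  ser <- unclass(config)
  ser$cohort <- unclass(ser$cohort)
  ser$cohort$phenotype <- lapply(ser$cohort$phenotype, as.list)
  ser$grid <- unclass(ser$grid)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(ser, path)
  }
  invisible(path)
}

#' Write a cohort's streams and manifest to disk
#'
#' One CSV per trial stream (columns `t, ax, ay, az, gx, gy, gz, heading`)
#' plus a JSON manifest recording participants, reference headings,
#' ground-truth hesitations and file paths.
#'
#' @param cohort A `vrt_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "streams"), recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(cohort$trials))
  for (i in seq_len(nrow(cohort$trials))) {
    row <- cohort$trials[i, ]
    rel <- file.path(
      "streams", sprintf("%s_trial%d.csv", row$participant_id, row$trial_id)
    )
    utils::write.csv(row$stream[[1]], file.path(dir, rel), row.names = FALSE)
    paths[i] <- rel
  }
  manifest <- list(
    seed = cohort$config$seed,
    participants = cohort$participants |>
      dplyr::select("participant_id", "group", "age", "sex", "occupation"),
    trials = cohort$trials |>
      dplyr::select(-"stream") |>
      dplyr::mutate(path = paths)
  )
  jsonlite::write_json(
    manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.json` and `streams/`.
#' @return A `vrt_cohort`-shaped list (without generator config).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  trials <- tibble::as_tibble(manifest$trials)
  trials$stream <- lapply(trials$path, function(p) {
    s <- tibble::as_tibble(utils::read.csv(file.path(dir, p)))
    attr(s, "sample_period_s") <- round(stats::median(diff(s$t)), 6)
    s
  })
  trials$path <- NULL
  structure(
    list(
      participants = tibble::as_tibble(manifest$participants),
      trials = trials,
      config = list(seed = manifest$seed)
    ),
    class = "vrt_cohort"
  )
}

#' Run the whole analysis end to end
#'
#' Simulate -> preprocess -> extract -> classify -> report. All
#' intermediate artifacts are persisted in `out_dir`: the cohort manifest
#' and stream CSVs, one feature-table CSV per trial, the per-cell results
#' summary CSV, the importance matrix CSV, a config snapshot and a run
#' log. Deterministic given the config's seeds.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created; must be writable).
#' @param quiet Suppress progress messages.
#' @return The results summary (`vrt_summary`), invisibly; artifacts on
#'   disk under `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "vrt_pipeline_config"))
  if (config$cohort$n_e33 + config$cohort$n_e34 == 0) {
    stop("invalid config: cohort has no participants")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = log_path, append = TRUE)
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    log_line("stage ", name, " start")
    out <- tryCatch(expr, error = function(e) {
      log_line("stage ", name, " FAILED: ", conditionMessage(e))
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
    log_line("stage ", name, " done")
    out
  }

  write_pipeline_config(config, file.path(out_dir, "config.json"))

  cohort <- stage("simulate", generate_cohort(config$cohort))
  stage("persist-cohort", write_cohort(cohort, out_dir))

  features <- stage("extract", {
    ft <- extract_feature_table(
      cohort,
      threshold_deg = config$threshold_deg, jerk_mode = config$jerk_mode,
      window = config$window, stop_frac = config$stop_frac,
      prominence_frac = config$prominence_frac
    )
    if (config$correlation_filter) {
      ft <- filter_correlated(ft, cutoff = config$correlation_cutoff)
    }
    dir.create(file.path(out_dir, "features"), showWarnings = FALSE)
    for (tid in sort(unique(ft$trial_id))) {
      utils::write.csv(
        dplyr::filter(ft, .data$trial_id == tid),
        file.path(out_dir, "features", sprintf("trial_%d.csv", tid)),
        row.names = FALSE
      )
    }
    ft
  })

  summary <- stage("classify", classify_trials(
    features,
    feature_sets = config$feature_sets, algorithms = config$algorithms,
    k = config$k, seed = config$seed, grid = config$grid,
    nested = config$nested
  ))

  stage("report", {
    dir.create(file.path(out_dir, "results"), showWarnings = FALSE)
    utils::write.csv(
      dplyr::select(summary, -"importance"),
      file.path(out_dir, "results", "summary.csv"),
      row.names = FALSE
    )
    imp_long <- purrr::map_dfr(seq_len(nrow(summary)), function(i) {
      imp <- summary$importance[[i]]
      if (is.null(imp)) return(NULL)
      tibble::tibble(
        trial_id = summary$trial_id[i],
        feature_set = summary$feature_set[i],
        algorithm = summary$algorithm[i],
        feature = names(imp), importance = unname(imp)
      )
    })
    utils::write.csv(
      imp_long, file.path(out_dir, "results", "importance.csv"),
      row.names = FALSE
    )
  })
  log_line("run complete")
  invisible(summary)
}

#' Render a human-readable report of a completed run
#'
#' Reads the persisted artifacts of [run_pipeline()] and writes
#' `report.md`: per feature set, the best algorithm and scores per trial,
#' plus the top features by importance for the best model of each trial.
#'
#' @param run_dir Directory produced by [run_pipeline()].
#' @return Path of the written report, invisibly.
#' @export
render_report <- function(run_dir) {
  summary_path <- file.path(run_dir, "results", "summary.csv")
  imp_path <- file.path(run_dir, "results", "importance.csv")
  if (!file.exists(summary_path)) {
    stop("missing artifact: ", summary_path, " (is this a completed run?)")
  }
  s <- tibble::as_tibble(utils::read.csv(summary_path))
  lines <- c("# Vestibular rotation task: classification report", "")
  for (fs in unique(s$feature_set)) {
    lines <- c(lines, paste0("## Feature set: ", fs), "")
    lines <- c(lines, "| Trial | Best F1 | Algorithm (F1) | Best accuracy | Algorithm (accuracy) |",
               "|---|---|---|---|---|")
    sub <- dplyr::filter(s, .data$feature_set == fs)
    for (tid in sort(unique(sub$trial_id))) {
      tr <- dplyr::filter(sub, .data$trial_id == tid)
      bf <- tr[which.max(tr$mean_f1), ]
      ba <- tr[which.max(tr$mean_accuracy), ]
      lines <- c(lines, sprintf(
        "| %d | %.3f | %s | %.3f | %s |",
        tid, bf$mean_f1, toupper(bf$algorithm),
        ba$mean_accuracy, toupper(ba$algorithm)
      ))
    }
    lines <- c(lines, "")
  }
  if (file.exists(imp_path)) {
    imp <- tibble::as_tibble(utils::read.csv(imp_path))
    best <- s |>
      dplyr::filter(.data$feature_set == "all") |>
      dplyr::group_by(.data$trial_id) |>
      dplyr::slice_max(.data$mean_f1, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    lines <- c(lines, "## Top features (best model per trial, all features)", "")
    for (i in seq_len(nrow(best))) {
      sub <- imp |>
        dplyr::filter(
          .data$trial_id == best$trial_id[i],
          .data$feature_set == "all",
          .data$algorithm == best$algorithm[i]
        ) |>
        dplyr::arrange(dplyr::desc(.data$importance)) |>
        dplyr::slice_head(n = 3)
      if (nrow(sub) > 0) {
        lines <- c(lines, sprintf(
          "- Trial %d (%s): %s", best$trial_id[i], toupper(best$algorithm[i]),
          paste(sprintf("%s (%.2f)", sub$feature, sub$importance), collapse = ", ")
        ))
      }
    }
    lines <- c(lines, "")
  }
  out <- file.path(run_dir, "report.md")
  writeLines(lines, out)
  invisible(out)
}
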