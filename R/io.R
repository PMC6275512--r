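cell_table_cols <- c("cell_id", "lineage_id", "parent_id", "condition",
                     "birth_time_h", "division_time_h", "birth_length_um",
                     "division_length_um", "censored")

#' Read and validate a cell table
#'
#' The cell-table CSV schema is the pipeline's exchange format, mirroring
#' deposited single-cell data on times and lengths at birth and division:
#' columns `cell_id, lineage_id, parent_id, condition, birth_time_h,
#' division_time_h, birth_length_um, division_length_um, censored`. Censored
#' rows (movie ends before division) have empty division fields and
#' `censored = 1`. Lines starting with `#` (provenance headers) are ignored.
#'
#' @param path CSV file path.
#' @return A validated data.frame.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(cell_table_cols, names(df))
  if (length(missing))
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "))
  df <- df[, cell_table_cols]
  if (nrow(df) == 0) return(df)
  validate_cell_table(df)
  df
}

validate_cell_table <- function(df) {
  num <- c("birth_time_h", "division_time_h", "birth_length_um",
           "division_length_um")
  for (col in num) if (!is.numeric(df[[col]]) && !all(is.na(df[[col]])))
    stop("schema error: column ", col, " is not numeric")
  if (any(df$birth_length_um <= 0, na.rm = TRUE) ||
      any(df$division_length_um <= 0, na.rm = TRUE))
    stop("validation error: non-positive lengths")
  unc <- df$censored == 0
  if (any(unc & (is.na(df$division_time_h) | is.na(df$division_length_um))))
    stop("validation error: uncensored rows must have division fields")
  if (any(df$division_time_h[unc] < df$birth_time_h[unc], na.rm = TRUE))
    stop("validation error: division_time_h before birth_time_h")
  invisible(df)
}

#' Write a cell table (with provenance header)
#'
#' @param cells Cell table.
#' @param path Output CSV path.
#' @param provenance Optional named character vector written as `# key: value`
#'   comment lines.
#' @export
write_cell_table <- function(cells, path, provenance = NULL) {
  validate_cell_table(cells[, cell_table_cols])
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(sprintf("# %s: %s", names(provenance), provenance), con)
  utils::write.csv(cells[, cell_table_cols], con, row.names = FALSE, na = "")
}

#' Read / write a trace table
#'
#' Per-frame length observations: columns `cell_id, time_h, length_um`.
#'
#' @param path CSV file path.
#' @return A data.frame.
#' @export
read_trace_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(c("cell_id", "time_h", "length_um"), names(df))
  if (length(missing))
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "))
  df
}

#' @rdname read_trace_table
#' @param traces Trace table.
#' @inheritParams write_cell_table
#' @export
write_trace_table <- function(traces, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(sprintf("# %s: %s", names(provenance), provenance), con)
  utils::write.csv(traces, con, row.names = FALSE, na = "")
}

#' Read a pipeline configuration (YAML)
#'
#' Keys: `scenario` (or `scenarios`, a vector), `seed`, `out_dir`, and
#' optional blocks `sim` (fields of [sim_config()]), `params` (fields of
#' [size_control_params()]), `light` (fields of [light_profile()]),
#' `coupling` (`knot_times`, `log_values` or `"infer"`), `analysis`
#' (`coverage`, `sampler`: `n_iter`, `n_chains`).
#'
#' @param path YAML file.
#' @return A list of class `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scenarios)) cfg$scenarios <- cfg$scenario
  if (is.null(cfg$scenarios)) stop("config error: no scenario(s) given")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg$config_file <- normalizePath(path)
  structure(cfg, class = "pipeline_config")
}

write_csv_prov <- function(df, path, provenance) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(provenance), provenance), con)
  utils::write.csv(df, con, row.names = FALSE, na = "")
}

provenance_for <- function(cfg, seed) {
  hash <- if (!is.null(cfg$config_file) && file.exists(cfg$config_file)) {
    unname(tools::md5sum(cfg$config_file))
  } else {
    tf <- tempfile(); on.exit(unlink(tf))
    writeLines(deparse(unclass(cfg)), tf)
    unname(tools::md5sum(tf))
  }
  c(config_hash = hash, seed = as.character(seed),
    artifact = paste0("cyanogate ",
                      as.character(utils::packageVersion("cyanogate"))))
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> fit size control -> infer coupling -> analyze on the
#' configured scenarios. Size-control parameters are fitted on a
#' clock-deletion scenario and, if the coupling is set to `"infer"`, the
#' coupling posterior is estimated from the wild-type scenario using those
#' fitted parameters (failing with a configuration error if no clock-deletion
#' scenario or explicit parameters are available). All outputs are written
#' under `out_dir` with provenance headers; results are deterministic given
#' the seed.
#'
#' @param config A `"pipeline_config"` (see [read_pipeline_config()]) or path
#'   to one.
#' @param out_dir Output directory (overrides the config).
#' @return Invisibly, a list with the per-stage results.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- config
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  if (is.null(out_dir)) stop("config error: no out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- provenance_for(cfg, cfg$seed)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(stage, ...) {
    msg <- sprintf("[%s] %s", stage, sprintf(...))
    cat(msg, "\n", file = log_path, append = TRUE)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  params <- if (!is.null(cfg$params)) do.call(size_control_params, cfg$params)
  results <- list()

  # --- simulate ---
  datasets <- stage("simulate", {
    out <- list()
    for (i in seq_along(cfg$scenarios)) {
      sc <- cfg$scenarios[[i]]
      sim_args <- cfg$sim
      sim_args$seed <- cfg$seed + i - 1L
      conf <- do.call(default_sim_config,
                      c(list(scenario = sc), sim_args))
      ds <- generate_dataset(sc, config = conf,
                             params = if (!is.null(params)) params)
      write_cell_table(ds$cells, file.path(out_dir, paste0("cells_", sc, ".csv")),
                       provenance = prov)
      write_trace_table(ds$traces, file.path(out_dir, paste0("traces_", sc, ".csv")),
                        provenance = prov)
      logf("simulate", "%s: %d cells, seed %d", sc, nrow(ds$cells), conf$seed)
      out[[sc]] <- ds
    }
    out
  })
  results$datasets <- datasets

  # --- fit size control (per condition, on clock-deletion data) ---
  cd <- grep("clockdel", names(datasets), value = TRUE)
  fit <- NULL
  if (length(cd)) {
    fit <- stage("fit-size-control", {
      ds <- datasets[[cd[1]]]
      f <- fit_size_control(ds$cells, noise_sd = ds$config$noise_sd)
      kv <- c(a = f$estimates["a"], k = f$estimates["k"], lam = f$estimates["lam"])
      writeLines(c(sprintf("# %s: %s", names(prov), prov),
                   sprintf("%s=%.6g", c("a", "k", "lam"), f$estimates)),
                 file.path(out_dir, "size_control_fit.txt"))
      logf("fit-size-control", "%s: a=%.3f k=%.3f lam=%.3f", cd[1],
           f$estimates["a"], f$estimates["k"], f$estimates["lam"])
      f
    })
  }
  results$size_control_fit <- fit

  # --- infer coupling on WT data ---
  wt <- grep("WT", names(datasets), value = TRUE)
  infer_requested <- is.null(cfg$coupling) ||
    identical(cfg$coupling, "infer") || identical(cfg$coupling$mode, "infer")
  if (length(wt) && infer_requested) {
    if (is.null(fit) && is.null(params))
      stop("config error: coupling inference needs size-control parameters ",
           "(a clock-deletion scenario or an explicit params block)")
    results$coupling_posterior <- stage("infer-coupling", {
      ds <- datasets[[wt[1]]]
      pf <- if (!is.null(fit)) fit$params else params
      sampler <- cfg$analysis$sampler
      post <- infer_coupling(ds$cells, ds$traces, pf,
                             dawn_offset = ds$profile,
                             n_iter = sampler$n_iter %||% 4000,
                             n_chains = sampler$n_chains %||% 2,
                             seed = cfg$seed)
      write_csv_prov(
        data.frame(knot_tau_h = post$knot_times, mean_G = post$mean,
                   ci_low = post$ci_low, ci_high = post$ci_high),
        file.path(out_dir, "coupling_posterior.csv"), prov)
      logf("infer-coupling", "%s: peak at tau = %.1f h", wt[1],
           coupling_peak_time(post))
      post
    })
  }

  # --- analyze ---
  results$analysis <- stage("analyze", {
    out <- list()
    rows <- list()
    for (sc in names(datasets)) {
      ds <- datasets[[sc]]
      cl <- tryCatch(cluster_subpopulations(ds$cells, ds$profile,
                                            seed = cfg$seed),
                     error = function(e) NULL)
      reg <- regress_added_vs_birth(ds$cells)
      win <- division_time_window(ds$cells,
                                  coverage = cfg$analysis$coverage %||% 0.9,
                                  dawn_offset = ds$profile)
      rows[[sc]] <- data.frame(
        condition = sc,
        n_components = if (is.null(cl)) NA else cl$n_components,
        pooled_slope = reg$slope,
        window_lo_h = win["t_lo"], window_hi_h = win["t_hi"])
      out[[sc]] <- list(clustering = cl, regression = reg, window = win)
      if (!is.null(cl))
        write_csv_prov(cl$labels,
                       file.path(out_dir, paste0("labels_", sc, ".csv")), prov)
      logf("analyze", "%s: %s components, slope %.3f, window [%.1f, %.1f] h",
           sc, if (is.null(cl)) "NA" else cl$n_components, reg$slope,
           win["t_lo"], win["t_hi"])
    }
    write_csv_prov(do.call(rbind, rows),
                   file.path(out_dir, "analysis_summary.csv"), prov)
    out
  })
  writeLines(sprintf("%s: %s", names(prov), prov),
             file.path(out_dir, "provenance.txt"))
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
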