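# column units written as comment headers and expected on read
TS_UNITS <- c(
  day = "days since first sample",
  treatment = "label", replicate = "label",
  chl_total = "ug chl-a/L", chl_cyano = "ug chl-a/L",
  chl_green = "ug chl-a/L", chl_diatom = "ug chl-a/L",
  po4 = "ug P/L", din = "ug N/L", biovolume = "um^3/ml"
)

#' Validate a mesocosm timeseries table
#'
#' Checks the long-format schema: required columns present, numeric
#' measurement columns, non-negative concentrations, no duplicate
#' replicate x day rows, and group chlorophyll fractions summing to the
#' total when present. Violations raise errors of condition class
#' `presspulse_schema` naming the offending column.
#'
#' @param ts data.frame to validate.
#' @param required columns that must be present.
#' @return `ts`, invisibly, when valid.
#' @export
validate_timeseries <- function(ts, required = c("day", "treatment",
                                                 "replicate", "chl_total")) {
  if (!is.data.frame(ts))
    pp_stop_schema("timeseries must be a data.frame")
  missing_cols <- setdiff(required, names(ts))
  if (length(missing_cols))
    pp_stop_schema(paste0("timeseries is missing required column(s): ",
                          paste(missing_cols, collapse = ", ")))
  num_cols <- intersect(names(ts), setdiff(names(TS_UNITS),
                                           c("treatment", "replicate")))
  for (cl in num_cols) {
    if (!is.numeric(ts[[cl]]))
      pp_stop_schema(sprintf("column `%s` must be numeric", cl))
  }
  conc <- intersect(names(ts), c("chl_total", "chl_cyano", "chl_green",
                                 "chl_diatom", "po4", "din", "biovolume"))
  for (cl in conc)
    if (any(ts[[cl]] < 0, na.rm = TRUE))
      pp_stop_schema(sprintf("column `%s` contains negative concentrations", cl))
  if (anyDuplicated(ts[, c("replicate", "day")]))
    pp_stop_schema("duplicate replicate x day rows")
  frac <- c("chl_cyano", "chl_green", "chl_diatom")
  if (all(frac %in% names(ts))) {
    s <- rowSums(ts[, frac])
    bad <- abs(s - ts$chl_total) > 1e-6 * pmax(1, ts$chl_total)
    if (any(bad, na.rm = TRUE))
      pp_stop_schema("group chlorophyll fractions do not sum to chl_total")
  }
  invisible(ts)
}

#' Write a mesocosm timeseries table to CSV
#'
#' Writes a long-format timeseries as CSV with a comment header (`#` lines)
#' documenting column units. The file round-trips losslessly through
#' [read_timeseries()].
#'
#' @param timeseries table as produced by [simulate_experiment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(timeseries, path) {
  validate_timeseries(timeseries)
  units <- TS_UNITS[intersect(names(TS_UNITS), names(timeseries))]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# mesocosm timeseries, one row per replicate x day",
               sprintf("# %s: %s", names(units), units)), con)
  write.csv(format(timeseries, digits = 15, trim = TRUE, scientific = FALSE),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a mesocosm timeseries table from CSV
#'
#' Reads a long-format CSV (comment lines starting with `#` are ignored)
#' and validates the schema: required columns present and numeric, no
#' duplicate replicate x day rows, non-negative concentrations, and group
#' chlorophyll fractions summing to the total when present. Violations
#' raise errors of condition class `presspulse_schema` naming the column.
#'
#' @param path CSV file path.
#' @return Validated data.frame.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path))
    pp_stop_schema(sprintf("file not found: %s", path))
  ts <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_timeseries(ts)
  ts
}

#' Assemble and validate a pipeline configuration
#'
#' @param design an [experiment_design()] or a list of its arguments.
#' @param params a [simulation_params()] or a list of its arguments.
#' @param thresholds list of analysis thresholds: `limitation_lower`,
#'   `limitation_upper` (molar N:P band), `lookback_frac`, `final_frac`,
#'   `unrecovered_mult` (window rules).
#' @param seed integer seed overriding `params$seed` when given.
#' @param out_dir directory where [run_pipeline()] writes its artifacts.
#' @param verbose print stage progress.
#' @return Object of class `pp_config`.
#' @export
pipeline_config <- function(design = experiment_design(),
                            params = simulation_params(),
                            thresholds = list(),
                            seed = NULL,
                            out_dir = tempfile("presspulse_run_"),
                            verbose = TRUE) {
  if (!inherits(design, "pp_design")) {
    if (!is.list(design)) pp_stop_invalid("`design` must be a list or pp_design")
    design <- do.call(experiment_design, design)
  }
  if (!inherits(params, "pp_sim_params")) {
    if (!is.list(params)) pp_stop_invalid("`params` must be a list or pp_sim_params")
    params <- do.call(simulation_params, params)
  }
  th_defaults <- list(limitation_lower = 16, limitation_upper = 25,
                      lookback_frac = 0.5, final_frac = 0.25,
                      unrecovered_mult = 5, smooth_span_days = 5)
  unknown <- setdiff(names(thresholds), names(th_defaults))
  if (length(unknown))
    pp_stop_invalid(paste0("unknown threshold key(s): ",
                           paste(unknown, collapse = ", ")))
  thresholds <- utils::modifyList(th_defaults, thresholds)
  if (!is.null(seed)) {
    check_finite_scalar(seed, "seed")
    params$seed <- as.integer(seed)
  }
  structure(list(design = design, params = params, thresholds = thresholds,
                 out_dir = out_dir, verbose = isTRUE(verbose)),
            class = "pp_config")
}

#' Read a pipeline configuration from YAML
#'
#' The file may contain `design`, `params`, `thresholds`, `seed` and
#' `out_dir` blocks mirroring the arguments of [pipeline_config()].
#' Unknown top-level keys are rejected.
#'
#' @param path YAML file path.
#' @return Object of class `pp_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    pp_stop_schema(sprintf("file not found: %s", path))
  raw <- yaml::read_yaml(path)
  known <- c("design", "params", "thresholds", "seed", "out_dir", "verbose")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    pp_stop_invalid(paste0("unknown config key(s): ",
                           paste(unknown, collapse = ", ")))
  if (!is.null(raw$design$tp_targets))
    raw$design$tp_targets <- lapply(raw$design$tp_targets,
                                    function(x) if (length(x)) as.numeric(x))
  if (!is.null(raw$params$chl_fractions))
    raw$params$chl_fractions <- unlist(raw$params$chl_fractions)
  do.call(pipeline_config, raw)
}

#' Run the full press-pulse analysis pipeline
#'
#' Executes, in order: simulation (or ingestion of a provided timeseries),
#' cycle segmentation, perturbation metrics, limitation classification,
#' biovolume period averages, and effect estimation; every intermediate
#' table is written as CSV under `config$out_dir` together with a
#' machine-readable `summary.json` and a plain-text run log. Identical
#' configuration and seed give identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param timeseries optional pre-existing timeseries table (or CSV path);
#'   when given, the simulation stage is skipped.
#' @return Invisible list with all tables (`timeseries`, `windows`,
#'   `metrics`, `biovolume_periods`, `limitation`, `trends`) and the
#'   output directory.
#' @export
run_pipeline <- function(config = pipeline_config(), timeseries = NULL) {
  stopifnot(inherits(config, "pp_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (config$verbose) message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  th <- config$thresholds

  say("presspulse pipeline (seed %d)", config$params$seed)
  if (is.null(timeseries)) {
    ts <- stage("simulate",
                simulate_experiment(config$design, config$params))
    say("simulate: %d rows (%d replicates x %d sampling days)",
        nrow(ts), length(unique(ts$replicate)), length(unique(ts$day)))
  } else {
    ts <- if (is.character(timeseries)) stage("read", read_timeseries(timeseries))
          else stage("validate", validate_timeseries(timeseries))
    say("ingest: %d rows", nrow(ts))
  }
  write_timeseries(ts, file.path(config$out_dir, "timeseries.csv"))

  windows <- stage("segment", segment_experiment(
    ts, config$design, lookback_frac = th$lookback_frac,
    final_frac = th$final_frac, unrecovered_mult = th$unrecovered_mult,
    smooth_span_days = th$smooth_span_days))
  say("segment: %d response windows (%d unrecovered)",
      nrow(windows), sum(!windows$recovered))
  write.csv(windows, file.path(config$out_dir, "windows.csv"),
            row.names = FALSE)

  metrics <- stage("metrics", compute_metrics(windows, config$design))
  say("metrics: %d rows (%d degenerate)", nrow(metrics),
      sum(metrics$degenerate))
  write.csv(metrics, file.path(config$out_dir, "metrics.csv"),
            row.names = FALSE)

  limitation <- stage("limitation", {
    lt <- limitation_thresholds(th$limitation_lower, th$limitation_upper)
    ok <- ts$din > 0 & ts$po4 > 0
    cls <- rep(NA_character_, nrow(ts))
    cls[ok] <- classify_limitation(ts$din[ok], ts$po4[ok], lt)
    data.frame(day = ts$day, treatment = ts$treatment,
               replicate = ts$replicate, din = ts$din, po4 = ts$po4,
               limitation = cls)
  })
  write.csv(limitation, file.path(config$out_dir, "limitation.csv"),
            row.names = FALSE)

  biovol <- NULL
  if ("biovolume" %in% names(ts)) {
    biovol <- stage("biovolume",
                    cycle_average_biovolume(ts, config$design))
    say("biovolume: %d period averages", nrow(biovol))
    write.csv(biovol, file.path(config$out_dir, "biovolume_periods.csv"),
              row.names = FALSE)
  }

  trends <- NULL
  if (length(unique(metrics$cycle)) >= 2L &&
      length(unique(metrics$treatment)) >= 2L) {
    trends <- stage("trends", fit_metric_trends(metrics))
    write.csv(trends$effects, file.path(config$out_dir, "effects.csv"),
              row.names = FALSE)
    say("trends: %d effect rows", nrow(trends$effects))
  } else {
    say("trends: skipped (needs >= 2 cycles and >= 2 treatments)")
  }

  summary <- list(
    seed = config$params$seed,
    n_replicates = length(unique(ts$replicate)),
    n_sampling_days = length(unique(ts$day)),
    n_windows = nrow(windows),
    n_metrics = nrow(metrics),
    n_degenerate = sum(metrics$degenerate),
    n_unrecovered = sum(!windows$recovered),
    n_biovolume_periods = if (is.null(biovol)) 0L else nrow(biovol),
    limitation_counts = as.list(table(limitation$limitation)),
    effects = if (is.null(trends)) NULL else trends$effects
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))

  invisible(list(timeseries = ts, windows = windows, metrics = metrics,
                 biovolume_periods = biovol, limitation = limitation,
                 trends = trends, out_dir = config$out_dir))
}
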