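#' Read and write glycemic trace CSV files
#'
#' Traces are stored as CSV with header
#' `time_min,glucose_mg_dl,insulin_pmol_l` at the integration resolution.
#'
#' @param trace a `glycemic_trace` from [simulate_day()].
#' @param path file path.
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   a `glycemic_trace` data.frame.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace)[, c("time_min", "glucose_mg_dl",
                                            "insulin_pmol_l")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  out <- utils::read.csv(path)
  need <- c("time_min", "glucose_mg_dl", "insulin_pmol_l")
  miss <- setdiff(need, names(out))
  if (length(miss) > 0) {
    stop("trace file ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  }
  class(out) <- c("glycemic_trace", "data.frame")
  out
}

#' Write an optimization history CSV
#'
#' @param history the `history` data.frame of an [evolve_plans()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_history_csv <- function(history, path) {
  utils::write.csv(history[, c("generation", "best_fitness", "gmin", "gmax",
                               "basal_U_per_h", "prandial_U_total")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an optimizer configuration file
#'
#' The YAML file mirrors [ea_config()] field-for-field; unknown fields are
#' rejected so typos fail loudly.
#'
#' @param path YAML file path.
#' @return an [ea_config()] object.
#' @export
read_ea_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  kv <- yaml::read_yaml(path)
  known <- names(formals(ea_config))
  bad <- setdiff(names(kv), known)
  if (length(bad) > 0) {
    stop("unknown config field(s) in ", path, ": ",
         paste(bad, collapse = ", "))
  }
  do.call(ea_config, kv)
}

#' @rdname read_ea_config
#' @param cfg an [ea_config()] object.
#' @export
write_ea_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "ea_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Run provenance: one manifest per simulate/optimize run.
write_manifest <- function(dir, kind, config, seed, files) {
  manifest <- list(
    kind = kind,
    package_version = as.character(utils::packageVersion("glycopt")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    outputs = files
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Simulate a plan and write trace, metrics and manifest
#'
#' @param patient a [patient_params()] object or preset name.
#' @param plan a [new_plan()] object or path to a plan file.
#' @param out_dir output directory (created if needed).
#' @param sim a [sim_config()] object.
#' @return list with the metrics and the written file paths, invisibly.
#' @export
run_simulate <- function(patient, plan = empty_plan(), out_dir = ".",
                         sim = sim_config()) {
  if (is.character(patient)) patient <- patient_preset(patient)
  if (is.character(plan)) plan <- read_plan(plan)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trace <- simulate_day(patient, plan, sim)
  metrics <- compute_day_metrics(trace, plan)
  trace_path <- file.path(out_dir, "trace.csv")
  metrics_path <- file.path(out_dir, "metrics.json")
  write_trace_csv(trace, trace_path)
  jsonlite::write_json(
    list(g_min = metrics$g_min, g_max = metrics$g_max,
         postprandial_2h = metrics$postprandial_2h,
         preprandial = metrics$preprandial,
         basal_total_U = metrics$basal_total,
         prandial_total_U = metrics$prandial_total,
         tir = as.list(metrics$tir),
         ada = ada_compliance(metrics)),
    metrics_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(out_dir, "simulate",
                 list(patient = patient$name, sim_dt = sim$dt,
                      burnin_days = sim$burnin_days),
                 seed = NA, files = c("trace.csv", "metrics.json"))
  invisible(list(metrics = metrics, trace = trace,
                 files = c(trace_path, metrics_path)))
}

#' Run the optimizer and write history, best plan and manifest
#'
#' @param patient a [patient_params()] object or preset name.
#' @param cfg an [ea_config()] object or path to a config file.
#' @param out_dir output directory (created if needed).
#' @param weights a [fitness_weights()] object.
#' @param sim a [sim_config()] object.
#' @param verbose passed to [evolve_plans()].
#' @return the [evolve_plans()] result, invisibly.
#' @export
run_optimize <- function(patient, cfg, out_dir = ".",
                         weights = fitness_weights(), sim = sim_config(),
                         verbose = FALSE) {
  if (is.character(patient)) patient <- patient_preset(patient)
  if (is.character(cfg)) cfg <- read_ea_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- evolve_plans(patient, cfg, weights, sim, verbose = verbose,
                      checkpoint_dir = file.path(out_dir, "checkpoints"))
  write_history_csv(res$history, file.path(out_dir, "history.csv"))
  write_plan(res$best_plan, file.path(out_dir, "best_plan.yaml"))
  write_manifest(out_dir, "optimize", unclass(cfg), seed = cfg$rng_seed,
                 files = c("history.csv", "best_plan.yaml"))
  invisible(res)
}

#' Score a stored trace against a stored plan
#'
#' Reads a trace CSV and a plan file, recomputes the day metrics and ADA
#' compliance, and writes a metrics JSON plus a band-occupancy CSV
#' (`band,fraction`).
#'
#' @param trace_path path to a trace CSV.
#' @param plan_path path to a plan file.
#' @param out_dir output directory.
#' @return the metrics, invisibly.
#' @export
run_report <- function(trace_path, plan_path, out_dir = ".") {
  trace <- read_trace_csv(trace_path)
  plan <- read_plan(plan_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  metrics <- compute_day_metrics(trace, plan)
  jsonlite::write_json(
    list(g_min = metrics$g_min, g_max = metrics$g_max,
         postprandial_2h = metrics$postprandial_2h,
         preprandial = metrics$preprandial,
         basal_total_U = metrics$basal_total,
         prandial_total_U = metrics$prandial_total,
         tir = as.list(metrics$tir),
         ada = ada_compliance(metrics)),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  utils::write.csv(
    data.frame(band = names(metrics$tir),
               fraction = as.numeric(metrics$tir)),
    file.path(out_dir, "band_occupancy.csv"), row.names = FALSE,
    quote = FALSE)
  invisible(metrics)
}
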