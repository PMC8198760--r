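#' Write / read a simulation configuration file
#'
#' Flat key/value YAML document mirroring [sim_config()]; the stimulus
#' schedule is stored as parallel lists.
#'
#' @param config A `sim_config`.
#' @param path File path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns a validated `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required for config files", call. = FALSE)
  }
  validate_sim_config(config)
  x <- unclass(config)
  x$stimulus_schedule <- as.list(config$stimulus_schedule)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required for config files", call. = FALSE)
  }
  x <- yaml::read_yaml(path)
  x$stimulus_schedule <- as.data.frame(x$stimulus_schedule)
  do.call(sim_config, x)
}

write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> QC -> event detection -> mixture/threshold/crossings
#' -> aligned analyses -> fate census on one configuration, persisting every
#' intermediate as CSV under `out_dir` and returning a manifest. The pipeline
#' is a pure function of the configuration (which includes the seed):
#' reruns produce identical outputs and an identical content-hash chain.
#'
#' @param config A [sim_config()]. `n_cells` must be positive and large
#'   enough for the mixture fit (>= 50).
#' @param out_dir Output directory (created if missing).
#' @param qc A [qc_config()].
#' @param max_fpr FPR bound for the threshold estimator.
#' @return Object of class `run_manifest`: list with `config_hash`, `seed`,
#'   `stages` (data frame: stage, file, rows), `file_hashes` (content hash
#'   per output file), `threshold` (the `threshold_result`), `census`
#'   (the `fate_census`), and `timestamp`.
#' @export
run_all <- function(config, out_dir = tempfile("g1run"), qc = qc_config(),
                    max_fpr = 0.05) {
  validate_sim_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  files <- character(0)
  rows <- integer(0)
  stages <- character(0)
  add <- function(stage_name, df, fname) {
    path <- write_stage_csv(df, out_dir, fname)
    files <<- c(files, path)
    rows <<- c(rows, nrow(df))
    stages <<- c(stages, stage_name)
  }

  sim <- stage("simulate", simulate_population(config))
  add("simulate", sim$traces, "traces.csv")
  add("simulate", sim$ground_truth$cells, "ground_truth_cells.csv")
  add("simulate", sim$endpoint, "endpoint.csv")

  qcres <- stage("qc", filter_traces(sim$traces, qc))
  add("qc", qcres$traces, "traces_kept.csv")
  add("qc", qcres$report, "qc_report.csv")

  events <- stage("events", compute_events(qcres$traces))
  add("events", events$cells, "events_cells.csv")
  add("events", events$intervals, "events_intervals.csv")

  kept_ids <- unique(qcres$traces$cell_id)
  ep <- sim$endpoint[sim$endpoint$cell_id %in% kept_ids, ]
  commit <- stage("commit", {
    mix <- fit_endpoint_mixture(ep$pparg_end)
    lab <- classify_endpoint(ep$pparg_end, mix)
    ref <- reference_values(qcres$traces, config$refresh_time_h)
    thr <- estimate_threshold(ref$pparg_au, lab, max_fpr = max_fpr,
                              mixture = mix,
                              reference_time_h = config$refresh_time_h)
    crossings <- gate_crossings(
      detect_crossings(qcres$traces, thr$threshold_au, refine_kink = TRUE),
      ep$cell_id, lab)
    list(mixture = mix, threshold = thr, crossings = crossings,
         endpoint_labels = lab)
  })
  add("commit", data.frame(commit$crossings,
                           endpoint_label = commit$endpoint_labels),
      "commit.csv")
  jsonlite::write_json(
    list(threshold_au = commit$threshold$threshold_au,
         achieved_fpr = commit$threshold$achieved_fpr,
         feasible = commit$threshold$feasible,
         mixture = list(weight = commit$mixture$weight,
                        mean = commit$mixture$mean, sd = commit$mixture$sd)),
    file.path(out_dir, "threshold.json"), auto_unbox = TRUE, digits = NA)
  files <- c(files, file.path(out_dir, "threshold.json"))
  rows <- c(rows, 1L)
  stages <- c(stages, "commit")

  aligned <- stage("align", align_to_crossing(qcres$traces, commit$crossings))
  add("align", aligned$summary, "aligned_summary.csv")

  corr <- stage("correlate",
                correlation_profile(aligned, ep[, setdiff(names(ep), "pparg_end")]))
  add("correlate", corr, "correlation_profile.csv")

  gaps <- stage("gaps", mitosis_to_threshold_gaps(commit$crossings, events))
  add("gaps", gaps$gaps, "gaps.csv")
  if (!is.null(gaps$histogram)) add("gaps", gaps$histogram, "gaps_histogram.csv")

  g1s <- stage("g1stats", g1_duration_stats(events))
  add("g1stats", g1s$total, "g1_total.csv")
  add("g1stats", g1s$pairs, "g1_pairs.csv")

  expo <- stage("exposure",
                exposure_binned_commitment(commit$crossings, events))
  add("exposure", expo, "exposure_bins.csv")

  cen <- stage("census",
               census(commit$crossings, events,
                      refresh_time_h = config$refresh_time_h,
                      traces = qcres$traces,
                      threshold_au = commit$threshold$threshold_au))
  add("census", cen$fates, "fates.csv")
  add("census", cen$pparg_high, "pparg_high.csv")

  manifest <- structure(list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    stages = data.frame(stage = stages, file = basename(files), rows = rows),
    file_hashes = vapply(files, function(f) rlang::hash(readLines(f)),
                         character(1)),
    threshold = commit$threshold,
    census = cen,
    out_dir = out_dir,
    timestamp = format(Sys.time(), tz = "UTC")
  ), class = "run_manifest")
  jsonlite::write_json(
    list(config_hash = manifest$config_hash, seed = manifest$seed,
         stages = manifest$stages,
         file_hashes = as.list(manifest$file_hashes),
         timestamp = manifest$timestamp),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> seed", x$seed, "config", substr(x$config_hash, 1, 8),
      "-", nrow(x$stages), "stage outputs in", x$out_dir, "\n")
  invisible(x)
}

#' Generate canned test fixtures
#'
#' Writes small datasets used by tests and examples: a 12-cell noise-free
#' cohort with a hand-checkable phase schedule, a 500-cell default cohort, a
#' decay series, and a 3x3 stimulus-grid level table. Regeneration with the
#' same seed is byte-identical.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return Invisible character vector of written file paths.
#' @export
make_fixtures <- function(dir = tempfile("g1fix"), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  clean <- sim_config(n_cells = 12, noise_cv = 0, heterogeneity_cv = 0,
                      g1_jitter_cv = 0, sg2m_jitter_cv = 0, apc_peak_cv = 0,
                      quiescent_fraction = 0,
                      stimulus_schedule = data.frame(
                        start_h = 0, end_h = 96,
                        adipo_strength = 0, mitogen_strength = 1),
                      seed = seed)
  sim12 <- simulate_population(clean)
  paths <- c(paths, write_stage_csv(sim12$traces, dir, "cohort12_traces.csv"))
  paths <- c(paths, write_stage_csv(sim12$ground_truth$mitoses, dir,
                                    "cohort12_mitoses.csv"))

  default <- sim_config(n_cells = 500, seed = seed)
  sim500 <- simulate_population(default)
  paths <- c(paths, write_stage_csv(sim500$traces, dir, "cohort500_traces.csv"))
  paths <- c(paths, write_stage_csv(sim500$endpoint, dir,
                                    "cohort500_endpoint.csv"))

  set.seed(seed)
  decay <- simulate_decay_series(half_life_h = 1, times_h = seq(0, 4, 0.5))
  paths <- c(paths, write_stage_csv(decay, dir, "decay_series.csv"))

  grid_levels <- expand.grid(mitogen = c(0.5, 1, 2), adipogen = c(0.5, 1, 2))
  paths <- c(paths, write_stage_csv(grid_levels, dir, "grid_levels.csv"))

  invisible(paths)
}
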