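#' Configuration, trace files, trial manifests and the batch pipeline
#'
#' Reports are JSON, series are CSV, configuration is YAML; everything a
#' run produces can be regenerated from the config file and the seed.
#'
#' @name cli_io
NULL

.CONFIG_DEFAULTS <- list(
  lambda_deg_s = 9,
  fit_above_cyc_deg = 0.2,
  criterion_fraction = 0.5,
  smooth_window = 20,
  optimal_freq = 0.2,
  seed = 1L,
  stimulus = list(velocity_deg_s = 12, reversal_period_s = 6,
                  duration_s = 60, dt_s = 0.04),
  n_boot = 1000
)

.CONFIG_KEYS <- c(names(.CONFIG_DEFAULTS), "manifest", "simulate", "out_dir",
                  "geometry", "log_level")

#' Load and validate a run configuration
#'
#' Reads a YAML config, fills defaults (lambda = 9 deg/s, fitting cutoff
#' 0.2 cyc/deg, 50% acuity criterion, 20-frame feedback window, standard
#' 12 deg/s / 6 s / 60 s protocol) and validates ranges. Unknown keys and
#' out-of-range values are rejected.
#'
#' @param path YAML file path, or a named list to validate directly.
#' @return validated config list of class `run_config`.
#' @export
load_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else if (is.list(path)) path else stop("path must be a file or a list")
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  for (k in names(.CONFIG_DEFAULTS))
    if (is.null(cfg[[k]])) cfg[[k]] <- .CONFIG_DEFAULTS[[k]]
  for (k in names(.CONFIG_DEFAULTS$stimulus))
    if (is.null(cfg$stimulus[[k]])) cfg$stimulus[[k]] <- .CONFIG_DEFAULTS$stimulus[[k]]
  if (!(cfg$lambda_deg_s > 0)) stop("lambda_deg_s must be > 0")
  if (cfg$fit_above_cyc_deg < 0) stop("fit_above_cyc_deg must be >= 0")
  if (!(cfg$criterion_fraction > 0 && cfg$criterion_fraction < 1))
    stop("criterion_fraction must be in (0, 1)")
  if (cfg$smooth_window < 1) stop("smooth_window must be >= 1")
  if (cfg$stimulus$velocity_deg_s < 0) stop("stimulus velocity must be >= 0")
  if (!is.null(cfg$manifest) && !file.exists(cfg$manifest))
    stop("manifest file not found: ", cfg$manifest)
  if (!is.null(cfg$geometry) && is.character(cfg$geometry) &&
      !file.exists(cfg$geometry))
    stop("geometry file not found: ", cfg$geometry)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = c("run_config", "list"))
}

#' @rdname load_config
#' @param config a config list.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(x)
    if (inherits(x, "list")) unclass(x) else x), path)
  invisible(path)
}

#' Write / read trace CSV files
#'
#' Traces are plain CSV with a `time_s` column plus any further sample
#' columns (gaze-trace files carry `cog_x..gaze_deg, valid`; simulated
#' traces carry `head_angle_deg, stim_angle_deg, srb_truth`). All fields,
#' including logical validity flags, round-trip losslessly.
#'
#' @param trace a data frame with a `time_s` column.
#' @param path CSV file path.
#' @return `read_trace` returns the data frame; malformed rows are
#'   reported with their line numbers.
#' @export
write_trace <- function(trace, path) {
  stopifnot(is.data.frame(trace), "time_s" %in% names(trace))
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || !nzchar(lines[1]))
    stop("empty trace file: ", path)
  header <- strsplit(lines[1], ",")[[1]]
  if (!"time_s" %in% gsub('"', "", header))
    stop("trace file lacks a time_s column: ", path)
  nfield <- length(header)
  bad <- which(vapply(strsplit(lines[-1], ",", fixed = TRUE), length, 1L)
               != nfield)
  if (length(bad))
    stop("malformed trace rows (wrong field count) at line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "), " of ", path)
  x <- utils::read.csv(path)
  if (nrow(x) && any(diff(x$time_s) <= 0))
    stop("time_s must be strictly increasing in ", path)
  x
}

#' Read a trial manifest
#'
#' One row per trial: `animal_id, trial_id, spatial_freq_cyc_deg,
#' condition, trace_path`, with `condition` either `moving` or `null`.
#' Relative trace paths resolve against the manifest's directory.
#'
#' @param path manifest CSV path.
#' @param check_paths verify that every trace file exists.
#' @return data frame with absolute `trace_path`s.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "trial_id", "spatial_freq_cyc_deg", "condition",
            "trace_path")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("manifest missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(m$condition %in% c("moving", "null")))
    stop("manifest condition must be 'moving' or 'null'")
  if (any(m$spatial_freq_cyc_deg[m$condition == "moving"] <= 0))
    stop("spatial frequencies of moving trials must be positive")
  base <- dirname(normalizePath(path))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", m$trace_path), m$trace_path,
                file.path(base, m$trace_path))
  if (check_paths && !all(file.exists(abs)))
    stop("manifest references missing trace files: ",
         paste(utils::head(abs[!file.exists(abs)], 3), collapse = ", "))
  m$trace_path <- abs
  m
}

# stimulus angle of the standard linear-reversal protocol at given times
.reference_stim_angle <- function(times, velocity, period) {
  k <- floor(times / period)
  dir <- (-1)^k
  velocity * period * (k %% 2) + dir * velocity * (times - k * period)
}

#' Simulate a full acuity experiment
#'
#' Generates, per animal, `n_trials` simulated traces at each spatial
#' frequency (plus `n_null` null-condition traces), with per-frequency
#' tracking probability following a known logistic
#' `p(f) = p_max / (1 + exp((f - true_b) / true_c))`. This is the
#' ground-truth generator used to validate the analysis pipeline: the
#' recovered acuity can be compared against `true_b`.
#'
#' @param n_animals,n_trials,n_null cohort sizes (defaults: 6 animals,
#'   10 trials per frequency, 10 null trials, as in a standard
#'   experiment).
#' @param frequencies spatial frequencies tested (default: the standard
#'   12-frequency staircase 0.0125..0.6 cyc/deg).
#' @param p_max asymptotic per-epoch tracking probability.
#' @param true_b,true_c logistic truth for `p(f)`.
#' @param tracking_noise_sd,idle_velocity_sd see [behavior_model()].
#' @param protocol rotation protocol for moving trials (default: the
#'   standard 12 deg/s, 6 s reversal, 60 s protocol at 25 samples/s).
#' @param seed master seed; all per-trial seeds derive from it.
#' @return list with `trials` (data frame `animal_id, trial_id,
#'   spatial_freq_cyc_deg, condition`) and `traces` (list of simulated
#'   trace data frames, parallel to `trials` rows).
#' @export
simulate_experiment <- function(n_animals = 6, n_trials = 10, n_null = 10,
                                frequencies = c(0.0125, 0.025, 0.05, 0.1,
                                                0.2, 0.3, 0.4, 0.425, 0.45,
                                                0.475, 0.5, 0.6),
                                p_max = 0.25, true_b = 0.40, true_c = 0.03,
                                tracking_noise_sd = 4, idle_velocity_sd = 6,
                                protocol = make_rotation_protocol(),
                                seed = 1L) {
  null_protocol <- make_rotation_protocol(
    velocity_deg_s = 0,
    reversal_period_s = attr(protocol, "reversal_period_s") %||% 6,
    duration_s = attr(protocol, "duration_s") %||% max(protocol$time_s),
    dt_s = stats::median(diff(protocol$time_s)))
  p_of <- function(f) p_max / (1 + exp((f - true_b) / true_c))
  grid <- expand.grid(trial_id = seq_len(n_trials),
                      spatial_freq_cyc_deg = frequencies,
                      animal_id = seq_len(n_animals))
  grid$condition <- "moving"
  trials <- grid
  if (n_null > 0) {
    nulls <- expand.grid(trial_id = seq_len(n_null),
                         spatial_freq_cyc_deg = NA_real_,
                         animal_id = seq_len(n_animals))
    nulls$condition <- "null"
    trials <- rbind(grid, nulls)
  }
  trials <- trials[, c("animal_id", "trial_id",
                       "spatial_freq_cyc_deg", "condition")]
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, nrow(trials)))
  traces <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    moving <- trials$condition[i] == "moving"
    model <- behavior_model(
      p_track = if (moving) p_of(trials$spatial_freq_cyc_deg[i]) else 0,
      tracking_noise_sd = tracking_noise_sd,
      idle_velocity_sd = idle_velocity_sd,
      seed = seeds[i])
    traces[[i]] <- simulate_trace(if (moving) protocol else null_protocol,
                                  model)
  }
  list(trials = trials, traces = traces)
}

#' Analyze a set of trials into an acuity report
#'
#' Scores every trace (null traces against the standard moving-velocity
#' profile), estimates the chance level from the null trials, builds the
#' chance-corrected normalized response curve, fits the logistic and
#' derives the visual acuity.
#'
#' @param trials trial table (`animal_id, trial_id, spatial_freq_cyc_deg,
#'   condition`).
#' @param traces list of trace data frames parallel to `trials` rows
#'   (columns `time_s, head_angle_deg, stim_angle_deg`).
#' @param config a [load_config()] result (or list of overrides).
#' @return report list: parameters, `chance_level`, `t_track` per trial,
#'   `response_curve`, `fit` (a, b, c, objective, converged), `acuity`.
#' @export
analyze_trials <- function(trials, traces, config = list()) {
  cfg <- load_config(config)
  stopifnot(nrow(trials) == length(traces))
  tt <- numeric(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tr <- traces[[i]]
    stim <- if (trials$condition[i] == "null")
      .reference_stim_angle(tr$time_s, cfg$stimulus$velocity_deg_s,
                            cfg$stimulus$reversal_period_s)
    else tr$stim_angle_deg
    tt[i] <- trace_t_track(tr$head_angle_deg, stim, tr$time_s,
                           cfg$lambda_deg_s)
  }
  trials$t_track <- tt
  nulls <- trials[trials$condition == "null", ]
  chance <- if (nrow(nulls)) {
    chance_level(split(nulls$t_track, nulls$animal_id))
  } else {
    warning("manifest has no null trials; chance level set to 0")
    0
  }
  moving <- trials[trials$condition == "moving", ]
  curve <- build_response_curve(moving, chance = chance,
                                optimal_freq = cfg$optimal_freq)
  fit <- fit_logistic(curve, fit_above_cyc_deg = cfg$fit_above_cyc_deg,
                      n_boot = cfg$n_boot, seed = cfg$seed)
  acuity <- if (fit$converged)
    visual_acuity(fit, cfg$criterion_fraction) else NA_real_
  list(parameters = list(lambda_deg_s = cfg$lambda_deg_s,
                         fit_above_cyc_deg = cfg$fit_above_cyc_deg,
                         criterion_fraction = cfg$criterion_fraction,
                         optimal_freq = attr(curve, "optimal_freq"),
                         seed = cfg$seed),
       chance_level = chance,
       trials = trials,
       response_curve = as.data.frame(curve),
       fit = list(a = unname(coef(fit)["a"]), b = unname(coef(fit)["b"]),
                  c = unname(coef(fit)["c"]), objective = fit$objective,
                  converged = fit$converged),
       bounds = fit$bounds,
       acuity_cyc_deg = acuity)
}

#' Run the full batch pipeline from a configuration
#'
#' Either simulates an experiment (config key `simulate`, a list of
#' [simulate_experiment()] arguments) or loads trials from a manifest
#' (config key `manifest`), analyzes them, and optionally writes a JSON
#' report plus the response-curve CSV to `out_dir`. Fully reproducible
#' from config and seed.
#'
#' @param config YAML path or config list (see [load_config()]).
#' @param verbose log the stages via `message()`.
#' @return the report list from [analyze_trials()], with a `timestamp`
#'   element added (the only non-deterministic field).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  cfg <- load_config(config)
  say <- function(...) if (verbose) message("[omr] ", ...)
  if (!is.null(cfg$simulate)) {
    say("simulating experiment")
    args <- cfg$simulate
    if (is.null(args$seed)) args$seed <- cfg$seed
    if (is.null(args$protocol))
      args$protocol <- make_rotation_protocol(
        cfg$stimulus$velocity_deg_s, cfg$stimulus$reversal_period_s,
        cfg$stimulus$duration_s, cfg$stimulus$dt_s)
    ex <- do.call(simulate_experiment, args)
  } else if (!is.null(cfg$manifest)) {
    say("loading manifest ", cfg$manifest)
    m <- read_manifest(cfg$manifest)
    ex <- list(trials = m[, c("animal_id", "trial_id",
                              "spatial_freq_cyc_deg", "condition")],
               traces = lapply(m$trace_path, read_trace))
  } else stop("config must provide either `simulate` or `manifest`")
  say("analyzing ", nrow(ex$trials), " trials")
  report <- analyze_trials(ex$trials, ex$traces, cfg)
  report$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  if (!is.null(cfg$out_dir)) {
    if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
    write_report(report, file.path(cfg$out_dir, "report.json"))
    utils::write.csv(report$response_curve,
                     file.path(cfg$out_dir, "response_curve.csv"),
                     row.names = FALSE)
    say("report written to ", cfg$out_dir)
  }
  report
}

#' Write a pipeline report as JSON
#'
#' @param report a report list from [run_pipeline()] / [analyze_trials()].
#' @param path output JSON path.
#' @export
write_report <- function(report, path) {
  report$trials <- NULL  # per-trial table goes to CSV, not the report
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}
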