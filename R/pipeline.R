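#' Build a pipeline run configuration
#'
#' Flat named list of every stage parameter with documented defaults. The
#' defaults encode the standard acquisition settings (20-s frames for
#' MS2-only movies, 30-s frames for triple-channel movies) and the default
#' kinetic regime of the synthetic generator.
#'
#' @param ... Overrides of the default keys (unknown keys are kept and
#'   flagged by [validate_config()]).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    schema_version = 1,
    seed = 1,
    n_traces = 20,
    duration_s = 3600,
    frame_interval_s = 20,        # MS2-only movies
    hub_frame_interval_s = 30,    # triple-channel movies
    k_ini = 0.25, k1_minus = 0.15, k1_plus = 1 / 6,
    k2_minus = 0.01, k2_plus = 1 / 145,
    kernel_preset = "loops-near-TSS",
    elongation_bp_s = 45, retention_s = 30,
    ms2_noise_sd = 0.5,           # molecule-equivalents
    ms2_gain = 50,                # a.u. per molecule (raw movie units)
    hub_lead_lag_s = 120,
    hub_gain = 1, hub_baseline = 0.1, hub_noise_sd = 0.02,
    smfish_unit_intensity = 120, smfish_noise_cv = 0.2,
    smfish_n_single = 2000, smfish_n_ats = 300,
    threshold_molecules = 3,
    gap_allow_frames = 20, min_on_frames = 5,
    interpolate_gap_frames = 4,
    window_min = 5, horizon_min = 60,
    deconv_stop_factor = 2, deconv_grid_oversample = 2,
    fit_candidates = c(2, 3), fit_alpha = 0.05,
    tau_window_frames = 4, tau_n_boot = 200,
    correlate_max_lag_frames = 10
  )
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = c("run_config", "list"))
}

#' Validate a run configuration
#'
#' Checks every constraint before execution and reports violations and
#' warnings (report-only: nothing is fixed or stopped here).
#'
#' @param config A `run_config` (or plain list of overrides).
#' @return data.frame (`key`, `level` in {"violation", "warning"},
#'   `message`); zero rows when fully valid.
#' @export
validate_config <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  issues <- list()
  note <- function(key, level, msg)
    issues[[length(issues) + 1L]] <<- data.frame(key = key, level = level,
                                                 message = msg)
  known <- names(run_config())
  for (key in setdiff(names(config), known))
    note(key, "warning", "unknown configuration key")
  pos <- c("duration_s", "frame_interval_s", "hub_frame_interval_s",
           "elongation_bp_s", "ms2_gain", "smfish_unit_intensity",
           "window_min", "horizon_min", "tau_window_frames")
  for (key in pos)
    if (!is.numeric(config[[key]]) || config[[key]] <= 0)
      note(key, "violation", "must be a positive number")
  nonneg <- c("k_ini", "k1_minus", "k1_plus", "k2_minus", "k2_plus",
              "ms2_noise_sd", "hub_lead_lag_s", "hub_gain", "hub_baseline",
              "hub_noise_sd", "smfish_noise_cv", "retention_s")
  for (key in nonneg)
    if (!is.numeric(config[[key]]) || any(config[[key]] < 0))
      note(key, "violation", "must be >= 0")
  if (config$n_traces < 1) note("n_traces", "violation", "need >= 1 trace")
  if (!config$kernel_preset %in% c("loops-near-TSS", "loops-near-3p"))
    note("kernel_preset", "violation", "unknown kernel preset")
  if (do.call(rbind, issues) |> is.null())
    data.frame(key = character(0), level = character(0),
               message = character(0))
  else do.call(rbind, issues)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline on self-generated synthetic data
#'
#' Executes the stages in dependency order: simulate promoter paths and
#' traces -> process traces (interpolation, active-period segmentation,
#' proportion active) -> calibrate against generated smFISH spots ->
#' deconvolve into initiation events -> fit waiting-time survival and infer
#' promoter kinetics -> steady-state check -> hub/transcription
#' cross-correlation. Artifacts (CSV tables and a JSON summary stamped with
#' the configuration hash and seed) are written under `out_dir`. Reruns
#' with the same configuration and seed are bit-identical.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("ms2run")) {
  issues <- validate_config(config)
  if (any(issues$level == "violation"))
    stop("invalid configuration:\n",
         paste(sprintf("  %s: %s", issues$key, issues$message),
               collapse = "\n"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  kin <- promoter_kinetics(config$k_ini, config$k1_minus, config$k1_plus,
                           config$k2_minus, config$k2_plus)
  kernel <- kernel_preset(config$kernel_preset, config$frame_interval_s,
                          config$elongation_bp_s, config$retention_s)

  # --- simulate ---------------------------------------------------------
  sims <- lapply(seq_len(config$n_traces), function(i) {
    path <- simulate_promoter_path(kin, config$duration_s,
                                   initial_state = "stationary")
    ev <- sample_initiations(path, kin$k_ini,
                             nucleus_id = sprintf("n%03d", i))
    tr <- render_ms2_trace(ev, kernel, config$frame_interval_s,
                           duration_s = config$duration_s,
                           noise_sd = config$ms2_noise_sd)
    raw <- tr; raw$intensity <- raw$intensity * config$ms2_gain
    hub <- generate_hub_trace(path, config$hub_lead_lag_s, config$hub_gain,
                              config$hub_baseline, config$hub_noise_sd,
                              frame_interval_s = config$frame_interval_s,
                              nucleus_id = sprintf("n%03d", i))
    list(path = path, events = ev, trace_raw = raw, hub = hub)
  })
  write_trace_table(lapply(sims, `[[`, "trace_raw"),
                    file.path(out_dir, "traces_ms2_raw.csv"))
  write_trace_table(lapply(sims, `[[`, "hub"),
                    file.path(out_dir, "traces_hub.csv"))

  # --- calibrate --------------------------------------------------------
  singles <- generate_smfish_spots(config$smfish_unit_intensity,
                                   rep(1, config$smfish_n_single),
                                   config$smfish_noise_cv)
  unit <- estimate_unit_intensity(singles$intensity)
  ats_counts <- pmax(1, stats::rpois(config$smfish_n_ats, 12))
  ats <- generate_smfish_spots(config$smfish_unit_intensity, ats_counts,
                               config$smfish_noise_cv)
  ms2_sample <- unlist(lapply(sims, function(s)
    s$trace_raw$intensity[s$trace_raw$intensity >
                            config$ms2_gain * config$threshold_molecules]))
  cal <- qq_calibrate(ms2_sample, ats_molecule_count(ats$intensity, unit),
                      unit_intensity = unit,
                      detection_floor_molecules = config$threshold_molecules)
  jsonlite::write_json(unclass(cal), file.path(out_dir, "calibration.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- process + deconvolve + waits ------------------------------------
  waits_all <- numeric(0)
  events_all <- list()
  period_rows <- list()
  for (s in sims) {
    molc <- apply_calibration(s$trace_raw, cal)
    periods <- segment_active_periods(molc, config$gap_allow_frames,
                                      config$min_on_frames,
                                      config$threshold_molecules)
    per_s <- periods_to_seconds(periods)
    if (nrow(per_s))
      period_rows[[length(period_rows) + 1L]] <-
        cbind(nucleus_id = molc$nucleus_id, per_s,
              interior = periods$interior)
    dec <- deconvolve(molc, kernel, noise_sd = config$ms2_noise_sd,
                      stop_factor = config$deconv_stop_factor,
                      grid_oversample = config$deconv_grid_oversample)
    events_all[[length(events_all) + 1L]] <- dec$events
    per_use <- if (nrow(per_s)) per_s else
      data.frame(start_s = 0, end_s = config$duration_s)
    waits_all <- c(waits_all, waiting_times(dec$events, per_use))
  }
  if (length(period_rows))
    utils::write.csv(do.call(rbind, period_rows),
                     file.path(out_dir, "active_periods.csv"),
                     row.names = FALSE)
  utils::write.csv(
    do.call(rbind, lapply(events_all, function(e)
      data.frame(nucleus_id = e$nucleus_id, time_s = e$times_s))),
    file.path(out_dir, "initiation_events.csv"), row.names = FALSE)

  # --- fit + infer ------------------------------------------------------
  curve <- empirical_survival(waits_all)
  utils::write.csv(as.data.frame(curve),
                   file.path(out_dir, "survival_curve.csv"),
                   row.names = FALSE)
  sel <- select_model(curve, candidates = config$fit_candidates,
                      alpha = config$fit_alpha)
  inferred <- if (sel$n_states == 3)
    tryCatch(infer_kinetics(sel$fits[["3"]]), error = function(e) NULL)
  else NULL

  pooled_events <- sort(unlist(lapply(events_all, `[[`, "times_s")))
  tau <- steady_state_tau(events_all[[1]],
                          window_frames = config$tau_window_frames,
                          frame_interval_s = config$frame_interval_s,
                          n_boot = config$tau_n_boot)

  # --- correlate --------------------------------------------------------
  profiles <- lapply(sims, function(s) {
    tryCatch(cross_correlate(paired_trace(s$hub, s$trace_raw),
                             config$correlate_max_lag_frames),
             error = function(e) NULL)
  })
  profiles <- Filter(Negate(is.null), profiles)
  agg <- if (length(profiles)) aggregate_profiles(profiles) else NULL

  summary <- list(
    config_hash = config_hash(config), seed = config$seed,
    n_traces = config$n_traces,
    n_waits = length(waits_all),
    unit_intensity = unit,
    qq_slope = cal$qq_slope, qq_intercept = cal$qq_intercept,
    n_states = sel$n_states, selection_passed = sel$passed,
    inferred = if (!is.null(inferred))
      inferred[c("k_ini", "k1_minus", "k1_plus", "k2_minus", "k2_plus",
                 "p_on", "off1_duration_s", "off2_duration_s")] else NULL,
    pooled_tau_s = tau$pooled_tau_s, tau_stable = tau$stable,
    mean_peak_lag_s = if (!is.null(agg))
      mean(agg$peak_lags) * config$frame_interval_s else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
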