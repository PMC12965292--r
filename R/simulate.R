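#' Ordered Pol II initiation times for one trace
#'
#' @param times_s Numeric vector of initiation times (seconds), sorted
#'   nondecreasing.
#' @param nucleus_id Trace/nucleus identifier.
#' @param span_s Optional length-2 span the events must lie in.
#' @return An object of class `initiation_events`.
#' @export
initiation_events <- function(times_s, nucleus_id = "n1", span_s = NULL) {
  times_s <- as.numeric(times_s)
  if (is.unsorted(times_s)) stop("initiation times must be nondecreasing")
  if (!is.null(span_s) && length(times_s) &&
      (min(times_s) < span_s[1] || max(times_s) > span_s[2]))
    stop("initiation times must lie within the trace span")
  structure(list(times_s = times_s, nucleus_id = nucleus_id, span_s = span_s),
            class = "initiation_events")
}

#' @export
print.initiation_events <- function(x, ...) {
  cat(sprintf("<initiation_events> %s: %d events\n",
              x$nucleus_id, length(x$times_s)))
  invisible(x)
}

#' Exact stochastic simulation of the promoter state path
#'
#' Gillespie simulation of the nonsequential three-state chain: exponential
#' sojourns, competing exits from ON (to OFF1 at `k1_minus`, to OFF2 at
#' `k2_minus`), single exits from each OFF back to ON. Initiation does not
#' change the state and is sampled separately ([sample_initiations()]).
#'
#' @param kinetics A `promoter_kinetics`.
#' @param duration_s Total simulated time (s), > 0.
#' @param initial_state `"ON"`, `"OFF1"`, `"OFF2"`, or `"stationary"` to draw
#'   the initial state from the stationary distribution.
#' @param seed Optional integer seed (local to this call).
#' @return A `state_path`: data.frame with columns `state`, `start_s`,
#'   `end_s`; contiguous segments covering exactly `[0, duration_s]`.
#' @export
simulate_promoter_path <- function(kinetics, duration_s,
                                   initial_state = "stationary",
                                   seed = NULL) {
  if (!is.finite(duration_s) || duration_s <= 0)
    stop("duration_s must be finite and > 0")
  if (!is.null(seed)) { old <- local_seed(seed); on.exit(restore_seed(old)) }
  exit_rates <- c(ON = kinetics$k1_minus + kinetics$k2_minus,
                  OFF1 = kinetics$k1_plus, OFF2 = kinetics$k2_plus)
  state <- if (identical(initial_state, "stationary")) {
    w1 <- if (kinetics$k1_minus > 0) kinetics$k1_minus / kinetics$k1_plus else 0
    w2 <- if (kinetics$k2_minus > 0) kinetics$k2_minus / kinetics$k2_plus else 0
    sample(c("ON", "OFF1", "OFF2"), 1, prob = c(1, w1, w2))
  } else match.arg(initial_state, c("ON", "OFF1", "OFF2"))
  t <- 0
  states <- character(0); starts <- numeric(0); ends <- numeric(0)
  while (t < duration_s) {
    rate <- exit_rates[[state]]
    dwell <- if (rate > 0) stats::rexp(1, rate) else Inf
    t_next <- min(t + dwell, duration_s)
    states <- c(states, state); starts <- c(starts, t); ends <- c(ends, t_next)
    t <- t_next
    if (t >= duration_s) break
    state <- if (state == "ON") {
      if (stats::runif(1) < kinetics$k1_minus / exit_rates[["ON"]]) "OFF1" else "OFF2"
    } else "ON"
  }
  structure(data.frame(state = states, start_s = starts, end_s = ends,
                       stringsAsFactors = FALSE),
            class = c("state_path", "data.frame"),
            duration_s = duration_s, kinetics = kinetics)
}

#' Fraction of a state path spent ON
#' @param path A `state_path`.
#' @export
on_fraction <- function(path) {
  sum((path$end_s - path$start_s)[path$state == "ON"]) /
    attr(path, "duration_s")
}

#' Sample Pol II initiation events along a state path
#'
#' Homogeneous Poisson process at rate `k_ini`, restricted to the ON
#' segments of the path.
#'
#' @param path A `state_path`.
#' @param k_ini Initiation rate while ON (/ s), >= 0.
#' @param seed Optional integer seed.
#' @param nucleus_id Identifier passed to the result.
#' @return An `initiation_events` object.
#' @export
sample_initiations <- function(path, k_ini, seed = NULL, nucleus_id = "n1") {
  if (k_ini < 0) stop("k_ini must be >= 0")
  if (!is.null(seed)) { old <- local_seed(seed); on.exit(restore_seed(old)) }
  on_seg <- path[path$state == "ON", , drop = FALSE]
  times <- numeric(0)
  if (k_ini > 0 && nrow(on_seg)) {
    lens <- on_seg$end_s - on_seg$start_s
    counts <- stats::rpois(nrow(on_seg), k_ini * lens)
    times <- unlist(mapply(function(a, b, n) sort(stats::runif(n, a, b)),
                           on_seg$start_s, on_seg$end_s, counts,
                           SIMPLIFY = FALSE))
  }
  initiation_events(sort(as.numeric(times)), nucleus_id = nucleus_id,
                    span_s = c(0, attr(path, "duration_s")))
}

#' Render an MS2 fluorescence trace from initiation events
#'
#' Trace value at each frame is the sum over events of the single-polymerase
#' kernel evaluated at (frame time - event time), in molecule-equivalents,
#' plus additive Gaussian noise. Frames are instantaneous samples.
#'
#' @param events An `initiation_events`.
#' @param kernel An `ms2_kernel`.
#' @param frame_interval_s Frame spacing (s), > 0.
#' @param duration_s Trace span (s); defaults to the event span.
#' @param noise_sd Additive Gaussian noise SD in molecule-equivalents.
#' @param seed Optional integer seed.
#' @param start_time_s Time of the first frame.
#' @return A `fluor_trace` (channel `"ms2"`).
#' @export
render_ms2_trace <- function(events, kernel, frame_interval_s = NULL,
                             duration_s = NULL, noise_sd = 0, seed = NULL,
                             start_time_s = 0) {
  if (is.null(frame_interval_s)) frame_interval_s <- kernel$frame_interval_s
  if (frame_interval_s <= 0) stop("frame_interval_s must be > 0")
  if (kernel$elongation_bp_s <= 0) stop("kernel elongation rate must be > 0")
  if (is.null(duration_s)) {
    duration_s <- if (!is.null(events$span_s)) events$span_s[2]
                  else if (length(events$times_s)) max(events$times_s) + kernel$t_end
                  else stop("duration_s required for an empty event set")
  }
  if (!is.null(seed)) { old <- local_seed(seed); on.exit(restore_seed(old)) }
  frames <- seq(start_time_s, start_time_s + duration_s, by = frame_interval_s)
  signal <- numeric(length(frames))
  for (te in events$times_s) {
    lo <- te + kernel$t_rise; hi <- te + kernel$t_end
    idx <- which(frames > lo & frames < hi)
    if (length(idx))
      signal[idx] <- signal[idx] + kernel_eval(kernel, frames[idx] - te)
  }
  if (noise_sd > 0) signal <- signal + stats::rnorm(length(signal), 0, noise_sd)
  fluor_trace(signal, frame_interval_s, nucleus_id = events$nucleus_id,
              channel = "ms2", start_time_s = start_time_s)
}

#' Generate a coactivator-hub intensity trace that leads transcription
#'
#' The hub signal is modelled as an exponentially smoothed transform of the
#' promoter ON indicator, advanced in time by `lead_lag_s`, scaled and offset,
#' with additive Gaussian noise; changes in the hub therefore precede changes
#' in promoter activity by `lead_lag_s` (default 120 s, i.e. hub enrichment
#' peaks about 2 minutes before transcription onset). Smoothing is applied
#' forward and backward (zero phase), so the planted lead is exactly
#' recoverable by cross-correlation against the activity; correlating
#' against a rendered MS2 trace shows an additional delay from the
#' reporter's transcription and retention time.
#'
#' @param path A `state_path`.
#' @param lead_lag_s Lead of the hub over transcription (s), >= 0.
#' @param gain,baseline Affine scaling of the smoothed activity, gain >= 0.
#' @param noise_sd Additive Gaussian noise SD.
#' @param frame_interval_s Frame spacing of the output trace.
#' @param smooth_tau_s Exponential smoothing time constant (s).
#' @param seed Optional integer seed.
#' @param nucleus_id Identifier for the trace.
#' @return A `fluor_trace` (channel `"hub"`).
#' @export
generate_hub_trace <- function(path, lead_lag_s = 120, gain = 1, baseline = 0,
                               noise_sd = 0, frame_interval_s = 30,
                               smooth_tau_s = 30, seed = NULL,
                               nucleus_id = "n1") {
  if (lead_lag_s < 0) stop("lead_lag_s must be >= 0")
  if (gain < 0) stop("gain must be >= 0")
  if (!is.null(seed)) { old <- local_seed(seed); on.exit(restore_seed(old)) }
  duration <- attr(path, "duration_s")
  dt0 <- min(1, frame_interval_s / 10)
  grid <- seq(0, duration, by = dt0)
  on_ind <- state_at(path, grid) == "ON"
  # forward-backward exponential moving average: zero-phase smoothing, so
  # the advance by lead_lag_s is not distorted by filter delay
  alpha <- dt0 / (smooth_tau_s + dt0)
  ema <- function(x) { acc <- x[1]
    vapply(x, function(v) acc <<- acc + alpha * (v - acc), numeric(1)) }
  smooth <- rev(ema(rev(ema(as.numeric(on_ind)))))
  frames <- seq(0, duration, by = frame_interval_s)
  query <- pmin(frames + lead_lag_s, duration)
  vals <- stats::approx(grid, smooth, xout = query, rule = 2)$y
  vals <- gain * vals + baseline
  if (noise_sd > 0) vals <- vals + stats::rnorm(length(vals), 0, noise_sd)
  fluor_trace(vals, frame_interval_s, nucleus_id = nucleus_id,
              channel = "hub", start_time_s = 0)
}

#' State of a path at given times
#' @param path A `state_path`.
#' @param t Numeric vector of times within the path span.
#' @return Character vector of states.
#' @export
state_at <- function(path, t) {
  idx <- findInterval(t, path$start_s, rightmost.closed = TRUE)
  idx[idx < 1] <- 1
  path$state[idx]
}

#' Simulate a two-allele nucleus population
#'
#' Each nucleus carries two independently firing alleles; only one (the
#' tagged allele) carries the MS2 loops. smFISH detects a nucleus as active
#' when at least one allele is active; MS2 detects it only when the tagged
#' allele is active. With allele activity probability p the expected
#' MS2/smFISH detected-fraction ratio is p / (1 - (1-p)^2) = 1 / (2 - p).
#'
#' @param n_nuclei Number of nuclei.
#' @param p_active_per_allele Per-allele activity probability in \[0, 1\].
#' @param seed Optional integer seed.
#' @return A data.frame with columns `allele1_active`, `allele2_active`,
#'   `tagged_allele` (1 or 2), plus attributes `smfish_fraction`,
#'   `ms2_fraction` and `detection_ratio`.
#' @export
generate_two_allele_population <- function(n_nuclei, p_active_per_allele,
                                           seed = NULL) {
  p <- p_active_per_allele
  if (p < 0 || p > 1) stop("p_active_per_allele must be in [0, 1]")
  if (!is.null(seed)) { old <- local_seed(seed); on.exit(restore_seed(old)) }
  a1 <- stats::runif(n_nuclei) < p
  a2 <- stats::runif(n_nuclei) < p
  tagged <- sample(1:2, n_nuclei, replace = TRUE)
  tab <- data.frame(allele1_active = a1, allele2_active = a2,
                    tagged_allele = tagged)
  smfish <- mean(a1 | a2)
  ms2 <- mean(ifelse(tagged == 1, a1, a2))
  attr(tab, "smfish_fraction") <- smfish
  attr(tab, "ms2_fraction") <- ms2
  attr(tab, "detection_ratio") <- if (smfish > 0) ms2 / smfish else 0
  tab
}

#' Generate an smFISH spot-intensity table
#'
#' Single-molecule spots cluster around `unit_intensity`; active
#' transcription site (ATS) spots carry `count x unit_intensity`.
#' Noise is multiplicative log-normal with coefficient of variation
#' `noise_cv` (median preserved).
#'
#' @param unit_intensity Intensity of one mRNA molecule (a.u.), > 0.
#' @param molecule_counts Integer molecule count per spot; 1 denotes a
#'   single-molecule (cytoplasmic) spot.
#' @param noise_cv Multiplicative noise CV (0 disables noise).
#' @param seed Optional integer seed.
#' @return data.frame with columns `spot_id`, `molecules`, `intensity`.
#' @export
generate_smfish_spots <- function(unit_intensity, molecule_counts,
                                  noise_cv = 0, seed = NULL) {
  if (unit_intensity <= 0) stop("unit_intensity must be > 0")
  if (!is.null(seed)) { old <- local_seed(seed); on.exit(restore_seed(old)) }
  n <- length(molecule_counts)
  base <- molecule_counts * unit_intensity
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    base <- base * stats::rlnorm(n, meanlog = 0, sdlog = sdlog)
  }
  data.frame(spot_id = seq_len(n), molecules = molecule_counts,
             intensity = base)
}

# Seed handling: run a generator under a caller-supplied seed without
# disturbing the global RNG stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
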