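#' Steady-state check on the mean inter-initiation interval
#'
#' At steady state the mean interval between successive Pol II initiation
#' events, tau, is 1 / (p_ON * k_ini); stability of the windowed tau over
#' time therefore indicates stationary kinetics. tau is estimated in sliding
#' windows of `window_frames` frames (default 4, i.e. 80 s at 20-s frames),
#' each windowed estimate gets a bootstrap percentile confidence interval,
#' and the verdict is "stable" when the confidence interval of the trend
#' slope of tau against window center contains zero.
#'
#' @param events An `initiation_events` or numeric vector of times (s).
#' @param window_frames Window width in frames (default 4).
#' @param frame_interval_s Frame spacing (s), default 20.
#' @param step_frames Window step (default 1 frame).
#' @param n_boot Bootstrap replicates per window (default 1000).
#' @param seed Optional integer seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @param min_events Minimum events per evaluated window (default 2);
#'   windows below this are skipped and counted in `n_skipped`.
#' @return List of class `steady_state_check`: `windows` (data.frame
#'   `center_s`, `tau_s`, `lower`, `upper`, `n_events`), `pooled_tau_s`
#'   (mean over all waits, not window-truncated), `stable`, `trend_slope`,
#'   `trend_ci`, `window_width_s`, `n_skipped`.
#' @export
steady_state_tau <- function(events, window_frames = 4, frame_interval_s = 20,
                             step_frames = 1, n_boot = 1000, seed = NULL,
                             conf = 0.95, min_events = 2) {
  times <- if (inherits(events, "initiation_events")) events$times_s else sort(events)
  if (length(times) < 2) stop("need at least 2 events")
  if (!is.null(seed)) { old <- local_seed(seed); on.exit(restore_seed(old)) }
  width <- window_frames * frame_interval_s
  step <- step_frames * frame_interval_s
  starts <- seq(min(times), max(times) - width, by = step)
  if (!length(starts)) stop("event span shorter than one window")
  rows <- list(); n_skipped <- 0L
  alpha <- (1 - conf) / 2
  for (s0 in starts) {
    inside <- times[times >= s0 & times < s0 + width]
    if (length(inside) < min_events) { n_skipped <- n_skipped + 1L; next }
    w <- diff(inside)
    if (!length(w)) { n_skipped <- n_skipped + 1L; next }
    boot <- replicate(n_boot, mean(sample(w, length(w), replace = TRUE)))
    ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      center_s = s0 + width / 2, tau_s = mean(w),
      lower = ci[1], upper = ci[2], n_events = length(inside))
  }
  windows <- if (length(rows)) do.call(rbind, rows)
  else data.frame(center_s = numeric(0), tau_s = numeric(0),
                  lower = numeric(0), upper = numeric(0),
                  n_events = integer(0))
  pooled <- mean(diff(times)[diff(times) > 0])
  stable <- NA; slope <- NA_real_; slope_ci <- c(NA_real_, NA_real_)
  if (nrow(windows) >= 3) {
    fit <- stats::lm(tau_s ~ center_s, data = windows)
    slope <- unname(stats::coef(fit)[2])
    slope_ci <- unname(stats::confint(fit, "center_s", level = conf)[1, ])
    stable <- slope_ci[1] <= 0 && slope_ci[2] >= 0
  }
  structure(list(windows = windows, pooled_tau_s = pooled, stable = stable,
                 trend_slope = slope, trend_ci = slope_ci,
                 window_width_s = width, n_skipped = n_skipped),
            class = "steady_state_check")
}

#' @export
print.steady_state_check <- function(x, ...) {
  cat(sprintf("<steady_state_check> %d windows of %g s; pooled tau %.3g s; %s\n",
              nrow(x$windows), x$window_width_s, x$pooled_tau_s,
              if (isTRUE(x$stable)) "stable" else if (isFALSE(x$stable))
                "UNSTABLE (tau trends with time)" else "verdict undetermined"))
  invisible(x)
}
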