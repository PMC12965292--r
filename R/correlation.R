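#' Cross-correlation of a paired hub/transcription trace
#'
#' Mean-subtracted Pearson correlation at integer-frame lags, computed on
#' the overlapping segment at each lag (no zero padding; traces are short).
#' Sign convention: the correlation at lag L compares hub(t + L) with
#' ms2(t), so a negative peak lag means the hub signal leads transcription
#' by |L| frames.
#'
#' @param pair A `paired_trace`, or the hub trace/vector (with `y` the ms2
#'   trace/vector).
#' @param max_lag_frames Largest |lag| evaluated.
#' @param y Second trace when `pair` is not a `paired_trace`.
#' @param min_overlap Minimum overlapping frames per evaluated lag
#'   (default 5); lags with less overlap are omitted.
#' @param detrend Remove a linear trend from both traces first
#'   (default FALSE: mean subtraction only, which Pearson correlation
#'   performs implicitly).
#' @return A `correlation_profile`: data.frame (`lag_frames`, `lag_s`, `r`,
#'   `r2`, `n`) with attributes `peak_lag_frames`, `peak_lag_s`, `peak_r`.
#' @export
cross_correlate <- function(pair, max_lag_frames, y = NULL, min_overlap = 5,
                            detrend = FALSE) {
  if (inherits(pair, "paired_trace")) {
    x <- pair$hub$intensity; yy <- pair$ms2$intensity
    dt <- pair$hub$frame_interval_s
  } else {
    x <- if (inherits(pair, "fluor_trace")) pair$intensity else pair
    yy <- if (inherits(y, "fluor_trace")) y$intensity else y
    dt <- if (inherits(pair, "fluor_trace")) pair$frame_interval_s else 1
  }
  if (is.null(yy)) stop("second trace missing")
  if (detrend) {
    x <- stats::resid(stats::lm(x ~ seq_along(x)))
    yy <- stats::resid(stats::lm(yy ~ seq_along(yy)))
  }
  n <- min(length(x), length(yy))
  x <- x[seq_len(n)]; yy <- yy[seq_len(n)]
  rows <- list()
  for (L in -max_lag_frames:max_lag_frames) {
    # hub(t + L) vs ms2(t)
    if (L >= 0) { xi <- x[(1 + L):n]; yi <- yy[1:(n - L)] }
    else { xi <- x[1:(n + L)]; yi <- yy[(1 - L):n] }
    if (length(xi) < min_overlap) next
    if (stats::sd(xi) == 0 || stats::sd(yi) == 0) next
    r <- stats::cor(xi, yi)
    rows[[length(rows) + 1L]] <- data.frame(lag_frames = L, lag_s = L * dt,
                                            r = r, r2 = r^2, n = length(xi))
  }
  if (!length(rows)) stop("no lag had sufficient overlap")
  prof <- do.call(rbind, rows)
  ipk <- which.max(prof$r)
  structure(prof, class = c("correlation_profile", "data.frame"),
            peak_lag_frames = prof$lag_frames[ipk],
            peak_lag_s = prof$lag_s[ipk], peak_r = prof$r[ipk],
            frame_interval_s = dt)
}

#' Autocorrelation with a secondary-peak (periodicity) report
#'
#' Normalized autocorrelation over nonnegative lags (r = 1 at lag 0) with
#' the first local maximum after the zero-lag peak reported as a
#' periodicity candidate when it clears the noise floor `3 / sqrt(n)`.
#'
#' @param trace A `fluor_trace` or numeric vector; must not be constant.
#' @param max_lag_frames Largest lag evaluated.
#' @param min_overlap Minimum overlap per lag (default 5).
#' @param noise_floor Significance threshold for the secondary peak;
#'   default `3 / sqrt(n)`.
#' @return A `correlation_profile` over lags >= 0 with attributes
#'   `secondary_peak_lag` (NA when none is significant) and
#'   `secondary_peak_r`.
#' @export
autocorrelate <- function(trace, max_lag_frames, min_overlap = 5,
                          noise_floor = NULL) {
  x <- if (inherits(trace, "fluor_trace")) trace$intensity else trace
  if (stats::sd(x) == 0) stop("constant trace has undefined autocorrelation")
  prof <- cross_correlate(trace, max_lag_frames, y = trace,
                          min_overlap = min_overlap)
  prof <- prof[prof$lag_frames >= 0, ]
  if (is.null(noise_floor)) noise_floor <- 3 / sqrt(length(x))
  r <- prof$r
  sec_lag <- NA_integer_; sec_r <- NA_real_
  if (length(r) >= 3) for (i in 2:(length(r) - 1)) {
    if (r[i] > r[i - 1] && r[i] >= r[i + 1] && r[i] > noise_floor) {
      sec_lag <- prof$lag_frames[i]; sec_r <- r[i]; break
    }
  }
  structure(prof, class = c("correlation_profile", "data.frame"),
            peak_lag_frames = 0L, peak_lag_s = 0,
            peak_r = prof$r[prof$lag_frames == 0],
            secondary_peak_lag = sec_lag, secondary_peak_r = sec_r,
            noise_floor = noise_floor)
}

#' Correlation of hub level with the transcription slope
#'
#' The transcription slope at each frame is a centered finite difference of
#' the MS2 trace over `slope_window_frames`; the hub level at the same
#' frame is then correlated with it. A positive correlation indicates that
#' hub enrichment and Pol II loading rate are quantitatively related.
#'
#' @param pair A `paired_trace`.
#' @param slope_window_frames Window for the finite difference (>= 2).
#' @return List: `r`, `p_value`, `scatter` (data.frame `frame`,
#'   `hub_level`, `ms2_slope`).
#' @export
level_vs_slope <- function(pair, slope_window_frames = 4) {
  if (slope_window_frames < 2) stop("slope window must span >= 2 frames")
  hub <- pair$hub$intensity; ms2 <- pair$ms2$intensity
  dt <- pair$ms2$frame_interval_s
  n <- min(length(hub), length(ms2))
  h <- max(1L, floor(slope_window_frames / 2))
  idx <- (1 + h):(n - h)
  if (!length(idx)) stop("traces too short for the slope window")
  slope <- (ms2[idx + h] - ms2[idx - h]) / (2 * h * dt)
  lev <- hub[idx]
  if (stats::sd(lev) == 0)
    stop("degenerate variance: hub level is constant")
  scatter <- data.frame(frame = idx - 1L, hub_level = lev, ms2_slope = slope)
  if (stats::sd(slope) == 0)  # e.g. a linear ramp: slope defined, r is not
    return(list(r = NA_real_, p_value = NA_real_, scatter = scatter))
  ct <- stats::cor.test(lev, slope)
  list(r = unname(ct$estimate), p_value = ct$p.value, scatter = scatter)
}

#' Aggregate correlation profiles across nuclei
#'
#' Lag-wise mean and SEM over a set of profiles sharing a lag grid, plus
#' the per-pair correlation matrix ordered by peak lag (the ordering used
#' for heatmap display).
#'
#' @param profiles Nonempty list of `correlation_profile` objects on a
#'   common lag grid.
#' @return List: `lags` (frames), `mean_r`, `sem_r`, `mean_r2`, `sem_r2`,
#'   `matrix` (pairs x lags, rows ordered by peak lag), `peak_lags`.
#' @export
aggregate_profiles <- function(profiles) {
  if (!length(profiles)) stop("empty profile set")
  lag_sets <- lapply(profiles, `[[`, "lag_frames")
  lags <- Reduce(intersect, lag_sets)
  if (!length(lags)) stop("profiles share no common lags")
  lags <- sort(lags)
  mat <- t(vapply(profiles, function(p)
    p$r[match(lags, p$lag_frames)], numeric(length(lags))))
  peaks <- vapply(profiles, function(p) attr(p, "peak_lag_frames"),
                  numeric(1))
  ord <- order(peaks)
  n <- nrow(mat)
  sem <- function(m) if (n > 1) apply(m, 2, stats::sd) / sqrt(n) else rep(0, ncol(m))
  list(lags = lags,
       mean_r = colMeans(mat), sem_r = sem(mat),
       mean_r2 = colMeans(mat^2), sem_r2 = sem(mat^2),
       matrix = mat[ord, , drop = FALSE], peak_lags = peaks[ord])
}
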