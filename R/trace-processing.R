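#' Filter raw spot tracks into retained fluorescence traces
#'
#' Retention rules: a track must be detected in more than `min_frames - 1`
#' frames (default: more than five, i.e. at least six), must contain no
#' internal detection gap longer than `max_gap_frames` (default two), and --
#' to avoid boundary censoring from nuclei drifting out of view -- must start
#' after its nucleus track begins and end before its nucleus track ends.
#'
#' @param spots data.frame of raw detections with columns `nucleus_id`,
#'   `frame` (integer), `intensity`; one row per detected frame.
#' @param nucleus_spans Optional data.frame (`nucleus_id`, `first_frame`,
#'   `last_frame`) giving each nucleus track's span; when supplied, traces
#'   touching their nucleus-track boundaries are dropped.
#' @param min_detected_frames Minimum number of detected frames (default 6,
#'   "more than five frames").
#' @param max_gap_frames Maximum internal gap, in missed frames (default 2).
#' @param frame_interval_s Frame spacing in seconds.
#' @return Named list of `fluor_trace` objects spanning each track's first to
#'   last detection, with internal missed frames flagged missing.
#' @export
filter_tracks <- function(spots, nucleus_spans = NULL,
                          min_detected_frames = 6, max_gap_frames = 2,
                          frame_interval_s = 20) {
  stopifnot(all(c("nucleus_id", "frame", "intensity") %in% names(spots)))
  out <- list()
  for (d in split(spots, spots$nucleus_id)) {
    d <- d[order(d$frame), ]
    frames <- d$frame
    if (length(frames) < min_detected_frames) next
    gaps <- diff(frames) - 1L
    if (any(gaps > max_gap_frames)) next
    if (!is.null(nucleus_spans)) {
      i <- match(d$nucleus_id[1], nucleus_spans$nucleus_id)
      if (is.na(i)) next
      if (frames[1] <= nucleus_spans$first_frame[i] ||
          frames[length(frames)] >= nucleus_spans$last_frame[i]) next
    }
    full <- seq(frames[1], frames[length(frames)])
    intens <- rep(NA_real_, length(full))
    intens[match(frames, full)] <- d$intensity
    tr <- fluor_trace(intens, frame_interval_s,
                      nucleus_id = as.character(d$nucleus_id[1]),
                      start_time_s = frames[1] * frame_interval_s)
    out[[tr$nucleus_id]] <- tr
  }
  out
}

#' Interpolate short detection gaps inside a trace
#'
#' Gaps of at most `max_gap_frames` missing frames (default 4, i.e. "fewer
#' than five") are filled with the mean of the two flanking measured frames.
#' Longer gaps and gaps touching the trace boundary are left untouched.
#'
#' @param trace A `fluor_trace`.
#' @param max_gap_frames Largest interpolated gap length.
#' @return The trace with interpolated frames marked present.
#' @export
interpolate_short_gaps <- function(trace, max_gap_frames = 4) {
  x <- trace$intensity; present <- trace$present
  r <- rle(present)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (j in seq_along(r$lengths)) {
    if (r$values[j]) next
    if (j == 1L || j == length(r$lengths)) next    # boundary gap
    if (r$lengths[j] > max_gap_frames) next
    fill <- mean(c(x[starts[j] - 1L], x[ends[j] + 1L]))
    x[starts[j]:ends[j]] <- fill
    present[starts[j]:ends[j]] <- TRUE
  }
  trace$intensity <- x; trace$present <- present
  trace
}

#' Segment a trace into active periods
#'
#' A frame is called ON when present and above `threshold`. ON runs separated
#' by fewer than `gap_allow_frames + 1` OFF frames (default: gaps of at most
#' 20 frames, "fewer than 21 frames", ~7 min at 20-s frames) are merged into
#' one active period; merged periods shorter than `min_on_frames` are
#' dropped. A period is flagged `interior` only when flanked by inactive
#' frames on both sides (found between two inactive periods); durations
#' should be quoted for interior periods only. Inactive periods lying between
#' two active ones are returned as an attribute.
#'
#' @param trace A `fluor_trace`.
#' @param gap_allow_frames Largest OFF gap that merges two ON runs.
#' @param min_on_frames Minimum merged period length, in frames.
#' @param threshold ON-call intensity threshold; the default 3
#'   molecule-equivalents reflects a detection floor of three molecules and
#'   applies to calibrated traces (set 0 for already-thresholded signals).
#' @return An `active_period_set`: data.frame (`start_frame`, `end_frame`,
#'   `interior`) with half-open 0-based frame periods, plus attributes
#'   `inactive_periods`, `merge_window_s`, `merge_lt_frames` and
#'   `frame_interval_s`.
#' @export
segment_active_periods <- function(trace, gap_allow_frames = 20,
                                   min_on_frames = 5, threshold = 3) {
  on <- trace$present & !is.na(trace$intensity) & trace$intensity > threshold
  n <- length(on)
  runs <- on_runs(on)
  if (nrow(runs)) {
    # merge runs separated by <= gap_allow_frames OFF frames
    merged <- runs[1, , drop = FALSE]
    if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)]
      if (gap <= gap_allow_frames) merged$end[nrow(merged)] <- runs$end[i]
      else merged <- rbind(merged, runs[i, ])
    }
    merged <- merged[merged$end - merged$start >= min_on_frames, , drop = FALSE]
  } else merged <- runs
  interior <- if (nrow(merged))
    merged$start > 0L & merged$end < n else logical(0)
  periods <- data.frame(start_frame = merged$start, end_frame = merged$end,
                        interior = interior)
  inactive <- if (nrow(periods) >= 2)
    data.frame(start_frame = periods$end_frame[-nrow(periods)],
               end_frame = periods$start_frame[-1])
  else data.frame(start_frame = integer(0), end_frame = integer(0))
  structure(periods,
            class = c("active_period_set", "data.frame"),
            inactive_periods = inactive,
            merge_lt_frames = gap_allow_frames + 1L,
            merge_window_s = (gap_allow_frames + 1L) * trace$frame_interval_s,
            frame_interval_s = trace$frame_interval_s,
            n_frames = n)
}

# 0-based half-open [start, end) runs of TRUE in a logical vector
on_runs <- function(on) {
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Active periods in seconds
#' @param periods An `active_period_set`.
#' @param interior_only Keep only interior periods (the durations the
#'   analysis quotes).
#' @return data.frame with `start_s`, `end_s`, `duration_s`.
#' @export
periods_to_seconds <- function(periods, interior_only = FALSE) {
  d <- as.data.frame(periods)
  if (interior_only) d <- d[d$interior, , drop = FALSE]
  dt <- attr(periods, "frame_interval_s")
  data.frame(start_s = d$start_frame * dt, end_s = d$end_frame * dt,
             duration_s = (d$end_frame - d$start_frame) * dt)
}

#' Fraction of nuclei switching on per time bin
#'
#' Fraction of all nuclei whose first active period starts within each
#' `window_min`-minute bin, over at most `horizon_min` minutes.
#'
#' @param traces List of `fluor_trace` sharing a common clock.
#' @param window_min Bin width in minutes (default 5).
#' @param horizon_min Analysis horizon in minutes (default 60).
#' @param threshold,gap_allow_frames,min_on_frames Passed to
#'   [segment_active_periods()].
#' @return data.frame (`bin_start_min`, `bin_end_min`, `n_onsets`,
#'   `fraction`).
#' @export
proportion_active <- function(traces, window_min = 5, horizon_min = 60,
                              threshold = 3, gap_allow_frames = 20,
                              min_on_frames = 5) {
  if (!length(traces)) stop("proportion_active needs at least one trace")
  onsets <- vapply(traces, function(tr) {
    p <- segment_active_periods(tr, gap_allow_frames, min_on_frames, threshold)
    if (nrow(p)) tr$start_time_s + p$start_frame[1] * tr$frame_interval_s
    else NA_real_
  }, numeric(1))
  breaks <- seq(0, horizon_min, by = window_min)
  onset_min <- onsets[!is.na(onsets)] / 60
  counts <- if (length(onset_min))
    table(cut(onset_min, breaks, right = FALSE, include.lowest = FALSE))
  else integer(length(breaks) - 1)
  data.frame(bin_start_min = breaks[-length(breaks)],
             bin_end_min = breaks[-1],
             n_onsets = as.integer(counts),
             fraction = as.integer(counts) / length(traces))
}

#' Align traces at transcription onset and average
#'
#' Each trace is aligned at the first frame of its first active period.
#' Frames after a trace's end are assigned 0 (the trace has ended, not gone
#' missing), and the mean and SEM at each aligned frame use all traces as
#' denominator.
#'
#' @param traces List of `fluor_trace`, each with at least one active period.
#' @param threshold,gap_allow_frames,min_on_frames ON-call parameters, as in
#'   [segment_active_periods()].
#' @return List with `matrix` (traces x aligned frames), `mean`, `sem`, and
#'   `n` (number of traces).
#' @export
align_onsets <- function(traces, threshold = 3, gap_allow_frames = 20,
                         min_on_frames = 5) {
  aligned <- lapply(traces, function(tr) {
    p <- segment_active_periods(tr, gap_allow_frames, min_on_frames, threshold)
    if (!nrow(p)) return(NULL)
    x <- tr$intensity[(p$start_frame[1] + 1L):length(tr$intensity)]
    x[is.na(x)] <- 0
    x
  })
  aligned <- Filter(Negate(is.null), aligned)
  if (!length(aligned)) stop("no trace has an active period")
  width <- max(lengths(aligned))
  mat <- t(vapply(aligned, function(x) c(x, rep(0, width - length(x))),
                  numeric(width)))
  n <- nrow(mat)
  mu <- colMeans(mat)
  sem <- if (n > 1) apply(mat, 2, stats::sd) / sqrt(n) else rep(0, width)
  list(matrix = mat, mean = mu, sem = sem, n = n)
}

#' Background-subtract and median-filter a trace
#'
#' Subtracts the trace minimum (background level), applies a running median
#' of width `median_filter_width`, and re-anchors the minimum at zero.
#'
#' @param trace A `fluor_trace` (missing frames are ignored for the minimum
#'   and left missing).
#' @param median_filter_width Odd window width (default 3).
#' @return The normalized trace.
#' @export
normalize_trace <- function(trace, median_filter_width = 3) {
  x <- trace$intensity
  if (!any(trace$present)) stop("trace has no measured frames")
  x <- x - min(x[trace$present])
  ok <- trace$present
  if (sum(ok) >= median_filter_width)
    x[ok] <- as.numeric(stats::runmed(x[ok], median_filter_width,
                                      endrule = "median"))
  x[ok] <- x[ok] - min(x[ok])
  trace$intensity <- x
  trace
}
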