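#' Uniformly sampled per-nucleus fluorescence trace
#'
#' @param intensity Numeric vector of per-frame intensities. `NA` marks a
#'   missing frame (equivalently set `present`).
#' @param frame_interval_s Frame spacing in seconds.
#' @param nucleus_id Identifier of the nucleus/track.
#' @param channel Channel tag, e.g. `"ms2"` or `"hub"`.
#' @param start_time_s Acquisition time of the first frame.
#' @param present Logical vector of per-frame detection flags; defaults to
#'   `!is.na(intensity)`.
#' @return An object of class `fluor_trace`.
#' @export
fluor_trace <- function(intensity, frame_interval_s, nucleus_id = "n1",
                        channel = "ms2", start_time_s = 0,
                        present = !is.na(intensity)) {
  intensity <- as.numeric(intensity)
  if (frame_interval_s <= 0) stop("frame_interval_s must be > 0")
  if (length(present) != length(intensity))
    stop("present flag length must match intensity")
  if (any(present & !is.finite(intensity)))
    stop("present frames must carry finite intensities")
  structure(list(nucleus_id = nucleus_id, channel = channel,
                 frame_interval_s = frame_interval_s,
                 start_time_s = start_time_s,
                 intensity = intensity, present = present),
            class = "fluor_trace")
}

#' Frame times of a trace, in seconds
#' @param trace A `fluor_trace`.
#' @export
trace_times <- function(trace) {
  trace$start_time_s +
    seq(0, by = trace$frame_interval_s, length.out = length(trace$intensity))
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("<fluor_trace> %s/%s: %d frames @ %gs, %d missing\n",
              x$nucleus_id, x$channel, length(x$intensity),
              x$frame_interval_s, sum(!x$present)))
  invisible(x)
}

#' @export
length.fluor_trace <- function(x) length(x$intensity)

#' Write a set of traces to the CSV trace-table dialect
#'
#' Columns: nucleus_id, frame, time_s, channel, intensity, x_um, y_um, z_um.
#' Missing frames are written with empty intensity. Frames are 0-based.
#'
#' @param traces A list of `fluor_trace` objects.
#' @param path Output CSV path.
#' @param positions Optional data.frame with columns nucleus_id, x_um, y_um,
#'   z_um giving a static position per nucleus; defaults to zeros.
#' @export
write_trace_table <- function(traces, path, positions = NULL) {
  rows <- lapply(traces, function(tr) {
    n <- length(tr$intensity)
    data.frame(nucleus_id = tr$nucleus_id, frame = seq_len(n) - 1L,
               time_s = trace_times(tr), channel = tr$channel,
               intensity = ifelse(tr$present, tr$intensity, NA_real_),
               x_um = 0, y_um = 0, z_um = 0)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(positions)) {
    idx <- match(tab$nucleus_id, positions$nucleus_id)
    for (col in c("x_um", "y_um", "z_um"))
      if (col %in% names(positions)) tab[[col]] <- positions[[col]][idx]
  }
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  invisible(tab)
}

#' Read a CSV trace table into a list of traces
#'
#' @param path CSV path in the dialect of [write_trace_table()].
#' @return Named list of `fluor_trace` objects (one per nucleus x channel).
#' @export
read_trace_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("nucleus_id", "frame", "time_s", "channel", "intensity")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("trace table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  key <- interaction(tab$nucleus_id, tab$channel, drop = TRUE)
  out <- lapply(split(tab, key), function(d) {
    d <- d[order(d$frame), ]
    dt <- if (nrow(d) > 1) diff(d$time_s[1:2]) else 1
    fluor_trace(d$intensity, frame_interval_s = dt,
                nucleus_id = d$nucleus_id[1], channel = d$channel[1],
                start_time_s = d$time_s[1])
  })
  out
}
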