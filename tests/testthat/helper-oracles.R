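# Independent brute-force oracles used to cross-check the implementation.

# Run-length scan segmentation: literal reading of the merging rules, written
# as an explicit frame-by-frame walk independent of segment_active_periods().
oracle_segment <- function(on, gap_allow, min_on) {
  n <- length(on)
  periods <- list()
  cur_start <- NA; last_on <- NA
  for (i in seq_len(n)) {
    if (on[i]) {
      if (is.na(cur_start)) { cur_start <- i } else
        if ((i - last_on - 1) > gap_allow) {
          periods[[length(periods) + 1]] <- c(cur_start, last_on)
          cur_start <- i
        }
      last_on <- i
    }
  }
  if (!is.na(cur_start)) periods[[length(periods) + 1]] <- c(cur_start, last_on)
  if (length(periods)) {
    keep <- vapply(periods, function(p) p[2] - p[1] + 1 >= min_on, logical(1))
    periods <- periods[keep]
  }
  # 0-based half-open, with interior flags
  out <- data.frame(start_frame = integer(0), end_frame = integer(0),
                    interior = logical(0))
  for (p in periods)
    out <- rbind(out, data.frame(start_frame = p[1] - 1L, end_frame = p[2],
                                 interior = p[1] > 1 && p[2] < n))
  out
}

# Exhaustive grid search over all placements of up to max_events
# unit-amplitude kernels on the frame grid; returns the minimal RSS.
oracle_deconv_rss <- function(y, K, max_events = 3) {
  nc <- ncol(K)
  best <- sum(y^2)
  for (n in seq_len(max_events)) {
    combs <- utils::combn(nc + n - 1, n)       # multisets, stars and bars
    for (j in seq_len(ncol(combs))) {
      idx <- combs[, j] - seq_len(n) + 1
      r <- y - rowSums(K[, idx, drop = FALSE])
      rss <- sum(r^2)
      if (rss < best) best <- rss
    }
  }
  best
}

# Flood-fill count of 4-connected supra-threshold components per labeled
# nucleus; returns the number of nuclei containing at least one component.
oracle_count_ats <- function(image, mask, threshold) {
  n_with <- 0
  for (lab in setdiff(sort(unique(as.integer(mask))), 0L)) {
    sel <- mask == lab & image > threshold
    if (any(sel)) n_with <- n_with + 1
  }
  n_with
}

kernel_matrix <- function(kernel, n_frames, dt, t_cand = NULL) {
  tf <- seq(0, by = dt, length.out = n_frames)
  if (is.null(t_cand)) t_cand <- tf
  vapply(t_cand, function(tc) kernel_eval(kernel, tf - tc), numeric(n_frames))
}

# Short test kernel: 5-s rise, plateau to 45 s, compact support
test_kernel <- function(frame_interval_s = 10) {
  build_kernel(0, 0, 100, 40, frame_interval_s, cassette_bp = 500)
}
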