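make_spots <- function(frames, id = "n1", intensity = 10) {
  data.frame(nucleus_id = id, frame = frames, intensity = intensity)
}

test_that("track filtering applies the detection-count and gap rules at their boundaries", {
  # exactly 5 detected frames: discarded ("more than five" required)
  expect_length(filter_tracks(make_spots(0:4)), 0)
  # 6 frames with an internal 2-frame gap: retained
  kept <- filter_tracks(make_spots(c(0, 1, 2, 5, 6, 7)))
  expect_length(kept, 1)
  expect_equal(sum(!kept[[1]]$present), 2)
  # 3-frame internal gap: discarded
  expect_length(filter_tracks(make_spots(c(0:5, 9:12))), 0)
})

test_that("boundary-censored tracks are dropped when nucleus spans are known", {
  spans <- data.frame(nucleus_id = c("a", "b", "c"),
                      first_frame = 0, last_frame = 50)
  spots <- rbind(make_spots(0:10, "a"),    # starts with the nucleus track
                 make_spots(40:50, "b"),   # ends with the nucleus track
                 make_spots(10:20, "c"))   # strictly inside
  kept <- filter_tracks(spots, nucleus_spans = spans)
  expect_equal(names(kept), "c")
})

test_that("short gaps are filled with the flanking mean, long and edge gaps are not", {
  tr <- fluor_trace(c(10, NA, 20), 20)
  expect_equal(interpolate_short_gaps(tr)$intensity, c(10, 15, 20))
  tr4 <- fluor_trace(c(10, rep(NA, 4), 20), 20)
  expect_equal(interpolate_short_gaps(tr4)$intensity, c(10, rep(15, 4), 20))
  tr5 <- fluor_trace(c(10, rep(NA, 5), 20), 20)
  out5 <- interpolate_short_gaps(tr5)
  expect_equal(sum(!out5$present), 5)
  edge <- fluor_trace(c(NA, 10, 20), 20)
  expect_equal(sum(!interpolate_short_gaps(edge)$present), 1)
})

test_that("active-period segmentation merges sub-threshold gaps at the documented boundary", {
  mk <- function(on) fluor_trace(ifelse(on, 10, 0), 20)
  on1 <- rep(FALSE, 60); on1[1:11] <- TRUE; on1[32:41] <- TRUE  # 20-frame gap
  p1 <- segment_active_periods(mk(on1), threshold = 1)
  expect_equal(nrow(p1), 1)
  on2 <- rep(FALSE, 62); on2[1:11] <- TRUE; on2[33:42] <- TRUE  # 21-frame gap
  p2 <- segment_active_periods(mk(on2), threshold = 1)
  expect_equal(nrow(p2), 2)
  # a run touching the trace start is not interior
  expect_false(p1$interior[1])
  expect_false(p2$interior[1]); expect_true(p2$interior[2])
  # one inactive period lies between the two active ones
  expect_equal(nrow(attr(p2, "inactive_periods")), 1)
  # all-OFF trace: empty set
  expect_equal(nrow(segment_active_periods(mk(rep(FALSE, 30)), threshold = 1)), 0)
  # the merge window is fewer than 21 frames, i.e. 7 min at 20-s frames
  expect_equal(attr(p1, "merge_lt_frames"), 21L)
  expect_equal(attr(p1, "merge_window_s"), 420)
})

test_that("segmentation equals the brute-force run-length oracle on random inputs", {
  set.seed(101)
  for (rep in 1:120) {
    n <- sample(10:200, 1)
    on <- runif(n) < runif(1, 0.1, 0.9)
    gap_allow <- sample(0:25, 1)
    min_on <- sample(1:6, 1)
    tr <- fluor_trace(ifelse(on, 5, 0), 20)
    got <- segment_active_periods(tr, gap_allow, min_on, threshold = 1)
    want <- oracle_segment(on, gap_allow, min_on)
    expect_equal(as.data.frame(got)[, c("start_frame", "end_frame", "interior")],
                 want, ignore_attr = TRUE)
  }
})

test_that("widening the merge window never increases the number of active periods", {
  set.seed(17)
  for (rep in 1:20) {
    on <- runif(150) < 0.4
    tr <- fluor_trace(ifelse(on, 5, 0), 20)
    counts <- vapply(c(0, 2, 5, 10, 20, 40), function(g)
      nrow(segment_active_periods(tr, g, 1, threshold = 1)), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("proportion active counts onsets per bin over all nuclei", {
  quiet <- lapply(1:4, function(i) fluor_trace(rep(0, 60), 20, paste0("q", i)))
  pa0 <- proportion_active(quiet, threshold = 1)
  expect_true(all(pa0$fraction == 0))
  expect_equal(nrow(pa0), 12)

  mk_onset <- function(frame_on, id) {
    x <- rep(0, 90); x[(frame_on + 1):(frame_on + 10)] <- 10
    fluor_trace(x, 20, id)
  }
  traces <- c(lapply(1:3, function(i) mk_onset(20, paste0("on", i))),  # 400 s, bin 2
              lapply(1:7, function(i) fluor_trace(rep(0, 90), 20, paste0("off", i))))
  pa <- proportion_active(traces, threshold = 1)
  expect_equal(pa$fraction[pa$bin_start_min == 5], 0.3)
  expect_equal(sum(pa$fraction), 0.3)
  # invariant to trace ordering, bounded in [0, 1]
  pa_rev <- proportion_active(rev(traces), threshold = 1)
  expect_equal(pa$fraction, pa_rev$fraction)
  expect_true(all(pa$fraction >= 0 & pa$fraction <= 1))
  expect_error(proportion_active(list()), "at least one")
})

test_that("onset alignment zero-fills ended traces before averaging", {
  one <- fluor_trace(c(0, 0, 5, 6, 7), 20)
  al1 <- align_onsets(list(one), threshold = 1, min_on_frames = 3)
  expect_equal(al1$mean, c(5, 6, 7))
  expect_equal(al1$sem, c(0, 0, 0))

  shifted <- fluor_trace(c(0, 5, 6, 7, 0), 20)
  al2 <- align_onsets(list(one, shifted), threshold = 1, min_on_frames = 3)
  expect_equal(al2$mean[1:3], c(5, 6, 7))

  # hand computation: onset-aligned lengths 3 and 5, zero-filled to width 5
  a <- fluor_trace(c(4, 4, 4), 20)            # active from frame 0
  b <- fluor_trace(c(6, 6, 6, 6, 6), 20)
  al3 <- align_onsets(list(a, b), threshold = 1, min_on_frames = 3)
  expect_equal(al3$mean, c(5, 5, 5, 3, 3))
  expect_equal(al3$n, 2)
})

test_that("normalization subtracts the minimum and median-filters", {
  flat <- normalize_trace(fluor_trace(c(5, 5, 5), 20))
  expect_equal(flat$intensity, c(0, 0, 0))
  spike <- normalize_trace(fluor_trace(c(3, 10, 3), 20))
  expect_equal(spike$intensity, c(0, 0, 0))  # 3-point median removes the spike
  # idempotent on monotone traces (median filter is the identity there)
  mono <- fluor_trace(c(2, 4, 7, 9, 12), 20)
  once <- normalize_trace(mono)
  expect_equal(normalize_trace(once)$intensity, once$intensity)
  expect_equal(min(once$intensity), 0)
})
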