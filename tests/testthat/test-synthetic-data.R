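test_that("an absorbing ON state yields a single segment spanning the duration", {
  k <- promoter_kinetics(0.2, 0, 0, 0, 0)
  p <- simulate_promoter_path(k, 500, initial_state = "ON", seed = 1)
  expect_equal(nrow(p), 1)
  expect_equal(p$state, "ON")
  expect_equal(c(p$start_s, p$end_s), c(0, 500))
})

test_that("state paths are contiguous and ergodic toward the closed-form pON", {
  k <- promoter_kinetics(0.2, 0.05, 0.1, 0.005, 0.01)
  expect_equal(k$p_on, 0.5)
  p <- simulate_promoter_path(k, 1e5, seed = 7)
  expect_equal(p$start_s[1], 0)
  expect_equal(p$end_s[nrow(p)], 1e5)
  expect_true(all(abs(p$start_s[-1] - p$end_s[-nrow(p)]) < 1e-9))
  expect_lt(abs(on_fraction(p) - k$p_on) / k$p_on, 0.02)
})

test_that("OFF sojourn times average to the reciprocal exit rate", {
  k <- default_kinetics()
  p <- simulate_promoter_path(k, 6e4, seed = 3)
  off1 <- p[p$state == "OFF1", ]
  off1 <- off1[off1$end_s < attr(p, "duration_s"), ]  # drop truncated tail
  expect_gt(nrow(off1), 500)
  expect_lt(abs(mean(off1$end_s - off1$start_s) - 1 / k$k1_plus) /
              (1 / k$k1_plus), 0.1)
})

test_that("initiation sampling is Poisson on ON segments", {
  k <- default_kinetics()
  p <- simulate_promoter_path(k, 2e4, seed = 5)
  expect_length(sample_initiations(p, 0, seed = 1)$times_s, 0)
  ev <- sample_initiations(p, k$k_ini, seed = 2)
  on_time <- on_fraction(p) * 2e4
  mu <- k$k_ini * on_time
  expect_lt(abs(length(ev$times_s) - mu), 3 * sqrt(mu))
  # all events fall inside ON segments
  expect_true(all(state_at(p, ev$times_s - 1e-9) == "ON"))
})

test_that("inter-initiation waits follow the analytic phase-type law", {
  k <- default_kinetics()
  p <- simulate_promoter_path(k, 3e4, seed = 11)
  ev <- sample_initiations(p, k$k_ini, seed = 12)
  w <- waiting_times(ev)
  expect_gt(length(w), 2000)
  ph <- phase_type_survival(k)
  ks <- suppressWarnings(stats::ks.test(w, ph$cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("trace rendering is the kernel sum: zero, single-event and linearity cases", {
  kern <- kernel_preset("loops-near-TSS", 20)
  empty <- render_ms2_trace(initiation_events(numeric(0)), kern, 20,
                            duration_s = 600)
  expect_true(all(empty$intensity == 0))

  one <- render_ms2_trace(initiation_events(100), kern, 20, duration_s = 600)
  tf <- trace_times(one)
  expect_equal(one$intensity, kernel_eval(kern, tf - 100))

  two <- render_ms2_trace(initiation_events(c(100, 180)), kern, 20,
                          duration_s = 600)
  other <- render_ms2_trace(initiation_events(180), kern, 20, duration_s = 600)
  expect_equal(two$intensity, one$intensity + other$intensity)

  # time invariance: shifting all events shifts the trace by the same amount
  shifted <- render_ms2_trace(initiation_events(100 + 40), kern, 20,
                              duration_s = 600)
  expect_equal(shifted$intensity[3:31], one$intensity[1:29])
})

test_that("hub traces lead promoter activity by the planted lag", {
  k <- default_kinetics()
  peaks <- vapply(1:5, function(i) {
    p <- simulate_promoter_path(k, 3600, seed = 40 + i)
    hub <- generate_hub_trace(p, lead_lag_s = 120, gain = 1, baseline = 0,
                              noise_sd = 0.02, frame_interval_s = 30,
                              seed = 50 + i)
    act <- as.numeric(state_at(p, seq(0, 3600, by = 30)) == "ON")
    attr(cross_correlate(hub$intensity, 8, y = act), "peak_lag_frames")
  }, numeric(1))
  # 120 s at 30-s frames = 4 frames, hub leading (negative lag)
  expect_true(all(abs(peaks - (-4)) <= 1))
  expect_equal(median(peaks), -4)

  p <- simulate_promoter_path(k, 1200, seed = 1)
  expect_error(generate_hub_trace(p, lead_lag_s = -5), "lead_lag")
  expect_error(generate_hub_trace(p, 0, gain = -1), "gain")
  # zero lag, no noise: hub is a monotone transform of smoothed activity
  hub0 <- generate_hub_trace(p, 0, gain = 2, baseline = 1, noise_sd = 0,
                             frame_interval_s = 30)
  expect_true(all(hub0$intensity >= 1 & hub0$intensity <= 3))
})

test_that("two-allele populations reproduce the closed-form detection ratio", {
  none <- generate_two_allele_population(1000, 0, seed = 1)
  expect_equal(attr(none, "smfish_fraction"), 0)
  expect_equal(attr(none, "ms2_fraction"), 0)

  all_on <- generate_two_allele_population(1000, 1, seed = 1)
  expect_equal(attr(all_on, "detection_ratio"), 1)

  p <- 0.05
  pop <- generate_two_allele_population(1e5, p, seed = 9)
  # MS2 sees only the tagged allele; smFISH sees either: ratio 1/(2-p)
  expect_lt(abs(attr(pop, "detection_ratio") - 1 / (2 - p)), 0.026)
})

test_that("smFISH spot tables scale with molecule count and keep the median", {
  exact <- generate_smfish_spots(7, c(1, 1, 35), noise_cv = 0)
  expect_equal(exact$intensity, c(7, 7, 245))
  spots <- generate_smfish_spots(100, rep(1, 1e4), noise_cv = 0.2, seed = 3)
  expect_lt(abs(stats::median(spots$intensity) - 100) / 100, 0.02)
})

test_that("all generators are seed-deterministic", {
  k <- default_kinetics()
  expect_identical(simulate_promoter_path(k, 5000, seed = 42),
                   simulate_promoter_path(k, 5000, seed = 42))
  p <- simulate_promoter_path(k, 5000, seed = 42)
  expect_identical(sample_initiations(p, k$k_ini, seed = 7),
                   sample_initiations(p, k$k_ini, seed = 7))
  expect_identical(generate_hub_trace(p, 120, seed = 7, noise_sd = 0.1),
                   generate_hub_trace(p, 120, seed = 7, noise_sd = 0.1))
  expect_identical(generate_smfish_spots(10, 1:50, 0.3, seed = 5),
                   generate_smfish_spots(10, 1:50, 0.3, seed = 5))
  s1 <- synthetic_scene(seed = 8); s2 <- synthetic_scene(seed = 8)
  expect_identical(render_scene(s1, seed = 9), render_scene(s2, seed = 9))
})
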