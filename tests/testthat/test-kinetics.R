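test_that("waiting times are computed within active periods only", {
  per <- data.frame(start_s = 0, end_s = 100)
  expect_equal(waiting_times(c(0, 10, 25), per), c(10, 15))
  # events split across two periods contribute no cross-period wait
  per2 <- data.frame(start_s = c(0, 200), end_s = c(100, 300))
  expect_equal(waiting_times(c(10, 20, 210, 260), per2), c(10, 50))
  # fewer than 2 events per period: empty sample
  expect_length(waiting_times(c(10, 210), per2), 0)
})

test_that("the empirical survival reproduces the hand-computed Greenwood variance", {
  w <- c(2, 5, 9, 14)
  sc <- empirical_survival(w)
  expect_equal(sc$surv[1], 0.75)
  expect_equal(sc$var[1], 0.75^2 * (1 / (4 * 3)))
  expect_equal(sc$var[1], 0.046875)
  expect_true(all(diff(sc$surv) <= 0))
  expect_true(all(sc$lower <= sc$surv & sc$surv <= sc$upper))
  # variance undefined at the final step (all at risk die)
  expect_true(is.na(sc$var[4]))
  expect_error(empirical_survival(5), "at least 2")
})

test_that("Greenwood bands cover an exponential truth at close to nominal rate", {
  set.seed(12)
  w <- rexp(2000, 1 / 30)
  sc <- empirical_survival(w)
  truth <- exp(-sc$time / 30)
  covered <- truth >= sc$lower & truth <= sc$upper
  expect_gte(mean(covered[is.finite(sc$var)]), 0.93)
})

test_that("the cumulative-integral initializer recovers exact decay constants", {
  t1 <- seq(0.01, 60, by = 0.01)
  i1 <- init_multiexp(t1, exp(-0.1 * t1), 1)
  expect_lt(abs(i1$rates + 0.1) / 0.1, 1e-6)

  t2 <- seq(0.01, 400, by = 0.05)
  s2 <- 0.7 * exp(-0.2 * t2) + 0.3 * exp(-0.01 * t2)
  i2 <- init_multiexp(t2, s2, 2)
  expect_lt(abs(i2$rates[1] + 0.2), 1e-4)
  expect_lt(abs(i2$rates[2] + 0.01), 1e-4)
  expect_false(i2$fallback)
  # components canonicalized by |rate| descending
  expect_true(all(diff(abs(i2$rates)) <= 0))
  expect_equal(i2$amplitudes, c(0.7, 0.3), tolerance = 1e-3)
})

test_that("the constrained fit reproduces exact multi-exponential curves within 1%", {
  A <- c(0.5, 0.45, 0.05); L <- c(-0.5, -0.09, -0.007)
  tt <- sort(c(seq(0.2, 20, by = 0.2), seq(21, 600, by = 3)))
  curve <- structure(
    data.frame(time = tt,
               surv = sapply(tt, function(t) sum(A * exp(L * t))),
               var = 1e-6, lower = 0, upper = 1),
    class = c("survival_curve", "data.frame"),
    waits = NULL)
  fit <- fit_multiexp(curve, 3)
  expect_equal(fit$amplitudes, A, tolerance = 0.01)
  expect_equal(fit$rates, L, tolerance = 0.01)
  expect_equal(sum(fit$amplitudes), 1, tolerance = 1e-9)
  expect_true(all(fit$rates < 0))
})

test_that("more components never fit worse (nesting of the MSD objective)", {
  k <- default_kinetics()
  p <- simulate_promoter_path(k, 15000, seed = 3)
  ev <- sample_initiations(p, k$k_ini, seed = 4)
  sc <- empirical_survival(waiting_times(ev))
  sel <- select_model(sc, candidates = 1:3)
  msds <- vapply(sel$fits, `[[`, numeric(1), "msd")
  expect_true(all(diff(msds) <= 1e-12))
})

test_that("model selection finds three states in the bursting regime and none extra for Poisson", {
  k <- default_kinetics()   # OFF means 6 s and 145 s
  p <- simulate_promoter_path(k, 28000, seed = 1)
  ev <- sample_initiations(p, k$k_ini, seed = 2)
  sel <- select_model(empirical_survival(waiting_times(ev)))
  expect_equal(sel$n_states, 3)
  expect_true(sel$passed)
  expect_false(sel$fits[["2"]]$ci_pass)
  expect_true(sel$fits[["3"]]$ci_pass)

  # constant-rate initiation: one exponential suffices, no spurious states
  pois <- promoter_kinetics(0.1, 0, 1, 0, 1)
  pp <- simulate_promoter_path(pois, 22000, initial_state = "ON", seed = 42)
  evp <- sample_initiations(pp, 0.1, seed = 43)
  selp <- select_model(empirical_survival(waiting_times(evp)), candidates = 1:3)
  expect_equal(selp$n_states, 1)
})

test_that("selection of the true model does not degrade with more data", {
  k <- default_kinetics()
  freq <- vapply(c(3500, 28000), function(dur) {
    hits <- vapply(1:8, function(i) {
      p <- simulate_promoter_path(k, dur, seed = 100 * dur + i)
      ev <- sample_initiations(p, k$k_ini, seed = 100 * dur + i + 1)
      w <- waiting_times(ev)
      if (length(w) < 25) return(NA)
      sel <- select_model(empirical_survival(w))
      sel$n_states == 3 && sel$passed
    }, logical(1))
    mean(hits, na.rm = TRUE)
  }, numeric(1))
  expect_gte(freq[2], freq[1])
})

test_that("windowed mean inter-initiation intervals flag stationarity correctly", {
  set.seed(61)
  # homogeneous Poisson events: stable, pooled tau near the rate reciprocal
  ev <- cumsum(rexp(800, 1 / 8))
  ss <- steady_state_tau(ev, window_frames = 4, frame_interval_s = 20,
                         n_boot = 200, seed = 1)
  expect_true(ss$stable)
  expect_equal(ss$window_width_s, 80)
  expect_lt(abs(ss$pooled_tau_s - 8) / 8, 0.1)
  expect_true(all(ss$windows$lower <= ss$windows$tau_s &
                    ss$windows$tau_s <= ss$windows$upper))

  # rate doubled mid-trace: unstable
  ev2 <- c(cumsum(rexp(400, 1 / 12)))
  ev2 <- c(ev2, max(ev2) + cumsum(rexp(800, 1 / 4)))
  ss2 <- steady_state_tau(ev2, window_frames = 4, frame_interval_s = 20,
                          n_boot = 200, seed = 2)
  expect_false(ss2$stable)
})

test_that("the pooled interval matches the reciprocal of pON times k_ini", {
  k <- default_kinetics()
  p <- simulate_promoter_path(k, 4e4, seed = 9)
  ev <- sample_initiations(p, k$k_ini, seed = 10)
  ss <- steady_state_tau(ev, n_boot = 50, seed = 3)
  expect_lt(abs(ss$pooled_tau_s - 1 / (k$p_on * k$k_ini)) /
              (1 / (k$p_on * k$k_ini)), 0.1)
})
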