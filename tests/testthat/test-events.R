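test_that("estimate_cadence finds the dominant stride frequency", {
  fs <- 200
  t <- seq(0, 60, by = 1 / fs)
  for (f0 in c(0.7, 0.9, 1.2)) {
    est <- estimate_cadence(sin(2 * pi * f0 * t), fs)
    expect_equal(est$stride_frequency, f0, tolerance = 0.01)
    expect_equal(est$cadence, 60 * est$stride_frequency)
  }
  expect_error(estimate_cadence(rep(0, 60 * fs), fs), "no locomotion")
  expect_error(estimate_cadence(sin(t[1:100]), fs), "no locomotion")
})

test_that("detect_strides recovers the planted mid-swing peaks", {
  tr <- short_trial()
  w <- sagittal_gyro(tr$left)
  fs <- tr$left$fs
  mask <- walking_mask(w, fs)
  cad <- estimate_cadence(w, fs, mask = mask)
  expect_equal(cad$stride_frequency, 1 / tr$profile$stride_duration_mean,
               tolerance = 0.03)
  ms <- detect_strides(w, fs, cad$stride_frequency, mask = mask)
  truth_ms <- tr$truth$events$left$ms
  expect_equal(length(ms), length(truth_ms))
  expect_lt(max(abs(ms - truth_ms)), 0.02)
})

test_that("detect_strides returns nothing at rest", {
  expect_length(detect_strides(rnorm(2000, 0, 0.01), 200, 0.9), 0)
})

test_that("gait events recover planted initial and final contacts", {
  tr <- short_trial()
  for (side in c("left", "right")) {
    w <- sagittal_gyro(tr[[side]])
    fs <- tr[[side]]$fs
    mask <- walking_mask(w, fs)
    cad <- estimate_cadence(w, fs, mask = mask)
    ms <- detect_strides(w, fs, cad$stride_frequency, mask = mask)
    ev <- detect_gait_events(w, fs, ms, accel = tr[[side]]$accel)
    truth <- tr$truth$events[[side]]
    # events are defined per mid-swing interval; align on stride count
    n <- length(ev$ic)
    expect_gte(n, length(truth$ic) - 2)
    match_ic <- vapply(ev$ic, function(x) min(abs(truth$ic - x)), 0)
    match_fc <- vapply(ev$fc, function(x) min(abs(truth$fc - x)), 0)
    expect_lt(max(match_ic), 0.02)
    expect_lt(max(match_fc), 0.02)
    expect_true(all(ev$ic < ev$fc))
  }
  expect_error(detect_gait_events(rnorm(100), 200, numeric(1)), "mid-swing")
})

test_that("rest gaps between mid-swing peaks are skipped, not bridged", {
  p <- gait_profile(trial_duration = 120, rest_breaks = list(c(50, 15)))
  tr <- simulate_trial(p, noise_model(seed = 3))
  w <- sagittal_gyro(tr$left)
  fs <- tr$left$fs
  mask <- walking_mask(w, fs)
  cad <- estimate_cadence(w, fs, mask = mask)
  ms <- detect_strides(w, fs, cad$stride_frequency, mask = mask)
  ev <- detect_gait_events(w, fs, ms, accel = tr$left$accel)
  expect_gte(ev$dropped, 1L)
  # no fabricated stride spans the rest window
  expect_false(any(ev$ic < 50 & ev$fc > 58))
})

test_that("temporal parameters match hand-built alternating events", {
  evs <- make_alternating_events(n = 20, D = 1.2, swing = 0.4)
  tp <- compute_temporal_params(evs$left, evs$right)
  expect_s3_class(tp, "temporal_params")
  expect_gt(nrow(tp$left), 10)
  expect_equal(tp$left$duration, rep(1.2, nrow(tp$left)))
  expect_equal(tp$left$step_duration, rep(0.6, nrow(tp$left)))
  # swing% = (next IC - FC)/stride: FC at 0.6 D, so swing = 40%
  expect_equal(unique(round(tp$left$swing_pct, 9)), 40)
  # alternating gait: double support = 1 - 2 * swing = 20% (the first stride
  # has no preceding contralateral final contact, hence NA)
  ds <- tp$left$double_support_pct
  expect_equal(unique(round(ds[!is.na(ds)], 9)), 20)
  expect_equal(unique(round(tp$right$swing_pct, 9)), 40)
  expect_equal(tp$cadence_series$cadence, rep(50, nrow(tp$left)))
})

test_that("temporal parameters recover the planted phase fractions", {
  tr <- short_trial()
  run <- function(side) {
    w <- sagittal_gyro(tr[[side]])
    fs <- tr[[side]]$fs
    mask <- walking_mask(w, fs)
    cad <- estimate_cadence(w, fs, mask = mask)
    ms <- detect_strides(w, fs, cad$stride_frequency, mask = mask)
    detect_gait_events(w, fs, ms, accel = tr[[side]]$accel)
  }
  tp <- compute_temporal_params(run("left"), run("right"))
  expect_equal(mean(tp$left$duration), 1.1, tolerance = 0.02)
  expect_equal(mean(tp$left$swing_pct), 40, tolerance = 0.05)
  expect_equal(mean(tp$left$double_support_pct, na.rm = TRUE), 20,
               tolerance = 0.08)
})
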