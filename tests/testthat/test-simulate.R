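test_that("gait_profile validates its arguments", {
  expect_s3_class(gait_profile(), "gait_profile")
  expect_equal(gait_profile(swing_fraction = 0.4)$double_support_fraction, 0.2)
  expect_equal(gait_profile(swing_fraction = 0.38)$double_support_fraction,
               0.24)
  expect_error(gait_profile(swing_fraction = 0.4,
                            double_support_fraction = 0.3), "inconsistent")
  expect_error(gait_profile(swing_fraction = 0.55), "swing_fraction")
  expect_error(gait_profile(stride_length_mean = -1), "geometry")
  expect_error(gait_profile(asym_factors = list(bogus = 1.1)), "asym_factors")
  expect_error(gait_profile(asym_factors = list(stride_length = -0.1)), "> 0")
  expect_error(gait_profile(rest_breaks = list(c(10, 20), c(15, 5))),
               "overlap")
  expect_error(simulate_trial(gait_profile(trial_duration = 3)), "too short")
})

test_that("noise_model validates and simulate_trial is bit-reproducible", {
  expect_error(noise_model(accel_noise_sd = -1), ">= 0")
  p <- gait_profile(trial_duration = 20)
  nm <- noise_model(accel_noise_sd = 0.1, gyro_noise_sd = 0.05,
                    gyro_bias = 0.01, seed = 5)
  a <- simulate_trial(p, nm)
  b <- simulate_trial(p, nm)
  expect_identical(a$left$accel, b$left$accel)
  expect_identical(a$right$gyro, b$right$gyro)
  expect_identical(a$truth$strides$left$length, b$truth$strides$left$length)
  c_ <- simulate_trial(p, noise_model(accel_noise_sd = 0.1, gyro_noise_sd = 0.05,
                                      gyro_bias = 0.01, seed = 6))
  expect_false(identical(a$left$accel, c_$left$accel))
})

test_that("planted truth is internally consistent", {
  tr <- short_trial()
  s <- tr$truth$strides$left
  p <- tr$profile
  expect_gt(nrow(s), 40)
  # event ordering and phase fractions per stride
  expect_true(all(s$ic < s$fc & s$fc < s$ms))
  expect_equal(s$fc - s$ic, (1 - s$swing_fraction) * s$duration,
               tolerance = 1e-12)
  # planted means match the profile (lognormal multipliers are mean 1)
  expect_equal(mean(s$duration), p$stride_duration_mean, tolerance = 0.02)
  expect_equal(mean(s$length), p$stride_length_mean, tolerance = 0.02)
  # right initial contacts interleave the left ones
  r <- tr$truth$strides$right
  for (j in seq_len(min(10, nrow(r)))) {
    k <- which(s$ic < r$ic[j] & s$ic + s$duration > r$ic[j])
    expect_length(k, 1)
  }
})

test_that("the foot is stationary throughout stance and moves in swing", {
  tr <- short_trial()
  t <- tr$truth$time
  pos <- tr$truth$path$left
  s <- tr$truth$strides$left
  k <- 5L
  stance <- t >= s$ic[k] & t <= s$fc[k] - 1e-9
  expect_lt(max(apply(pos[stance, , drop = FALSE], 2,
                      function(v) diff(range(v)))), 1e-12)
  swing <- t > s$fc[k] & t < s$ic[k] + s$duration[k]
  expect_gt(diff(range(pos[swing, 1])), 0.9 * s$length[k])
  # per-stride displacement equals the planted stride length exactly
  i_end <- max(which(stance))
  nxt <- t >= s$ic[k + 1L] & t <= s$fc[k + 1L]
  expect_equal(pos[which(nxt)[1], 1] - pos[i_end, 1], s$length[k],
               tolerance = 1e-9)
})

test_that("gyro channel integrates to the planted shank angle", {
  tr <- short_trial()
  th <- gaitsci:::cumtrapz(tr$truth$time, tr$left$gyro[, 3])
  expect_equal(th, tr$truth$theta$left, tolerance = 1e-9)
  # net rotation per stride is ~0, so the angle stays bounded
  expect_lt(max(abs(tr$truth$theta$left)), 1.5)
})

test_that("rest breaks leave a gap with no strides", {
  p <- gait_profile(trial_duration = 90, rest_breaks = list(c(40, 10)))
  tr <- simulate_trial(p, noise_model(seed = 3))
  s <- tr$truth$strides$left
  expect_false(any(s$ic > 39 & s$ic < 50))
  expect_true(any(s$ic < 39) && any(s$ic > 50))
  # distinct bouts on both sides of the rest
  expect_gt(length(unique(s$bout)), 1)
})

test_that("asymmetry factors scale the left side as planted", {
  p <- gait_profile(trial_duration = 60,
                    asym_factors = list(stride_length = 1.2,
                                        swing_fraction = 0.9))
  tr <- simulate_trial(p, noise_model(seed = 9))
  sl <- tr$truth$strides$left
  sr <- tr$truth$strides$right
  expect_equal(mean(sl$length) / mean(sr$length), 1.2, tolerance = 0.03)
  expect_equal(unique(sl$swing_fraction), 0.4 * 0.9)
  expect_equal(unique(sr$swing_fraction), 0.4)
})

test_that("speed drift shows up in the planted stride lengths", {
  p <- gait_profile(trial_duration = 240, stride_duration_cv = 0,
                    stride_length_cv = 0, speed_drift = -0.05)
  tr <- simulate_trial(p, noise_model(seed = 2))
  s <- tr$truth$strides$left
  fit <- stats::coef(stats::lm(s$length ~ I(s$ic + s$duration / 2)))
  # planted: length multiplier 1 + drift * t / 60
  expect_equal(unname(fit[2] / fit[1]), -0.05 / 60, tolerance = 0.02)
})

test_that("cohort feature simulator plants clusters and validates", {
  expect_error(simulate_cohort_features(list(list(mean = 0, sd = 1, n = 5))),
               "two clusters")
  expect_error(simulate_cohort_features(list(list(mean = c(0, 0), sd = 1, n = 5),
                                             list(mean = 1, sd = 1, n = 5))),
               "dimensionality")
  specs <- list(list(mean = c(0, 0), sd = 0.1, n = 10),
                list(mean = c(5, 5), sd = 0.1, n = 12))
  cf <- simulate_cohort_features(specs, seed = 4, sixmwt = c(500, 200))
  expect_equal(dim(cf$features), c(22, 2))
  expect_identical(cf$labels, rep(1:2, c(10, 12)))
  expect_equal(colMeans(cf$features[cf$labels == 2, ]), c(F1 = 5, F2 = 5),
               tolerance = 0.1)
  expect_gt(mean(cf$sixmwt_distance[cf$labels == 1]),
            mean(cf$sixmwt_distance[cf$labels == 2]))
  expect_identical(simulate_cohort_features(specs, seed = 4)$features,
                   simulate_cohort_features(specs, seed = 4)$features)
})

test_that("longitudinal cohort simulator has the documented structure", {
  coh <- simulate_longitudinal_cohort(seed = 8)
  expect_equal(length(unique(coh$subject_id)), 23)
  expect_equal(nrow(coh), sum(c(rep(2, 10), rep(3, 9), rep(4, 4))))
  expect_true(all(c("day", "sixmwt_distance", "G1", "G10") %in% names(coh)))
  expect_true(all(tapply(coh$day, coh$subject_id, function(d) all(diff(d) > 0))))
  expect_error(simulate_longitudinal_cohort(trials_per_subject = c(1, 1)),
               "two or more")
  expect_error(simulate_longitudinal_cohort(beta = c(1, 2)), "length")
})
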