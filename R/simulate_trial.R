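#' Gait profile for the synthetic trial generator
#'
#' Describes the planted walking pattern of a simulated 6-minute walk test:
#' stride timing, spatial stride geometry, gait-phase fractions, left/right
#' asymmetry, stride-to-stride variability, within-trial speed drift and rest
#' breaks.  In an alternating bipedal gait the double-support fraction is
#' determined by the swing fraction (both feet are grounded exactly when both
#' are in stance, so double support = 1 - 2 x swing); it is therefore derived
#' from `swing_fraction` when not supplied, and an inconsistent pair is an
#' error.
#'
#' @param stride_duration_mean Mean stride duration, s.
#' @param stride_duration_cv Stride-to-stride coefficient of variation of the
#'   duration, as a fraction (0.03 = 3%).
#' @param stride_length_mean Mean stride length, m.
#' @param stride_height_mean Maximum vertical ankle displacement per stride, m.
#' @param stride_width_mean Maximum lateral ankle displacement per stride, m.
#' @param stride_length_cv Stride-to-stride cov of stride length (fraction).
#' @param swing_fraction Swing phase as a fraction of the stride.
#' @param double_support_fraction Both-feet-grounded fraction of the stride;
#'   must equal `1 - 2 * swing_fraction`.  Default derives it.
#' @param asym_factors Named list of left/right multiplicative ratios applied
#'   to the left side; supported names: `stride_length`, `stride_height`,
#'   `stride_width`, `swing_fraction`, `step_duration`.  All must be > 0.
#' @param speed_drift Fractional change of walking speed per minute (e.g.
#'   -0.02 = the walker slows by 2% of the initial speed each minute).
#' @param rest_breaks List of `c(start_s, duration_s)` rest intervals.
#' @param trial_duration Trial length, s (default 360, a 6-minute walk test).
#' @return An object of class `gait_profile`.
#' @export
gait_profile <- function(stride_duration_mean = 1.1,
                         stride_duration_cv = 0.03,
                         stride_length_mean = 1.2,
                         stride_height_mean = 0.12,
                         stride_width_mean = 0.05,
                         stride_length_cv = stride_duration_cv,
                         swing_fraction = 0.4,
                         double_support_fraction = NULL,
                         asym_factors = list(),
                         speed_drift = 0,
                         rest_breaks = list(),
                         trial_duration = 360) {
  if (stride_duration_mean <= 0 || trial_duration <= 0) {
    stop("durations must be > 0")
  }
  if (stride_length_mean <= 0 || stride_height_mean < 0 || stride_width_mean < 0) {
    stop("stride geometry must be positive")
  }
  if (swing_fraction <= 0 || swing_fraction >= 0.5) {
    stop("swing_fraction must lie in (0, 0.5) so a double-support phase exists")
  }
  ds <- 1 - 2 * swing_fraction
  if (!is.null(double_support_fraction)) {
    if (abs(double_support_fraction - ds) > 1e-6) {
      stop(sprintf(paste0("double_support_fraction %.3f is inconsistent with ",
                          "swing_fraction %.3f (alternating gait forces ",
                          "double support = 1 - 2*swing = %.3f)"),
                   double_support_fraction, swing_fraction, ds))
    }
  }
  allowed <- c("stride_length", "stride_height", "stride_width",
               "swing_fraction", "step_duration")
  if (length(asym_factors)) {
    if (is.null(names(asym_factors)) || !all(names(asym_factors) %in% allowed)) {
      stop("asym_factors names must be among: ", paste(allowed, collapse = ", "))
    }
    if (any(unlist(asym_factors) <= 0)) stop("asym factors must be > 0")
  }
  if (length(rest_breaks)) {
    rb <- do.call(rbind, lapply(rest_breaks, function(r) r[1:2]))
    rb <- rb[order(rb[, 1]), , drop = FALSE]
    if (any(rb[, 2] <= 0)) stop("rest durations must be > 0")
    ends <- rb[, 1] + rb[, 2]
    if (nrow(rb) > 1 && any(rb[-1, 1] < ends[-nrow(rb)])) {
      stop("rest breaks overlap")
    }
    rest_breaks <- lapply(seq_len(nrow(rb)), function(i) rb[i, ])
  }
  structure(list(stride_duration_mean = stride_duration_mean,
                 stride_duration_cv = stride_duration_cv,
                 stride_length_mean = stride_length_mean,
                 stride_height_mean = stride_height_mean,
                 stride_width_mean = stride_width_mean,
                 stride_length_cv = stride_length_cv,
                 swing_fraction = swing_fraction,
                 double_support_fraction = ds,
                 asym_factors = asym_factors,
                 speed_drift = speed_drift,
                 rest_breaks = rest_breaks,
                 trial_duration = trial_duration),
            class = "gait_profile")
}

#' Sensor noise model
#'
#' White Gaussian measurement noise plus a constant per-trial gyroscope bias,
#' emulating the thermo-mechanical noise of MEMS inertial sensors.  The same
#' seed reproduces a simulated trial bit for bit.
#'
#' @param accel_noise_sd Accelerometer noise sd, m/s^2.
#' @param gyro_noise_sd Gyroscope noise sd, rad/s.
#' @param gyro_bias Constant gyroscope bias, rad/s, applied to all channels.
#' @param seed Integer RNG seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(accel_noise_sd = 0, gyro_noise_sd = 0, gyro_bias = 0,
                        seed = 1L) {
  if (accel_noise_sd < 0 || gyro_noise_sd < 0) stop("noise sds must be >= 0")
  structure(list(accel_noise_sd = accel_noise_sd, gyro_noise_sd = gyro_noise_sd,
                 gyro_bias = gyro_bias, seed = as.integer(seed)),
            class = "noise_model")
}

# quintic smoothstep: zero 1st and 2nd derivatives at both ends
smoothstep5 <- function(v) 6 * v^5 - 15 * v^4 + 10 * v^3
smoothstep5_dd <- function(v) 120 * v^3 - 180 * v^2 + 60 * v
# symmetric bump peaking at 1 (v = 0.5), zero 1st and 2nd derivatives at ends
bump3 <- function(v) 64 * v^3 * (1 - v)^3
bump3_dd <- function(v) 384 * v * (1 - v) * ((1 - 2 * v)^2 - v * (1 - v))

#' Simulate a two-sensor ankle IMU trial with planted ground truth
#'
#' Generates one 6-minute-walk-test-style trial for a pair of ankle sensors.
#' Each stride's ankle endpoint follows a smooth (C2) closed-loop 3D path that
#' reaches the planted stride length, height and width exactly and is
#' stationary throughout stance (which provides the mid-stance zero-velocity
#' window).  The accelerometer is the exact second time-derivative of that
#' path expressed in a sensor frame whose sagittal tilt follows the shank
#' angle, plus gravity, plus noise; the sagittal gyroscope channel is the
#' shank angular velocity plus bias plus noise.  Both sides share one 200 Hz
#' time base.
#'
#' @param profile A [gait_profile()].
#' @param noise A [noise_model()].
#' @param fs Sampling rate, Hz.
#' @return An object of class `imu_trial`: list with `left` and `right`
#'   [imu_recording()]s and `truth`, a ground-truth list holding per-side
#'   event times (`ic`, `fc`, `ms`), per-stride planted spatial/temporal
#'   parameters, the planted endpoint paths and shank angles, and nominal
#'   per-trial values.
#' @examples
#' trial <- simulate_trial(gait_profile(trial_duration = 30), noise_model(seed = 7))
#' trial$left
#' nrow(trial$truth$strides$left)
#' @export
simulate_trial <- function(profile, noise = noise_model(), fs = 200) {
  stopifnot(inherits(profile, "gait_profile"), inherits(noise, "noise_model"))
  p <- profile
  pad <- 1.0
  if (p$trial_duration < 2 * p$stride_duration_mean + 2 * pad) {
    stop("trial too short")
  }
  with_seed(noise$seed, {
    tl <- build_timeline(p)
    t <- seq(0, p$trial_duration, by = 1 / fs)
    left <- synth_side(t, tl$left, fs)
    right <- synth_side(t, tl$right, fs)
    add_noise <- function(sig) {
      n <- length(t)
      accel <- sig$accel
      gyro <- sig$gyro
      if (noise$accel_noise_sd > 0) {
        accel <- accel + matrix(stats::rnorm(3 * n, 0, noise$accel_noise_sd), n, 3)
      }
      gyro <- gyro + noise$gyro_bias
      if (noise$gyro_noise_sd > 0) {
        gyro <- gyro + matrix(stats::rnorm(3 * n, 0, noise$gyro_noise_sd), n, 3)
      }
      list(accel = accel, gyro = gyro)
    }
    ln <- add_noise(left)
    rn <- add_noise(right)
    truth <- list(
      events = list(left = tl$left$events, right = tl$right$events),
      strides = list(left = tl$left$strides, right = tl$right$strides),
      time = t,
      path = list(left = left$pos, right = right$pos),
      theta = list(left = left$theta, right = right$theta),
      profile_summary = list(
        stride_duration = p$stride_duration_mean,
        stride_length = p$stride_length_mean,
        stride_height = p$stride_height_mean,
        stride_width = p$stride_width_mean,
        swing_pct = 100 * p$swing_fraction,
        double_support_pct = 100 * p$double_support_fraction,
        n_strides = list(left = nrow(tl$left$strides),
                         right = nrow(tl$right$strides))
      )
    )
    structure(list(
      left = imu_recording(t, ln$accel, ln$gyro, side = "left", sensor_id = "simL"),
      right = imu_recording(t, rn$accel, rn$gyro, side = "right", sensor_id = "simR"),
      truth = truth, profile = p, noise = noise
    ), class = "imu_trial")
  })
}

#' @export
print.imu_trial <- function(x, ...) {
  cat(sprintf("<imu_trial> simulated %.0f s walk, %d/%d strides (L/R)\n",
              x$profile$trial_duration,
              nrow(x$truth$strides$left), nrow(x$truth$strides$right)))
  invisible(x)
}

# Places body strides (left IC to next left IC) on the timeline, honouring
# rest breaks at stride boundaries, then derives both feet's stride records.
build_timeline <- function(p) {
  pad <- 1.0
  f <- function(key) p$asym_factors[[key]] %||% 1
  sdlog_T <- sqrt(log(1 + p$stride_duration_cv^2))
  sdlog_L <- sqrt(log(1 + p$stride_length_cv^2))
  rests <- p$rest_breaks
  ri <- 1L
  cursor <- pad
  ics <- numeric(0)   # left initial contacts
  durs <- numeric(0)
  bout <- integer(0)  # bout id per left stride
  b <- 1L
  repeat {
    Tk <- p$stride_duration_mean *
      stats::rlnorm(1, meanlog = -sdlog_T^2 / 2, sdlog = sdlog_T)
    # honour the next rest break: stop walking at its start, resume after
    if (ri <= length(rests) && cursor + Tk > rests[[ri]][1]) {
      cursor <- rests[[ri]][1] + rests[[ri]][2]
      ri <- ri + 1L
      b <- b + 1L
      next
    }
    if (cursor + Tk > p$trial_duration - pad) break
    ics <- c(ics, cursor)
    durs <- c(durs, Tk)
    bout <- c(bout, b)
    cursor <- cursor + Tk
  }
  if (length(ics) < 2L) stop("trial too short")
  phi <- {
    fs_step <- f("step_duration")
    fs_step / (1 + fs_step)   # left-step fraction of the stride
  }
  sw_L <- min(p$swing_fraction * f("swing_fraction"), 0.49)
  sw_R <- p$swing_fraction
  drift <- function(tt) pmax(1 + p$speed_drift * tt / 60, 0.05)

  make_strides <- function(ic, dur, bout, sw, len_mult, h_mult = 1, w_mult = 1) {
    n <- length(ic)
    L <- p$stride_length_mean * len_mult * drift(ic + dur / 2) *
      stats::rlnorm(n, meanlog = -sdlog_L^2 / 2, sdlog = sdlog_L)
    data.frame(
      ic = ic, duration = dur, fc = ic + (1 - sw) * dur,
      ms = ic + (1 - sw / 2) * dur,
      length = L,
      height = p$stride_height_mean * h_mult,
      width = p$stride_width_mean * w_mult,
      swing_fraction = sw, bout = bout
    )
  }
  left <- make_strides(ics, durs, bout, sw_L, f("stride_length"),
                       f("stride_height"), f("stride_width"))
  # right initial contacts: phase phi within each left stride; a right stride
  # needs two consecutive right ICs within the same bout
  ric <- ics + phi * durs
  keep <- which(diff(c(bout, -1L)) == 0L)  # strides with a successor in-bout
  r_ic <- ric[keep]
  r_dur <- ric[keep + 1L] - ric[keep]
  right <- make_strides(r_ic, r_dur, bout[keep], sw_R, 1)
  events_of <- function(s) list(ic = s$ic, fc = s$fc, ms = s$ms)
  list(left = list(strides = left, events = events_of(left), phi = phi),
       right = list(strides = right, events = events_of(right), phi = 1 - phi))
}

# Synthesises one foot's planted path, shank angle and ideal sensor streams.
synth_side <- function(t, side_tl, fs) {
  s <- side_tl$strides
  n <- length(t)
  pos <- matrix(0, n, 3)  # global: x forward, y lateral, z vertical
  acc <- matrix(0, n, 3)
  omega <- numeric(n)
  cur_x <- 0
  fill_from <- 1L
  for (k in seq_len(nrow(s))) {
    ic <- s$ic[k]; D <- s$duration[k]; sw <- s$swing_fraction[k]
    st <- 1 - sw
    # uniform grid: t[i] = (i-1)/fs
    i0 <- max(1L, as.integer(ceiling(ic * fs - 1e-9)) + 1L)
    i1 <- min(n, as.integer(ceiling((ic + D) * fs + 1 - 1e-9)) - 1L)
    if (i0 > fill_from) pos[fill_from:(i0 - 1L), 1] <- cur_x
    idx <- i0:i1
    u <- (t[idx] - ic) / D
    swing <- u >= st
    v <- (u[swing] - st) / sw
    px <- rep(cur_x, length(idx))
    py <- numeric(length(idx))
    pz <- numeric(length(idx))
    px[swing] <- cur_x + s$length[k] * smoothstep5(v)
    py[swing] <- s$width[k] * bump3(v)
    pz[swing] <- s$height[k] * bump3(v)
    pos[idx, 1] <- px; pos[idx, 2] <- py; pos[idx, 3] <- pz
    Tsw <- sw * D
    acc[idx[swing], 1] <- s$length[k] * smoothstep5_dd(v) / Tsw^2
    acc[idx[swing], 2] <- s$width[k] * bump3_dd(v) / Tsw^2
    acc[idx[swing], 3] <- s$height[k] * bump3_dd(v) / Tsw^2
    cur_x <- cur_x + s$length[k]
    fill_from <- i1 + 1L
  }
  if (fill_from <= n) pos[fill_from:n, 1] <- cur_x
  # sagittal angular velocity: positive mid-swing peak, negative troughs at
  # initial and final contact, amplitudes balanced so net rotation per stride
  # is zero and the shank angle stays bounded
  A_ms <- 4.5
  for (k in seq_len(nrow(s))) {
    D <- s$duration[k]; sw <- s$swing_fraction[k]
    sig_ms <- sw * D / 6
    sig_tr <- 0.05 * D
    A_tr <- A_ms * sig_ms / (2 * sig_tr)
    omega <- add_gauss(omega, t, s$ms[k], sig_ms, A_ms)
    omega <- add_gauss(omega, t, s$ic[k], sig_tr, -A_tr)
    omega <- add_gauss(omega, t, s$fc[k], sig_tr, -A_tr)
  }
  theta <- cumtrapz(t, omega)
  # sensor frame: x along the shank (up at theta = 0), y forward, z lateral;
  # the frame pitches with the shank about the lateral axis
  h <- cbind(acc[, 1], acc[, 2], acc[, 3] + GRAVITY)  # a_global - gravity vec
  ct <- cos(theta); st_ <- sin(theta)
  hx <- ct * h[, 1] - st_ * h[, 3]
  hz <- st_ * h[, 1] + ct * h[, 3]
  accel_s <- cbind(hz, hx, h[, 2])
  gyro_s <- cbind(0, 0, omega)
  list(accel = accel_s, gyro = gyro_s, pos = pos, theta = theta)
}

add_gauss <- function(w, t, center, sigma, amp) {
  lo <- center - 5 * sigma
  hi <- center + 5 * sigma
  i0 <- max(1L, findInterval(lo, t))
  i1 <- min(length(t), findInterval(hi, t) + 1L)
  idx <- i0:i1
  w[idx] <- w[idx] + amp * exp(-0.5 * ((t[idx] - center) / sigma)^2)
  w
}
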