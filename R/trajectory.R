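# Quaternion helpers (scalar-first, unit quaternions mapping sensor -> global).

quat_mult <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12 || abs(angle) < 1e-15) return(c(1, 0, 0, 0))
  c(cos(angle / 2), sin(angle / 2) * axis / n)
}

# Rotate row-vectors v (N x 3) by quaternions q (N x 4), sensor -> global.
quat_rotate_rows <- function(q, v) {
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  vx <- v[, 1]; vy <- v[, 2]; vz <- v[, 3]
  # t = 2 q_vec x v ; v' = v + w t + q_vec x t
  tx <- 2 * (y * vz - z * vy)
  ty <- 2 * (z * vx - x * vz)
  tz <- 2 * (x * vy - y * vx)
  cbind(vx + w * tx + (y * tz - z * ty),
        vy + w * ty + (z * tx - x * tz),
        vz + w * tz + (x * ty - y * tx))
}

#' Magnetometer-free orientation estimation
#'
#' Strapdown integration of the gyroscope with the inclination corrected
#' toward the accelerometer gravity direction by a complementary filter.  The
#' correction is applied only on quasi-static samples (specific-force
#' magnitude within `acc_gate` of g), the standard guard that keeps swing-
#' phase movement acceleration from polluting the tilt estimate.  Heading is
#' left free (no magnetometer).
#'
#' @param recording An [imu_recording()].
#' @param gain Complementary-filter correction gain per sample (default 0.01,
#'   about a 0.5 s time constant at 200 Hz).
#' @param acc_gate Accel magnitude gate, m/s^2.
#' @return An object of class `orientation_series`: N x 4 matrix of unit
#'   quaternions (scalar first) mapping the sensor frame to a global frame
#'   with gravity along -z.
#' @export
estimate_orientation <- function(recording, gain = 0.01, acc_gate = 1.0) {
  acc <- recording$accel
  gyr <- recording$gyro
  t <- recording$t
  n <- length(t)
  amag <- sqrt(rowSums(acc^2))
  if (mean(amag) < 1 && mean(sqrt(rowSums(gyr^2))) < 1e-6) {
    stop("invalid recording: free-fall (no gravity, no rotation)")
  }
  # initial tilt from the first 0.25 s mean specific force
  i0 <- max(2L, sum(t <= t[1] + 0.25))
  a0 <- colMeans(acc[1:i0, , drop = FALSE])
  a0n <- sqrt(sum(a0^2))
  q <- if (a0n > 1) {
    a0 <- a0 / a0n
    ang <- acos(max(-1, min(1, a0[3])))
    quat_axis_angle(c(a0[2], -a0[1], 0), ang)
  } else {
    c(1, 0, 0, 0)
  }
  ez <- c(0, 0, 1)
  out <- matrix(0, n, 4)
  out[1, ] <- q
  for (k in 2:n) {
    dt <- t[k] - t[k - 1]
    w <- gyr[k - 1, ]
    wn <- sqrt(sum(w^2))
    if (wn > 1e-12) {
      q <- quat_mult(q, c(cos(wn * dt / 2), sin(wn * dt / 2) * w / wn))
    }
    if (abs(amag[k] - GRAVITY) < acc_gate && amag[k] > 1e-6) {
      a <- acc[k, ] / amag[k]
      # measured up-direction in global coordinates
      vg <- quat_rotate_rows(matrix(q, 1), matrix(a, 1))[1, ]
      cosang <- max(-1, min(1, sum(vg * ez)))
      ang <- acos(cosang)
      if (ang > 1e-9) {
        axis <- c(vg[2] * ez[3] - vg[3] * ez[2],
                  vg[3] * ez[1] - vg[1] * ez[3],
                  vg[1] * ez[2] - vg[2] * ez[1])
        q <- quat_mult(quat_axis_angle(axis, gain * ang), q)
      }
    }
    q <- q / sqrt(sum(q^2))
    out[k, ] <- q
  }
  structure(out, class = "orientation_series")
}

#' Inclination angle of an orientation series
#'
#' Angle between the sensor axis that initially points up and the global
#' vertical, per sample; used to validate drift behaviour on static inputs.
#'
#' @param orientation An `orientation_series`.
#' @param up_sensor Unit vector of the up-pointing sensor axis.
#' @return Numeric vector of inclination angles, rad.
#' @export
orientation_inclination <- function(orientation, up_sensor = c(1, 0, 0)) {
  v <- quat_rotate_rows(unclass(orientation),
                        matrix(up_sensor, nrow(orientation), 3, byrow = TRUE))
  acos(pmax(-1, pmin(1, v[, 3])))
}

#' Mid-stance zero-velocity anchors
#'
#' The mid-stance instant of each stride is the sample of minimum gyroscope
#' norm (25 ms moving average) within the central 20-80% of the stance
#' window; the foot is closest to still there, making it the zero-velocity
#' anchor for strapdown integration.
#'
#' @param recording An [imu_recording()].
#' @param events A `gait_events` object for the same side.
#' @return Integer vector of sample indices, one per stride with a valid
#'   stance window (`NA` where missing).
#' @export
midstance_anchors <- function(recording, events) {
  gn <- moving_average(sqrt(rowSums(recording$gyro^2)),
                       round(0.025 * recording$fs))
  t <- recording$t
  vapply(seq_along(events$ic), function(j) {
    st0 <- events$ic[j]
    st1 <- events$fc[j]
    if (is.na(st0) || is.na(st1) || st1 <= st0) return(NA_integer_)
    lo <- st0 + 0.2 * (st1 - st0)
    hi <- st0 + 0.8 * (st1 - st0)
    idx <- which(t >= lo & t <= hi)
    if (length(idx) < 2L) return(NA_integer_)
    idx[which.min(gn[idx])]
  }, integer(1))
}

#' Reconstruct per-stride 3D ankle trajectories
#'
#' For each stride bounded by two mid-stance anchors: the accelerometer is
#' rotated to the global frame, gravity is subtracted, velocity is obtained by
#' trapezoidal integration with a zero-velocity update at both anchors
#' (residual drift removed by linear detrending between them), and a second
#' trapezoidal integration yields displacement.  The horizontal axes are then
#' rotated so the stride's net displacement defines the forward axis, which
#' also neutralises the free heading of the magnetometer-free orientation.
#' Spatial parameters are read off the trajectory: stride length (net
#' horizontal displacement), height (maximum vertical excursion) and width
#' (maximum absolute lateral excursion).
#'
#' @param recording An [imu_recording()].
#' @param orientation An `orientation_series` from [estimate_orientation()].
#' @param events A `gait_events` for the same side.
#' @param min_displacement Strides with net displacement below this (m) are
#'   flagged as probable turns and excluded (`turn = TRUE`).
#' @return An object of class `stride_set`: list with `strides`, a data frame
#'   (`ic`, `duration`, `length`, `height`, `width`, `speed`, `turn`), and
#'   `trajectories`, a list of M x 3 displacement matrices
#'   (forward, lateral, vertical) with origin at the stride start.
#' @export
reconstruct_strides <- function(recording, orientation, events,
                                min_displacement = 0.2) {
  anchors <- midstance_anchors(recording, events)
  t <- recording$t
  a_glob <- quat_rotate_rows(unclass(orientation), recording$accel)
  a_glob[, 3] <- a_glob[, 3] - GRAVITY
  strides <- list()
  trajs <- list()
  m <- length(events$ic)
  for (j in seq_len(m - 1L)) {
    i0 <- anchors[j]; i1 <- anchors[j + 1L]
    if (is.na(i0) || is.na(i1) || i1 - i0 < 4L) next
    D <- events$ic[j + 1L] - events$ic[j]
    if (D > 1.8 * stats::median(diff(events$ic))) next  # spans a rest break
    idx <- i0:i1
    tt <- t[idx]
    vel <- apply(a_glob[idx, , drop = FALSE], 2, function(a) cumtrapz(tt, a))
    # ZUPT at both anchors: v(t0) = 0 by construction, force v(t1) = 0 by
    # first-order detrend (removes the linear drift that integrated noise
    # and residual gravity leakage produce)
    ramp <- (tt - tt[1]) / (tt[length(tt)] - tt[1])
    vel <- vel - outer(ramp, vel[length(tt), ])
    disp <- apply(vel, 2, function(v) cumtrapz(tt, v))
    net <- disp[nrow(disp), 1:2]
    len <- sqrt(sum(net^2))
    ang <- atan2(net[2], net[1])
    fwd <- cos(ang) * disp[, 1] + sin(ang) * disp[, 2]
    lat <- -sin(ang) * disp[, 1] + cos(ang) * disp[, 2]
    traj <- cbind(forward = fwd, lateral = lat, vertical = disp[, 3])
    strides[[length(strides) + 1L]] <- data.frame(
      ic = events$ic[j], duration = D, length = len,
      height = max(disp[, 3]) - disp[1, 3],
      width = max(abs(lat)),
      speed = len / D,
      turn = len < min_displacement
    )
    trajs[[length(trajs) + 1L]] <- traj
  }
  df <- do.call(rbind, strides) %||%
    data.frame(ic = numeric(0), duration = numeric(0), length = numeric(0),
               height = numeric(0), width = numeric(0), speed = numeric(0),
               turn = logical(0))
  structure(list(strides = df, trajectories = trajs), class = "stride_set")
}

#' @export
print.stride_set <- function(x, ...) {
  s <- x$strides
  ok <- !s$turn
  cat(sprintf("<stride_set> %d strides (%d kept, %d turn-flagged)\n",
              nrow(s), sum(ok), sum(!ok)))
  if (any(ok)) {
    cat(sprintf("  mean length %.2f m, height %.3f m, width %.3f m, speed %.2f m/s\n",
                mean(s$length[ok]), mean(s$height[ok]), mean(s$width[ok]),
                mean(s$speed[ok])))
  }
  invisible(x)
}

#' Walking speed and sensor-estimated distance
#'
#' Per-stride speed is stride length over stride duration; the sensor distance
#' is the sum of one foot's stride lengths.  Rest time contributes elapsed
#' time but no distance.
#'
#' @param stride_set A `stride_set` (turn-flagged strides are excluded).
#' @return List with `per_stride` (data frame `t`, `speed`, `length`,
#'   `cadence`), `mean_speed` (m/s) and `distance` (m).
#' @export
compute_walking_speed <- function(stride_set) {
  s <- stride_set$strides
  s <- s[!s$turn, , drop = FALSE]
  if (nrow(s) == 0L) stop("no strides")
  list(per_stride = data.frame(t = s$ic + s$duration / 2, speed = s$speed,
                               length = s$length, cadence = 60 / s$duration),
       mean_speed = mean(s$speed),
       distance = sum(s$length))
}
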