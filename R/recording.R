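#' IMU recording container
#'
#' Bundles one ankle sensor's time-synchronised tri-axial accelerometer and
#' gyroscope streams.  Internal canonical units are seconds, m/s^2 and rad/s;
#' [read_recording()] converts g and deg/s on ingestion.
#'
#' @param t Numeric vector of timestamps in seconds, strictly increasing,
#'   nominally 200 Hz.
#' @param accel N x 3 matrix of specific force in m/s^2 (a stationary sensor
#'   reads +g on its up-pointing axis).
#' @param gyro N x 3 matrix of angular velocity in rad/s.
#' @param side `"left"` or `"right"`.
#' @param sensor_id Free-form sensor identifier.
#' @return An object of class `imu_recording`: a list with elements `t`,
#'   `accel`, `gyro`, `side`, `sensor_id`, `fs` (median sampling rate, Hz).
#' @examples
#' t <- seq(0, 1, by = 1 / 200)
#' acc <- cbind(9.80665, 0, 0)[rep(1, length(t)), ]
#' rec <- imu_recording(t, acc, matrix(0, length(t), 3), side = "left")
#' rec
#' @export
imu_recording <- function(t, accel, gyro, side = c("left", "right"),
                          sensor_id = "unknown") {
  side <- match.arg(side)
  accel <- as.matrix(accel)
  gyro <- as.matrix(gyro)
  if (ncol(accel) != 3L) stop("accel must have 3 columns")
  if (ncol(gyro) != 3L) stop("gyro must have 3 columns")
  n <- length(t)
  if (nrow(accel) != n || nrow(gyro) != n) {
    stop("timestamps, accel and gyro must have equal length")
  }
  bad <- which(diff(t) <= 0)
  if (length(bad)) {
    stop(sprintf("timestamps not strictly increasing (first offence at index %d)",
                 bad[1] + 1L))
  }
  if (max(abs(accel)) > 16 * GRAVITY * 1.01) {
    stop("accelerometer values exceed the +-16 g sensor span")
  }
  if (max(abs(gyro)) > 2000 * pi / 180 * 1.01) {
    stop("gyroscope values exceed the +-2000 deg/s sensor span")
  }
  fs <- 1 / stats::median(diff(t))
  structure(list(t = as.numeric(t), accel = unname(accel), gyro = unname(gyro),
                 side = side, sensor_id = sensor_id, fs = fs),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %s ankle, sensor '%s'\n", x$side, x$sensor_id))
  cat(sprintf("  %d samples @ %.1f Hz, %.1f s (%.3f .. %.3f s)\n",
              length(x$t), x$fs, diff(range(x$t)), x$t[1], x$t[length(x$t)]))
  invisible(x)
}

#' Pick the sagittal-plane gyroscope channel
#'
#' The channel perpendicular to the sagittal plane carries the shank rotation
#' during walking and dominates the gyroscope variance.  The sign is flipped,
#' if necessary, so the swing phase produces positive peaks (strap orientation
#' is not guaranteed in the field).
#'
#' @param recording An [imu_recording()].
#' @return Numeric vector: the sagittal angular velocity omega_z in rad/s,
#'   with attribute `"channel"` (column index used) and `"flipped"`.
#' @export
sagittal_gyro <- function(recording) {
  v <- apply(recording$gyro, 2, stats::var)
  ch <- which.max(v)
  w <- recording$gyro[, ch]
  hi <- stats::quantile(w, 0.999, names = FALSE)
  lo <- stats::quantile(w, 0.001, names = FALSE)
  flipped <- abs(lo) > abs(hi)
  if (flipped) w <- -w
  attr(w, "channel") <- ch
  attr(w, "flipped") <- flipped
  w
}

#' Segment a trial into walking and rest
#'
#' Rest is flagged where the 2 s moving variance of the sagittal angular
#' velocity falls below `var_threshold` (default 0.01 (rad/s)^2).
#'
#' @param omega_z Sagittal angular velocity, rad/s.
#' @param fs Sampling rate, Hz.
#' @param var_threshold Variance threshold, (rad/s)^2.
#' @param window_s Moving window length, s.
#' @return Logical vector, `TRUE` where walking.
#' @export
walking_mask <- function(omega_z, fs, var_threshold = 0.01, window_s = 2) {
  k <- round(window_s * fs)
  m1 <- moving_average(as.numeric(omega_z), k)
  m2 <- moving_average(as.numeric(omega_z)^2, k)
  pmax(m2 - m1^2, 0) >= var_threshold
}
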