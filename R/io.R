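#' Write an IMU recording to CSV
#'
#' The dialect is a plain comma-separated table with header
#' `t,ax,ay,az,gx,gy,gz` preceded by a `# units:` comment line declaring the
#' accelerometer and gyroscope units.  Values are written in the canonical
#' units (m/s^2, rad/s) at full double precision.
#'
#' @param recording An [imu_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units: accel=m/s^2 gyro=rad/s side=%s sensor_id=%s",
                     recording$side, recording$sensor_id), con)
  df <- data.frame(t = recording$t,
                   ax = recording$accel[, 1], ay = recording$accel[, 2],
                   az = recording$accel[, 3],
                   gx = recording$gyro[, 1], gy = recording$gyro[, 2],
                   gz = recording$gyro[, 3])
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an IMU recording from CSV
#'
#' Accepts accelerometer units `m/s^2` or `g` and gyroscope units `rad/s` or
#' `deg/s`; values are normalised to m/s^2 and rad/s.  Sample gaps longer than
#' three nominal intervals are flagged in the `gaps` attribute.
#'
#' @param path File path.
#' @param format Only `"csv"` is supported.
#' @param side Optional override of the side declared in the file.
#' @return An [imu_recording()].
#' @export
read_recording <- function(path, format = c("csv"), side = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "# units:")) {
    stop("recording file must declare units in a '# units:' comment line")
  }
  kv <- parse_units_line(header)
  accel_unit <- kv[["accel"]] %||% stop("units line missing accel unit")
  gyro_unit <- kv[["gyro"]] %||% stop("units line missing gyro unit")
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("t", "ax", "ay", "az")
  if (!all(need %in% names(df))) stop("missing accel: columns ax,ay,az required")
  if (!all(c("gx", "gy", "gz") %in% names(df))) stop("missing gyro")
  accel <- as.matrix(df[, c("ax", "ay", "az")])
  gyro <- as.matrix(df[, c("gx", "gy", "gz")])
  accel <- accel * switch(accel_unit,
                          "m/s^2" = 1, "m/s2" = 1, "g" = GRAVITY,
                          stop("unknown accel unit: ", accel_unit))
  gyro <- gyro * switch(gyro_unit,
                        "rad/s" = 1, "deg/s" = pi / 180, "°/s" = pi / 180,
                        stop("unknown gyro unit: ", gyro_unit))
  t <- df$t
  bad <- which(diff(t) <= 0)
  if (length(bad)) {
    stop(sprintf("non-monotone timestamps (first offence at index %d)", bad[1] + 1L))
  }
  side <- side %||% kv[["side"]] %||% "left"
  rec <- imu_recording(t, accel, gyro, side = side,
                       sensor_id = kv[["sensor_id"]] %||% basename(path))
  dt <- diff(t)
  gap_idx <- which(dt > 3 * stats::median(dt))
  attr(rec, "gaps") <- t[gap_idx]
  rec
}

parse_units_line <- function(line) {
  body <- sub("^# units:\\s*", "", line)
  parts <- strsplit(trimws(body), "\\s+")[[1]]
  parts <- parts[nzchar(parts)]
  kv <- strsplit(parts, "=", fixed = TRUE)
  out <- lapply(kv, function(p) if (length(p) == 2L) p[2] else NA_character_)
  names(out) <- vapply(kv, `[`, "", 1L)
  out
}

#' Resample a left/right sensor pair onto a common time base
#'
#' Both streams are linearly interpolated onto one uniform 200 Hz grid over
#' their overlapping interval (boundaries trimmed by 0.1 s), emulating a pair
#' of time-synchronised sensors.
#'
#' @param left,right [imu_recording()] objects.
#' @param fs Target sampling rate, Hz.
#' @param min_overlap_s Minimum required overlap, s.
#' @return List with elements `left` and `right`, both on identical timestamp
#'   vectors.
#' @export
synchronize_pair <- function(left, right, fs = 200, min_overlap_s = 30) {
  t0 <- max(left$t[1], right$t[1])
  t1 <- min(left$t[length(left$t)], right$t[length(right$t)])
  if (t1 - t0 < min_overlap_s) {
    stop(sprintf("overlap %.1f s is shorter than the required %.0f s",
                 max(t1 - t0, 0), min_overlap_s))
  }
  grid <- seq(t0 + 0.1, t1 - 0.1, by = 1 / fs)
  resample <- function(rec) {
    interp_mat <- function(m) {
      apply(m, 2, function(col) stats::approx(rec$t, col, xout = grid)$y)
    }
    imu_recording(grid, interp_mat(rec$accel), interp_mat(rec$gyro),
                  side = rec$side, sensor_id = rec$sensor_id)
  }
  list(left = resample(left), right = resample(right))
}

#' Write and read a simulated trial
#'
#' A trial directory holds `left.csv` and `right.csv` in the package CSV
#' dialect plus, for simulated trials, the planted ground truth as a sidecar
#' `truth.json`.
#'
#' @param trial A list with elements `left`, `right` and optionally `truth`
#'   (as returned by [simulate_trial()]).
#' @param dir Directory to create/fill.
#' @return `dir` (write) or a trial list (read), invisibly for the writer.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_recording(trial$left, file.path(dir, "left.csv"))
  write_recording(trial$right, file.path(dir, "right.csv"))
  if (!is.null(trial$truth)) {
    jsonlite::write_json(truth_to_list(trial$truth),
                         file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_trial
#' @export
read_trial <- function(dir) {
  out <- list(left = read_recording(file.path(dir, "left.csv"), side = "left"),
              right = read_recording(file.path(dir, "right.csv"), side = "right"))
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) out$truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
  out
}

truth_to_list <- function(truth) {
  keep <- c("events", "strides", "profile_summary")
  truth[intersect(keep, names(truth))]
}

#' Construct per-trial metadata
#'
#' One row per trial: subject, cohort, timing and the clinical scores used by
#' the cohort analyses (lower-extremity motor scores per leg, SCIM, WISCI,
#' walking-aid/orthosis flags, demographics).
#'
#' @param subject_id Character.
#' @param cohort `"SCI"` or `"HC"` (healthy control).
#' @param days_since_injury Days; `NA` for controls.
#' @param measured_6mwt_distance Metres, >= 0.
#' @param lems_left,lems_right Lower-extremity motor score per leg, 0-25.
#' @param ... Further scalar clinical/demographic fields (SCIM, WISCI, age, ...).
#' @return A one-row `data.frame`.
#' @export
trial_metadata <- function(subject_id, cohort = c("SCI", "HC"),
                           days_since_injury = NA_real_,
                           measured_6mwt_distance = NA_real_,
                           lems_left = NA_real_, lems_right = NA_real_, ...) {
  cohort <- match.arg(cohort)
  if (!is.na(measured_6mwt_distance) && measured_6mwt_distance < 0) {
    stop("6MWT distance must be >= 0")
  }
  for (l in c(lems_left, lems_right)) {
    if (!is.na(l) && (l < 0 || l > 25)) stop("per-leg LEMS must lie in 0..25")
  }
  data.frame(subject_id = subject_id, cohort = cohort,
             days_since_injury = days_since_injury,
             measured_6mwt_distance = measured_6mwt_distance,
             lems_left = lems_left, lems_right = lems_right, ...,
             stringsAsFactors = FALSE)
}
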