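#' Coefficient of variation (percent)
#'
#' Sample standard deviation (n - 1 denominator) over the mean, times 100.
#'
#' @param values Numeric vector of per-stride values (>= 2).
#' @return cov in percent.
#' @examples
#' compute_cov(c(0.9, 1.0, 1.1))  # 10
#' @export
compute_cov <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least two values")
  m <- mean(values)
  if (m == 0) stop("mean is zero; cov undefined")
  stats::sd(values) / m * 100
}

#' Left/right asymmetry by the symmetry index (percent)
#'
#' `|mean_left - mean_right| / (0.5 (mean_left + mean_right)) x 100`.
#'
#' @param mean_left,mean_right Side means of a gait parameter.
#' @return Asymmetry in percent (0 for perfect symmetry, up to 200).
#' @examples
#' compute_asym(1.1, 0.9)  # 20
#' @export
compute_asym <- function(mean_left, mean_right) {
  s <- mean_left + mean_right
  if (s == 0) stop("both side means are zero; asymmetry undefined")
  abs(mean_left - mean_right) / (0.5 * s) * 100
}

#' Speed-matched healthy reference
#'
#' Builds, per gait parameter, a piecewise-linear interpolant of the control
#' cohort's values over walking speed (ties averaged, queries outside the
#' control speed range clamped to the endpoints and flagged), plus the
#' pointwise-mean normalized cyclogram shape per view.
#'
#' @param control_sets List of `gait_parameter_set` objects from healthy
#'   control trials (>= 3, spanning >= `min_span` m/s of mean speed).
#' @param min_span Minimum speed span, m/s.
#' @return An object of class `healthy_reference`.
#' @export
build_reference <- function(control_sets, min_span = 0.3) {
  if (length(control_sets) < 3L) stop("need at least three control trials")
  speeds <- vapply(control_sets, function(s) s[["speed_mean"]], 0)
  if (diff(range(speeds)) < min_span) {
    stop(sprintf("control speeds span %.2f m/s; need at least %.2f",
                 diff(range(speeds)), min_span))
  }
  params <- setdiff(Reduce(intersect, lapply(control_sets, names)),
                    "speed_mean")
  tabs <- lapply(params, function(pn) {
    val <- vapply(control_sets, function(s) s[[pn]], 0)
    keep <- !is.na(val)
    if (sum(keep) < 2L) return(NULL)
    list(speed = speeds[keep], value = val[keep])
  })
  names(tabs) <- params
  tabs <- Filter(Negate(is.null), tabs)
  shapes <- lapply(c(side = "side", top = "top"), function(view) {
    sh <- lapply(control_sets, function(s) attr(s, "cyclograms")[[view]])
    sh <- Filter(Negate(is.null), sh)
    if (!length(sh)) return(NULL)
    Reduce(`+`, sh) / length(sh)
  })
  structure(list(tables = tabs, speed_range = range(speeds),
                 shapes = shapes),
            class = "healthy_reference")
}

#' @export
print.healthy_reference <- function(x, ...) {
  cat(sprintf("<healthy_reference> %d parameters, speeds %.2f-%.2f m/s\n",
              length(x$tables), x$speed_range[1], x$speed_range[2]))
  invisible(x)
}

#' Look up a reference value at a walking speed
#'
#' @param reference A `healthy_reference`.
#' @param parameter Parameter name.
#' @param speed Walking speed, m/s.
#' @return The interpolated reference value, with attribute `extrapolated` set
#'   when `speed` lies outside the control range (value clamped).
#' @export
reference_value <- function(reference, parameter, speed) {
  tab <- reference$tables[[parameter]]
  if (is.null(tab)) stop("no reference for parameter: ", parameter)
  v <- interp_clamp(tab$speed, tab$value, speed)
  attr(v, "extrapolated") <- speed < reference$speed_range[1] |
    speed > reference$speed_range[2]
  v
}

#' Difference to speed-matched reference (percent)
#'
#' `(mean - ref(speed)) / ref(speed) x 100`; the sign is preserved, so a
#' parameter below the healthy-control value at the same speed is negative
#' (e.g. an abbreviated double-support phase).
#'
#' @param mean_value Trial mean of the parameter.
#' @param speed Trial mean walking speed, m/s.
#' @param reference A `healthy_reference`.
#' @param parameter Parameter name in the reference tables.
#' @return d2r in percent.
#' @export
compute_d2r <- function(mean_value, speed, reference, parameter) {
  ref <- as.numeric(reference_value(reference, parameter, speed))
  if (ref == 0) stop("reference value is zero; d2r undefined")
  (mean_value - ref) / ref * 100
}

#' Fatigue/change metrics over the trial
#'
#' Ordinary least squares of a per-stride parameter against stride mid-time;
#' the change is the slope divided by the intercept (fractional change per
#' second), and the speed inconsistency is the absolute change in speed.
#'
#' @param t Stride mid-times, s.
#' @param values Per-stride parameter values.
#' @return The change (slope/intercept, 1/s).
#' @examples
#' t <- seq(0, 360, by = 1.2)
#' compute_change(t, 1 - 0.1 * t / 360)  # ~ -2.78e-4
#' @export
compute_change <- function(t, values) {
  keep <- !is.na(values)
  t <- t[keep]; values <- values[keep]
  if (length(t) < 10L) stop("need at least 10 strides")
  if (diff(range(t)) < 120) stop("need at least 120 s of strides")
  fit <- stats::lm.fit(cbind(1, t), values)
  ab <- fit$coefficients
  if (ab[1] == 0) stop("intercept is zero; change undefined")
  unname(ab[2] / ab[1])
}

#' Movement smoothness: modified spectral arc length
#'
#' The magnitude spectrum of the sagittal angular velocity over the
#' concatenated walking segments is normalized by its maximum; the adaptive
#' cutoff is the largest frequency at or below `f_max` where the normalized
#' magnitude still reaches `amp_threshold`, and the smoothness is the negated
#' arc length of the normalized spectrum over `[0, cutoff]` (frequency axis
#' scaled by the cutoff).  Always <= 0; values closer to 0 are smoother.
#'
#' @param omega_z Sagittal angular velocity, rad/s.
#' @param fs Sampling rate, Hz.
#' @param mask Optional logical walking mask.
#' @param f_max Maximum cutoff frequency, Hz.
#' @param amp_threshold Normalized amplitude threshold for the adaptive cutoff.
#' @return Spectral arc length (dimensionless, <= 0).
#' @export
compute_smoothness <- function(omega_z, fs, mask = NULL, f_max = 20,
                               amp_threshold = 0.05) {
  w <- as.numeric(omega_z)
  if (!is.null(mask)) w <- w[mask]
  if (length(w) < 10 * fs) stop("need at least 10 s of walking")
  nfft <- max(2^ceiling(log2(length(w))), 16384L)
  mag <- abs(stats::fft(c(w, numeric(nfft - length(w)))))[1:(nfft %/% 2)]
  freq <- (seq_len(nfft %/% 2) - 1) * fs / nfft
  keep <- freq <= f_max
  mag <- mag[keep]; freq <- freq[keep]
  magn <- mag / max(mag)
  above <- which(magn >= amp_threshold)
  cutoff <- freq[above[length(above)]]
  sel <- freq <= cutoff
  f <- freq[sel] / cutoff
  v <- magn[sel]
  -sum(sqrt(diff(f)^2 + diff(v)^2))
}
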