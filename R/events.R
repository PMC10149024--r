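#' Estimate walking cadence from the sagittal angular velocity spectrum
#'
#' A fast Fourier transform of the walking-segment gyroscope signal gives the
#' dominant stride frequency; the largest spectral magnitude between 0.3 and
#' 1.5 Hz is taken as the stride rate and converted to cadence.
#'
#' @param omega_z Sagittal angular velocity, rad/s (see [sagittal_gyro()]).
#' @param fs Sampling rate, Hz.
#' @param mask Optional logical walking mask (from [walking_mask()]); rest
#'   samples are excluded before the transform.
#' @param band Search band for the stride frequency, Hz.
#' @return List with `stride_frequency` (Hz) and `cadence` (strides/min).
#' @examples
#' t <- seq(0, 60, by = 1 / 200)
#' estimate_cadence(sin(2 * pi * 0.9 * t), fs = 200)
#' @export
estimate_cadence <- function(omega_z, fs, mask = NULL, band = c(0.3, 1.5)) {
  w <- as.numeric(omega_z)
  if (!is.null(mask)) w <- w[mask]
  if (length(w) < 10 * fs || all(w == 0)) stop("no locomotion detected")
  w <- w - mean(w)
  if (stats::sd(w) < 1e-12) stop("no locomotion detected")
  nfft <- max(2^ceiling(log2(length(w))), 32768L)
  spec <- abs(stats::fft(c(w, numeric(nfft - length(w)))))[1:(nfft %/% 2)]
  freq <- (seq_len(nfft %/% 2) - 1) * fs / nfft
  in_band <- freq >= band[1] & freq <= band[2]
  if (!any(in_band)) stop("no locomotion detected")
  f0 <- freq[in_band][which.max(spec[in_band])]
  list(stride_frequency = f0, cadence = 60 * f0)
}

#' Detect strides as mid-swing peaks of the sagittal angular velocity
#'
#' Local maxima of omega_z are accepted as mid-swing peaks when they exceed an
#' adaptive height threshold (`max(0.2 x 95th percentile of |omega_z| during
#' walking, 0.5 rad/s)`) and are separated by at least 0.6 stride periods;
#' both the window and the threshold therefore adapt to the walker's cadence
#' and signal amplitude.  Rest periods yield no peaks.
#'
#' @param omega_z Sagittal angular velocity, rad/s.
#' @param fs Sampling rate, Hz.
#' @param stride_frequency Dominant stride frequency, Hz (from
#'   [estimate_cadence()]).
#' @param mask Optional logical walking mask.
#' @return Numeric vector of mid-swing peak times (s, relative to the first
#'   sample).  May be empty.
#' @export
detect_strides <- function(omega_z, fs, stride_frequency, mask = NULL) {
  w <- as.numeric(omega_z)
  if (is.null(mask)) mask <- rep(TRUE, length(w))
  if (!any(mask)) return(numeric(0))
  thr <- max(0.2 * stats::quantile(abs(w[mask]), 0.95, names = FALSE), 0.5)
  min_dist <- max(1L, round(0.6 / stride_frequency * fs))
  idx <- find_peaks(w, min_height = thr, min_distance = min_dist)
  idx <- idx[mask[idx]]
  (idx - 1L) / fs
}

#' Detect initial and final contacts around each mid-swing peak
#'
#' Between two consecutive mid-swing peaks the sagittal angular velocity shows
#' two negative troughs: the first (just after the swing ends) marks the
#' initial contact of the new stride, the last (just before the next
#' mid-swing) marks its final contact (toe-off).  Search windows are scaled by
#' the stride period.  The accelerometer magnitude is checked for a
#' corroborating peak within +-50 ms of each initial contact and reported as
#' a flag.  Mid-swing intervals longer than 1.8 median intervals (rest gaps)
#' produce no events.
#'
#' @param omega_z Sagittal angular velocity, rad/s.
#' @param fs Sampling rate, Hz.
#' @param midswing_times Mid-swing peak times, s (from [detect_strides()]).
#' @param accel Optional N x 3 accelerometer matrix for corroboration.
#' @return An object of class `gait_events`: list with vectors `ic`, `fc`
#'   (initial/final contact times per stride, stance k = `[ic[k], fc[k]]`),
#'   `ms` (mid-swing times), logical `ic_corroborated`, and `dropped`
#'   (count of stride intervals without a candidate).
#' @export
detect_gait_events <- function(omega_z, fs, midswing_times, accel = NULL) {
  if (length(midswing_times) < 2L) stop("need at least two mid-swing peaks")
  w <- as.numeric(omega_z)
  t_of <- function(i) (i - 1L) / fs
  i_of <- function(tt) pmin(length(w), pmax(1L, round(tt * fs) + 1L))
  gaps <- diff(midswing_times)
  med_gap <- stats::median(gaps)
  amag <- if (!is.null(accel)) abs(sqrt(rowSums(accel^2)) - GRAVITY) else NULL
  ic <- fc <- numeric(0)
  corr <- logical(0)
  dropped <- 0L
  for (k in seq_along(gaps)) {
    if (gaps[k] > 1.8 * med_gap) { dropped <- dropped + 1L; next }
    p <- midswing_times[k]
    np <- midswing_times[k + 1L]
    Tk <- np - p
    ic_win <- i_of(c(p + 0.08 * Tk, p + 0.45 * Tk))
    fc_win <- i_of(c(np - 0.40 * Tk, np - 0.06 * Tk))
    if (diff(ic_win) < 2 || diff(fc_win) < 2) { dropped <- dropped + 1L; next }
    i_ic <- ic_win[1] + which.min(w[ic_win[1]:ic_win[2]]) - 1L
    i_fc <- fc_win[1] + which.min(w[fc_win[1]:fc_win[2]]) - 1L
    if (i_fc <= i_ic) { dropped <- dropped + 1L; next }
    ic <- c(ic, t_of(i_ic))
    fc <- c(fc, t_of(i_fc))
    corr <- c(corr, if (is.null(amag)) NA else {
      win <- i_of(c(t_of(i_ic) - 0.05, t_of(i_ic) + 0.05))
      length(find_peaks(amag[win[1]:win[2]], min_height = 0.5)) > 0
    })
  }
  structure(list(ic = ic, fc = fc, ms = midswing_times,
                 ic_corroborated = corr, dropped = dropped),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d strides (%d mid-swing peaks, %d dropped)\n",
              length(x$ic), length(x$ms), x$dropped))
  invisible(x)
}

#' Temporal gait parameters from both sides' events
#'
#' Per stride (consecutive same-side initial contacts): stride duration, step
#' duration (to the following contralateral initial contact), swing percent
#' (`(next IC - FC) / stride x 100`) and double-support percent (total time
#' both feet are grounded within the stride, the sum of the two
#' double-support intervals).  Strides spanning rest breaks, and strides whose
#' contralateral events cannot be matched, are dropped.
#'
#' @param events_left,events_right `gait_events` for the two sides, on the
#'   common trial time base.
#' @return List of class `temporal_params` with per-side data frames
#'   (`left`, `right`; columns `ic`, `duration`, `step_duration`, `swing_pct`,
#'   `double_support_pct`) and `cadence_series` (time, strides/min).
#' @export
compute_temporal_params <- function(events_left, events_right) {
  one_side <- function(ev, ev_opp) {
    m <- length(ev$ic)
    if (m < 2L) return(data.frame())
    dur <- diff(ev$ic)
    ok <- dur <= 1.8 * stats::median(dur)
    rows <- lapply(which(ok), function(j) {
      t0 <- ev$ic[j]; t1 <- ev$ic[j + 1L]; fcj <- ev$fc[j]
      D <- t1 - t0
      opp_ic <- ev_opp$ic[ev_opp$ic > t0 & ev_opp$ic < t1][1]
      opp_fc <- ev_opp$fc[ev_opp$fc > t0 & ev_opp$fc < t1][1]
      if (is.na(opp_ic) || is.na(fcj) || fcj <= t0 || fcj >= t1) return(NULL)
      ds <- if (!is.na(opp_fc) && opp_fc < opp_ic) {
        (opp_fc - t0) + (fcj - opp_ic)
      } else {
        NA_real_
      }
      data.frame(ic = t0, duration = D, step_duration = opp_ic - t0,
                 swing_pct = 100 * (t1 - fcj) / D,
                 double_support_pct = 100 * ds / D)
    })
    do.call(rbind, rows) %||% data.frame()
  }
  left <- one_side(events_left, events_right)
  right <- one_side(events_right, events_left)
  cad <- if (nrow(left)) {
    data.frame(t = left$ic + left$duration / 2, cadence = 60 / left$duration)
  } else {
    data.frame(t = numeric(0), cadence = numeric(0))
  }
  structure(list(left = left, right = right, cadence_series = cad),
            class = "temporal_params")
}
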