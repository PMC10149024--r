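# Canonical feature ordering of the per-trial gait parameter set.
gait_parameter_names <- function() {
  base <- c("stride_duration", "step_duration", "swing", "double_support",
            "stride_length", "stride_width", "stride_height")
  stat_names <- unlist(lapply(base, function(b) {
    stats <- c("mean", "cov", if (b != "stride_length") "asym", "d2r")
    paste(b, stats, sep = "_")
  }))
  c("speed_mean", stat_names,
    "cyclogram_side_ssd", "cyclogram_side_acc", "cyclogram_side_area",
    "cyclogram_side_area_raw",
    "cyclogram_top_ssd", "cyclogram_top_acc", "cyclogram_top_area",
    "cyclogram_top_area_raw",
    "smoothness",
    "change_speed", "change_stride_length", "change_cadence",
    "speed_inconsistency")
}

#' Select the analysis side
#'
#' Side-specific gait parameters enter the feature vector from the more
#' impaired side, defined as the side with the lower lower-extremity motor
#' score (LEMS).  Healthy controls, and LEMS ties, use the right side.
#'
#' @param cohort `"SCI"` or `"HC"`.
#' @param lems_left,lems_right Per-leg LEMS (0-25); may be `NA` for controls.
#' @param force Optional `"left"`/`"right"` override.
#' @return `"left"` or `"right"`.
#' @export
analysis_side <- function(cohort = c("SCI", "HC"), lems_left = NA,
                          lems_right = NA, force = NULL) {
  cohort <- match.arg(cohort)
  if (!is.null(force)) return(match.arg(force, c("left", "right")))
  if (cohort == "HC") return("right")
  if (is.na(lems_left) || is.na(lems_right)) {
    stop("SCI trial needs both per-leg LEMS scores (or a forced side)")
  }
  if (lems_left < lems_right) "left" else "right"
}

#' Extract the full per-trial gait parameter set from a sensor pair
#'
#' Runs the whole pipeline on one trial: sagittal-channel selection, rest
#' segmentation, FFT cadence, adaptive stride/event detection, temporal
#' parameters, orientation estimation, per-stride trajectory reconstruction
#' with zero-velocity updates, spatial parameters, cyclogram metrics,
#' smoothness and change/fatigue metrics, then assembles the named feature
#' vector with statistical features (mean, cov, asym, d2r) and the
#' more-impaired-side rule.
#'
#' @param left,right [imu_recording()]s of the two ankles on a common time
#'   base (resampled via [synchronize_pair()] if not).
#' @param cohort `"SCI"` or `"HC"`.
#' @param lems_left,lems_right Per-leg lower-extremity motor scores.
#' @param side Optional forced analysis side.
#' @param reference Optional [build_reference()] result; required for the d2r
#'   and cyclogram-SSD entries (otherwise `NA`).
#' @return An object of class `gait_parameter_set`: a named numeric vector in
#'   the fixed ordering of `gait_parameter_names()`, with attributes `side`
#'   (analysis side), `cyclograms` (mean normalized shapes of the analysis
#'   side), `per_side` (side-level summaries) and `n_strides`.
#' @export
extract_gait_parameters <- function(left, right, cohort = c("SCI", "HC"),
                                    lems_left = NA, lems_right = NA,
                                    side = NULL, reference = NULL) {
  cohort <- match.arg(cohort)
  if (length(left$t) != length(right$t) ||
      any(abs(left$t - right$t) > 1e-9)) {
    sp <- synchronize_pair(left, right)
    left <- sp$left; right <- sp$right
  }
  fs <- left$fs
  per_side <- lapply(list(left = left, right = right), function(rec) {
    w <- sagittal_gyro(rec)
    mask <- walking_mask(w, fs)
    cad <- estimate_cadence(w, fs, mask = mask)
    ms <- detect_strides(w, fs, cad$stride_frequency, mask = mask)
    ev <- detect_gait_events(w, fs, ms, accel = rec$accel)
    list(rec = rec, w = w, mask = mask, cadence = cad, events = ev)
  })
  temporal <- compute_temporal_params(per_side$left$events,
                                      per_side$right$events)
  for (sd_ in c("left", "right")) {
    ps <- per_side[[sd_]]
    orient <- estimate_orientation(ps$rec)
    ss <- reconstruct_strides(ps$rec, orient, ps$events)
    per_side[[sd_]]$strides <- ss
    per_side[[sd_]]$speedinfo <- tryCatch(compute_walking_speed(ss),
                                          error = function(e) NULL)
    per_side[[sd_]]$cyclo <- lapply(c(side = "side", top = "top"),
                                    function(v) {
      tryCatch(compute_cyclogram(ss, view = v), error = function(e) NULL)
    })
    per_side[[sd_]]$smoothness <- tryCatch(
      compute_smoothness(ps$w, fs, mask = ps$mask), error = function(e) NA_real_)
  }
  aside <- analysis_side(cohort, lems_left, lems_right, force = side)
  ap <- per_side[[aside]]
  if (is.null(ap$speedinfo)) stop("no usable strides on the analysis side")
  speed <- ap$speedinfo$mean_speed

  base_values <- function(sd_) {
    tp <- temporal[[sd_]]
    st <- per_side[[sd_]]$strides$strides
    st <- st[!st$turn, , drop = FALSE]
    list(stride_duration = tp$duration,
         step_duration = tp$step_duration,
         swing = tp$swing_pct,
         double_support = tp$double_support_pct,
         stride_length = st$length,
         stride_width = st$width,
         stride_height = st$height)
  }
  bv <- lapply(list(left = "left", right = "right"), base_values)
  out <- stats::setNames(rep(NA_real_, length(gait_parameter_names())),
                         gait_parameter_names())
  out["speed_mean"] <- speed
  for (b in names(bv$left)) {
    va <- bv[[aside]][[b]]
    va <- va[!is.na(va)]
    ml <- mean(bv$left[[b]], na.rm = TRUE)
    mr <- mean(bv$right[[b]], na.rm = TRUE)
    out[paste0(b, "_mean")] <- mean(va)
    out[paste0(b, "_cov")] <- if (length(va) >= 2L) compute_cov(va) else NA
    if (b != "stride_length") {
      out[paste0(b, "_asym")] <- tryCatch(compute_asym(ml, mr),
                                          error = function(e) NA_real_)
    }
    if (!is.null(reference)) {
      out[paste0(b, "_d2r")] <- tryCatch(
        compute_d2r(mean(va), speed, reference, paste0(b, "_mean")),
        error = function(e) NA_real_)
    }
  }
  cyclo_attr <- list()
  for (v in c("side", "top")) {
    cs <- ap$cyclo[[v]]
    if (is.null(cs)) next
    pref <- paste0("cyclogram_", v, "_")
    out[paste0(pref, "acc")] <- cyclogram_acc(cs)
    out[paste0(pref, "area")] <- cyclogram_area(close_shape(cs$mean_shape))
    raw_areas <- vapply(cs$raw, function(s) cyclogram_area(close_shape(s)), 0)
    out[paste0(pref, "area_raw")] <- mean(raw_areas)
    cyclo_attr[[v]] <- cs$mean_shape
    if (!is.null(reference) && !is.null(reference$shapes[[v]])) {
      out[paste0(pref, "ssd")] <- cyclogram_ssd(cs$mean_shape,
                                                reference$shapes[[v]])
    }
  }
  out["smoothness"] <- ap$smoothness
  pst <- ap$speedinfo$per_stride
  chg <- function(vals) tryCatch(compute_change(pst$t, vals),
                                 error = function(e) NA_real_)
  out["change_speed"] <- chg(pst$speed)
  out["change_stride_length"] <- chg(pst$length)
  out["change_cadence"] <- chg(pst$cadence)
  out["speed_inconsistency"] <- abs(out["change_speed"])
  structure(out, class = "gait_parameter_set", side = aside,
            cyclograms = cyclo_attr,
            n_strides = c(left = length(per_side$left$events$ic),
                          right = length(per_side$right$events$ic)),
            per_side = list(
              left = vapply(bv$left, mean, 0, na.rm = TRUE),
              right = vapply(bv$right, mean, 0, na.rm = TRUE)),
            temporal = temporal)
}

close_shape <- function(shape) rbind(shape, shape[1, ])

#' @export
print.gait_parameter_set <- function(x, ...) {
  cat(sprintf("<gait_parameter_set> analysis side: %s, %d features\n",
              attr(x, "side"), length(x)))
  v <- unclass(x)
  attributes(v) <- list(names = names(x))
  print(round(v, 4))
  invisible(x)
}

#' Flatten gait parameter sets into a feature table
#'
#' @param sets List of `gait_parameter_set` objects.
#' @return Data frame, one row per trial, columns in the canonical ordering.
#' @export
feature_table <- function(sets) {
  as.data.frame(do.call(rbind, lapply(sets, function(s) {
    v <- unclass(s); attributes(v) <- list(names = names(s)); v
  })))
}
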