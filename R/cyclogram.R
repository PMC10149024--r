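#' Per-stride cyclograms (normalized 2D ankle loops)
#'
#' Projects each stride's reconstructed trajectory onto one plane -- side view
#' (forward-vertical) or top view (forward-lateral) -- resamples it to
#' `n_points` uniformly in normalized stride time (phase-anchored at the
#' stride start / initial contact), centres it at its centroid and scales it
#' to unit root-mean-square radius.  The closing of the loop comes from the
#' displacement-per-stride construction (start and end are both mid-stance,
#' near-zero motion).
#'
#' @param stride_set A `stride_set` from [reconstruct_strides()] (turn-flagged
#'   strides excluded), or a plain list of M x >=2 trajectory matrices.
#' @param view `"side"` (forward, vertical) or `"top"` (forward, lateral).
#' @param n_points Number of resampled points per cycle.
#' @return An object of class `cyclogram_set`: list with `shapes` (list of
#'   `n_points` x 2 normalized shapes), `raw` (same, before normalization)
#'   and `mean_shape` (pointwise average of the normalized shapes).
#' @export
compute_cyclogram <- function(stride_set, view = c("side", "top"),
                              n_points = 100L) {
  view <- match.arg(view)
  trajs <- if (inherits(stride_set, "stride_set")) {
    keep <- !stride_set$strides$turn
    stride_set$trajectories[keep]
  } else {
    stride_set
  }
  if (length(trajs) < 5L) stop("need at least 5 strides for cyclograms")
  cols <- if (view == "side") c(1L, 3L) else c(1L, 2L)
  shapes <- list()
  raws <- list()
  for (tr in trajs) {
    xy <- as.matrix(tr)[, cols, drop = FALSE]
    m <- nrow(xy)
    u <- seq(0, 1, length.out = m)
    uo <- seq(0, 1, length.out = n_points)
    res <- cbind(stats::approx(u, xy[, 1], xout = uo)$y,
                 stats::approx(u, xy[, 2], xout = uo)$y)
    cen <- sweep(res, 2, colMeans(res))
    rms <- sqrt(mean(rowSums(cen^2)))
    if (rms < 1e-12) next  # degenerate all-zero shape
    raws[[length(raws) + 1L]] <- res
    shapes[[length(shapes) + 1L]] <- cen / rms
  }
  if (length(shapes) < 5L) stop("fewer than 5 non-degenerate strides")
  structure(list(shapes = shapes, raw = raws,
                 mean_shape = Reduce(`+`, shapes) / length(shapes),
                 view = view),
            class = "cyclogram_set")
}

#' @export
print.cyclogram_set <- function(x, ...) {
  cat(sprintf("<cyclogram_set> %s view, %d cycles of %d points\n",
              x$view, length(x$shapes), nrow(x$mean_shape)))
  invisible(x)
}

#' Cyclogram shape deviation: sum of squared differences
#'
#' Pointwise squared distance between two normalized cyclograms sharing the
#' same start-phase convention (initial contact).  0 means the shapes are
#' identical; because shapes are centred and scaled first, the measure is
#' independent of stride length and of uniform offsets.
#'
#' @param shape,reference `n x 2` normalized shape matrices.
#' @return SSD (dimensionless, >= 0).
#' @export
cyclogram_ssd <- function(shape, reference) {
  shape <- as.matrix(shape); reference <- as.matrix(reference)
  if (!all(dim(shape) == dim(reference))) {
    stop("shape and reference must have matching dimensions")
  }
  sum((shape - reference)^2)
}

#' Cycle-to-cycle consistency: angular component of the coefficient of
#' correspondence
#'
#' For each of the normalized-time segments joining consecutive shape points,
#' the segment direction angle is computed in every cycle; the circular mean
#' resultant length of those angles across cycles is computed per segment and
#' averaged over segments.  100% means every cycle traces the same direction
#' sequence; random directions give values near 0.  Zero-length segments are
#' excluded from their segment's contribution.
#'
#' @param cyclograms A `cyclogram_set`, or a list of `n x 2` shapes (>= 5).
#' @return ACC in percent (0-100).
#' @export
cyclogram_acc <- function(cyclograms) {
  shapes <- if (inherits(cyclograms, "cyclogram_set")) cyclograms$shapes
            else cyclograms
  if (length(shapes) < 5L) stop("need at least 5 cycles")
  n <- nrow(shapes[[1]])
  # angle matrix: (n-1) segments x cycles
  ang <- vapply(shapes, function(s) {
    d <- diff(as.matrix(s))
    a <- atan2(d[, 2], d[, 1])
    a[rowSums(d^2) < 1e-24] <- NA  # zero-length segment
    a
  }, numeric(n - 1L))
  rbar <- apply(ang, 1, function(a) {
    a <- a[!is.na(a)]
    if (length(a) < 2L) return(NA_real_)
    sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  })
  100 * mean(rbar, na.rm = TRUE)
}

#' Enclosed cyclogram area
#'
#' Absolute shoelace polygon area of the closed shape (first and last points
#' joined).  Self-intersecting loops are allowed; the convention is the
#' absolute value of the signed area.
#'
#' @param shape An `n x 2` shape matrix (normalized or raw scale).
#' @return Area (dimensionless for normalized shapes, m^2 for raw).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 101)[-101]
#' cyclogram_area(cbind(cos(th), sin(th)))  # ~ pi
#' @export
cyclogram_area <- function(shape) {
  s <- as.matrix(shape)
  x <- s[, 1]; y <- s[, 2]
  n <- nrow(s)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}
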