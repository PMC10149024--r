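# Internal numerical helpers shared across modules.

GRAVITY <- 9.80665  # m/s^2, fixed convention for the whole package

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the random seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so simulation functions are deterministic without
#' clobbering the session's stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Cumulative trapezoidal integral of y over t; same length as y, starts at 0.
cumtrapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum(diff(t) * (y[-1] + y[-n]) / 2))
}

# Definite trapezoidal integral.
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum(diff(t) * (y[-1] + y[-n]) / 2)
}

# Centered moving average with edge replication; k must be odd-ish (coerced).
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  n <- length(x)
  if (k >= n) return(rep(mean(x), n))
  cs <- cumsum(c(0, x))
  half <- (k - 1L) %/% 2L
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Local maxima indices of x with minimum height and minimum spacing (samples).
# Equal-height neighbours collapse to the earliest sample; spacing conflicts are
# resolved greedily by descending height, earliest-first on ties.
find_peaks <- function(x, min_height = -Inf, min_distance = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  # rising-then-falling, tolerant of flat tops (take first sample of a plateau)
  rise <- c(FALSE, d > 0)
  fall <- c(cummax_run(d), FALSE)
  cand <- which(rise & fall)
  cand <- cand[x[cand] >= min_height]
  if (length(cand) <= 1L || min_distance <= 1L) return(cand)
  ord <- cand[order(-x[cand], cand)]
  keep <- logical(0)
  chosen <- integer(0)
  for (i in ord) {
    if (all(abs(i - chosen) >= min_distance)) chosen <- c(chosen, i)
  }
  sort(chosen)
}

# helper for find_peaks: at position i, TRUE if the next nonzero diff is negative
cummax_run <- function(d) {
  nxt <- rev(Reduce(function(acc, v) if (v != 0) v else acc, rev(d),
                    accumulate = TRUE))
  nxt < 0
}

# linear interpolation clamped to the data range
interp_clamp <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, rule = 2, ties = mean)$y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
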