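# Shared helpers for the test suite.

# Manually constructed gait_events (bypasses detection) for unit-testing the
# temporal-parameter and trajectory stages against hand-computed oracles.
make_events <- function(ic, fc, ms = (ic + fc) / 2) {
  structure(list(ic = ic, fc = fc, ms = ms,
                 ic_corroborated = rep(NA, length(ic)), dropped = 0L),
            class = "gait_events")
}

# Perfect alternating event trains: left IC at 0, D, 2D, ...; right shifted by
# D/2; FC at IC + (1 - swing) * D.  Returns both sides' events.
make_alternating_events <- function(n = 20, D = 1.2, swing = 0.4) {
  icl <- (seq_len(n) - 1) * D
  icr <- icl + D / 2
  list(left = make_events(icl, icl + (1 - swing) * D),
       right = make_events(icr, icr + (1 - swing) * D))
}

# A short simulated trial shared by several expensive tests (computed once).
short_trial <- local({
  cache <- NULL
  function(duration = 60, seed = 11, noise = noise_model(seed = seed)) {
    key <- paste(duration, seed, noise$accel_noise_sd, noise$gyro_noise_sd)
    if (!is.null(cache) && identical(cache$key, key)) return(cache$trial)
    tr <- simulate_trial(gait_profile(trial_duration = duration), noise)
    cache <<- list(key = key, trial = tr)
    tr
  }
})

# Planted 4-cluster centre patterns: first 8 features informative, last
# (p - 8) pure noise.  Minimum pairwise centre distance is 2 * scale.
cluster_centers <- function(scale = 4, p = 10) {
  pat <- rbind(rep(0, 8),
               c(1, 1, 1, 1, 0, 0, 0, 0),
               c(0, 0, 0, 0, 1, 1, 1, 1),
               c(1, 1, -1, -1, 1, 1, -1, -1))
  cbind(scale * pat, matrix(0, 4, p - 8))
}

cluster_specs_from_centers <- function(centers, n_per = 15, sd = 1) {
  lapply(seq_len(nrow(centers)), function(k) {
    list(mean = centers[k, ], sd = sd, n = n_per)
  })
}

# Unit circle sampled at m points (open polyline; close_shape-style closure is
# the consumer's concern).
circle_shape <- function(m = 100, noise_sd = 0, seed = NULL) {
  th <- seq(0, 2 * pi, length.out = m + 1)[-(m + 1)]
  s <- cbind(cos(th), sin(th))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    s <- s + matrix(stats::rnorm(2 * m, 0, noise_sd), m, 2)
  }
  s
}
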