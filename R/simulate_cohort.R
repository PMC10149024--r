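#' Simulate a cluster-structured gait feature table
#'
#' Draws rows from per-cluster multivariate normals with diagonal covariance,
#' as a planted-truth harness for the clustering stage.
#'
#' @param cluster_specs List of cluster specifications, each a list with
#'   `mean` (feature-mean vector), `sd` (feature-sd vector, recycled) and `n`
#'   (rows, >= 2).  At least two clusters; all means must share one
#'   dimensionality.
#' @param seed Integer seed.
#' @param feature_names Optional column names (default `F1..Fp`).
#' @param sixmwt Optional vector of per-cluster mean 6MWT distances (m); when
#'   given, a noisy `sixmwt_distance` column is added (sd 20 m) so cluster
#'   relabelling by walking capacity can be exercised.
#' @return List with `features` (data frame), `labels` (integer vector of
#'   true cluster ids) and, if requested, `sixmwt_distance`.
#' @export
simulate_cohort_features <- function(cluster_specs, seed = 1L,
                                     feature_names = NULL, sixmwt = NULL) {
  if (length(cluster_specs) < 2L) stop("need at least two clusters")
  p <- length(cluster_specs[[1]]$mean)
  for (cs in cluster_specs) {
    if (length(cs$mean) != p) stop("cluster specs have mismatched dimensionality")
    if ((cs$n %||% 0) < 2L) stop("each cluster needs n >= 2")
  }
  with_seed(seed, {
    rows <- lapply(seq_along(cluster_specs), function(k) {
      cs <- cluster_specs[[k]]
      sds <- rep(cs$sd, length.out = p)
      m <- matrix(stats::rnorm(cs$n * p), cs$n, p)
      sweep(sweep(m, 2, sds, `*`), 2, cs$mean, `+`)
    })
    x <- do.call(rbind, rows)
    colnames(x) <- feature_names %||% paste0("F", seq_len(p))
    labels <- rep(seq_along(cluster_specs),
                  vapply(cluster_specs, function(cs) as.integer(cs$n), 0L))
    out <- list(features = as.data.frame(x), labels = labels)
    if (!is.null(sixmwt)) {
      out$sixmwt_distance <- stats::rnorm(length(labels), sixmwt[labels], 20)
    }
    out
  })
}

#' Simulate a longitudinal 6MWT cohort with planted improvement structure
#'
#' Generates repeat six-minute-walk-test series per subject: days since
#' injury, per-trial 6MWT distance and a per-trial gait feature vector.  The
#' change in distance between consecutive tests is
#' `delta_mean + X beta + noise`, so with `beta = 0` improvement beyond the
#' SEM is chance-level, and with a nonzero `beta` it is predictable from the
#' gait features only (the days/distance predictors of feature set 1 stay
#' uninformative).
#'
#' @param trials_per_subject Integer vector, one entry per subject (>= 1; at
#'   least one subject needs >= 2).  The default reproduces a cohort of 10
#'   subjects with 2 trials, 9 with 3 and 4 with 4 (40 consecutive pairs).
#' @param n_features Number of gait features (standard normal across trials).
#' @param beta Effect of the gait features on the next distance change;
#'   scalar 0 or a length-`n_features` vector.
#' @param delta_mean Mean distance change between consecutive tests, m.  The
#'   default equals the 16.5 m SEM so the two improvement classes are
#'   balanced in expectation.
#' @param delta_sd Noise sd of the distance change, m.
#' @param seed Integer seed.
#' @return Data frame with `subject_id`, `trial`, `day` (days since injury),
#'   `sixmwt_distance` and feature columns `G1..Gk`.
#' @export
simulate_longitudinal_cohort <- function(trials_per_subject = c(rep(2L, 10),
                                                                rep(3L, 9),
                                                                rep(4L, 4)),
                                         n_features = 10L,
                                         beta = 0,
                                         delta_mean = 16.5,
                                         delta_sd = 40,
                                         seed = 1L) {
  if (!any(trials_per_subject >= 2L)) {
    stop("at least one subject needs two or more trials")
  }
  if (length(beta) == 1L) beta <- rep(beta, n_features)
  if (length(beta) != n_features) stop("beta must have length n_features")
  with_seed(seed, {
    rows <- list()
    for (s in seq_along(trials_per_subject)) {
      m <- trials_per_subject[s]
      day0 <- round(stats::rlnorm(1, meanlog = log(200), sdlog = 1))
      gaps <- round(stats::runif(max(m - 1L, 0), 30, 150))
      days <- day0 + cumsum(c(0, gaps))
      x <- matrix(stats::rnorm(m * n_features), m, n_features)
      dist <- numeric(m)
      dist[1] <- max(stats::rnorm(1, 350, 150), 20)
      if (m > 1L) {
        for (j in 2:m) {
          delta <- delta_mean + sum(x[j - 1L, ] * beta) +
            stats::rnorm(1, 0, delta_sd)
          dist[j] <- max(dist[j - 1L] + delta, 0)
        }
      }
      df <- data.frame(subject_id = sprintf("S%02d", s), trial = seq_len(m),
                       day = days, sixmwt_distance = dist)
      colnames(x) <- paste0("G", seq_len(n_features))
      rows[[s]] <- cbind(df, as.data.frame(x))
    }
    do.call(rbind, rows)
  })
}
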