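#' Prediction configuration
#'
#' Defaults follow the published improvement-prediction setup: an SEM of
#' 16.5 m on the 6MWT distance (changes beyond it count as real improvement),
#' the chronic phase starting 365 days after injury, at most 10 selected
#' features, and a 0.9 redundancy threshold.  Random-forest hyperparameters
#' are unstated in the source method; 500 trees with unlimited depth are the
#' documented defaults.
#'
#' @param sem_m Standard error of measurement of the 6MWT, m (> 0).
#' @param chronic_day First day of the chronic phase, days post-injury.
#' @param n_top_features Maximum features kept in set 2 (>= 1).
#' @param corr_threshold Redundancy threshold (absolute Pearson r).
#' @param n_trees Random-forest trees.
#' @param nested Refit scaling/redundancy/importance selection inside each
#'   training fold (`TRUE`, no leakage) or once on all data (`FALSE`).
#' @param seed Integer seed.
#' @return A `prediction_config` list.
#' @export
prediction_config <- function(sem_m = 16.5, chronic_day = 365,
                              n_top_features = 10L, corr_threshold = 0.9,
                              n_trees = 500L, nested = TRUE, seed = 1L) {
  if (sem_m <= 0) stop("sem_m must be > 0")
  if (n_top_features < 1L) stop("n_top_features must be >= 1")
  structure(list(sem_m = sem_m, chronic_day = chronic_day,
                 n_top_features = as.integer(n_top_features),
                 corr_threshold = corr_threshold, n_trees = as.integer(n_trees),
                 nested = nested, seed = as.integer(seed)),
            class = "prediction_config")
}

#' Build present/future observation pairs
#'
#' One observation per consecutive 6MWT pair within a subject, labelled
#' `improved` when the future distance exceeds the present one by strictly
#' more than the SEM.  Chronic-shift rule: when a subject's first test lies
#' beyond `chronic_day` days post-injury, all that subject's day values are
#' shifted so the first test sits at `chronic_day` (any later timing carries
#' no additional information once the patient is chronic).  Subjects with a
#' single trial contribute nothing.
#'
#' @param trials Data frame with columns `subject_id`, `day`,
#'   `sixmwt_distance` and any per-trial gait feature columns.
#' @param config A [prediction_config()].
#' @return Data frame of class `observation_pairs`: `subject_id`,
#'   `present_distance`, `days_since_injury` (after the shift),
#'   `days_until_next`, `improved` (factor), plus the present trial's gait
#'   feature columns.
#' @export
build_observations <- function(trials, config = prediction_config()) {
  need <- c("subject_id", "day", "sixmwt_distance")
  if (!all(need %in% names(trials))) {
    stop("trials must have columns: ", paste(need, collapse = ", "))
  }
  feat_cols <- setdiff(names(trials), c(need, "trial"))
  obs <- list()
  for (sid in unique(trials$subject_id)) {
    tr <- trials[trials$subject_id == sid, , drop = FALSE]
    tr <- tr[order(tr$day), , drop = FALSE]
    if (anyDuplicated(tr$day)) stop("duplicate trial dates for subject ", sid)
    if (nrow(tr) < 2L) next
    if (tr$day[1] > config$chronic_day) {
      tr$day <- tr$day - (tr$day[1] - config$chronic_day)
    }
    for (j in seq_len(nrow(tr) - 1L)) {
      delta <- tr$sixmwt_distance[j + 1L] - tr$sixmwt_distance[j]
      row <- data.frame(subject_id = sid,
                        present_distance = tr$sixmwt_distance[j],
                        days_since_injury = tr$day[j],
                        days_until_next = tr$day[j + 1L] - tr$day[j],
                        improved = factor(delta > config$sem_m,
                                          levels = c(FALSE, TRUE),
                                          labels = c("not_improved", "improved")))
      obs[[length(obs) + 1L]] <- cbind(row, tr[j, feat_cols, drop = FALSE])
    }
  }
  out <- do.call(rbind, obs) %||% data.frame()
  rownames(out) <- NULL
  class(out) <- c("observation_pairs", class(out))
  out
}

#' Assemble the two predictor sets
#'
#' Feature set 1 holds only the present 6MWT distance, the days since injury
#' at the present test and the days until the future test.  Feature set 2
#' additionally holds all sensor-derived gait parameters.  Columns are
#' standardized; within set 2, one of each highly correlated pair is removed.
#' (The importance-based top-k reduction happens inside the cross-validation,
#' where a forest is available to rank features.)
#'
#' @param observations An `observation_pairs` data frame.
#' @param config A [prediction_config()].
#' @return List with `set1` and `set2` (numeric matrices), `labels` (factor)
#'   and `subject_ids`.
#' @export
make_feature_sets <- function(observations, config = prediction_config()) {
  if (nrow(observations) < 2L) stop("need at least two observations")
  if (nlevels(droplevels(observations$improved)) < 2L) {
    stop("both improvement labels must be present")
  }
  set1_cols <- c("present_distance", "days_since_injury", "days_until_next")
  gait_cols <- setdiff(names(observations),
                       c(set1_cols, "subject_id", "improved"))
  gait_cols <- gait_cols[vapply(observations[gait_cols], is.numeric, TRUE)]
  s1 <- scale(as.matrix(observations[, set1_cols, drop = FALSE]))
  s2raw <- as.matrix(observations[, c(set1_cols, gait_cols), drop = FALSE])
  s2raw <- s2raw[, apply(s2raw, 2, function(v) stats::sd(v) > 1e-12),
                 drop = FALSE]
  s2 <- scale(s2raw)
  s2 <- drop_redundant(s2, config$corr_threshold)
  list(set1 = s1, set2 = s2, labels = observations$improved,
       subject_ids = observations$subject_id)
}

# Remove one column of each pair with |pearson r| > threshold (the later one).
drop_redundant <- function(x, threshold) {
  if (ncol(x) < 2L) return(x)
  cm <- abs(stats::cor(x))
  drop <- logical(ncol(x))
  for (j in 2:ncol(x)) {
    if (any(cm[seq_len(j - 1L), j] > threshold & !drop[seq_len(j - 1L)])) {
      drop[j] <- TRUE
    }
  }
  x[, !drop, drop = FALSE]
}

#' Leave-one-subject-out random-forest cross-validation
#'
#' For each subject, a binary random forest is trained on all other subjects'
#' observations and evaluated on the held-out subject.  By default (`nested`),
#' standardization, redundancy removal and the importance-based top-k feature
#' selection are refit inside each training fold and applied to the test
#' subject, so no information leaks across folds.  A fold whose training set
#' is single-class predicts the majority class.
#'
#' @param features Numeric predictor matrix (rows = observations).
#' @param labels Factor of `not_improved` / `improved`.
#' @param subject_ids Subject of each observation (fold unit).
#' @param config A [prediction_config()].
#' @param select Apply redundancy removal + top-k importance selection inside
#'   folds (default `TRUE`; set 1's three predictors skip selection).
#' @return Object of class `cv_result`: `predicted` (factor), `accuracy`
#'   ((TP+TN)/N), `confusion` (absolute) and `confusion_norm` (row-normalized),
#'   `importance` (mean decrease in Gini, averaged over folds).
#' @export
loso_cv <- function(features, labels, subject_ids,
                    config = prediction_config(), select = TRUE) {
  # canonical subject order: results do not depend on input block ordering
  ord <- order(as.character(subject_ids))
  x <- as.matrix(features)[ord, , drop = FALSE]
  labels <- factor(labels)[ord]
  subject_ids <- subject_ids[ord]
  subjects <- unique(subject_ids)
  if (length(subjects) < 3L) stop("need at least three subjects")
  pred <- factor(rep(NA_character_, nrow(x)), levels = levels(labels))
  imp <- stats::setNames(numeric(ncol(x)), colnames(x))
  imp_n <- 0L
  for (i in seq_along(subjects)) {
    test <- subject_ids == subjects[i]
    xtr <- x[!test, , drop = FALSE]
    ytr <- droplevels(labels[!test])
    if (nlevels(ytr) < 2L) {
      pred[test] <- names(which.max(table(ytr)))
      next
    }
    if (config$nested) {
      ctr <- colMeans(xtr)
      scl <- apply(xtr, 2, stats::sd)
      scl[scl < 1e-12] <- 1
      xtr_s <- scale(xtr, ctr, scl)
      xte_s <- scale(x[test, , drop = FALSE], ctr, scl)
    } else {
      xtr_s <- xtr
      xte_s <- x[test, , drop = FALSE]
    }
    keep <- colnames(xtr_s)
    if (select && ncol(xtr_s) > config$n_top_features) {
      xtr_s <- drop_redundant(xtr_s, config$corr_threshold)
      rf0 <- with_seed(config$seed + i,
                       randomForest::randomForest(xtr_s, ytr,
                                                  ntree = config$n_trees))
      ii <- randomForest::importance(rf0)[, 1]
      keep <- names(sort(ii, decreasing = TRUE))[
        seq_len(min(config$n_top_features, length(ii)))]
      xtr_s <- xtr_s[, keep, drop = FALSE]
    }
    rf <- with_seed(config$seed + 1000L + i,
                    randomForest::randomForest(xtr_s, ytr,
                                               ntree = config$n_trees))
    pred[test] <- stats::predict(rf, xte_s[, colnames(xtr_s), drop = FALSE])
    fi <- randomForest::importance(rf)[, 1]
    imp[names(fi)] <- imp[names(fi)] + fi
    imp_n <- imp_n + 1L
  }
  conf <- table(truth = labels, predicted = pred)
  acc <- sum(diag(conf)) / sum(conf)
  # report predictions in the caller's row order
  pred_out <- pred
  pred_out[ord] <- pred
  structure(list(predicted = pred_out, accuracy = acc, confusion = conf,
                 confusion_norm = prop.table(conf, 1),
                 importance = sort(imp / max(imp_n, 1L), decreasing = TRUE)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> accuracy %.3f (N = %d)\n",
              x$accuracy, sum(x$confusion)))
  print(x$confusion)
  invisible(x)
}

#' Compare improvers and non-improvers feature by feature
#'
#' Kruskal-Wallis test of each feature between the two improvement classes,
#' with class medians and significance stars.
#'
#' @param features Numeric matrix or data frame.
#' @param labels Factor with both classes present.
#' @return Data frame: `feature`, `median_improved`, `median_not_improved`,
#'   `p`, `stars`.
#' @export
compare_improvers <- function(features, labels) {
  labels <- factor(labels)
  if (any(table(labels) == 0L) || nlevels(labels) < 2L) {
    stop("both classes must be non-empty")
  }
  x <- as.data.frame(features)
  out <- do.call(rbind, lapply(names(x), function(f) {
    p <- stats::kruskal.test(x[[f]], labels)$p.value
    med <- tapply(x[[f]], labels, stats::median)
    mi <- if ("improved" %in% names(med)) med[["improved"]] else med[[2]]
    mn <- if ("not_improved" %in% names(med)) med[["not_improved"]] else med[[1]]
    data.frame(feature = f, median_improved = unname(mi),
               median_not_improved = unname(mn), p = p)
  }))
  out$stars <- ifelse(out$p < 0.001, "***",
                      ifelse(out$p < 0.01, "**", ifelse(out$p < 0.05, "*", "")))
  out
}
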