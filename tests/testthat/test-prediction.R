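test_that("build_observations pairs consecutive trials and labels strictly", {
  cfg <- prediction_config(sem_m = 16.5)
  trials <- data.frame(
    subject_id = c("A", "A", "A", "B", "B", "C"),
    day = c(100, 150, 300, 50, 90, 200),
    sixmwt_distance = c(200, 216.5, 250, 300, 330, 400),
    g1 = 1:6)
  obs <- build_observations(trials, cfg)
  # one pair per consecutive trial; single-trial subject C contributes nothing
  expect_equal(nrow(obs), 3)
  # delta = 16.5 is NOT an improvement (strictly greater than the SEM)
  expect_identical(as.character(obs$improved),
                   c("not_improved", "improved", "improved"))
  expect_equal(obs$days_until_next, c(50, 150, 40))
  # present-trial features travel with the observation
  expect_equal(obs$g1, c(1, 2, 4))
  expect_error(build_observations(trials[, 1:2], cfg), "columns")
  dup <- trials[c(1, 1), ]
  expect_error(build_observations(dup, cfg), "duplicate")
})

test_that("chronic subjects are shifted to the chronic-phase start day", {
  cfg <- prediction_config(chronic_day = 365)
  trials <- data.frame(subject_id = "Z", day = c(900, 1000),
                       sixmwt_distance = c(100, 200))
  obs <- build_observations(trials, cfg)
  expect_equal(obs$days_since_injury, 365)
  expect_equal(obs$days_until_next, 100)
  # sub-chronic subjects keep their days
  early <- data.frame(subject_id = "Y", day = c(100, 200),
                      sixmwt_distance = c(100, 200))
  expect_equal(build_observations(early, cfg)$days_since_injury, 100)
})

test_that("feature sets have the documented composition", {
  coh <- simulate_longitudinal_cohort(seed = 14)
  obs <- build_observations(coh)
  expect_equal(nrow(obs), 40)
  fs <- make_feature_sets(obs)
  expect_identical(colnames(fs$set1),
                   c("present_distance", "days_since_injury", "days_until_next"))
  expect_true(all(colnames(fs$set1) %in% colnames(fs$set2)))
  expect_true(all(paste0("G", 1:10) %in% colnames(fs$set2) |
                    ncol(fs$set2) < 13))  # minus any redundant columns
  expect_equal(unname(colMeans(fs$set1)), rep(0, 3), tolerance = 1e-9)
  expect_equal(unname(apply(fs$set2, 2, sd)), rep(1, ncol(fs$set2)),
               tolerance = 1e-9)
})

test_that("drop_redundant removes the later of a correlated pair", {
  set.seed(15)
  a <- rnorm(50)
  x <- cbind(A = a, B = rnorm(50), C = a + rnorm(50, 0, 0.01))
  out <- gaitsci:::drop_redundant(scale(x), 0.9)
  expect_identical(colnames(out), c("A", "B"))
})

test_that("loso_cv is deterministic and invariant to row reordering", {
  coh <- simulate_longitudinal_cohort(seed = 16)
  obs <- build_observations(coh)
  fs <- make_feature_sets(obs)
  cfg <- prediction_config(seed = 2)
  r1 <- loso_cv(fs$set1, fs$labels, fs$subject_ids, cfg)
  r2 <- loso_cv(fs$set1, fs$labels, fs$subject_ids, cfg)
  expect_identical(r1$predicted, r2$predicted)
  expect_equal(r1$accuracy, sum(diag(r1$confusion)) / sum(r1$confusion))
  # permute whole subject blocks: same accuracy, predictions follow the rows
  set.seed(16)
  perm <- sample(nrow(fs$set1))
  r3 <- loso_cv(fs$set1[perm, , drop = FALSE], fs$labels[perm],
                fs$subject_ids[perm], cfg)
  expect_equal(r3$accuracy, r1$accuracy)
  expect_identical(as.character(r3$predicted),
                   as.character(r1$predicted)[perm])
  expect_identical(dim(r1$confusion), c(2L, 2L))
  expect_equal(rowSums(r1$confusion_norm), c(not_improved = 1, improved = 1))
})

test_that("loso_cv applies nested top-k selection for wide feature sets", {
  coh <- simulate_longitudinal_cohort(n_features = 15, beta = 25, seed = 17)
  obs <- build_observations(coh)
  fs <- make_feature_sets(obs)
  cfg <- prediction_config(seed = 3, n_top_features = 10)
  r <- loso_cv(fs$set2, fs$labels, fs$subject_ids, cfg)
  expect_s3_class(r, "cv_result")
  expect_true(all(!is.na(r$predicted)))
  expect_lte(sum(r$importance > 0), ncol(fs$set2))
  expect_error(loso_cv(fs$set2[1:3, ], fs$labels[1:3], c("a", "a", "b"), cfg),
               "three subjects")
})

test_that("compare_improvers reports per-feature class contrasts", {
  set.seed(18)
  lab <- factor(rep(c("improved", "not_improved"), each = 20))
  x <- data.frame(up = rnorm(40) + 2 * (lab == "improved"), flat = rnorm(40))
  ci <- compare_improvers(x, lab)
  expect_identical(ci$feature, c("up", "flat"))
  expect_lt(ci$p[1], 0.01)
  expect_gt(ci$median_improved[1], ci$median_not_improved[1])
  expect_error(compare_improvers(x, factor(rep("improved", 40),
                                           levels = levels(lab))),
               "non-empty")
})
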