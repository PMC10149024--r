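test_that("fit_pca standardizes, retains by explained variance, and matches prcomp", {
  set.seed(5)
  x <- as.data.frame(matrix(rnorm(300), 50, 6))
  pca <- fit_pca(x, variance_target = 0.65)
  pr <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  expl <- pr$sdev^2 / sum(pr$sdev^2)
  expect_equal(pca$explained, expl)
  expect_equal(pca$n_retained, which(cumsum(expl) >= 0.65)[1])
  expect_equal(abs(pca$loadings), abs(pr$rotation), tolerance = 1e-9)
  # loadings are orthonormal
  expect_equal(crossprod(pca$loadings), diag(ncol(x)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(dim(pca$scores), c(50, pca$n_retained))
})

test_that("fit_pca handles missing rows and constant features", {
  set.seed(6)
  x <- as.data.frame(matrix(rnorm(100), 20, 5))
  x[3, 2] <- NA
  pca <- fit_pca(x)
  expect_identical(pca$rows_used, setdiff(1:20, 3))
  pm <- fit_pca(x, impute = "median")
  expect_identical(pm$rows_used, 1:20)
  x$V6 <- 1
  expect_warning(fit_pca(x[-3, ]), "constant")
})

test_that("choose_k finds the planted number of clusters", {
  for (k_true in 2:4) {
    centers <- matrix(0, k_true, 4)
    for (k in seq_len(k_true)) centers[k, k] <- 10
    cf <- simulate_cohort_features(
      cluster_specs_from_centers(centers, n_per = 12, sd = 0.5), seed = k_true)
    k_hat <- choose_k(as.matrix(cf$features))
    expect_equal(as.integer(k_hat), k_true)
    expect_true(is.numeric(attr(k_hat, "merge_heights")))
  }
  expect_error(choose_k(matrix(0, 3, 2)), "at least four")
})

test_that("cluster_kmeans is deterministic and orders labels by 6MWT", {
  centers <- rbind(c(0, 0), c(8, 0), c(0, 8))
  cf <- simulate_cohort_features(
    cluster_specs_from_centers(centers, n_per = 10, sd = 0.5), seed = 7,
    sixmwt = c(200, 600, 400))
  a1 <- cluster_kmeans(as.matrix(cf$features), 3, seed = 1,
                       sixmwt_distance = cf$sixmwt_distance)
  a2 <- cluster_kmeans(as.matrix(cf$features), 3, seed = 1,
                       sixmwt_distance = cf$sixmwt_distance)
  expect_identical(as.integer(a1), as.integer(a2))
  # cluster 1 must be the fastest walkers, labels decreasing with distance
  m <- tapply(cf$sixmwt_distance, as.integer(a1), mean)
  expect_true(all(diff(m) < 0))
  # planted cluster 2 (distance 600) becomes label 1
  expect_equal(unique(as.integer(a1)[cf$labels == 2]), 1L)
  expect_error(cluster_kmeans(as.matrix(cf$features), 1), "k must be")
})

test_that("core-feature selection recovers planted discriminative features", {
  cf <- simulate_cohort_features(
    cluster_specs_from_centers(cluster_centers(scale = 4, p = 10)), seed = 9)
  pca <- fit_pca(cf$features)
  core <- select_core_features(pca, cf$features, cf$labels)
  informative <- paste0("F", 1:8)
  expect_gt(length(core), 0)
  expect_true(all(core %in% informative))
  expect_true(all(attr(core, "kruskal_p") < 0.05))
})

test_that("redundant features are pruned by Kruskal-Wallis p", {
  set.seed(10)
  g <- rep(1:3, each = 20)
  base <- rnorm(60) + g
  x <- data.frame(A = base, B = base + rnorm(60, 0, 0.01),
                  C = rnorm(60) + 0.8 * g, D = rnorm(60))
  pca <- fit_pca(x, variance_target = 0.99)
  core <- select_core_features(pca, x, g, top_per_pc = 4)
  # A and B correlate > 0.9; only one survives
  expect_lt(sum(c("A", "B") %in% core), 2)
  expect_false("D" %in% core)
})

test_that("dunn_test agrees with kruskal.test for two groups", {
  set.seed(11)
  x <- c(rnorm(15), rnorm(15, 1))
  g <- rep(1:2, each = 15)
  dt <- dunn_test(x, g)
  kw <- stats::kruskal.test(x, g)
  expect_equal(dt$z^2, unname(kw$statistic), tolerance = 1e-9)
  expect_equal(dt$p, 2 * stats::pnorm(-abs(dt$z)))
  # three groups: one row per pair, Holm >= unadjusted
  x3 <- c(x, rnorm(15, 2))
  dt3 <- dunn_test(x3, rep(1:3, each = 15))
  expect_equal(nrow(dt3), 3)
  expect_true(all(dt3$p_holm >= dt3$p))
})

test_that("compare_clusters produces the documented tables", {
  cf <- simulate_cohort_features(
    cluster_specs_from_centers(rbind(c(0, 0), c(6, 0), c(0, 6)), n_per = 12,
                               sd = 0.7), seed = 12)
  dat <- cf$features
  set.seed(12)
  dat$aid <- factor(sample(c("none", "cane"), nrow(dat), replace = TRUE))
  cc <- compare_clusters(dat, cf$labels, core_features = c("F1", "F2"))
  expect_s3_class(cc, "cluster_comparison")
  expect_setequal(cc$continuous$variable, c("F1", "F2"))
  expect_identical(cc$categorical$variable, "aid")
  expect_true(all(cc$continuous$p[cc$continuous$stars == "***"] < 0.001))
  expect_named(cc$dunn, c("F1", "F2"))
  expect_equal(nrow(cc$dunn$F1), 3)
  expect_error(compare_clusters(dat, rep(1, nrow(dat))), "2 non-empty")
})

test_that("identify_gait_clusters chains the full procedure", {
  cf <- simulate_cohort_features(
    cluster_specs_from_centers(cluster_centers(scale = 4, p = 10)), seed = 13,
    sixmwt = c(600, 450, 300, 150))
  res <- identify_gait_clusters(cf$features,
                                sixmwt_distance = cf$sixmwt_distance)
  expect_s3_class(res, "cluster_result")
  expect_equal(res$k, 4L)
  expect_length(res$assignments, 60)
  skip_if_not_installed("mclust")
  expect_gt(mclust::adjustedRandIndex(res$assignments, cf$labels), 0.8)
})
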