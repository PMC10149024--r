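#' PCA of the gait feature table
#'
#' Standardizes features to zero mean and unit sd (constant features are
#' dropped with a warning), runs a principal component analysis, and retains
#' the smallest number of components whose cumulative explained variance
#' reaches `variance_target`.
#'
#' @param features Data frame or matrix of per-trial gait features (rows with
#'   missing values are dropped unless `impute = "median"`).
#' @param variance_target Cumulative explained-variance target in (0, 1].
#' @param impute `"drop"` (default) or `"median"`.
#' @return An object of class `pca_model`: list with `center`, `scale`,
#'   `loadings` (features x PCs, orthonormal columns), `explained` (variance
#'   fractions), `n_retained`, `scores` (rows x retained PCs) and `rows_used`.
#' @export
fit_pca <- function(features, variance_target = 0.65, impute = c("drop", "median")) {
  impute <- match.arg(impute)
  x <- as.matrix(features)
  rows_used <- seq_len(nrow(x))
  if (anyNA(x)) {
    if (impute == "median") {
      for (j in seq_len(ncol(x))) {
        x[is.na(x[, j]), j] <- stats::median(x[, j], na.rm = TRUE)
      }
    } else {
      rows_used <- which(stats::complete.cases(x))
      x <- x[rows_used, , drop = FALSE]
    }
  }
  if (nrow(x) < 2L) stop("need at least two complete trials")
  sds <- apply(x, 2, stats::sd)
  const <- sds < 1e-12 | is.na(sds)
  if (any(const)) {
    warning("dropping constant feature(s): ",
            paste(colnames(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  explained <- pr$sdev^2 / sum(pr$sdev^2)
  n_ret <- max(1L, which(cumsum(explained) >= min(variance_target, 1))[1])
  if (is.na(n_ret)) n_ret <- length(explained)
  structure(list(center = pr$center, scale = pr$scale,
                 loadings = pr$rotation, explained = explained,
                 n_retained = n_ret,
                 scores = pr$x[, seq_len(n_ret), drop = FALSE],
                 rows_used = rows_used),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d features, %d PCs retained (%.1f%% variance)\n",
              nrow(x$loadings), x$n_retained,
              100 * sum(x$explained[seq_len(x$n_retained)])))
  invisible(x)
}

#' Choose the number of clusters from a Ward dendrogram
#'
#' Hierarchical clustering with Ward's criterion on the PC scores; the chosen
#' k maximises the relative drop in merge height between having k - 1 and k
#' clusters (the dendrogram elbow), ties resolved to the smaller k.
#'
#' @param pc_scores Matrix of retained PC scores (or a `pca_model`).
#' @param k_range Candidate cluster counts, within `[2, n - 1]`.
#' @return Chosen k, with attribute `"merge_heights"`.
#' @export
choose_k <- function(pc_scores, k_range = 2:8) {
  if (inherits(pc_scores, "pca_model")) pc_scores <- pc_scores$scores
  n <- nrow(pc_scores)
  if (n < 4L) stop("need at least four trials to choose k")
  k_range <- k_range[k_range >= 2 & k_range <= n - 1L]
  hc <- stats::hclust(stats::dist(pc_scores), method = "ward.D2")
  H <- sort(hc$height, decreasing = TRUE)  # H[j]: merge reducing j+1 -> j
  rel_drop <- vapply(k_range, function(k) {
    if (k > length(H)) return(NA_real_)
    val <- (H[k - 1L] - H[k]) / H[k - 1L]
    if (!is.finite(val)) 0 else val
  }, 0)
  best <- k_range[which.max(rel_drop)]  # which.max: earliest (smallest k) tie
  structure(best, merge_heights = H)
}

#' K-means clustering on the retained principal components
#'
#' Multiple-restart k-means (best total within-cluster sum of squares kept)
#' with a fixed seed for determinism.  Cluster labels are re-indexed by
#' decreasing cluster-mean 6MWT distance when distances are supplied (cluster
#' 1 = best walkers), otherwise by decreasing cluster size.
#'
#' @param pc_scores Matrix of retained PC scores (or a `pca_model`).
#' @param k Number of clusters (>= 2, <= n).
#' @param seed Integer seed.
#' @param sixmwt_distance Optional per-trial 6MWT distances (m) for label
#'   ordering.
#' @param nstart Random restarts.
#' @return Integer vector of cluster assignments (1..k) with attribute
#'   `"centers"`.
#' @export
cluster_kmeans <- function(pc_scores, k, seed = 1L, sixmwt_distance = NULL,
                           nstart = 50L) {
  if (inherits(pc_scores, "pca_model")) pc_scores <- pc_scores$scores
  n <- nrow(pc_scores)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k exceeds the number of trials")
  km <- with_seed(seed, stats::kmeans(pc_scores, centers = k, nstart = nstart,
                                      iter.max = 100L))
  cl <- km$cluster
  ord <- if (!is.null(sixmwt_distance)) {
    order(-vapply(seq_len(k), function(g) mean(sixmwt_distance[cl == g]), 0))
  } else {
    order(-tabulate(cl, k))
  }
  relab <- match(cl, ord)
  structure(relab, centers = km$centers[ord, , drop = FALSE])
}

#' Core discriminative gait parameters
#'
#' Takes the union of the five features with the largest absolute loading on
#' each retained PC, keeps those differing significantly across clusters
#' (Kruskal-Wallis, `p < alpha`), and removes redundancy: among pairs with
#' absolute Pearson correlation above `corr_threshold`, the feature with the
#' larger Kruskal-Wallis p is dropped.  The result is ordered by PC and
#' absolute loading.
#'
#' @param pca A `pca_model`.
#' @param features The feature table the PCA was fit on.
#' @param assignments Cluster assignments for the rows used by the PCA.
#' @param alpha Kruskal-Wallis significance level.
#' @param corr_threshold Absolute Pearson correlation above which two
#'   features are redundant.
#' @param top_per_pc Candidates per PC.
#' @return Character vector of core feature names (possibly empty, with a
#'   warning), with attribute `"kruskal_p"`.
#' @export
select_core_features <- function(pca, features, assignments, alpha = 0.05,
                                 corr_threshold = 0.9, top_per_pc = 5L) {
  x <- as.data.frame(features)[pca$rows_used, rownames(pca$loadings),
                               drop = FALSE]
  cand <- character(0)
  for (pc in seq_len(pca$n_retained)) {
    ld <- abs(pca$loadings[, pc])
    top <- names(sort(ld, decreasing = TRUE))[seq_len(min(top_per_pc, length(ld)))]
    cand <- c(cand, setdiff(top, cand))
  }
  g <- factor(assignments)
  kw <- vapply(cand, function(f) {
    stats::kruskal.test(x[[f]], g)$p.value
  }, 0)
  keep <- cand[kw < alpha]
  if (length(keep) > 1L) {
    cm <- abs(stats::cor(x[, keep, drop = FALSE]))
    drop <- character(0)
    pairs <- which(upper.tri(cm) & cm > corr_threshold, arr.ind = TRUE)
    if (nrow(pairs)) {
      ord <- order(-cm[pairs])
      for (r in ord) {
        a <- keep[pairs[r, 1]]; b <- keep[pairs[r, 2]]
        if (a %in% drop || b %in% drop) next
        drop <- c(drop, if (kw[a] > kw[b]) a else b)
      }
    }
    keep <- setdiff(keep, drop)
  }
  if (!length(keep)) warning("no core features survived the filters")
  structure(keep, kruskal_p = kw[keep])
}

#' Cluster comparison statistics
#'
#' Kruskal-Wallis tests for continuous variables, Fisher's exact test for
#' categorical ones (Monte-Carlo p above 2 x 2, fixed seed), and pairwise
#' Dunn post-hoc tests for each core gait parameter -- optionally including a
#' healthy-control group as an extra comparison group.  Significance stars at
#' 0.05 / 0.01 / 0.001.
#'
#' @param data Data frame of the variables to compare.
#' @param assignments Group assignments (cluster ids; may include `"HC"`).
#' @param continuous,categorical Character vectors naming the columns of each
#'   type (defaults: numeric columns are continuous, the rest categorical).
#' @param core_features Columns that additionally get pairwise Dunn tests.
#' @param seed Seed for the Monte-Carlo Fisher p.
#' @return An object of class `cluster_comparison`: list with `continuous`
#'   (variable, H, p, stars), `categorical` (variable, p, stars) and `dunn`
#'   (named list of pairwise tables with z, unadjusted p, Holm-adjusted p).
#' @export
compare_clusters <- function(data, assignments, continuous = NULL,
                             categorical = NULL, core_features = character(0),
                             seed = 1L) {
  g <- factor(assignments)
  if (any(table(g) == 0L) || nlevels(g) < 2L) stop("need >= 2 non-empty groups")
  is_num <- vapply(data, is.numeric, TRUE)
  continuous <- continuous %||% names(data)[is_num]
  categorical <- categorical %||% setdiff(names(data), continuous)
  stars <- function(p) {
    ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
  }
  cont <- do.call(rbind, lapply(continuous, function(v) {
    kt <- stats::kruskal.test(data[[v]], g)
    data.frame(variable = v, H = unname(kt$statistic), p = kt$p.value)
  })) %||% data.frame()
  if (nrow(cont)) cont$stars <- stars(cont$p)
  cat_ <- do.call(rbind, lapply(categorical, function(v) {
    tab <- table(data[[v]], g)
    p <- if (all(dim(tab) == 2L)) {
      stats::fisher.test(tab)$p.value
    } else {
      with_seed(seed, stats::fisher.test(tab, simulate.p.value = TRUE,
                                         B = 10000L)$p.value)
    }
    data.frame(variable = v, p = p)
  })) %||% data.frame()
  if (nrow(cat_)) cat_$stars <- stars(cat_$p)
  dunn <- lapply(stats::setNames(core_features, core_features), function(v) {
    dunn_test(data[[v]], g)
  })
  structure(list(continuous = cont, categorical = cat_, dunn = dunn),
            class = "cluster_comparison")
}

#' Pairwise Dunn post-hoc test
#'
#' Rank-based multiple-comparison z statistics after a Kruskal-Wallis test,
#' with the standard tie correction.  P-values are two-sided and reported
#' unadjusted (as used with alpha = 0.05) together with a Holm-adjusted
#' column for transparency.
#'
#' @param x Numeric response.
#' @param g Group factor.
#' @return Data frame with `group1`, `group2`, `z`, `p`, `p_holm`.
#' @export
dunn_test <- function(x, g) {
  g <- factor(g)
  keep <- !is.na(x)
  x <- x[keep]; g <- droplevels(g[keep])
  n <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  s2 <- n * (n + 1) / 12 - tie_term
  lev <- levels(g)
  mr <- tapply(r, g, mean)
  ng <- tapply(r, g, length)
  combs <- utils::combn(lev, 2)
  z <- apply(combs, 2, function(pr) {
    (mr[pr[1]] - mr[pr[2]]) /
      sqrt(s2 * (1 / ng[pr[1]] + 1 / ng[pr[2]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = combs[1, ], group2 = combs[2, ], z = as.numeric(z),
             p = as.numeric(p), p_holm = stats::p.adjust(p, "holm"),
             row.names = NULL)
}

#' Full gait-cluster identification procedure
#'
#' Convenience wrapper chaining [fit_pca()], [choose_k()], [cluster_kmeans()]
#' and [select_core_features()].
#'
#' @param features Per-trial gait feature table.
#' @param sixmwt_distance Optional distances for cluster-label ordering.
#' @param variance_target,k_range,alpha,corr_threshold,seed Passed through.
#' @return List of class `cluster_result`: `pca`, `k`, `assignments`,
#'   `core_features`.
#' @export
identify_gait_clusters <- function(features, sixmwt_distance = NULL,
                                   variance_target = 0.65, k_range = 2:8,
                                   alpha = 0.05, corr_threshold = 0.9,
                                   seed = 1L) {
  pca <- fit_pca(features, variance_target)
  k <- choose_k(pca, k_range)
  cl <- cluster_kmeans(pca, as.integer(k), seed = seed,
                       sixmwt_distance = sixmwt_distance[pca$rows_used])
  core <- select_core_features(pca, features, cl, alpha = alpha,
                               corr_threshold = corr_threshold)
  structure(list(pca = pca, k = as.integer(k), assignments = as.integer(cl),
                 core_features = core),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d, sizes: %s\n", x$k,
              paste(tabulate(x$assignments, x$k), collapse = "/")))
  cat("  core features:", paste(x$core_features, collapse = ", "), "\n")
  invisible(x)
}
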