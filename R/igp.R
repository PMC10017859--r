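# In-Group Proportion (IGP) cluster-reproducibility validation.
#
# The IGP of a cluster is the proportion of test observations assigned to
# it (by nearest training centroid) whose nearest test-set neighbor
# carries the same assignment.  Values near 1 mean the training centroids
# predict co-membership in independent data, i.e. the cluster reproduces.

#' Assign points to their nearest centroid
#'
#' @param X numeric matrix of points (one per row).
#' @param centroids numeric matrix of centroids, same number of columns.
#' @param metric `"cosine"` or `"one_minus_pearson"` (the correlation
#'   distance used by correlation-based reproducibility tools).
#' @return integer vector of 1-based centroid labels; ties go to the
#'   lowest centroid index.
#' @export
classify_to_centroids <- function(X, centroids,
                                  metric = c("cosine", "one_minus_pearson")) {
  metric <- match.arg(metric)
  X <- if (inherits(X, "embedding_matrix")) X$vectors else as.matrix(X)
  centroids <- as.matrix(centroids)
  if (ncol(X) != ncol(centroids)) {
    stop("dimension mismatch: points have ", ncol(X), " columns, centroids ",
         ncol(centroids), call. = FALSE)
  }
  if (metric == "cosine") {
    sims <- tcrossprod(l2_normalize_rows(X), l2_normalize_rows(centroids))
  } else {
    sims <- stats::cor(t(X), t(centroids))
  }
  max.col(sims, ties.method = "first")
}

#' Per-cluster In-Group Proportion
#'
#' For each cluster `j`, the proportion of test points labeled `j` whose
#' nearest test neighbor (self excluded, same metric) is also labeled `j`.
#' A cluster with fewer than two assigned test points has an undefined
#' proportion and is reported as `NA`, excluded from summaries.
#'
#' @param X_test numeric matrix of test points.
#' @param centroid_labels integer labels of the test points (from
#'   [classify_to_centroids()]).
#' @param metric `"cosine"` or `"one_minus_pearson"`.
#' @param n_clusters number of clusters; defaults to `max(centroid_labels)`.
#' @return object of class `igp_report`: `per_cluster_igp` (named numeric,
#'   `NA` for undefined clusters), `summary` (over defined values:
#'   `median`, `iqr`, `mean`, `sd`, `q1`, `q3`, `range`), `n_test`,
#'   `undefined_clusters`.
#' @export
igp <- function(X_test, centroid_labels,
                metric = c("cosine", "one_minus_pearson"),
                n_clusters = max(centroid_labels)) {
  metric <- match.arg(metric)
  X_test <- if (inherits(X_test, "embedding_matrix")) X_test$vectors else as.matrix(X_test)
  n <- nrow(X_test)
  if (n < 2) stop("need at least two test points", call. = FALSE)
  if (length(centroid_labels) != n) {
    stop("labels length does not match test set", call. = FALSE)
  }

  D <- pairwise_distance(X_test, metric)
  diag(D) <- Inf
  nn_label <- centroid_labels[max.col(-D, ties.method = "first")]

  per <- rep(NA_real_, n_clusters)
  for (j in seq_len(n_clusters)) {
    members <- which(centroid_labels == j)
    if (length(members) >= 2) {
      per[j] <- mean(nn_label[members] == j)
    }
  }
  names(per) <- paste0("cluster", seq_len(n_clusters))

  structure(list(per_cluster_igp = per,
                 summary = summarize_igp(per),
                 n_test = n,
                 undefined_clusters = unname(which(is.na(per)))),
            class = "igp_report")
}

# Summary statistics over the defined per-cluster IGP values, using
# linear-interpolation quantiles for internal consistency with the
# upper-hinge threshold.
#' @keywords internal
summarize_igp <- function(per) {
  v <- per[!is.na(per)]
  if (length(v) == 0) {
    return(list(median = NA_real_, iqr = NA_real_, mean = NA_real_,
                sd = NA_real_, q1 = NA_real_, q3 = NA_real_,
                range = NA_real_))
  }
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2], iqr = q[3] - q[1], mean = mean(v),
       sd = stats::sd(v), q1 = q[1], q3 = q[3],
       range = max(v) - min(v))
}

#' @export
print.igp_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<igp_report> %d clusters (%d undefined), mean IGP = %.3f, median = %.3f\n",
              length(x$per_cluster_igp), length(x$undefined_clusters),
              s$mean, s$median))
  invisible(x)
}

#' Replicated train/test IGP validation
#'
#' Repeats, `n_runs` times: draw a fresh random train/test partition, fit
#' spherical k-means on the training rows, assign the test rows to the
#' fitted centroids, and compute the per-cluster IGP.  Each run gets its
#' own seed derived from the master seed, so the whole experiment is
#' reproducible.
#'
#' @param X numeric matrix or `embedding_matrix` of all points.
#' @param k number of clusters.
#' @param n_runs number of independent runs.
#' @param train_size training-set size (`< nrow(X)`).
#' @param metric IGP/assignment metric, see [igp()].
#' @param max_iter,init,restarts passed to [spherical_kmeans()].
#' @param seed master integer seed.
#' @return object of class `igp_replication`: `reports` (list of
#'   `igp_report`), `summary_table` (one row per run with columns
#'   `Iteration`, `Median`, `IQR`, `Mean`, `SD`, `Q1`, `Q3`, `Range`),
#'   `n_train`, `n_test`, `seed`.
#' @export
replicate_igp <- function(X, k, n_runs = 10, train_size,
                          metric = c("cosine", "one_minus_pearson"),
                          max_iter = 10, init = "cosine_plus_plus",
                          restarts = 5, seed = 1L) {
  metric <- match.arg(metric)
  X <- if (inherits(X, "embedding_matrix")) X$vectors else as.matrix(X)
  n <- nrow(X)
  if (train_size >= n || train_size < 1) {
    stop("train_size must be in [1, n)", call. = FALSE)
  }
  reports <- vector("list", n_runs)
  rows <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run_seed <- seed + 1000L * r
    part <- partition_records(seq_len(n), train_size, seed = run_seed)
    fit <- spherical_kmeans(X[part$train_ids, , drop = FALSE], k,
                            max_iter = max_iter, init = init,
                            restarts = restarts, seed = run_seed)
    test_labels <- classify_to_centroids(X[part$test_ids, , drop = FALSE],
                                         fit$centroids, metric = metric)
    rep_r <- igp(X[part$test_ids, , drop = FALSE], test_labels,
                 metric = metric, n_clusters = k)
    reports[[r]] <- rep_r
    s <- rep_r$summary
    rows[[r]] <- data.frame(Iteration = r - 1L, Median = s$median,
                            IQR = s$iqr, Mean = s$mean, SD = s$sd,
                            Q1 = s$q1, Q3 = s$q3, Range = s$range)
  }
  structure(list(reports = reports,
                 summary_table = do.call(rbind, rows),
                 n_train = as.integer(train_size),
                 n_test = as.integer(n - train_size),
                 seed = as.integer(seed)),
            class = "igp_replication")
}

#' @export
print.igp_replication <- function(x, ...) {
  cat(sprintf("<igp_replication> %d runs, train %d / test %d\n",
              nrow(x$summary_table), x$n_train, x$n_test))
  print(x$summary_table, row.names = FALSE)
  invisible(x)
}
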