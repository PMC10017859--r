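# Spherical k-means: points and centroids live on the unit sphere and the
# dissimilarity is the cosine distance 1 - cos(x, c).  Model selection is
# supported by the elbow (inertia) curve, the Calinski-Harabasz index and
# the mean silhouette.

#' @keywords internal
init_centroids <- function(Xn, k, method, seed) {
  n <- nrow(Xn)
  with_seed(seed, {
    if (method == "random") {
      Xn[sample.int(n, k), , drop = FALSE]
    } else if (method == "cosine_plus_plus") {
      # k-means++ seeding under the cosine distance
      idx <- sample.int(n, 1)
      for (j in seq_len(k - 1)) {
        sims <- tcrossprod(Xn, Xn[idx, , drop = FALSE])
        dmin <- 1 - apply(sims, 1, max)      # distance to nearest seed
        dmin[idx] <- 0
        p <- pmax(dmin, 0)
        if (sum(p) <= 0) p <- rep(1, n)
        idx <- c(idx, sample.int(n, 1, prob = p))
      }
      Xn[idx, , drop = FALSE]
    } else if (method == "similar_cut_like") {
      # fast farthest-first style seeding: start from a random point, then
      # repeatedly take the point whose maximum similarity to the chosen
      # seeds is smallest
      idx <- sample.int(n, 1)
      for (j in seq_len(k - 1)) {
        sims <- tcrossprod(Xn, Xn[idx, , drop = FALSE])
        smax <- apply(sims, 1, max)
        smax[idx] <- Inf
        idx <- c(idx, which.min(smax))
      }
      Xn[idx, , drop = FALSE]
    } else {
      stop("unknown init method: ", method, call. = FALSE)
    }
  })
}

#' @keywords internal
skmeans_single <- function(Xn, k, max_iter, init, seed, sparsity = NULL) {
  n <- nrow(Xn)
  C <- init_centroids(Xn, k, init, seed)
  labels <- rep(0L, n)
  inertia_trace <- numeric(0)
  events <- character(0)
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    sims <- tcrossprod(Xn, C)                      # n x k
    new_labels <- max.col(sims, ties.method = "first")
    inertia <- sum(1 - sims[cbind(seq_len(n), new_labels)])
    inertia_trace <- c(inertia_trace, inertia)
    if (identical(new_labels, labels)) {
      converged <- TRUE
      labels <- new_labels
      break
    }
    labels <- new_labels

    for (j in seq_len(k)) {
      members <- which(labels == j)
      if (length(members) == 0) {
        # empty-cluster repair: reseed with the point farthest (max cosine
        # distance) from its current centroid
        own_sim <- sims[cbind(seq_len(n), labels)]
        far <- which.min(own_sim)
        C[j, ] <- Xn[far, ]
        labels[far] <- j
        events <- c(events, sprintf("iter %d: cluster %d reseeded from point %d",
                                    iter, j, far))
        next
      }
      ctr <- colSums(Xn[members, , drop = FALSE])
      if (!is.null(sparsity)) {
        df <- colSums(Xn[members, , drop = FALSE] > 0)
        ctr[df < sparsity * length(members)] <- 0
      }
      nrm <- sqrt(sum(ctr^2))
      if (nrm < 1e-300) {
        ctr <- Xn[members[1], ]
        nrm <- 1
        events <- c(events, sprintf("iter %d: cluster %d degenerate mean", iter, j))
      }
      C[j, ] <- ctr / nrm
    }
  }

  # final assignment/inertia consistent with the returned centroids
  sims <- tcrossprod(Xn, C)
  labels <- max.col(sims, ties.method = "first")
  inertia <- sum(1 - sims[cbind(seq_len(n), labels)])
  list(centroids = C, labels = labels, inertia = inertia,
       inertia_trace = inertia_trace, converged = converged, events = events)
}

#' Spherical k-means clustering
#'
#' Alternates assignment (nearest centroid by cosine distance, ties broken
#' toward the lowest centroid index) and update (centroid = L2-normalized
#' mean of members) on L2-normalized input rows.  Stops when labels are
#' unchanged or after `max_iter` sweeps.  Among `restarts` seeded runs the
#' model with the lowest cosine inertia is returned.  An empty cluster is
#' repaired by reseeding it with the point farthest from its current
#' centroid; repairs are recorded in `$events`.
#'
#' If `minimum_df_factor` is given and the input is non-negative (sparse
#' term-frequency style data), centroid coordinates supported by fewer
#' than that fraction of member rows are zeroed before renormalization;
#' on data with negative entries (e.g. dense embedded coordinates) the
#' request is a no-op and a warning is issued.
#'
#' @param X numeric matrix, one row per point; rows must be nonzero and
#'   are normalized internally.
#' @param k number of clusters, `k <= n`.
#' @param max_iter maximum assignment/update sweeps per restart.
#' @param init `"cosine_plus_plus"` (default), `"similar_cut_like"`, or
#'   `"random"`.
#' @param restarts independent seeded initializations.
#' @param seed integer; restart r uses `seed + r - 1`.
#' @param minimum_df_factor optional sparsity fraction in `[0, 1]`.
#' @return object of class `spherical_kmeans`: `centroids` (k x d,
#'   unit-norm rows), `labels` (1-based), `inertia`,
#'   `inertia_trace` (per-iteration inertia of the winning restart), `k`,
#'   `max_iter`, `init`, `seed`, `converged`, `events`.
#' @export
spherical_kmeans <- function(X, k, max_iter = 10,
                             init = c("cosine_plus_plus", "similar_cut_like",
                                      "random"),
                             restarts = 1, seed = 1L,
                             minimum_df_factor = NULL) {
  init <- match.arg(init)
  X <- if (inherits(X, "embedding_matrix")) X$vectors else as.matrix(X)
  n <- nrow(X)
  if (k > n) stop("k = ", k, " exceeds number of points n = ", n,
                  call. = FALSE)
  Xn <- l2_normalize_rows(X)

  sparsity <- NULL
  if (!is.null(minimum_df_factor)) {
    if (all(X >= 0)) {
      sparsity <- minimum_df_factor
    } else {
      warning("minimum_df_factor ignored: input has negative entries ",
              "(dense coordinates, not term frequencies)", call. = FALSE)
    }
  }

  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- skmeans_single(Xn, k, max_iter, init, seed + r - 1, sparsity)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }

  structure(list(centroids = best$centroids, labels = best$labels,
                 inertia = best$inertia, inertia_trace = best$inertia_trace,
                 k = as.integer(k), max_iter = as.integer(max_iter),
                 init = init, seed = as.integer(seed),
                 restarts = as.integer(restarts),
                 converged = best$converged, events = best$events),
            class = "spherical_kmeans")
}

#' @export
print.spherical_kmeans <- function(x, ...) {
  cat(sprintf("<spherical_kmeans> k = %d, n = %d, inertia = %.6g, %s\n",
              x$k, length(x$labels), x$inertia,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' Calinski-Harabasz index
#'
#' `CH = [B / (k - 1)] / [W / (n - k)]` with between-cluster dispersion
#' `B = sum_j n_j ||c_j - c_bar||^2` and within-cluster dispersion
#' `W = sum_i ||x_i - c_{label(i)}||^2`, both Euclidean on the rows as
#' given.  A zero within-cluster dispersion returns `Inf` with a warning.
#'
#' @param X numeric matrix.
#' @param labels cluster labels, at least two non-empty clusters.
#' @return a non-negative number (possibly `Inf`).
#' @export
calinski_harabasz <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop("need at least two clusters", call. = FALSE)
  if (length(unique(labels)) != k) stop("empty cluster", call. = FALSE)
  if (n <= k) stop("need n > k", call. = FALSE)
  cbar <- colMeans(X)
  B <- 0; W <- 0
  for (j in seq_len(k)) {
    rows <- X[labels == j, , drop = FALSE]
    cj <- colMeans(rows)
    B <- B + nrow(rows) * sum((cj - cbar)^2)
    W <- W + sum(sweep(rows, 2, cj)^2)
  }
  if (W == 0) {
    warning("zero within-cluster dispersion; CH is infinite", call. = FALSE)
    return(Inf)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' @keywords internal
pairwise_distance <- function(X, metric) {
  if (metric == "euclidean") {
    as.matrix(stats::dist(X))
  } else if (metric == "cosine") {
    1 - tcrossprod(l2_normalize_rows(X))
  } else if (metric == "one_minus_pearson") {
    1 - stats::cor(t(X))
  } else {
    stop("unknown metric: ", metric, call. = FALSE)
  }
}

#' Mean silhouette coefficient
#'
#' For each point, `a` is its mean distance to the other members of its
#' cluster, `b` the smallest mean distance to any other cluster, and the
#' silhouette is `(b - a) / max(a, b)`.  Points in singleton clusters get
#' silhouette 0.
#'
#' @param X numeric matrix.
#' @param labels cluster labels; at least two non-empty clusters.
#' @param metric `"cosine"` or `"euclidean"`.
#' @return mean silhouette over all points, in `[-1, 1]`.
#' @export
silhouette_mean <- function(X, labels, metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  n <- nrow(X)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop("silhouette undefined for a single cluster", call. = FALSE)
  D <- pairwise_distance(X, metric)
  sizes <- tabulate(labels, k)
  s <- numeric(n)
  for (i in seq_len(n)) {
    li <- labels[i]
    if (sizes[li] == 1) { s[i] <- 0; next }
    a <- sum(D[i, labels == li]) / (sizes[li] - 1)   # excludes self (D=0)
    b <- Inf
    for (j in seq_len(k)) {
      if (j == li) next
      b <- min(b, mean(D[i, labels == j]))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Model-selection scan over candidate cluster counts
#'
#' Fits [spherical_kmeans()] at every `k` in `k_grid` (same parameters and
#' seed each time) and reports, per `k`, the cosine inertia, the
#' Calinski-Harabasz index and the mean cosine silhouette from the same
#' fitted model.  Use [knee_k()] on the result for the elbow rule.
#'
#' @param X numeric matrix.
#' @param k_grid strictly increasing integer vector, `max(k_grid) <= n`.
#' @param max_iter,init,restarts,seed passed to [spherical_kmeans()].
#' @return a `data.frame` (class `cluster_scan`) with columns `k`,
#'   `inertia`, `calinski_harabasz`, `mean_silhouette`.
#' @export
elbow_scan <- function(X, k_grid, max_iter = 10, init = "cosine_plus_plus",
                       restarts = 5, seed = 1L) {
  X <- if (inherits(X, "embedding_matrix")) X$vectors else as.matrix(X)
  if (any(diff(k_grid) <= 0)) stop("k_grid must be strictly increasing",
                                   call. = FALSE)
  if (max(k_grid) > nrow(X)) stop("max(k_grid) exceeds n", call. = FALSE)
  Xn <- l2_normalize_rows(X)
  rows <- lapply(k_grid, function(k) {
    fit <- spherical_kmeans(Xn, k, max_iter = max_iter, init = init,
                            restarts = restarts, seed = seed)
    data.frame(
      k = k,
      inertia = fit$inertia,
      calinski_harabasz = if (k >= 2 && nrow(Xn) > k)
        calinski_harabasz(Xn, fit$labels) else NA_real_,
      mean_silhouette = if (k >= 2)
        silhouette_mean(Xn, fit$labels, "cosine") else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cluster_scan", "data.frame")
  out
}

#' Elbow rule on a cluster scan
#'
#' Returns the `k` at the knee of the inertia curve: the point with the
#' largest perpendicular distance from the chord joining the curve's
#' endpoints.
#'
#' @param scan a `cluster_scan` data frame from [elbow_scan()].
#' @return the selected `k` (integer).
#' @export
knee_k <- function(scan) {
  as.integer(scan$k[knee_point(scan$k, scan$inertia)])
}
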