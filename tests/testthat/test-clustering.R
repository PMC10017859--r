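test_that("single-cluster centroid is the normalized mean direction", {
  X <- rbind(c(1, 0), c(0, 1))
  fit <- spherical_kmeans(X, k = 1, seed = 1)
  expect_equal(unname(fit$centroids[1, ]), c(1, 1) / sqrt(2),
               tolerance = 1e-9)
  expect_equal(sqrt(sum(fit$centroids^2)), 1, tolerance = 1e-9)
})

test_that("antipodal bundles separate exactly with near-zero inertia", {
  X <- make_antipodal_bundles()
  fit <- spherical_kmeans(X, k = 2, restarts = 5, seed = 2)
  labels <- fit$labels
  expect_equal(length(unique(labels[1:20])), 1)
  expect_equal(length(unique(labels[21:40])), 1)
  expect_false(labels[1] == labels[21])
  expect_lte(fit$inertia, 1e-6)
})

test_that("planted spherical mixture is recovered with high adjusted Rand", {
  ds <- sample_vmf_mixture(n = 600, d = 10, k = 6, kappa = 40, seed = 11)
  fit <- spherical_kmeans(ds$X, k = 6, max_iter = 10, restarts = 10,
                          seed = 3)
  ari <- adjusted_rand(fit$labels, ds$labels)
  expect_gte(ari, 0.95)
  if (requireNamespace("mclust", quietly = TRUE)) {
    expect_equal(ari, mclust::adjustedRandIndex(fit$labels, ds$labels),
                 tolerance = 1e-12)
  }
})

test_that("inertia descends monotonically within a run", {
  set.seed(13)
  for (rep in 1:5) {
    X <- matrix(rnorm(80 * 6), 80, 6)
    fit <- spherical_kmeans(X, k = 4, max_iter = 20, seed = rep)
    expect_true(all(diff(fit$inertia_trace) <= 1e-12))
  }
})

test_that("labels are invariant under positive rescaling of rows", {
  set.seed(17)
  X <- matrix(rnorm(50 * 5), 50, 5)
  scales <- runif(50, 0.1, 10)
  f1 <- spherical_kmeans(X, k = 3, restarts = 3, seed = 4)
  f2 <- spherical_kmeans(X * scales, k = 3, restarts = 3, seed = 4)
  expect_identical(f1$labels, f2$labels)
})

test_that("tiny instances match exhaustive enumeration of assignments", {
  # with enough restarts the fitted inertia equals the global optimum
  # found by brute force over all label assignments
  set.seed(19)
  for (rep in 1:3) {
    n <- 7; k <- 2
    X <- matrix(rnorm(n * 3), n, 3)
    Xn <- X / sqrt(rowSums(X^2))
    best <- Inf
    grid <- expand.grid(rep(list(1:k), n))
    for (r in seq_len(nrow(grid))) {
      lab <- as.integer(grid[r, ])
      if (length(unique(lab)) < k) next
      inert <- 0
      for (j in 1:k) {
        mem <- Xn[lab == j, , drop = FALSE]
        ctr <- colSums(mem); ctr <- ctr / sqrt(sum(ctr^2))
        inert <- inert + sum(1 - mem %*% ctr)
      }
      best <- min(best, inert)
    }
    fit <- spherical_kmeans(X, k = k, max_iter = 50, restarts = 40,
                            seed = rep)
    expect_equal(fit$inertia, best, tolerance = 1e-9)
  }
})

test_that("sparsity projection prunes rare terms only on non-negative data", {
  set.seed(23)
  tf <- matrix(rpois(30 * 12, 1.2), 30, 12)
  tf[, 12] <- 0; tf[1, 12] <- 5       # a term supported by one document
  tf[rowSums(tf) == 0, 1] <- 1
  fit <- spherical_kmeans(tf, k = 2, restarts = 3, seed = 1,
                          minimum_df_factor = 0.3)
  expect_true(any(fit$centroids == 0))

  dense <- matrix(rnorm(30 * 5), 30, 5)
  expect_warning(
    spherical_kmeans(dense, k = 2, seed = 1, minimum_df_factor = 0.05),
    "ignored")
})

test_that("Calinski-Harabasz matches the hand example and a brute oracle", {
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  expect_equal(calinski_harabasz(X, c(1, 1, 2, 2)), 200.0)

  # degenerate: zero within-cluster scatter
  Xd <- matrix(c(0, 0, 5, 5), ncol = 1)
  expect_warning(ch <- calinski_harabasz(Xd, c(1, 1, 2, 2)), "infinite")
  expect_identical(ch, Inf)

  set.seed(29)
  X <- matrix(rnorm(30 * 3), 30, 3)
  lab <- sample(1:3, 30, replace = TRUE)
  # brute-force evaluation of the formula
  n <- 30; k <- 3
  cbar <- colMeans(X); B <- 0; W <- 0
  for (j in 1:k) {
    rows <- X[lab == j, , drop = FALSE]
    cj <- colMeans(rows)
    B <- B + nrow(rows) * sum((cj - cbar)^2)
    for (i in seq_len(nrow(rows))) W <- W + sum((rows[i, ] - cj)^2)
  }
  expect_equal(calinski_harabasz(X, lab), (B / (k - 1)) / (W / (n - k)),
               tolerance = 1e-10)
  expect_error(calinski_harabasz(X, rep(1, 30)), "two clusters")
})

test_that("mean silhouette matches the exhaustive pairwise oracle", {
  X <- make_antipodal_bundles(n_per = 10)
  expect_gte(silhouette_mean(X, rep(1:2, each = 10), "cosine"), 0.99)

  set.seed(37)
  for (metric in c("cosine", "euclidean")) {
    X <- matrix(rnorm(25 * 4), 25, 4)
    lab <- sample(1:3, 25, replace = TRUE)
    expect_equal(silhouette_mean(X, lab, metric),
                 silhouette_brute(X, lab, metric), tolerance = 1e-12)
  }
  # independent library cross-check on the euclidean metric
  if (requireNamespace("cluster", quietly = TRUE)) {
    set.seed(38)
    X <- matrix(rnorm(30 * 3), 30, 3)
    lab <- sample(1:3, 30, replace = TRUE)
    ref <- mean(cluster::silhouette(lab, dist(X))[, "sil_width"])
    expect_equal(silhouette_mean(X, lab, "euclidean"), ref,
                 tolerance = 1e-10)
  }
  expect_error(silhouette_mean(X, rep(1, 30)), "single cluster")
})

test_that("random labels on structureless data give silhouette near zero", {
  set.seed(41)
  X <- matrix(runif(200 * 5), 200, 5)
  lab <- sample(1:4, 200, replace = TRUE)
  expect_lt(abs(silhouette_mean(X, lab, "euclidean")), 0.1)
})

test_that("elbow scan produces one diagnostics row per k and finds the
           planted count", {
  ds <- sample_vmf_mixture(n = 600, d = 10, k = 6, kappa = 40, seed = 11)
  scan <- elbow_scan(ds$X, 2:10, restarts = 5, seed = 3)
  expect_equal(nrow(scan), 9)
  expect_equal(scan$k, 2:10)
  expect_true(all(scan$mean_silhouette >= -1 & scan$mean_silhouette <= 1))
  expect_equal(knee_k(scan), 6)
  # inertia non-increasing in k with adequate restarts
  expect_true(all(diff(scan$inertia) <= 1e-8))
})
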