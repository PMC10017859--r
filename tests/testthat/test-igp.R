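test_that("nearest-centroid classification matches an exhaustive loop", {
  C <- diag(3)
  expect_equal(classify_to_centroids(C, C), 1:3)     # identity assignment
  expect_equal(classify_to_centroids(matrix(rnorm(15), 5, 3),
                                     C[1, , drop = FALSE]),
               rep(1L, 5))                           # single centroid

  set.seed(43)
  X <- matrix(rnorm(20 * 5), 20, 5)
  cent <- matrix(rnorm(4 * 5), 4, 5)
  for (metric in c("cosine", "one_minus_pearson")) {
    got <- classify_to_centroids(X, cent, metric)
    want <- sapply(seq_len(20), function(i) {
      d <- sapply(seq_len(4), function(j) {
        if (metric == "cosine") 1 - cosine_similarity(X[i, ], cent[j, ])
        else 1 - cor(X[i, ], cent[j, ])
      })
      which.min(d)
    })
    expect_equal(got, want)
  }
  expect_error(classify_to_centroids(X, matrix(0.1, 2, 3)), "mismatch")
})

test_that("well-separated bundles give IGP 1 for both clusters", {
  X <- make_antipodal_bundles(n_per = 15)
  centroids <- rbind(colMeans(X[1:15, ]), colMeans(X[16:30, ]))
  labels <- classify_to_centroids(X, centroids)
  rep <- igp(X, labels)
  expect_equal(unname(rep$per_cluster_igp), c(1, 1))
  expect_equal(rep$summary$mean, 1)
})

test_that("clusters with fewer than two test points are undefined", {
  set.seed(47)
  X <- matrix(rnorm(10 * 4), 10, 4)
  labels <- c(rep(1L, 9), 2L)       # cluster 2 holds a single point
  rep <- igp(X, labels, n_clusters = 3)
  expect_true(is.na(rep$per_cluster_igp[2]))
  expect_true(is.na(rep$per_cluster_igp[3]))   # no points at all
  expect_equal(rep$undefined_clusters, c(2L, 3L))
  expect_false(is.na(rep$summary$mean))        # summary over defined only
  expect_error(igp(X[1, , drop = FALSE], 1L), "two test points")
})

test_that("per-cluster IGP equals the O(n^2) brute-force oracle", {
  set.seed(53)
  for (metric in c("cosine", "one_minus_pearson")) {
    X <- matrix(rnorm(40 * 6), 40, 6)
    labels <- sample(1:4, 40, replace = TRUE)
    rep <- igp(X, labels, metric = metric)
    expect_identical(unname(rep$per_cluster_igp), igp_brute(X, labels, metric))
    ok <- rep$per_cluster_igp[!is.na(rep$per_cluster_igp)]
    expect_true(all(ok >= 0 & ok <= 1))
  }
})

test_that("replicated IGP runs are reproducible row-for-row", {
  ds <- sample_vmf_mixture(n = 240, d = 8, k = 4, kappa = 40, seed = 59)
  r1 <- replicate_igp(ds$X, k = 4, n_runs = 2, train_size = 130,
                      restarts = 3, seed = 61)
  expect_equal(nrow(r1$summary_table), 2)
  expect_equal(r1$summary_table$Iteration, c(0, 1))
  expect_named(r1$summary_table, c("Iteration", "Median", "IQR", "Mean",
                                   "SD", "Q1", "Q3", "Range"))
  expect_equal(r1$n_train, 130)
  expect_equal(r1$n_test, 110)

  r2 <- replicate_igp(ds$X, k = 4, n_runs = 2, train_size = 130,
                      restarts = 3, seed = 61)
  expect_identical(r1$summary_table, r2$summary_table)

  single <- replicate_igp(ds$X, k = 4, n_runs = 1, train_size = 130,
                          restarts = 3, seed = 61)
  expect_equal(nrow(single$summary_table), 1)
  expect_length(single$reports, 1)
})

test_that("merging planted clusters cannot raise the minimum defined IGP", {
  ds <- sample_vmf_mixture(n = 300, d = 8, k = 4, kappa = 60, seed = 67)
  part <- partition_records(seq_len(300), 160, seed = 67)
  Xtr <- ds$X[part$train_ids, ]; Xte <- ds$X[part$test_ids, ]

  fit4 <- spherical_kmeans(Xtr, 4, restarts = 5, seed = 1)
  igp4 <- igp(Xte, classify_to_centroids(Xte, fit4$centroids))
  # merge two centroids into their normalized midpoint -> 3 centroids
  merged <- rbind(fit4$centroids[1, ] + fit4$centroids[2, ],
                  fit4$centroids[3, ], fit4$centroids[4, ])
  merged <- merged / sqrt(rowSums(merged^2))
  igp3 <- igp(Xte, classify_to_centroids(Xte, merged))

  min4 <- min(igp4$per_cluster_igp, na.rm = TRUE)
  min3 <- min(igp3$per_cluster_igp, na.rm = TRUE)
  expect_lte(min3, min4 + 1e-12)
})

test_that("structureless data scores materially below separated data", {
  sep <- sample_vmf_mixture(n = 400, d = 10, k = 5, kappa = 60, seed = 71)
  nul <- sample_vmf_mixture(n = 400, d = 10, k = 1, kappa = 0, seed = 71)
  r_sep <- replicate_igp(sep$X, k = 5, n_runs = 2, train_size = 220,
                         restarts = 3, seed = 73)
  r_nul <- replicate_igp(nul$X, k = 5, n_runs = 2, train_size = 220,
                         restarts = 3, seed = 73)
  expect_gt(mean(r_sep$summary_table$Mean),
            mean(r_nul$summary_table$Mean) + 0.2)
})
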