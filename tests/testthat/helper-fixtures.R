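# Deterministic fixtures shared across test files.

# The three path/text variants of the education question that motivate the
# two dedup key modes: same text under two section paths, plus a paraphrase.
education_records <- function() {
  question_records(
    form_id = c("F1", "F2", "F3"),
    field_path = c("economic/Education/", "Educational Data/",
                   "social/Education History/"),
    field_name = c("What Is The Highest Grade You Have Completed",
                   "What Is The Highest Grade You Have Completed",
                   "Highest grade attained")
  )
}

# 1-d curve lifted into 10-d ambient space with additive noise.  With 10
# ambient dimensions, 5 neighbors cannot reconstruct a point exactly, so
# the LLE reconstruction error is a meaningful nonzero quantity.
make_noisy_curve <- function(n = 150, D = 10, sd = 0.4, seed = 5) {
  set.seed(seed)
  t <- sort(runif(n, 0, 4 * pi))
  base <- cbind(cos(t), sin(t), t / (2 * pi))
  base %*% matrix(rnorm(3 * D), 3, D) + matrix(rnorm(n * D, sd = sd), n, D)
}

# points exactly on a 2-d linear subspace of 10-d space
make_subspace_data <- function(n = 200, seed = 42) {
  set.seed(seed)
  B <- qr.Q(qr(matrix(rnorm(10 * 2), 10, 2)))
  matrix(rnorm(n * 2), n, 2) %*% t(B)
}

# two tight antipodal bundles on the unit sphere
make_antipodal_bundles <- function(n_per = 20, d = 5, seed = 3, eps = 1e-4) {
  set.seed(seed)
  mu <- c(1, rep(0, d - 1))
  up <- matrix(rep(mu, n_per), ncol = d, byrow = TRUE) +
    matrix(rnorm(n_per * d, sd = eps), n_per, d)
  dn <- -up
  X <- rbind(up, dn)
  X / sqrt(rowSums(X^2))
}

# minimal JSON Schema exercising nesting, enum and array leaves
example_schema <- function() {
  jsonlite::fromJSON('{
    "type": "object",
    "properties": {
      "economic": {
        "type": "object",
        "properties": {
          "Education": {
            "type": "object",
            "properties": {
              "What Is The Highest Grade You Have Completed": {"type": "string"}
            }
          }
        }
      },
      "Primary language": {"type": "string",
                           "enum": ["English", "Spanish", "Other"]},
      "Current medications": {"type": "array", "items": {"type": "string"}},
      "Date of birth": {"type": "string"}
    }
  }', simplifyVector = FALSE)
}

# brute-force mean silhouette, O(n^2) double loop
silhouette_brute <- function(X, labels, metric) {
  n <- nrow(X)
  dfun <- function(i, j) {
    if (metric == "euclidean") sqrt(sum((X[i, ] - X[j, ])^2))
    else 1 - sum(X[i, ] * X[j, ]) / sqrt(sum(X[i, ]^2) * sum(X[j, ]^2))
  }
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(vapply(own, function(j) dfun(i, j), numeric(1)))
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      mem <- which(labels == cl)
      b <- min(b, mean(vapply(mem, function(j) dfun(i, j), numeric(1))))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# brute-force per-cluster IGP via an explicit nearest-neighbor loop
igp_brute <- function(X, labels, metric = "cosine") {
  n <- nrow(X)
  dfun <- function(i, j) {
    if (metric == "cosine")
      1 - sum(X[i, ] * X[j, ]) / sqrt(sum(X[i, ]^2) * sum(X[j, ]^2))
    else 1 - cor(X[i, ], X[j, ])
  }
  nn <- integer(n)
  for (i in seq_len(n)) {
    best <- Inf; bi <- NA_integer_
    for (j in seq_len(n)) {
      if (j == i) next
      d <- dfun(i, j)
      if (d < best) { best <- d; bi <- j }
    }
    nn[i] <- bi
  }
  ks <- sort(unique(labels))
  out <- rep(NA_real_, max(labels))
  for (k in ks) {
    mem <- which(labels == k)
    if (length(mem) >= 2) out[k] <- mean(labels[nn[mem]] == k)
  }
  out
}

# adjusted Rand index from the pair-counting contingency formula,
# independent of any clustering code under test
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}
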