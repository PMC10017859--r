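# Locally linear embedding, implemented from first principles, plus the
# reconstruction-error sweep used to choose the reduced dimension d.
#
# LLE reconstructs each point from its K nearest neighbors with weights
# summing to one, then finds low-dimensional coordinates Y that preserve
# those weights.  The embedding quality is summarized by
#   Phi(Y) = sum_i || Y_i - sum_j W_ij Y_j ||^2 ,
# the residual of the same reconstruction in the embedded space.

#' @keywords internal
lle_neighbors <- function(X, K) {
  n <- nrow(X)
  d2 <- as.matrix(stats::dist(X))^2
  nn <- matrix(0L, n, K)
  for (i in seq_len(n)) {
    ord <- order(d2[i, ])          # stable: ties resolved by lowest index
    ord <- ord[ord != i]
    nn[i, ] <- ord[seq_len(K)]
  }
  nn
}

# Reconstruction weights for one neighborhood.  The local Gram matrix is
# conditioned by adding reg * trace(G) / K to its diagonal before solving,
# which resolves the singular case of duplicated or coplanar neighbors.
#' @keywords internal
lle_weights <- function(X, nn, reg = 1e-3) {
  n <- nrow(X)
  K <- ncol(nn)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    Z <- sweep(X[nn[i, ], , drop = FALSE], 2, X[i, ])
    G <- tcrossprod(Z)
    tr <- sum(diag(G))
    ridge <- if (tr > 0) reg * tr / K else reg
    diag(G) <- diag(G) + ridge
    w <- solve(G, rep(1, K))
    W[i, nn[i, ]] <- w / sum(w)
  }
  W
}

#' @keywords internal
fix_eigvec_signs <- function(Y) {
  for (j in seq_len(ncol(Y))) {
    m <- which.max(abs(Y[, j]))
    if (Y[m, j] < 0) Y[, j] <- -Y[, j]
  }
  Y
}

# Full LLE decomposition: weights plus the eigensystem of
# M = (I - W)' (I - W).  The eigensystem is computed once so a sweep over
# several output dimensions d can reuse it (the bottom d+1 eigenvectors of
# M give the d-dimensional embedding for every d).
#' @keywords internal
lle_decompose <- function(X, K, reg = 1e-3) {
  n <- nrow(X)
  nn <- lle_neighbors(X, K)
  W <- lle_weights(X, nn, reg)
  IW <- diag(n) - W
  M <- crossprod(IW)
  eig <- eigen(M, symmetric = TRUE)   # eigenvalues in decreasing order
  list(W = W, values = rev(eig$values),          # ascending
       vectors = eig$vectors[, n:1, drop = FALSE], nn = nn)
}

#' @keywords internal
lle_embed_from_decomposition <- function(dec, d) {
  # discard the constant eigenvector (smallest eigenvalue ~ 0); take the
  # next d, fixing each column's sign so the largest-magnitude entry is
  # positive for run-to-run comparability
  Y <- dec$vectors[, 2:(d + 1), drop = FALSE]
  Y <- fix_eigvec_signs(Y)
  resid <- Y - dec$W %*% Y
  phi <- sum(resid^2)
  list(Y = Y, phi = phi)
}

#' Fit a locally linear embedding
#'
#' Three steps: (1) K nearest neighbors per point by Euclidean distance
#' (ties broken toward the lowest index); (2) reconstruction weights per
#' point minimizing the local reconstruction error subject to rows summing
#' to 1, with Tikhonov regularization `reg * trace(G) / K` on the local
#' Gram matrix; (3) embedded coordinates from the bottom `d + 1`
#' eigenvectors of `(I - W)' (I - W)`, discarding the constant one.
#' Columns of `Y` are unit-norm, mutually orthogonal, and centered.
#'
#' @param X numeric matrix (n points x D features), all entries finite.
#' @param K neighbor count, `1 <= K < n`.
#' @param d output dimension, `1 <= d < n`.
#' @param reg regularization factor for the local Gram matrix.
#' @return object of class `lle_fit`: list with `Y` (n x d), `phi`
#'   (reconstruction error, see above), `W` (n x n weight matrix), `K`,
#'   `d`, `reg`.
#' @export
lle_fit <- function(X, K = 5, d = 2, reg = 1e-3) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (!all(is.finite(X))) stop("X has non-finite entries", call. = FALSE)
  if (K < 1 || K >= n) stop("need 1 <= K < n (n = ", n, ")", call. = FALSE)
  if (d < 1 || d >= n) stop("need 1 <= d < n (n = ", n, ")", call. = FALSE)
  dec <- lle_decompose(X, K, reg)
  emb <- lle_embed_from_decomposition(dec, d)
  structure(list(Y = emb$Y, phi = emb$phi, W = dec$W,
                 K = as.integer(K), d = as.integer(d), reg = reg),
            class = "lle_fit")
}

#' @export
print.lle_fit <- function(x, ...) {
  cat(sprintf("<lle_fit> n = %d, K = %d, d = %d, phi = %.4g\n",
              nrow(x$Y), x$K, x$d, x$phi))
  invisible(x)
}

#' Reconstruction-error sweep over candidate output dimensions
#'
#' For each of `replications` subsamples (drawn without replacement,
#' `subsample_size` points each), fits LLE once and evaluates the
#' reconstruction error at every `d` in `d_grid`; the per-`d` errors are
#' then aggregated across replications.  The neighbor graph, weights and
#' eigensystem depend only on the subsample and `K`, so one decomposition
#' per replication serves the whole grid.
#'
#' @param X data matrix.
#' @param K neighbor count.
#' @param d_grid integer vector of candidate output dimensions, each
#'   `< subsample_size`.
#' @param replications number of random subsamples.
#' @param subsample_size points per subsample (`<= nrow(X)`); defaults to
#'   all rows.
#' @param seed integer seed; the whole sweep is deterministic given it.
#' @param reg regularization factor, as in [lle_fit()].
#' @return a `data.frame` (class `lle_sweep`) with one row per `d`:
#'   `d`, `mean_phi`, `min_phi`, `max_phi`, `median_phi`, `iqr_phi`,
#'   `sd_phi`, `replications`.
#' @export
sweep_dimensions <- function(X, K, d_grid, replications = 10,
                             subsample_size = nrow(X), seed = 1L,
                             reg = 1e-3) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(d_grid) == 0) stop("d_grid is empty", call. = FALSE)
  d_grid <- sort(unique(as.integer(d_grid)))
  if (subsample_size > n) stop("subsample_size exceeds n", call. = FALSE)
  if (max(d_grid) >= subsample_size) {
    stop("every d must be < subsample_size", call. = FALSE)
  }

  phis <- matrix(NA_real_, replications, length(d_grid))
  for (r in seq_len(replications)) {
    idx <- with_seed(seed + r, sample.int(n, subsample_size))
    dec <- lle_decompose(X[idx, , drop = FALSE], K, reg)
    for (j in seq_along(d_grid)) {
      phis[r, j] <- lle_embed_from_decomposition(dec, d_grid[j])$phi
    }
  }

  out <- data.frame(
    d = d_grid,
    mean_phi = colMeans(phis),
    min_phi = apply(phis, 2, min),
    max_phi = apply(phis, 2, max),
    median_phi = apply(phis, 2, stats::median),
    iqr_phi = apply(phis, 2, stats::IQR),
    sd_phi = apply(phis, 2, stats::sd),
    replications = replications
  )
  class(out) <- c("lle_sweep", "data.frame")
  out
}

# Index of the knee of a curve: the point with maximum perpendicular
# distance from the chord joining the curve's endpoints.
#' @keywords internal
knee_point <- function(x, y) {
  m <- length(x)
  if (m == 1) return(1L)
  x0 <- x[1]; y0 <- y[1]; x1 <- x[m]; y1 <- y[m]
  dx <- x1 - x0; dy <- y1 - y0
  len <- sqrt(dx^2 + dy^2)
  dist <- abs((x - x0) * dy - (y - y0) * dx) / max(len, .Machine$double.eps)
  which.max(dist)
}

#' Choose the embedding dimension from a sweep table
#'
#' `manual` mode returns a user-supplied `d` after checking it was swept;
#' `knee` mode returns the `d` maximizing the perpendicular distance of
#' `(d, mean_phi)` from the chord joining the first and last grid points.
#'
#' @param table an `lle_sweep` data frame.
#' @param mode `"manual"` or `"knee"`.
#' @param d required in manual mode.
#' @return the selected dimension (integer).
#' @export
select_dimension <- function(table, mode = c("manual", "knee"), d = NULL) {
  mode <- match.arg(mode)
  if (nrow(table) == 0) stop("empty sweep table", call. = FALSE)
  if (mode == "manual") {
    if (is.null(d)) stop("manual mode requires d", call. = FALSE)
    if (!d %in% table$d) {
      stop("d = ", d, " is not in the sweep table", call. = FALSE)
    }
    return(as.integer(d))
  }
  as.integer(table$d[knee_point(table$d, table$mean_phi)])
}

#' Write a sweep table as CSV
#'
#' Column headers mirror the usual presentation of a reconstruction-error
#' table: the dimension, the average error, and its dispersion statistics
#' across replications.
#'
#' @param table an `lle_sweep` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_table <- function(table, path) {
  out <- data.frame(
    `Dimension (d)` = table$d,
    `Average reconstruction error` = table$mean_phi,
    `Minimum reconstruction error` = table$min_phi,
    `Maximum reconstruction error` = table$max_phi,
    `Median reconstruction error` = table$median_phi,
    `IQR of reconstruction error` = table$iqr_phi,
    `Standard deviation of reconstruction error` = table$sd_phi,
    Replications = table$replications,
    check.names = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
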