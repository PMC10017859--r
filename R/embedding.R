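# Text embedding: a pluggable encoder contract plus cosine-similarity
# primitives.  The built-in encoder hashes character n-grams (3-5) into
# term-frequency buckets and projects them to D dimensions with a seeded
# Gaussian random projection, so semantically overlapping strings land
# close on the unit sphere without any model download.  An external
# sentence encoder (e.g. a 768-d transformer) plugs in as a plain function.

#' Deterministic hashed n-gram encoder
#'
#' Creates the built-in text encoder: character n-grams (sizes 3-5 by
#' default) of the normalized string are hashed into `buckets`
#' term-frequency slots, which a fixed seeded Gaussian matrix projects to
#' `dim` dimensions; rows are then L2-normalized.  Two encoders with the
#' same parameters and seed produce bitwise-identical embeddings.
#'
#' @param dim output embedding dimension.
#' @param seed integer seed for the projection matrix.
#' @param buckets number of hash buckets for the n-gram counts.
#' @param ngram integer vector of n-gram sizes.
#' @return an object of class `ngram_encoder`.
#' @export
ngram_encoder <- function(dim = 256, seed = 1L, buckets = 4096L,
                          ngram = 3:5) {
  stopifnot(dim >= 2, buckets >= dim, all(ngram >= 1))
  structure(
    list(dim = as.integer(dim), seed = as.integer(seed),
         buckets = as.integer(buckets), ngram = as.integer(ngram),
         tag = sprintf("ngram-tf/d%d-b%d-n%s-s%d", dim, buckets,
                       paste(range(ngram), collapse = "to"), seed)),
    class = "ngram_encoder"
  )
}

# Polynomial rolling hash of a string into [1, buckets].  Arithmetic stays
# below 2^53 so doubles are exact.
#' @keywords internal
hash_string <- function(s, buckets) {
  h <- 0
  for (b in utf8ToInt(s)) {
    h <- (h * 131 + b) %% 16777213  # prime < 2^24
  }
  as.integer(h %% buckets) + 1L
}

#' @keywords internal
text_to_buckets <- function(text, buckets, ngram) {
  s <- normalize_text(text)
  s <- paste0("^", s, "$")  # mark boundaries so short strings still differ
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  len <- length(chars)
  grams <- character(0)
  for (n in ngram) {
    if (len >= n) {
      starts <- seq_len(len - n + 1L)
      grams <- c(grams, vapply(starts, function(i)
        paste(chars[i:(i + n - 1L)], collapse = ""), character(1)))
    }
  }
  if (length(grams) == 0) grams <- s
  vapply(grams, hash_string, integer(1), buckets = buckets, USE.NAMES = FALSE)
}

#' Encode texts as a unit-norm embedding matrix
#'
#' Applies the encoder backend to each input string, preserving input
#' order, and L2-normalizes every row so cosine similarity downstream is a
#' plain dot product.  The backend is either an [ngram_encoder()] object or
#' a function `function(texts) -> numeric matrix` wrapping an external
#' sentence encoder (one row per text); external rows are renormalized on
#' ingestion.
#'
#' @param texts character vector of non-empty strings.
#' @param backend an `ngram_encoder` or an encoding function.
#' @param ids optional row identifiers; defaults to `t1`, `t2`, ...
#' @param encoder_tag tag recorded on the result (defaults to the
#'   backend's own tag, or `"external"` for a function backend).
#' @return an `embedding_matrix`: list with `ids`, `vectors` (n x D
#'   matrix), `encoder_tag`, `unit_norm = TRUE`.
#' @export
encode_texts <- function(texts, backend = ngram_encoder(), ids = NULL,
                         encoder_tag = NULL) {
  if (length(texts) == 0) stop("no texts to encode", call. = FALSE)
  empty <- which(is.na(texts) | !nzchar(trimws(texts)))
  if (length(empty) > 0) {
    stop("empty string input at index/indices: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  if (is.null(ids)) ids <- paste0("t", seq_along(texts))
  if (anyDuplicated(ids)) stop("duplicate ids", call. = FALSE)

  if (inherits(backend, "ngram_encoder")) {
    enc <- backend
    # sparse TF matrix over hash buckets
    ij <- lapply(texts, text_to_buckets, buckets = enc$buckets,
                 ngram = enc$ngram)
    rows <- rep(seq_along(texts), lengths(ij))
    tf <- Matrix::sparseMatrix(i = rows, j = unlist(ij), x = 1,
                               dims = c(length(texts), enc$buckets))
    proj <- with_seed(enc$seed,
                      matrix(stats::rnorm(enc$buckets * enc$dim),
                             nrow = enc$buckets, ncol = enc$dim))
    vec <- as.matrix(tf %*% proj)
    tag <- if (is.null(encoder_tag)) enc$tag else encoder_tag
  } else if (is.function(backend)) {
    vec <- backend(texts)
    if (!is.matrix(vec) || nrow(vec) != length(texts)) {
      stop("external backend must return one matrix row per input text",
           call. = FALSE)
    }
    tag <- if (is.null(encoder_tag)) "external" else encoder_tag
  } else {
    stop("backend must be an ngram_encoder or a function; ",
         "use ngram_encoder() if no external sentence encoder is available",
         call. = FALSE)
  }

  vec <- l2_normalize_rows(vec)
  rownames(vec) <- ids
  structure(list(ids = as.character(ids), vectors = vec,
                 encoder_tag = tag, unit_norm = TRUE),
            class = "embedding_matrix")
}

#' @keywords internal
l2_normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm < 1e-300)) {
    stop("zero row encountered during normalization", call. = FALSE)
  }
  m / nrm
}

#' Cosine similarity of two vectors
#'
#' `x . y / (||x|| ||y||)`; symmetric, scale-invariant, always in
#' `[-1, 1]`.
#'
#' @param x,y numeric vectors of equal length, both nonzero.
#' @return a single number in `[-1, 1]`.
#' @export
cosine_similarity <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    stop("cosine similarity undefined for the zero vector", call. = FALSE)
  }
  sum(x * y) / (nx * ny)
}

#' Pairwise cosine similarities between two embedding sets
#'
#' Entry (i, j) is the cosine similarity of row i of `A` and row j of `B`.
#' For unit-norm inputs this is the plain cross product.
#'
#' @param A,B `embedding_matrix` objects or plain numeric matrices with the
#'   same number of columns.
#' @return an `nrow(A)` x `nrow(B)` numeric matrix.
#' @export
pairwise_similarity <- function(A, B = A) {
  ma <- if (inherits(A, "embedding_matrix")) A$vectors else as.matrix(A)
  mb <- if (inherits(B, "embedding_matrix")) B$vectors else as.matrix(B)
  if (ncol(ma) != ncol(mb)) {
    stop("embedding dimensions differ: ", ncol(ma), " vs ", ncol(mb),
         call. = FALSE)
  }
  ma <- l2_normalize_rows(ma)
  mb <- l2_normalize_rows(mb)
  tcrossprod(ma, mb)
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("<embedding_matrix> %d texts x %d dims, encoder %s\n",
              nrow(x$vectors), ncol(x$vectors), x$encoder_tag))
  invisible(x)
}

#' Write an embedding matrix with its JSON sidecar
#'
#' Vectors go to a delimited text matrix, metadata (ids, encoder tag,
#' dimension, norm flag) to a JSON sidecar next to it.
#'
#' @param emb an `embedding_matrix`.
#' @param path output path for the matrix (TSV, no row names).
#' @return `path`, invisibly.
#' @export
write_embedding <- function(emb, path) {
  utils::write.table(emb$vectors, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(ids = emb$ids, encoder_tag = emb$encoder_tag,
               dim = ncol(emb$vectors), unit_norm = emb$unit_norm)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an embedding matrix written by [write_embedding()]
#' @param path matrix path (the sidecar is `<path>.json`).
#' @return an `embedding_matrix`.
#' @export
read_embedding <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  vec <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(vec) <- list(meta$ids, NULL)
  structure(list(ids = meta$ids, vectors = vec,
                 encoder_tag = meta$encoder_tag,
                 unit_norm = isTRUE(meta$unit_norm)),
            class = "embedding_matrix")
}
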