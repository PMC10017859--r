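# Mapping discovered SDOH categories onto a reference taxonomy (e.g. the
# PhenX SDOH protocol names) by cosine similarity of embedded category
# strings, thresholded at the boxplot upper hinge Q3 + 1.5 * IQR.

#' Read a category taxonomy from CSV
#'
#' Expects columns `Category`, `Subcategory 1`, `Subcategory 2`,
#' `Subcategory 3`, `Definition`.  Empty subcategory cells become `NA`;
#' subcategories must fill left-to-right (no Subcategory 2 without
#' Subcategory 1).
#'
#' @param path CSV path.
#' @return a `data.frame` of class `sdoh_taxonomy` with columns
#'   `category`, `subcategory1`, `subcategory2`, `subcategory3`,
#'   `definition`.
#' @export
read_taxonomy <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("Category", "Subcategory 1", "Subcategory 2", "Subcategory 3",
            "Definition")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("taxonomy is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  blank_to_na <- function(x) { x <- trimws(x); x[!nzchar(x)] <- NA; x }
  out <- data.frame(
    category = trimws(tab$Category),
    subcategory1 = blank_to_na(tab[["Subcategory 1"]]),
    subcategory2 = blank_to_na(tab[["Subcategory 2"]]),
    subcategory3 = blank_to_na(tab[["Subcategory 3"]]),
    definition = trimws(tab$Definition),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(out$category)) || any(!nzchar(out$definition))) {
    stop("category and definition must be non-empty", call. = FALSE)
  }
  gap <- (is.na(out$subcategory1) & !is.na(out$subcategory2)) |
         (is.na(out$subcategory2) & !is.na(out$subcategory3))
  if (any(gap)) {
    stop("subcategories must fill left-to-right at row(s): ",
         paste(which(gap), collapse = ", "), call. = FALSE)
  }
  class(out) <- c("sdoh_taxonomy", "data.frame")
  out
}

#' The bundled SDOH category taxonomy
#'
#' Loads the package's fixture: the final SDOH category table (category,
#' up to three nested subcategories, and a free-text definition per row)
#' produced by the clustering-plus-expert-labeling workflow this package
#' implements.
#'
#' @return an `sdoh_taxonomy` data frame.
#' @export
sdoh_taxonomy <- function() {
  read_taxonomy(system.file("extdata", "sdoh_taxonomy.csv",
                            package = "sdohmap", mustWork = TRUE))
}

#' Concatenate taxonomy rows into category strings
#'
#' Joins, per row, the non-empty fields `category`, `subcategory1`,
#' `subcategory2`, `subcategory3`, `definition` — in that order — with
#' `", "` as the delimiter, yielding the string that gets embedded for
#' taxonomy mapping.
#'
#' @param entries an `sdoh_taxonomy` data frame.
#' @return character vector, one string per row, order preserved.
#' @export
build_category_strings <- function(entries) {
  vapply(seq_len(nrow(entries)), function(i) {
    parts <- c(entries$category[i], entries$subcategory1[i],
               entries$subcategory2[i], entries$subcategory3[i],
               entries$definition[i])
    paste(parts[!is.na(parts) & nzchar(parts)], collapse = ", ")
  }, character(1))
}

#' Distinct node keys for taxonomy rows
#'
#' The category plus its subcategory path, joined with `"/"`, so rows
#' sharing a top-level category remain distinct mapping nodes.
#'
#' @param entries an `sdoh_taxonomy` data frame.
#' @return character vector of keys.
#' @export
category_keys <- function(entries) {
  vapply(seq_len(nrow(entries)), function(i) {
    parts <- c(entries$category[i], entries$subcategory1[i],
               entries$subcategory2[i], entries$subcategory3[i])
    paste(parts[!is.na(parts) & nzchar(parts)], collapse = "/")
  }, character(1))
}

#' Boxplot upper-hinge threshold
#'
#' `Q3 + 1.5 * (Q3 - Q1)`, the boxplot upper fence.  Quantiles use linear
#' interpolation between order statistics by default (`type = 7`); other
#' conventions (e.g. Tukey-style hinges via `type = 2`) can be selected.
#' A constant or singleton input returns that value (IQR = 0).
#'
#' @param values numeric vector with at least one finite value.
#' @param type quantile type passed to [stats::quantile()].
#' @return the threshold (single number).
#' @export
upper_hinge_threshold <- function(values, type = 7) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("no finite values", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = type)
  q[2] + 1.5 * (q[2] - q[1])
}

#' Map categories onto a reference taxonomy
#'
#' Embeds the category strings and the reference names with the same
#' encoder, computes all pairwise cosine similarities, sets the threshold
#' to the upper hinge of that full similarity distribution (unless one is
#' injected), and keeps the strictly-greater-than-threshold pairs as
#' edges.  Coverage is the percentage of categories with at least one
#' edge; one category may map to several reference names.
#'
#' @param category_strings character vector (see
#'   [build_category_strings()]).
#' @param reference_names character vector of reference taxonomy names.
#' @param backend encoder backend for [encode_texts()]; ignored when
#'   `similarity` is supplied.
#' @param category_keys optional node keys for the categories; defaults to
#'   the strings themselves.
#' @param threshold optional injected threshold; default is
#'   `upper_hinge_threshold()` of all pairwise similarities.
#' @param similarity optional precomputed `|categories| x |references|`
#'   similarity matrix, bypassing the encoder.
#' @param quantile_type quantile convention for the hinge.
#' @return object of class `taxonomy_mapping`: `edges` (data frame
#'   `category_key`, `reference_name`, `similarity`), `threshold`,
#'   `coverage_percent`, `unmapped` (category keys without edges),
#'   `similarities` (the full matrix, histogram-ready).
#' @export
map_categories <- function(category_strings, reference_names,
                           backend = ngram_encoder(),
                           category_keys = NULL, threshold = NULL,
                           similarity = NULL, quantile_type = 7) {
  if (length(category_strings) == 0 || length(reference_names) == 0) {
    stop("both category and reference lists must be non-empty",
         call. = FALSE)
  }
  if (is.null(category_keys)) category_keys <- category_strings
  if (anyDuplicated(category_keys)) {
    stop("category keys must be unique", call. = FALSE)
  }

  if (is.null(similarity)) {
    emb_cat <- encode_texts(category_strings, backend,
                            ids = paste0("c", seq_along(category_strings)))
    emb_ref <- encode_texts(reference_names, backend,
                            ids = paste0("r", seq_along(reference_names)))
    similarity <- pairwise_similarity(emb_cat, emb_ref)
  } else {
    similarity <- as.matrix(similarity)
    if (nrow(similarity) != length(category_strings) ||
        ncol(similarity) != length(reference_names)) {
      stop("similarity matrix shape does not match the input lists",
           call. = FALSE)
    }
  }
  dimnames(similarity) <- list(category_keys, reference_names)

  if (is.null(threshold)) {
    threshold <- upper_hinge_threshold(as.vector(similarity),
                                       type = quantile_type)
  }

  hits <- which(similarity > threshold, arr.ind = TRUE)
  edges <- data.frame(
    category_key = category_keys[hits[, 1]],
    reference_name = reference_names[hits[, 2]],
    similarity = similarity[hits],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(match(edges$category_key, category_keys),
                       -edges$similarity), , drop = FALSE]
  rownames(edges) <- NULL

  mapped <- unique(edges$category_key)
  coverage <- 100 * length(mapped) / length(category_keys)
  structure(list(edges = edges, threshold = threshold,
                 coverage_percent = coverage,
                 unmapped = setdiff(category_keys, mapped),
                 similarities = similarity),
            class = "taxonomy_mapping")
}

#' @export
print.taxonomy_mapping <- function(x, ...) {
  cat(sprintf("<taxonomy_mapping> %d edges, threshold = %.4f, coverage = %.2f%% (%d unmapped)\n",
              nrow(x$edges), x$threshold, x$coverage_percent,
              length(x$unmapped)))
  invisible(x)
}

#' Write a taxonomy mapping to disk
#'
#' Emits the edge list and the similarity histogram values as CSV, and the
#' threshold/coverage/unmapped report as JSON.
#'
#' @param mapping a `taxonomy_mapping`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_mapping <- function(mapping, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(mapping$edges, file.path(dir, "mapping_edges.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(similarity = as.vector(mapping$similarities)),
                   file.path(dir, "similarity_histogram.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(threshold = mapping$threshold,
         coverage_percent = mapping$coverage_percent,
         unmapped = mapping$unmapped),
    file.path(dir, "mapping_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
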