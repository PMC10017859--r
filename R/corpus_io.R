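# Reading, normalizing, deduplicating and partitioning question records.
#
# A question record is one field of an intake form: the verbatim question
# text ("field name") plus the slash-separated section/subsection hierarchy
# it appeared under ("field path", e.g. "economic/Education/").

#' Construct a question-record data frame
#'
#' Builds the canonical record table used throughout the package.  Each row
#' is one form field: a form identifier, the section-path the question
#' appeared under, the verbatim question text, and optional metadata.
#'
#' @param form_id character vector of form identifiers.
#' @param field_path character vector of slash-separated section paths.
#'   A path is either `""` (question at the form root) or ends with `"/"`;
#'   individual segments may not contain `"/"`.
#' @param field_name character vector of verbatim question texts; must be
#'   non-empty after whitespace collapse.
#' @param value_kind one of `"free_text"`, `"number"`, `"choice"`,
#'   `"multi_answer"` per record (recycled if length 1).
#' @param allowed_values list of character vectors (or `NULL` entries);
#'   required exactly when `value_kind` is `"choice"` or `"multi_answer"`.
#' @param date_of_conduct optional ISO dates (character or `Date`), `NA`
#'   where unknown.
#' @param site_id optional site identifiers, `NA` where unknown.
#' @param record_id optional record identifiers; generated (`"q000001"`,
#'   ...) when omitted.
#'
#' @return A `data.frame` of class `question_records` with columns
#'   `record_id`, `form_id`, `field_path`, `field_name`, `value_kind`,
#'   `allowed_values` (list column), `date_of_conduct`, `site_id`.
#' @export
question_records <- function(form_id, field_path, field_name,
                             value_kind = "free_text",
                             allowed_values = NULL,
                             date_of_conduct = NA_character_,
                             site_id = NA_character_,
                             record_id = NULL) {
  n <- length(field_name)
  form_id <- rep_len(as.character(form_id), n)
  field_path <- rep_len(as.character(field_path), n)
  value_kind <- rep_len(as.character(value_kind), n)
  date_of_conduct <- rep_len(as.character(date_of_conduct), n)
  site_id <- rep_len(as.character(site_id), n)
  if (is.null(record_id)) {
    record_id <- sprintf("q%06d", seq_len(n))
  }
  if (is.null(allowed_values)) {
    allowed_values <- rep(list(NULL), n)
  }
  stopifnot(length(field_path) == n, length(allowed_values) == n)

  df <- data.frame(
    record_id = as.character(record_id),
    form_id = form_id,
    field_path = field_path,
    field_name = as.character(field_name),
    value_kind = value_kind,
    date_of_conduct = date_of_conduct,
    site_id = site_id,
    stringsAsFactors = FALSE
  )
  df$allowed_values <- allowed_values
  df <- df[, c("record_id", "form_id", "field_path", "field_name",
               "value_kind", "allowed_values", "date_of_conduct", "site_id")]
  class(df) <- c("question_records", "data.frame")
  validate_question_records(df)
  df
}

#' @keywords internal
validate_question_records <- function(df) {
  bad_name <- !nzchar(normalize_text(df$field_name))
  if (any(bad_name)) {
    stop("field_name empty after whitespace collapse at row(s): ",
         paste(which(bad_name), collapse = ", "), call. = FALSE)
  }
  path <- df$field_path
  bad_path <- nzchar(path) & !endsWith(path, "/")
  if (any(bad_path)) {
    stop("field_path must be \"\" or end with \"/\" at row(s): ",
         paste(which(bad_path), collapse = ", "), call. = FALSE)
  }
  kinds <- c("free_text", "number", "choice", "multi_answer")
  bad_kind <- !df$value_kind %in% kinds
  if (any(bad_kind)) {
    stop("unknown value_kind at row(s): ",
         paste(which(bad_kind), collapse = ", "), call. = FALSE)
  }
  needs_values <- df$value_kind %in% c("choice", "multi_answer")
  has_values <- !vapply(df$allowed_values, is.null, logical(1))
  if (any(needs_values != has_values)) {
    stop("allowed_values must be present iff value_kind is choice/",
         "multi_answer; offending row(s): ",
         paste(which(needs_values != has_values), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$record_id)) {
    stop("duplicate record_id values", call. = FALSE)
  }
  invisible(df)
}

#' Collapse whitespace and case-fold a string
#'
#' The normalization applied before question-distinctness comparisons:
#' leading/trailing whitespace stripped, internal runs of whitespace
#' collapsed to one space, then lower-cased.  No stemming and no
#' punctuation stripping, so the rule stays auditable.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalize_text <- function(x) {
  tolower(trimws(gsub("\\s+", " ", x)))
}

#' Load question records from delimited text or JSON lines
#'
#' Reads a file with one question record per row/line.  Delimited input
#' (`.csv` comma, `.tsv`/`.txt` tab, or explicit `sep`) must carry a header
#' with at least `form_id`, `field_path`, `field_name`; JSON-lines input
#' (`.jsonl`/`.ndjson`) must carry the same keys per object.  Optional
#' fields (`value_kind`, `allowed_values`, `date_of_conduct`, `site_id`,
#' `record_id`) are picked up when present and left absent (`NA`/`NULL`)
#' otherwise, never coerced to empty strings.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"delim"` or `"jsonl"`.
#' @param sep field separator for delimited input; default chosen from the
#'   extension.
#' @return a `question_records` data frame, rows in input order.  An empty
#'   file with a valid header yields zero rows.
#' @export
load_question_records <- function(path, format = c("auto", "delim", "jsonl"),
                                  sep = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("jsonl", "ndjson", "json")) "jsonl" else "delim"
  }
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) return(question_records(character(), character(), character())[0, ])
    rows <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                      error = function(e) stop("malformed JSON at line ", i,
                                               ": ", conditionMessage(e),
                                               call. = FALSE))
      rec
    })
    need <- c("form_id", "field_path", "field_name")
    for (i in seq_along(rows)) {
      missing_keys <- setdiff(need, names(rows[[i]]))
      if (length(missing_keys) > 0) {
        stop("line ", i, " missing mandatory key(s): ",
             paste(missing_keys, collapse = ", "), call. = FALSE)
      }
    }
    get_chr <- function(key, default = NA_character_) {
      vapply(rows, function(r) {
        v <- r[[key]]
        if (is.null(v) || length(v) == 0) default else as.character(v)[1]
      }, character(1))
    }
    av <- lapply(rows, function(r) {
      v <- r[["allowed_values"]]
      if (is.null(v) || length(v) == 0) NULL else as.character(v)
    })
    vk <- get_chr("value_kind", "free_text")
    vk[is.na(vk)] <- "free_text"
    rid <- get_chr("record_id")
    question_records(
      form_id = get_chr("form_id"),
      field_path = get_chr("field_path"),
      field_name = get_chr("field_name"),
      value_kind = vk,
      allowed_values = av,
      date_of_conduct = get_chr("date_of_conduct"),
      site_id = get_chr("site_id"),
      record_id = if (all(is.na(rid))) NULL else rid
    )
  } else {
    if (is.null(sep)) {
      ext <- tolower(tools::file_ext(path))
      sep <- if (ext %in% c("tsv", "txt")) "\t" else ","
    }
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             quote = "\"", stringsAsFactors = FALSE,
                             check.names = FALSE, comment.char = "",
                             colClasses = "character")
    need <- c("form_id", "field_path", "field_name")
    missing_cols <- setdiff(need, names(tab))
    if (length(missing_cols) > 0) {
      stop("input is missing mandatory column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    if (nrow(tab) == 0) return(question_records(character(), character(), character())[0, ])
    bad <- which(is.na(tab$field_name) | !nzchar(trimws(tab$field_name)))
    if (length(bad) > 0) {
      stop("missing field_name at data row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    opt <- function(col, default = NA_character_) {
      if (col %in% names(tab)) {
        v <- tab[[col]]
        v[!nzchar(v) | is.na(v)] <- default
        v
      } else rep(default, nrow(tab))
    }
    av_col <- opt("allowed_values")
    av <- lapply(av_col, function(s) {
      if (is.na(s)) NULL else strsplit(s, ";", fixed = TRUE)[[1]]
    })
    vk <- opt("value_kind", "free_text")
    rid <- opt("record_id")
    question_records(
      form_id = tab$form_id,
      field_path = tab$field_path,
      field_name = tab$field_name,
      value_kind = vk,
      allowed_values = av,
      date_of_conduct = opt("date_of_conduct"),
      site_id = opt("site_id"),
      record_id = if (all(is.na(rid))) NULL else rid
    )
  }
}

#' Write question records as JSON lines
#'
#' Canonical on-disk form of the record table: one JSON object per line
#' with absent optional fields omitted rather than written as empty
#' strings.
#'
#' @param records a `question_records` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_question_records <- function(records, path) {
  lines <- vapply(seq_len(nrow(records)), function(i) {
    rec <- list(
      record_id = records$record_id[i],
      form_id = records$form_id[i],
      field_path = records$field_path[i],
      field_name = records$field_name[i],
      value_kind = records$value_kind[i]
    )
    if (!is.null(records$allowed_values[[i]])) {
      rec$allowed_values <- records$allowed_values[[i]]
    }
    if (!is.na(records$date_of_conduct[i])) {
      rec$date_of_conduct <- records$date_of_conduct[i]
    }
    if (!is.na(records$site_id[i])) rec$site_id <- records$site_id[i]
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Flatten a JSON-Schema form definition into question records
#'
#' Walks a JSON Schema depth-first.  Nested `object` properties encode the
#' form's section/subsection hierarchy, so each non-object leaf property
#' becomes one record whose `field_path` is the concatenation of its
#' ancestor property names joined and terminated by `"/"`, and whose
#' `field_name` is the leaf property name (the question text).  `string`
#' and `number`/`integer` leaves become `free_text`/`number`; a leaf
#' carrying an `enum` becomes `choice` with the enumerated values; an
#' `array` leaf becomes `multi_answer` (its item enum, when present, gives
#' the allowed values).
#'
#' @param schema a JSON Schema as an R list (e.g. from
#'   [jsonlite::fromJSON()] with `simplifyVector = FALSE`) or a path to a
#'   JSON file.
#' @param form_id identifier stamped on every produced record.
#' @return a `question_records` data frame; leaves of unsupported type are
#'   skipped with a warning naming their JSON pointer.
#' @export
flatten_json_schema <- function(schema, form_id) {
  if (is.character(schema) && length(schema) == 1) {
    schema <- jsonlite::fromJSON(schema, simplifyVector = FALSE)
  }
  root_type <- schema$type
  if (is.null(root_type) && !is.null(schema$properties)) root_type <- "object"
  if (is.null(root_type) || !identical(root_type, "object")) {
    stop("schema root must be an object type", call. = FALSE)
  }

  acc <- new.env(parent = emptyenv())
  acc$path <- character()
  acc$name <- character()
  acc$kind <- character()
  acc$values <- list()
  acc$skipped <- character()

  walk <- function(node, path, pointer) {
    props <- node$properties
    if (is.null(props)) return(invisible(NULL))
    for (prop in names(props)) {
      child <- props[[prop]]
      cptr <- paste0(pointer, "/properties/", prop)
      ctype <- child$type
      if (is.null(ctype) && !is.null(child$properties)) ctype <- "object"
      if (identical(ctype, "object")) {
        walk(child, c(path, prop), cptr)
      } else {
        enum_vals <- child$enum
        kind <- NULL
        vals <- NULL
        if (!is.null(enum_vals)) {
          kind <- "choice"
          vals <- as.character(unlist(enum_vals))
        } else if (identical(ctype, "array")) {
          kind <- "multi_answer"
          item_enum <- child$items$enum
          vals <- if (!is.null(item_enum)) as.character(unlist(item_enum)) else character(0)
        } else if (identical(ctype, "string")) {
          kind <- "free_text"
        } else if (ctype %in% c("number", "integer")) {
          kind <- "number"
        }
        if (is.null(kind)) {
          acc$skipped <- c(acc$skipped, cptr)
        } else {
          fp <- if (length(path) == 0) "" else paste0(paste(path, collapse = "/"), "/")
          acc$path <- c(acc$path, fp)
          acc$name <- c(acc$name, prop)
          acc$kind <- c(acc$kind, kind)
          acc$values <- c(acc$values, list(vals))
        }
      }
    }
  }
  walk(schema, character(), "#")

  if (length(acc$skipped) > 0) {
    warning("skipped unsupported leaf type at: ",
            paste(acc$skipped, collapse = ", "), call. = FALSE)
  }
  if (length(acc$name) == 0) {
    return(question_records(character(), character(), character())[0, ])
  }
  question_records(
    form_id = form_id,
    field_path = acc$path,
    field_name = acc$name,
    value_kind = acc$kind,
    allowed_values = acc$values
  )
}

#' Count distinct questions under a dedup key
#'
#' Two keying modes reflect the two ways a question corpus can be counted:
#' by section path plus question text, or by question text alone.  Titles
#' that differ only in case or whitespace collapse to one key (see
#' [normalize_text()]).
#'
#' @param records a `question_records` data frame.
#' @param key_mode `"path_and_text"` (key is normalized path + `"|"` +
#'   normalized text) or `"text_only"`.
#' @return list with `keys` (unique keys in order of first occurrence),
#'   `count`, and `key_of` (the key of every input record).
#' @export
distinct_questions <- function(records,
                               key_mode = c("path_and_text", "text_only")) {
  key_mode <- match.arg(key_mode)
  if (nrow(records) == 0) {
    return(list(keys = character(0), count = 0L, key_of = character(0)))
  }
  key_of <- if (key_mode == "path_and_text") {
    paste0(normalize_text(records$field_path), "|",
           normalize_text(records$field_name))
  } else {
    normalize_text(records$field_name)
  }
  keys <- unique(key_of)
  list(keys = keys, count = length(keys), key_of = key_of)
}

#' Randomly partition record ids into train and test sets
#'
#' Uniform split without replacement, reproducible for a fixed seed.  The
#' generator state is restored on exit so callers' random streams are
#' unaffected.
#'
#' @param ids vector of record ids (no duplicates).
#' @param train_size number of ids assigned to the training set; must
#'   satisfy `0 < train_size < length(ids)`.
#' @param seed integer seed.
#' @return list of class `record_partition` with `train_ids`, `test_ids`,
#'   `seed`.
#' @export
partition_records <- function(ids, train_size, seed) {
  n <- length(ids)
  if (anyDuplicated(ids)) stop("ids contain duplicates", call. = FALSE)
  if (train_size <= 0 || train_size >= n) {
    stop("train_size must satisfy 0 < train_size < ", n,
         " (got ", train_size, ")", call. = FALSE)
  }
  idx <- with_seed(seed, sample.int(n, train_size))
  out <- list(train_ids = ids[sort(idx)], test_ids = ids[-sort(idx)],
              seed = as.integer(seed))
  class(out) <- "record_partition"
  out
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's state.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
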