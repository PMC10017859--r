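# End-to-end orchestration: ingest -> embed -> reduce -> cluster ->
# validate -> map, with a flat append-only reproducibility manifest.
# Each stage gets its own seed derived from the master seed
# (stage_seed = master_seed + 1000 * stage_index) so stages are
# independently re-runnable.

#' @keywords internal
default_pipeline_config <- function() {
  list(
    seed = 1L,
    simulate = list(enabled = TRUE, categories = NULL, n_per_category = 25,
                    duplicate_rate = 0.2),
    ingest = list(records_file = NULL, key_mode = "text_only"),
    embed = list(dim = 256, buckets = 4096),
    reduce = list(enabled = TRUE, K = 5, d_grid = c(2, 3, 5, 8),
                  replications = 3, subsample_size = NULL,
                  mode = "knee", d = NULL),
    cluster = list(k = NULL, k_grid = 2:10, max_iter = 10,
                   init = "cosine_plus_plus", restarts = 5),
    validate = list(n_runs = 3, train_size = NULL),
    map = list(reference_file = NULL, reference_names = NULL,
               quantile_type = 7)
  )
}

#' @keywords internal
merge_config <- function(base, override) {
  for (key in names(override)) {
    if (is.list(base[[key]]) && is.list(override[[key]])) {
      base[[key]] <- merge_config(base[[key]], override[[key]])
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' @keywords internal
validate_pipeline_config <- function(config) {
  known <- names(default_pipeline_config())
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1) {
    stop("config field 'seed' must be a single integer", call. = FALSE)
  }
  if (!isTRUE(config$simulate$enabled) &&
      is.null(config$ingest$records_file)) {
    stop("config field 'ingest.records_file' is required when ",
         "'simulate.enabled' is FALSE", call. = FALSE)
  }
  invisible(config)
}

#' @keywords internal
manifest_stage <- function(manifest, name, parameters, seed,
                           inputs = character(0), outputs = character(0)) {
  hash_files <- function(paths) {
    paths <- paths[file.exists(paths)]
    if (length(paths) == 0) return(list())
    h <- tools::md5sum(paths)
    stats::setNames(as.list(unname(h)), basename(paths))
  }
  manifest$stages[[name]] <- list(
    stage = name,
    parameters = parameters,
    seed = seed,
    input_hashes = hash_files(inputs),
    output_hashes = hash_files(outputs),
    software = paste0("sdohmap ", as.character(utils::packageVersion("sdohmap"))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  manifest
}

#' Run the harmonization pipeline end to end
#'
#' Executes ingest (or synthetic simulation) -> embed -> reduce (sweep +
#' dimension selection) -> cluster (scan + fit) -> IGP validation ->
#' taxonomy mapping, writing each stage's artifacts under `out_dir` and a
#' reproducibility manifest (`manifest.json`) last.  The mapping stage is
#' marked `"skipped"` when no reference taxonomy is configured; dimension
#' reduction can be disabled to cluster the raw embedding space.
#'
#' Deterministic given the config: re-running with identical config and
#' inputs reproduces identical content hashes for every deterministic
#' stage (timestamps live outside the hashed artifacts).
#'
#' @param config nested list (see `default_pipeline_config()` internals
#'   for the schema) or a path to a JSON/YAML config file.  Unknown fields
#'   are rejected by name.
#' @param out_dir artifact directory, created if needed.
#' @return the manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("reading YAML configs requires the yaml package; ",
             "use JSON or pass a list", call. = FALSE)
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    }
  }
  config <- merge_config(default_pipeline_config(), config)
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  master_seed <- as.integer(config$seed)
  stage_seed <- function(i) master_seed + 1000L * i
  manifest <- list(master_seed = master_seed, stages = list())

  # -- stage 1: ingest / simulate ------------------------------------------
  if (isTRUE(config$simulate$enabled)) {
    cats <- config$simulate$categories
    if (is.null(cats)) cats <- synthetic_categories()
    corpus <- generate_question_corpus(
      cats, n_per_category = config$simulate$n_per_category,
      duplicate_rate = config$simulate$duplicate_rate,
      seed = stage_seed(1))
    records <- corpus$records
    records_path <- file.path(out_dir, "records.jsonl")
    write_question_records(records, records_path)
    truth_path <- file.path(out_dir, "true_categories.json")
    jsonlite::write_json(as.list(corpus$true_category), truth_path,
                         auto_unbox = TRUE)
    manifest <- manifest_stage(
      manifest, "simulate",
      parameters = list(categories = cats,
                        n_per_category = config$simulate$n_per_category,
                        duplicate_rate = config$simulate$duplicate_rate),
      seed = stage_seed(1), outputs = c(records_path, truth_path))
  } else {
    records <- load_question_records(config$ingest$records_file)
    records_path <- file.path(out_dir, "records.jsonl")
    write_question_records(records, records_path)
    manifest <- manifest_stage(
      manifest, "ingest",
      parameters = list(records_file = config$ingest$records_file),
      seed = NA, inputs = config$ingest$records_file,
      outputs = records_path)
  }

  # dedup at the analysis boundary; raw records stay on disk untouched
  key_mode <- config$ingest$key_mode
  dd_both <- distinct_questions(records, "path_and_text")
  dd_text <- distinct_questions(records, "text_only")
  dedup_path <- file.path(out_dir, "dedup_report.csv")
  utils::write.csv(
    data.frame(key_mode = c("path_and_text", "text_only"),
               count = c(dd_both$count, dd_text$count)),
    dedup_path, row.names = FALSE)
  dd <- if (key_mode == "path_and_text") dd_both else dd_text
  first_idx <- !duplicated(dd$key_of)
  analysis_records <- records[first_idx, , drop = FALSE]
  texts <- analysis_records$field_name
  ids <- analysis_records$record_id

  # -- stage 2: embed -------------------------------------------------------
  backend <- ngram_encoder(dim = config$embed$dim,
                           buckets = config$embed$buckets,
                           seed = stage_seed(2))
  emb <- encode_texts(texts, backend, ids = ids)
  emb_path <- file.path(out_dir, "embeddings.tsv")
  write_embedding(emb, emb_path)
  manifest <- manifest_stage(
    manifest, "embed",
    parameters = list(encoder = emb$encoder_tag, n = length(ids),
                      key_mode = key_mode),
    seed = stage_seed(2), inputs = records_path,
    outputs = c(dedup_path, emb_path, paste0(emb_path, ".json")))

  # -- stage 3: reduce ------------------------------------------------------
  if (isTRUE(config$reduce$enabled)) {
    sub <- config$reduce$subsample_size
    if (is.null(sub)) sub <- nrow(emb$vectors)
    sweep <- sweep_dimensions(emb$vectors, K = config$reduce$K,
                              d_grid = config$reduce$d_grid,
                              replications = config$reduce$replications,
                              subsample_size = sub, seed = stage_seed(3))
    sweep_path <- file.path(out_dir, "reduction_sweep.csv")
    write_sweep_table(sweep, sweep_path)
    d_sel <- select_dimension(sweep, mode = config$reduce$mode,
                              d = config$reduce$d)
    red <- lle_fit(emb$vectors, K = config$reduce$K, d = d_sel)
    coords <- red$Y
    rownames(coords) <- ids
    coords_path <- file.path(out_dir, "coordinates.tsv")
    utils::write.table(coords, coords_path, sep = "\t", col.names = FALSE)
    manifest <- manifest_stage(
      manifest, "reduce",
      parameters = list(K = config$reduce$K, d = d_sel,
                        mode = config$reduce$mode, phi = red$phi),
      seed = stage_seed(3), inputs = emb_path,
      outputs = c(sweep_path, coords_path))
  } else {
    coords <- emb$vectors
    coords_path <- emb_path
  }

  # -- stage 4: cluster -----------------------------------------------------
  k <- config$cluster$k
  scan_path <- NULL
  if (is.null(k)) {
    scan <- elbow_scan(coords, k_grid = config$cluster$k_grid,
                       max_iter = config$cluster$max_iter,
                       init = config$cluster$init,
                       restarts = config$cluster$restarts,
                       seed = stage_seed(4))
    scan_path <- file.path(out_dir, "cluster_scan.csv")
    utils::write.csv(scan, scan_path, row.names = FALSE)
    k <- knee_k(scan)
  }
  fit <- spherical_kmeans(coords, k, max_iter = config$cluster$max_iter,
                          init = config$cluster$init,
                          restarts = config$cluster$restarts,
                          seed = stage_seed(4))
  labels_path <- file.path(out_dir, "cluster_labels.csv")
  utils::write.csv(data.frame(record_id = ids, cluster = fit$labels),
                   labels_path, row.names = FALSE)
  centroids_path <- file.path(out_dir, "centroids.tsv")
  utils::write.table(fit$centroids, centroids_path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  model_path <- file.path(out_dir, "cluster_model.json")
  jsonlite::write_json(list(k = fit$k, inertia = fit$inertia,
                            max_iter = fit$max_iter, init = fit$init,
                            converged = fit$converged),
                       model_path, auto_unbox = TRUE, digits = NA)
  manifest <- manifest_stage(
    manifest, "cluster",
    parameters = list(k = k, max_iter = config$cluster$max_iter,
                      init = config$cluster$init,
                      restarts = config$cluster$restarts),
    seed = stage_seed(4), inputs = coords_path,
    outputs = c(labels_path, centroids_path, model_path,
                if (!is.null(scan_path)) scan_path))

  # -- stage 5: validate (IGP) ---------------------------------------------
  train_size <- config$validate$train_size
  if (is.null(train_size)) train_size <- floor(nrow(coords) * 1937 / 3582)
  igp_rep <- replicate_igp(coords, k = k, n_runs = config$validate$n_runs,
                           train_size = train_size,
                           max_iter = config$cluster$max_iter,
                           init = config$cluster$init,
                           restarts = config$cluster$restarts,
                           seed = stage_seed(5))
  igp_path <- file.path(out_dir, "igp_summary.csv")
  utils::write.csv(igp_rep$summary_table, igp_path, row.names = FALSE)
  manifest <- manifest_stage(
    manifest, "validate",
    parameters = list(n_runs = config$validate$n_runs,
                      train_size = igp_rep$n_train,
                      test_size = igp_rep$n_test, k = k),
    seed = stage_seed(5), inputs = coords_path, outputs = igp_path)

  # -- stage 6: map ---------------------------------------------------------
  ref_names <- config$map$reference_names
  if (is.null(ref_names) && !is.null(config$map$reference_file)) {
    ref_names <- readLines(config$map$reference_file, warn = FALSE)
    ref_names <- ref_names[nzchar(trimws(ref_names))]
  }
  if (is.null(ref_names)) {
    manifest$stages[["map"]] <- list(stage = "map", status = "skipped",
                                     reason = "no reference taxonomy configured")
  } else {
    tax <- sdoh_taxonomy()
    mapping <- map_categories(build_category_strings(tax), ref_names,
                              backend = backend,
                              category_keys = category_keys(tax),
                              quantile_type = config$map$quantile_type)
    map_dir <- file.path(out_dir, "mapping")
    write_mapping(mapping, map_dir)
    manifest <- manifest_stage(
      manifest, "map",
      parameters = list(n_categories = nrow(tax),
                        n_references = length(ref_names),
                        threshold = mapping$threshold,
                        coverage_percent = mapping$coverage_percent,
                        quantile_type = config$map$quantile_type),
      seed = NA, inputs = coords_path,
      outputs = file.path(map_dir, c("mapping_edges.csv",
                                     "similarity_histogram.csv",
                                     "mapping_report.json")))
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}

#' Apply expert relabels on top of algorithmic cluster assignments
#'
#' Subject-matter experts review the clustering and move individual
#' questions to the cluster they judge correct.  Overrides are applied on
#' top of the algorithmic labels; an audit log records every change and
#' the overall override fraction (reported, not enforced).
#'
#' @param labels named integer vector: algorithmic cluster per record id.
#' @param relabels data frame with columns `record_id`, `cluster` (the
#'   expert's assignment), or a CSV path with those columns.
#' @param n_clusters number of valid clusters; defaults to `max(labels)`.
#' @return list with `labels` (revised assignments), `audit` (data frame
#'   `record_id`, `before`, `after`), `override_fraction_percent`.
#' @export
apply_sme_relabels <- function(labels, relabels,
                               n_clusters = max(labels)) {
  if (is.character(relabels) && length(relabels) == 1) {
    relabels <- utils::read.csv(relabels, stringsAsFactors = FALSE)
  }
  if (nrow(relabels) == 0) {
    return(list(labels = labels,
                audit = data.frame(record_id = character(0),
                                   before = integer(0), after = integer(0)),
                override_fraction_percent = 0))
  }
  bad_rec <- setdiff(relabels$record_id, names(labels))
  bad_cl <- setdiff(relabels$cluster, seq_len(n_clusters))
  offenders <- c(
    if (length(bad_rec) > 0) paste("unknown record id(s):",
                                   paste(bad_rec, collapse = ", ")),
    if (length(bad_cl) > 0) paste("unknown cluster id(s):",
                                  paste(bad_cl, collapse = ", ")))
  if (length(offenders) > 0) {
    stop(paste(offenders, collapse = "; "), call. = FALSE)
  }
  before <- labels[relabels$record_id]
  labels[relabels$record_id] <- relabels$cluster
  changed <- before != relabels$cluster
  audit <- data.frame(record_id = relabels$record_id[changed],
                      before = unname(before[changed]),
                      after = relabels$cluster[changed],
                      stringsAsFactors = FALSE)
  list(labels = labels, audit = audit,
       override_fraction_percent = 100 * nrow(audit) / length(labels))
}
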