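test_that("delimited and JSON-lines loaders round-trip question records", {
  recs <- education_records()

  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(form_id = recs$form_id, field_path = recs$field_path,
                       field_name = recs$field_name), csv, row.names = FALSE)
  got <- load_question_records(csv)
  expect_equal(got$field_path, recs$field_path)
  expect_equal(got$field_name, recs$field_name)
  expect_equal(got$field_path[1], "economic/Education/")
  expect_true(all(is.na(got$site_id)))  # absent optionals stay absent

  jl <- tempfile(fileext = ".jsonl")
  write_question_records(recs, jl)
  back <- load_question_records(jl)
  expect_equal(back$field_name, recs$field_name)
  expect_equal(back$record_id, recs$record_id)
})

test_that("empty input yields an empty record list, not an error", {
  csv <- tempfile(fileext = ".csv")
  writeLines("form_id,field_path,field_name", csv)
  expect_equal(nrow(load_question_records(csv)), 0)
  jl <- tempfile(fileext = ".jsonl")
  writeLines(character(0), jl)
  expect_equal(nrow(load_question_records(jl)), 0)
})

test_that("malformed input is reported by column and row", {
  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(form_id = "F1", field_path = "a/"), csv,
            row.names = FALSE)
  expect_error(load_question_records(csv), "field_name")

  csv2 <- tempfile(fileext = ".csv")
  writeLines(c("form_id,field_path,field_name",
               "F1,a/,first question", "F2,b/,"), csv2)
  expect_error(load_question_records(csv2), "row\\(s\\): 2")
})

test_that("JSON-Schema flattening reproduces the section hierarchy", {
  recs <- flatten_json_schema(example_schema(), "F1")
  edu <- recs[recs$field_name == "What Is The Highest Grade You Have Completed", ]
  expect_equal(nrow(edu), 1)
  expect_equal(edu$field_path, "economic/Education/")

  # root-level leaves get the empty path
  dob <- recs[recs$field_name == "Date of birth", ]
  expect_equal(dob$field_path, "")
  expect_equal(dob$value_kind, "free_text")

  # enum -> choice with its values; array -> multi_answer
  lang <- recs[recs$field_name == "Primary language", ]
  expect_equal(lang$value_kind, "choice")
  expect_length(lang$allowed_values[[1]], 3)
  meds <- recs[recs$field_name == "Current medications", ]
  expect_equal(meds$value_kind, "multi_answer")

  expect_error(flatten_json_schema(list(type = "string"), "F1"),
               "root must be an object")
})

test_that("schema round-trip: rebuilt paths match generated hierarchies", {
  set.seed(9)
  for (rep in 1:5) {
    # build a random 2-level section tree with leaf questions
    sections <- paste0("S", seq_len(sample(2:4, 1)))
    schema <- list(type = "object", properties = list())
    expected <- character(0)
    for (s in sections) {
      subs <- paste0(s, "_sub", seq_len(sample(1:3, 1)))
      props <- list()
      for (sub in subs) {
        qs <- paste0(sub, " question ", seq_len(sample(1:3, 1)))
        leafs <- setNames(rep(list(list(type = "string")), length(qs)), qs)
        props[[sub]] <- list(type = "object", properties = leafs)
        expected <- c(expected, paste0(s, "/", sub, "/"))
      }
      schema$properties[[s]] <- list(type = "object", properties = props)
    }
    recs <- flatten_json_schema(schema, "Fx")
    expect_setequal(unique(recs$field_path), unique(expected))
  }
})

test_that("distinctness counting matches the worked path/text example", {
  recs <- education_records()
  expect_equal(distinct_questions(recs, "path_and_text")$count, 3)
  expect_equal(distinct_questions(recs, "text_only")$count, 2)

  empty <- recs[0, ]
  expect_equal(distinct_questions(empty, "path_and_text")$count, 0)
  expect_equal(distinct_questions(empty, "text_only")$count, 0)

  copies <- recs[rep(1, 100), ]
  copies$record_id <- sprintf("r%03d", 1:100)
  expect_equal(distinct_questions(copies, "path_and_text")$count, 1)
  expect_equal(distinct_questions(copies, "text_only")$count, 1)

  # normalization: case and internal whitespace do not split keys
  variant <- recs
  variant$field_name[2] <- "what is   the highest grade you have completed"
  expect_equal(distinct_questions(variant, "text_only")$count, 2)
})

test_that("text-only distinct count never exceeds path+text count", {
  set.seed(31)
  for (rep in 1:10) {
    corpus <- generate_question_corpus(
      sample(synthetic_categories(), 3), n_per_category = 8,
      duplicate_rate = runif(1, 0, 0.4), seed = rep)
    recs <- corpus$records
    expect_lte(distinct_questions(recs, "text_only")$count,
               distinct_questions(recs, "path_and_text")$count)
  }
})

test_that("record partition is a reproducible disjoint split", {
  ids <- sprintf("q%04d", 1:3582)
  p <- partition_records(ids, 1937, seed = 7)
  expect_length(p$train_ids, 1937)
  expect_length(p$test_ids, 1645)
  expect_length(intersect(p$train_ids, p$test_ids), 0)
  expect_setequal(c(p$train_ids, p$test_ids), ids)

  p2 <- partition_records(ids, 1937, seed = 7)
  expect_identical(p, p2)
  p3 <- partition_records(ids, 1937, seed = 8)
  expect_false(identical(p$train_ids, p3$train_ids))

  expect_error(partition_records(ids, length(ids), seed = 1), "train_size")
  expect_error(partition_records(ids, 0, seed = 1), "train_size")
})

test_that("record invariants are enforced on construction", {
  expect_error(question_records("F1", "a/", "   "), "field_name")
  expect_error(question_records("F1", "a/b", "q"), "end with")
  expect_error(question_records("F1", "a/", "q", value_kind = "choice"),
               "allowed_values")
  expect_silent(question_records("F1", "a/", "q", value_kind = "choice",
                                 allowed_values = list(c("yes", "no"))))
})
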