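test_that("the bundled taxonomy loads with its invariants intact", {
  tax <- sdoh_taxonomy()
  expect_s3_class(tax, "sdoh_taxonomy")
  expect_equal(nrow(tax), 36)
  expect_true(all(nzchar(tax$category)))
  expect_true(all(nzchar(tax$definition)))
  # subcategories fill left-to-right
  expect_false(any(is.na(tax$subcategory1) & !is.na(tax$subcategory2)))
  expect_false(any(is.na(tax$subcategory2) & !is.na(tax$subcategory3)))
  # node keys distinguish rows sharing a top-level category
  keys <- category_keys(tax)
  expect_false(anyDuplicated(keys) > 0)
  expect_true("Health/Mental/Behavioral/Gambling" %in% keys)
})

test_that("category strings join non-empty fields in order with comma-space", {
  tax <- sdoh_taxonomy()
  strings <- build_category_strings(tax)
  expect_length(strings, nrow(tax))
  gambling <- strings[category_keys(tax) == "Health/Mental/Behavioral/Gambling"]
  expect_equal(gambling,
               "Health, Mental, Behavioral, Gambling, Addicted to playing games of chance for money")
  # a row with no subcategories is "Category, Definition" only
  leisure <- strings[tax$category == "Leisure" & is.na(tax$subcategory1)]
  expect_equal(leisure, "Leisure, Free time, hobbies, interests, activities")
})

test_that("upper hinge matches the reference quantile routine", {
  expect_equal(upper_hinge_threshold(rep(0.3, 4)), 0.3)   # IQR = 0
  expect_equal(upper_hinge_threshold(0.7), 0.7)           # singleton
  # linear-interpolation quantiles: Q1 = 2.75, Q3 = 6.25 on 1..8
  q <- unname(quantile(1:8, c(0.25, 0.75), type = 7))
  expect_equal(q, c(2.75, 6.25))
  expect_equal(upper_hinge_threshold(1:8), q[2] + 1.5 * (q[2] - q[1]))
  expect_equal(upper_hinge_threshold(1:8), 11.5)
  expect_error(upper_hinge_threshold(numeric(0)), "no finite")

  set.seed(79)
  v <- runif(50)
  q2 <- unname(quantile(v, c(0.25, 0.75), type = 7))
  expect_equal(upper_hinge_threshold(v), q2[2] + 1.5 * diff(q2),
               tolerance = 1e-12)
})

test_that("mapping a list onto itself yields full coverage at similarity 1", {
  tax <- sdoh_taxonomy()
  strings <- build_category_strings(tax)
  m <- map_categories(strings, strings, backend = ngram_encoder(dim = 64),
                      category_keys = category_keys(tax))
  expect_equal(m$coverage_percent, 100)
  expect_length(m$unmapped, 0)
  self_sims <- diag(m$similarities)
  expect_equal(unname(self_sims), rep(1, nrow(tax)), tolerance = 1e-9)
})

test_that("strict-inequality thresholding on a hand-set matrix", {
  S <- matrix(c(0.9, 0.1, 0.2, 0.15), nrow = 2, byrow = TRUE)
  m <- map_categories(c("A", "B"), c("P1", "P2"), similarity = S,
                      threshold = 0.5)
  expect_equal(nrow(m$edges), 1)
  expect_equal(m$edges$category_key, "A")
  expect_equal(m$edges$reference_name, "P1")
  expect_equal(m$coverage_percent, 50)
  expect_equal(m$unmapped, "B")

  # equality is excluded: similarity exactly at the threshold is no edge
  m_eq <- map_categories("A", "P1", similarity = matrix(0.5),
                         threshold = 0.5)
  expect_equal(nrow(m_eq$edges), 0)

  # one category may map to several references
  m_multi <- map_categories("A", c("P1", "P2", "P3"),
                            similarity = matrix(c(0.8, 0.7, 0.1), 1),
                            threshold = 0.5)
  expect_equal(nrow(m_multi$edges), 2)
})

test_that("coverage is non-increasing as the threshold rises", {
  set.seed(83)
  S <- matrix(runif(15 * 8, -0.2, 0.9), 15, 8)
  cats <- paste0("cat", 1:15)
  refs <- paste0("ref", 1:8)
  thresholds <- sort(runif(12, -0.2, 0.95))
  cov <- sapply(thresholds, function(th) {
    map_categories(cats, refs, similarity = S,
                   threshold = th)$coverage_percent
  })
  expect_true(all(diff(cov) <= 0))
})

test_that("default threshold is the hinge of all pairwise similarities", {
  set.seed(89)
  S <- matrix(runif(12), 4, 3)
  m <- map_categories(paste0("c", 1:4), paste0("r", 1:3), similarity = S)
  expect_equal(m$threshold, upper_hinge_threshold(as.vector(S)))
  expect_true(all(m$edges$similarity > m$threshold))
  expect_true(all(m$similarities >= -1 & m$similarities <= 1))
})

test_that("mapping artifacts write and reload consistently", {
  S <- matrix(c(0.9, 0.1, 0.2, 0.15), nrow = 2, byrow = TRUE)
  m <- map_categories(c("A", "B"), c("P1", "P2"), similarity = S,
                      threshold = 0.5)
  dir <- file.path(tempdir(), "map-out")
  write_mapping(m, dir)
  edges <- read.csv(file.path(dir, "mapping_edges.csv"))
  expect_equal(nrow(edges), 1)
  report <- jsonlite::fromJSON(file.path(dir, "mapping_report.json"))
  expect_equal(report$coverage_percent, 50)
  hist <- read.csv(file.path(dir, "similarity_histogram.csv"))
  expect_equal(sort(hist$similarity), sort(as.vector(S)))
})

test_that("taxonomy reading validates structure", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("Category,Subcategory 1,Subcategory 2,Subcategory 3,Definition",
               "Health,,Mental,,bad row"), path)
  expect_error(read_taxonomy(path), "left-to-right")
  path2 <- tempfile(fileext = ".csv")
  writeLines("Category,Definition", path2)
  expect_error(read_taxonomy(path2), "missing column")
})
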