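test_that("the bundled lung document loads with the published stage array", {
  lung <- lung_tab()
  expect_equal(unique(lung$groupings$stage),
               c("Occult", "0", "IA", "IB", "IIA", "IIB", "IIIA", "IIIB", "IV"))
  expect_equal(nrow(lung$groupings), 28L)
  expect_equal(lung$axes$axis[order(lung$axes$rank)], c("M", "N", "T"))
  # per-stage row counts of the transcribed array
  expect_equal(as.integer(table(lung$groupings$stage)[
    c("Occult", "0", "IA", "IB", "IIA", "IIB", "IIIA", "IIIB", "IV")]),
    c(1L, 1L, 2L, 1L, 4L, 2L, 8L, 7L, 2L))
  expect_identical(validate_staging_table(lung),
                   validate_staging_table(lung))  # pure
  expect_equal(nrow(validate_staging_table(lung)), 0L)
})

test_that("a minimal one-grouping document loads; broken references do not", {
  path <- tempfile(fileext = ".json")
  write_staging_table(minimal_table(), path)
  tab <- read_staging_table(path)
  expect_equal(nrow(tab$groupings), 1L)
  expect_equal(tab$groupings$stage, "I")

  # grouping referencing an undefined T9 classification is a load error
  bad <- edited_lung_doc(function(doc) {
    doc$stages[[3]]$groupings[[1]]$T <- "T9"
    doc
  })
  expect_error(read_staging_table(bad), class = "tnm_load_error")
  expect_error(read_staging_table(bad), "T9")

  # duplicate stage label is a load error naming the path
  dup <- edited_lung_doc(function(doc) {
    doc$stages[[2]]$stage <- "Occult"
    doc
  })
  expect_error(read_staging_table(dup), class = "tnm_load_error")

  expect_error(read_staging_table(tempfile()), class = "tnm_load_error")
})

test_that("write/load round-trips preserve structure and row order", {
  lung <- lung_tab()
  p1 <- tempfile(fileext = ".json")
  write_staging_table(lung, p1)
  expect_equal(read_staging_table(p1), lung)

  # serialized grouping order matches the transcription order stage by stage
  doc <- jsonlite::fromJSON(p1, simplifyVector = FALSE)
  iiia <- purrr::detect(doc$stages, ~ .x$stage == "IIIA")
  expect_equal(vapply(iiia$groupings, function(g) g$T, character(1)),
               c("T1a", "T1b", "T2a", "T2b", "T3", "T3", "T4", "T4"))

  expect_equal(
    read_staging_table(write_staging_table(minimal_table(),
                                           tempfile(fileext = ".json"))),
    minimal_table())

  # property: round-trip identity over generated small tables
  for (seed in c(11L, 23L, 37L, 58L, 71L)) {
    tab <- random_staging_table(seed)
    p <- tempfile(fileext = ".json")
    write_staging_table(tab, p)
    expect_equal(read_staging_table(p, validate = FALSE), tab,
                 info = paste("seed", seed))
  }
})

test_that("the validator flags each seeded defect with a stable issue code", {
  lung <- lung_tab()

  # duplicate grouping row
  dup <- lung
  dup$groupings <- dplyr::bind_rows(
    dup$groupings,
    dplyr::mutate(dup$groupings[3, ], gid = 29L, row = 3L))
  iss <- validate_staging_table(dup)
  expect_true("DUPLICATE_GROUPING" %in% iss$code[iss$severity == "error"])

  # negative-polarity phrasing: the M0 question written as a negation
  neg <- edited_lung_doc(function(doc) {
    k <- which(vapply(doc$classifications, function(c) c$code,
                      character(1)) == "M0")
    doc$classifications[[k]]$question$clauses <-
      list("Is there no distant metastasis?")
    doc$classifications[[k]]$question$affirms <- TRUE
    doc
  })
  iss <- validate_staging_table(read_staging_table(neg))
  expect_true("NEGATIVE_POLARITY" %in% iss$code[iss$severity == "lint"])

  # a clause embedding an un-decomposed OR
  mixed <- edited_lung_doc(function(doc) {
    doc$classifications[[1]]$question$clauses <-
      list("Is the tumor unassessable OR occult?")
    doc
  })
  iss <- validate_staging_table(read_staging_table(mixed))
  expect_true("MIXED_BOOLEAN" %in% iss$code[iss$severity == "lint"])

  # undefined classification reference
  undef <- lung
  undef$groupings$req[[5]]["T"] <- "T9"
  undef <- staging_table(undef$tumor_type, undef$axes,
                         undef$classifications,
                         undef$groupings[, c("stage", "req")])
  iss <- validate_staging_table(undef)
  expect_true("UNDEFINED_CLASSIFICATION" %in% iss$code[iss$severity == "error"])

  # overlapping groupings: a wildcard row that subsumes an explicit row
  over <- minimal_table()
  over2 <- staging_table(
    over$tumor_type, over$axes, over$classifications,
    tibble::tibble(stage = c("I", "II"),
                   req = list(c(T = "T1", N = "N0", M = "M0"),
                              c(T = NA, N = "N0", M = "M0"))))
  iss <- validate_staging_table(over2)
  expect_true("OVERLAPPING_GROUPINGS" %in% iss$code[iss$severity == "lint"])

  # classification used in a grouping without question clauses
  noq <- edited_lung_doc(function(doc) {
    k <- which(vapply(doc$classifications, function(c) c$code,
                      character(1)) == "N3")
    doc$classifications[[k]]$question$clauses <- list()
    doc
  })
  iss <- validate_staging_table(read_staging_table(noq, validate = FALSE))
  expect_true("MISSING_QUESTION" %in% iss$code[iss$severity == "error"])
})

test_that("the catalogue resolves tumor type and selectors to a document", {
  p <- resolve_table_path("lung")
  expect_true(file.exists(p))
  expect_equal(read_staging_table(p)$tumor_type, "lung")
  expect_error(resolve_table_path("myeloma"), class = "tnm_load_error")
  expect_error(resolve_table_path("lung", c(phase = "pathologic")),
               class = "tnm_load_error")
})
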