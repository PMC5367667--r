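# Shared fixtures, built in code.

lung_tab <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- lung_staging_table()
    cache
  }
})

# smallest valid table: one stage, one grouping (T1, N0, M0)
minimal_table <- function() {
  staging_table(
    tumor_type = "minimal",
    axes = tibble::tibble(axis = c("T", "N", "M"), rank = c(3L, 2L, 1L)),
    classifications = tibble::tibble(
      axis = c("T", "N", "M"), code = c("T1", "N0", "M0"),
      level = c(1, 0, 0), sublevel = NA_character_, parent = NA_character_,
      criteria = c("small localized tumor", "node negative",
                   "metastasis absent"),
      clauses = list("Is the tumor small and localized?",
                     "Are the regional nodes uninvolved?",
                     "Is there evidence of distant metastasis?"),
      connective = NA_character_, affirms = c(TRUE, TRUE, FALSE)
    ),
    groupings = tibble::tibble(
      stage = "I", req = list(c(T = "T1", N = "N0", M = "M0")))
  )
}

# deep-copy a staging table through its document form with one field edited;
# `edit` receives and returns the document list
edited_lung_doc <- function(edit) {
  doc <- jsonlite::fromJSON(
    system.file("extdata", "lung.json", package = "tnmstager"),
    simplifyVector = FALSE)
  doc <- edit(doc)
  path <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null",
                              digits = NA), path, useBytes = TRUE)
  path
}

# the answer sequence of the worked IIIB example
iiib_answers <- function() {
  data.frame(axis = c("M", "M", "N", "T"),
             code = c("M1b", "M1a", "N3", "T4"),
             answer = c("no", "no", "yes", "yes"))
}

stages_of <- function(session) {
  session$table$groupings$stage[
    match(session$candidates, session$table$groupings$gid)]
}
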