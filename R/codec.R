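#' Read a staging table from a JSON document
#'
#' Staging tables are authored as JSON documents, one per tumor type (or per
#' tumor type and selector combination). The document layout is described in
#' the package vignette; the bundled lung table
#' (`system.file("extdata", "lung.json", package = "tnmstager")`) is the
#' canonical example. Loading is deterministic and order-preserving: the
#' order of stages and of groupings within a stage in the document is the
#' prognostic order the engine and the lookup oracle use.
#'
#' @param path Path to a staging-table JSON document.
#' @param validate If `TRUE` (default), run [validate_staging_table()] after
#'   parsing and raise a load error naming each problem if any error-severity
#'   issue is found. Lints never block loading.
#' @return A [staging_table].
#' @seealso [write_staging_table()], [validate_staging_table()],
#'   [lung_staging_table()]
#' @examples
#' lung <- read_staging_table(
#'   system.file("extdata", "lung.json", package = "tnmstager"))
#' lung
#' @export
read_staging_table <- function(path, validate = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("staging table document does not exist: ", path),
          class = "tnm_load_error")
  }
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      abort(paste0("failed to parse JSON document '", path, "': ",
                   conditionMessage(e)),
            class = "tnm_load_error")
    }
  )
  table <- parse_staging_document(doc, path = path)
  if (isTRUE(validate)) {
    issues <- validate_staging_table(table)
    errs <- issues[issues$severity == "error", , drop = FALSE]
    if (nrow(errs) > 0) {
      abort(paste0(
        "invalid staging table '", path, "':\n",
        paste0("  [", errs$code, "] at ", errs$path, ": ", errs$message,
               collapse = "\n")),
        class = "tnm_load_error")
    }
  }
  table
}

# Convert a parsed JSON document (nested lists) into a staging_table.
parse_staging_document <- function(doc, path = "<document>") {
  fail <- function(where, msg) {
    abort(paste0("invalid staging table '", path, "' at ", where, ": ", msg),
          class = "tnm_load_error")
  }
  if (!is.list(doc)) fail("$", "document root must be an object")
  if (!identical(doc$format, "tnm-staging-table")) {
    fail("$.format", "expected \"tnm-staging-table\"")
  }
  for (f in c("tumor_type", "axes", "classifications", "stages")) {
    if (is.null(doc[[f]])) fail(paste0("$.", f), "required field is missing")
  }

  axes <- purrr::map_dfr(doc$axes, function(a) {
    if (is.null(a$axis) || is.null(a$rank)) {
      fail("$.axes[]", "each axis needs 'axis' and 'rank'")
    }
    tibble(axis = a$axis, rank = as.integer(a$rank),
           name = a$name %||% a$axis)
  })

  classifications <- purrr::map_dfr(doc$classifications, function(cl) {
    for (f in c("axis", "code", "level", "criteria", "question")) {
      if (is.null(cl[[f]])) {
        fail(paste0("$.classifications[", cl$code %||% "?", "]"),
             paste0("required field '", f, "' is missing"))
      }
    }
    q <- cl$question
    tibble(
      axis = cl$axis, code = cl$code, level = as.numeric(cl$level),
      sublevel = as.character(cl$sublevel %||% NA_character_),
      parent = as.character(cl$parent %||% NA_character_),
      criteria = cl$criteria,
      clauses = list(vapply(q$clauses, as.character, character(1))),
      connective = as.character(q$connective %||% NA_character_),
      affirms = isTRUE(q$affirms %||% TRUE)
    )
  })

  groupings <- purrr::map_dfr(doc$stages, function(st) {
    if (is.null(st$stage) || is.null(st$groupings)) {
      fail("$.stages[]", "each stage needs 'stage' and 'groupings'")
    }
    purrr::map_dfr(st$groupings, function(g) {
      req <- vapply(axes$axis, function(ax) {
        v <- g[[ax]]
        if (is.null(v)) {
          fail(paste0("$.stages[", st$stage, "]"),
               paste0("grouping is missing a requirement for axis ", ax))
        }
        if (identical(v, "*")) NA_character_ else as.character(v)
      }, character(1))
      tibble(stage = st$stage, req = list(req))
    })
  })

  # duplicate stage blocks are a load error (the constructor also catches the
  # non-contiguous case, but the codec names the document path)
  labels <- vapply(doc$stages, function(st) st$stage, character(1))
  if (anyDuplicated(labels)) {
    fail("$.stages", paste0("duplicate stage label: ",
                            paste(unique(labels[duplicated(labels)]),
                                  collapse = ", ")))
  }

  selectors <- unlist(doc$selectors %||% list())
  if (is.null(selectors)) selectors <- character()

  staging_table(
    tumor_type = doc$tumor_type,
    axes = axes,
    classifications = classifications,
    groupings = groupings,
    selectors = selectors
  )
}

#' Write a staging table to a JSON document
#'
#' The inverse of [read_staging_table()]: serialises a staging table back to
#' the JSON document layout, preserving axis, classification, stage and
#' grouping order, so that `read_staging_table(write_staging_table(t))` is
#' structurally identical to `t`.
#'
#' @param table A [staging_table].
#' @param path File path to write to, or `NULL` to return the JSON string.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
write_staging_table <- function(table, path = NULL) {
  stopifnot(inherits(table, "staging_table"))
  doc <- staging_document(table)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null",
                           digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

# staging_table -> plain list mirroring the JSON document layout
staging_document <- function(table) {
  unbox_na <- function(x) if (is.na(x)) NULL else x
  list(
    format = "tnm-staging-table",
    version = 1L,
    tumor_type = table$tumor_type,
    selectors = if (length(table$selectors) == 0) {
      stats::setNames(list(), character())
    } else {
      as.list(table$selectors)
    },
    axes = purrr::pmap(table$axes, function(axis, rank, name) {
      list(axis = axis, rank = rank, name = name)
    }),
    classifications = lapply(seq_len(nrow(table$classifications)), function(i) {
      cl <- table$classifications[i, ]
      out <- list(axis = cl$axis, code = cl$code, level = cl$level)
      if (!is.na(cl$sublevel)) out$sublevel <- cl$sublevel
      if (!is.na(cl$parent)) out$parent <- cl$parent
      out$criteria <- cl$criteria
      out$question <- c(
        list(clauses = as.list(cl$clauses[[1]])),
        if (!is.na(cl$connective)) list(connective = cl$connective),
        list(affirms = cl$affirms)
      )
      out
    }),
    stages = {
      blocks <- unique(table$groupings$stage)
      lapply(blocks, function(s) {
        rows <- table$groupings[table$groupings$stage == s, ]
        list(stage = s, groupings = lapply(rows$req, function(r) {
          as.list(ifelse(is.na(r), "*", r))
        }))
      })
    }
  )
}

#' The bundled lung-cancer staging table
#'
#' Convenience loader for the lung (non-small-cell) staging table shipped
#' with the package: 20 T/N/M classifications with criteria and yes/no
#' questions, and 28 TNM groupings across the stages Occult, 0, IA, IB,
#' IIA, IIB, IIIA, IIIB and IV (the stage IV rows carry "Any T"/"Any N"
#' wildcard requirements).
#'
#' @return A [staging_table].
#' @examples
#' lung_staging_table()
#' @export
lung_staging_table <- function() {
  read_staging_table(
    system.file("extdata", "lung.json", package = "tnmstager"))
}

#' Resolve a staging table through the catalogue
#'
#' A catalogue maps a tumor type plus secondary selector answers (subtype,
#' anatomic location, age limit, phase of staging) to a staging-table
#' document, implementing table selection as data. The bundled catalogue
#' lists only the lung table.
#'
#' @param tumor_type Tumor type name.
#' @param selectors Named character vector of selector answers; must match
#'   the entry's selectors exactly (entries with no selectors match an empty
#'   vector).
#' @param catalogue Path to a catalogue JSON file; defaults to the bundled
#'   catalogue.
#' @return The path to the matching staging-table document.
#' @examples
#' resolve_table_path("lung")
#' @export
resolve_table_path <- function(tumor_type, selectors = character(),
                               catalogue = system.file(
                                 "extdata", "catalogue.json",
                                 package = "tnmstager")) {
  if (!file.exists(catalogue)) {
    abort(paste0("catalogue does not exist: ", catalogue),
          class = "tnm_load_error")
  }
  entries <- jsonlite::fromJSON(catalogue, simplifyVector = FALSE)$tables
  hit <- purrr::detect(entries, function(e) {
    es <- unlist(e$selectors %||% list())
    identical(e$tumor_type, tumor_type) &&
      length(es) == length(selectors) &&
      all(names(selectors) %in% names(es)) &&
      all(es[names(selectors)] == selectors)
  })
  if (is.null(hit)) {
    abort(paste0("no catalogue entry for tumor type '", tumor_type, "'",
                 if (length(selectors)) paste0(" with selectors ",
                   paste(names(selectors), selectors, sep = "=", collapse = ", "))
                 else ""),
          class = "tnm_load_error")
  }
  file.path(dirname(catalogue), hit$file)
}
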