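#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

#' Construct a staging table
#'
#' A staging table is the complete specification of TNM staging for one tumor
#' type: the classification axes, the classification vocabulary with criteria
#' and yes/no questions, and the ordered anatomic stage groups with their TNM
#' groupings. Most users will load one with [read_staging_table()] rather than
#' build one by hand; this constructor is the entry point for programmatic
#' authoring and for the random-table generator.
#'
#' @param tumor_type Character scalar naming the tumor type (e.g. `"lung"`).
#' @param axes Data frame with columns `axis` (character code, e.g. `"T"`,
#'   `"N"`, `"M"` or a prognostic-factor axis code) and `rank` (integer
#'   extent-of-spread priority, 1 = highest; M outranks N outranks T). An
#'   optional `name` column carries a display name.
#' @param classifications Data frame with one row per classification: columns
#'   `axis`, `code`, `level` (numeric level within the axis; higher = more
#'   advanced), `sublevel` (single letter or `NA`), `parent` (code of a
#'   coarser classification on the same axis, or `NA`), `criteria` (verbatim
#'   definition text), `clauses` (list column of character vectors: the
#'   atomic yes/no question clauses), `connective` (`"OR"`, `"AND"`, or `NA`
#'   for single-clause questions) and `affirms` (logical: does an overall
#'   "yes" mean the classification applies? `FALSE` for questions that were
#'   rewritten into the affirmative from a negative definition, such as the
#'   lung M0 question).
#' @param groupings Data frame with one row per TNM grouping: columns `stage`
#'   (stage label), and `req` (list column of named character vectors, one
#'   element per axis; `NA` denotes a wildcard requirement such as "Any T").
#'   Stage labels must appear in contiguous blocks; block order defines the
#'   prognostic ordering (best prognosis first).
#' @param selectors Named character vector of secondary selection tags
#'   (tumor subtype, anatomic location, age limit, phase of staging).
#'
#' @return An object of class `staging_table`: a list with tibble fields
#'   `axes`, `classifications`, `groupings` (the latter gains `gid`,
#'   `prognostic_order` and within-stage `row` columns), plus `tumor_type`
#'   and `selectors`.
#'
#' @details Construction checks only structural well-formedness (required
#'   columns, T/N/M present, contiguous stage blocks). Semantic invariants —
#'   reference integrity, duplicate groupings, question coverage — are
#'   checked by [validate_staging_table()], so that deliberately defective
#'   tables can be built and inspected.
#'
#' @examples
#' tab <- staging_table(
#'   tumor_type = "minimal",
#'   axes = data.frame(axis = c("T", "N", "M"), rank = c(3, 2, 1)),
#'   classifications = data.frame(
#'     axis = c("T", "N", "M"), code = c("T1", "N0", "M0"),
#'     level = c(1, 0, 0), sublevel = NA, parent = NA,
#'     criteria = c("small tumor", "node negative", "metastasis absent"),
#'     clauses = I(list("Is the tumor small?", "Are nodes uninvolved?",
#'                      "Is there evidence of distant metastasis?")),
#'     connective = NA, affirms = c(TRUE, TRUE, FALSE)
#'   ),
#'   groupings = data.frame(
#'     stage = "I", req = I(list(c(T = "T1", N = "N0", M = "M0")))
#'   )
#' )
#' tab
#' @export
staging_table <- function(tumor_type, axes, classifications, groupings,
                          selectors = character()) {
  axes <- as_tibble(axes)
  classifications <- as_tibble(classifications)
  groupings <- as_tibble(groupings)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0) {
      abort(paste0(what, " is missing column(s): ", paste(miss, collapse = ", ")),
            class = "tnm_load_error")
    }
  }
  need(axes, c("axis", "rank"), "axes")
  need(classifications,
       c("axis", "code", "level", "sublevel", "parent", "criteria",
         "clauses", "connective", "affirms"),
       "classifications")
  need(groupings, c("stage", "req"), "groupings")

  if (!all(c("T", "N", "M") %in% axes$axis)) {
    abort("axes must include T, N and M", class = "tnm_load_error")
  }
  if (anyDuplicated(axes$axis)) {
    abort("axis codes must be unique", class = "tnm_load_error")
  }
  if (anyDuplicated(axes$rank)) {
    abort("axis ranks must be distinct (the extent-of-spread ordering is total)",
          class = "tnm_load_error")
  }
  if (!"name" %in% names(axes)) axes$name <- axes$axis
  axes <- axes |>
    mutate(axis = as.character(.data$axis), rank = as.integer(.data$rank)) |>
    arrange(.data$rank)

  classifications <- classifications |>
    mutate(
      axis = as.character(.data$axis),
      code = as.character(.data$code),
      level = as.numeric(.data$level),
      sublevel = as.character(.data$sublevel),
      parent = as.character(.data$parent),
      criteria = as.character(.data$criteria),
      connective = as.character(.data$connective),
      affirms = as.logical(.data$affirms)
    )
  if (!is.list(classifications$clauses)) {
    classifications$clauses <- as.list(classifications$clauses)
  }
  classifications$clauses <- lapply(classifications$clauses, as.character)

  # stage blocks must be contiguous so that block order can define prognosis
  stg <- as.character(groupings$stage)
  blocks <- rle(stg)$values
  if (anyDuplicated(blocks)) {
    abort(paste0("stage label(s) appear in non-contiguous blocks: ",
                 paste(unique(blocks[duplicated(blocks)]), collapse = ", ")),
          class = "tnm_load_error")
  }
  if (nrow(groupings) == 0) {
    abort("a staging table needs at least one grouping", class = "tnm_load_error")
  }
  req <- lapply(groupings$req, function(r) {
    r <- vapply(r, as.character, character(1))
    if (is.null(names(r)) || any(names(r) == "")) {
      abort("each grouping requirement must be a named vector keyed by axis",
            class = "tnm_load_error")
    }
    # one entry per declared axis, in axis-rank order
    miss <- setdiff(axes$axis, names(r))
    extra <- setdiff(names(r), axes$axis)
    if (length(miss) > 0 || length(extra) > 0) {
      abort(paste0("grouping requirement axes must match the declared axes; ",
                   if (length(miss)) paste0("missing: ", paste(miss, collapse = ", "), " ") else "",
                   if (length(extra)) paste0("undeclared: ", paste(extra, collapse = ", ")) else ""),
            class = "tnm_load_error")
    }
    r[axes$axis]
  })
  groupings <- tibble(
    gid = seq_len(nrow(groupings)),
    stage = stg,
    prognostic_order = match(stg, blocks),
    row = stats::ave(seq_along(stg), stg, FUN = seq_along),
    req = req
  )

  out <- structure(
    list(
      tumor_type = as.character(tumor_type),
      selectors = selectors,
      axes = axes,
      classifications = classifications,
      groupings = groupings
    ),
    class = "staging_table"
  )
  out$match <- build_match_matrices(out)
  out
}

# Precomputed grouping-vs-classification match relations, one row per
# grouping and one column per defined (axis, code). `any` is the full match
# relation used by selection ("yes" keeps matching rows); `explicit` marks
# rows whose explicit requirement is the code or one of its descendants
# (the rows an exclusion removes). Everything downstream of the polling
# cycle reads these instead of recomputing hierarchy walks.
build_match_matrices <- function(table) {
  cls <- table$classifications
  keys <- paste(cls$axis, cls$code, sep = "\r")
  anc <- lapply(seq_len(nrow(cls)), function(i)
    ancestors_of(table, cls$axis[i], cls$code[i]))
  names(anc) <- keys
  gids <- table$groupings$gid
  m_any <- matrix(FALSE, nrow = length(gids), ncol = length(keys),
                  dimnames = list(gids, keys))
  m_exp <- m_any
  m_exact <- m_any
  m_wild <- matrix(FALSE, nrow = length(gids), ncol = nrow(table$axes),
                   dimnames = list(gids, table$axes$axis))
  for (g in seq_along(gids)) {
    r <- table$groupings$req[[g]]
    m_wild[g, ] <- is.na(r[table$axes$axis])
    for (k in seq_along(keys)) {
      ax <- cls$axis[k]; cd <- cls$code[k]
      rv <- r[[ax]]
      if (is.na(rv)) {
        m_any[g, k] <- TRUE
      } else {
        rk <- paste(ax, rv, sep = "\r")
        desc <- !is.null(anc[[rk]]) && cd %in% anc[[rk]]  # cd ancestor of rv
        m_any[g, k] <- rv == cd || desc || rv %in% anc[[k]]
        m_exp[g, k] <- rv == cd || desc
        m_exact[g, k] <- rv == cd
      }
    }
  }
  list(any = m_any, explicit = m_exp, exact = m_exact, wild = m_wild,
       keys = keys, axis = cls$axis, code = cls$code)
}

#' @export
print.staging_table <- function(x, ...) {
  cat("<staging_table> ", x$tumor_type, "\n", sep = "")
  if (length(x$selectors) > 0) {
    cat("  selectors: ",
        paste(names(x$selectors), unname(x$selectors), sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  cat("  axes: ", paste(x$axes$axis, collapse = " > "),
      " (extent-of-spread order)\n", sep = "")
  cat("  ", nrow(x$classifications), " classifications, ",
      nrow(x$groupings), " groupings in ",
      length(unique(x$groupings$stage)), " stages: ",
      paste(unique(x$groupings$stage), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tabular views of a staging table
#'
#' `stage_groupings()` returns the stage array as a wide tibble (one row per
#' TNM grouping, one column per axis, wildcards shown as `"Any <axis>"`);
#' `classification_bank()` returns the classification vocabulary with
#' criteria and rendered question text.
#'
#' @param table A `staging_table`.
#' @return A tibble.
#' @examples
#' lung <- lung_staging_table()
#' stage_groupings(lung)
#' classification_bank(lung)
#' @export
stage_groupings <- function(table) {
  stopifnot(inherits(table, "staging_table"))
  wide <- do.call(rbind, lapply(table$groupings$req, function(r) {
    ifelse(is.na(r), paste("Any", names(r)), r)
  }))
  colnames(wide) <- table$axes$axis
  bind_cols(
    table$groupings |> select("gid", "stage", "prognostic_order", "row"),
    as_tibble(as.data.frame(wide, stringsAsFactors = FALSE))
  )
}

#' @rdname stage_groupings
#' @export
classification_bank <- function(table) {
  stopifnot(inherits(table, "staging_table"))
  table$classifications |>
    mutate(question = vapply(seq_len(n()), function(i) {
      render_question(.data$clauses[[i]], .data$connective[i])
    }, character(1))) |>
    select("axis", "code", "level", "sublevel", "parent", "criteria",
           "question", "affirms")
}

render_question <- function(clauses, connective) {
  if (length(clauses) <= 1) return(as.character(clauses)[1] %||% "")
  conn <- if (is.na(connective)) "OR" else connective
  paste(clauses, collapse = paste0(" ", conn, " "))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

# ---- vocabulary helpers ------------------------------------------------------

assert_axis <- function(table, axis) {
  if (!axis %in% table$axes$axis) {
    abort(paste0("unknown axis '", axis, "'"), class = "tnm_vocabulary_error")
  }
}

assert_code <- function(table, axis, code) {
  assert_axis(table, axis)
  ok <- table$classifications$axis == axis & table$classifications$code == code
  if (!any(ok)) {
    abort(paste0("unknown classification '", code, "' on axis ", axis),
          class = "tnm_vocabulary_error")
  }
  invisible(TRUE)
}

# full ancestor chain (parent, grandparent, ...) of a code on an axis
ancestors_of <- function(table, axis, code) {
  cls <- table$classifications
  out <- character(0)
  cur <- code
  repeat {
    i <- which(cls$axis == axis & cls$code == cur)
    if (length(i) == 0) break
    p <- cls$parent[i[1]]
    if (is.na(p) || p %in% out) break
    out <- c(out, p)
    cur <- p
  }
  out
}

is_ancestor <- function(table, axis, a, b) {
  # TRUE iff a is a strict ancestor (coarser version) of b
  a %in% ancestors_of(table, axis, b)
}

#' Does a TNM grouping match a classification on one axis?
#'
#' The elementary relation of the exclusionary algorithm: a grouping matches
#' a classification on an axis when its requirement on that axis is a
#' wildcard ("Any T" matches every T code), is the classification itself, or
#' is hierarchically compatible with it — the requirement is the
#' classification's parent (a row requiring T1 is satisfied by T1a) or the
#' classification is the requirement's parent (selecting T1 keeps rows
#' requiring T1a or T1b). Groupings that do not match a selected
#' classification are the ones the algorithm excludes.
#'
#' @param table A `staging_table`.
#' @param grouping Either a `gid` (integer id from `table$groupings`) or a
#'   named requirement vector as stored in the `req` list column.
#' @param axis Axis code.
#' @param code Classification code on that axis.
#' @return Logical scalar.
#' @examples
#' lung <- lung_staging_table()
#' g <- stage_groupings(lung)
#' iv <- g$gid[g$stage == "IV"][1]          # "IV  Any T  Any N  M1a"
#' grouping_matches(lung, iv, "T", "T3")    # wildcard: TRUE
#' @export
grouping_matches <- function(table, grouping, axis, code) {
  assert_code(table, axis, code)
  req <- if (is.numeric(grouping)) {
    table$groupings$req[[match(grouping, table$groupings$gid)]]
  } else {
    grouping
  }
  r <- req[[axis]]
  if (is.na(r)) return(TRUE)
  if (r == code) return(TRUE)
  is_ancestor(table, axis, r, code) || is_ancestor(table, axis, code, r)
}

# vectorised over the groupings of a table: logical per gid
matching_gids <- function(table, gids, axis, code) {
  unname(table$match$any[as.character(gids), paste(axis, code, sep = "\r")])
}

# gids whose EXPLICIT requirement on `axis` is `code` or a descendant of it
explicit_or_descendant <- function(table, gids, axis, code) {
  unname(table$match$explicit[as.character(gids),
                              paste(axis, code, sep = "\r")])
}

# concrete (childless) codes on an axis — used when a scenario must pick a
# concrete value under a wildcard requirement
leaf_codes <- function(table, axis) {
  cls <- table$classifications |> filter(.data$axis == !!axis)
  setdiff(cls$code, cls$parent[!is.na(cls$parent)])
}
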