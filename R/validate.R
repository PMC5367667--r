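#' Validate a staging table
#'
#' Checks the semantic invariants of a staging table and returns a tibble of
#' issues rather than raising: `severity == "error"` issues make the table
#' unusable (and block [read_staging_table()] unless `validate = FALSE`);
#' `severity == "lint"` issues flag authoring-style problems derived from
#' the question-design rules (itemise complex definitions, disambiguate
#' combined AND/OR conditions, minimise negative phrasing) and never block
#' loading.
#'
#' @section Checks:
#' Errors:
#' * `UNDEFINED_CLASSIFICATION` — a grouping requires a code that is not in
#'   the classification vocabulary.
#' * `UNDEFINED_PARENT`, `PARENT_NOT_COARSER` — a classification's parent is
#'   missing from its axis, or does not have strictly coarser granularity.
#' * `DUPLICATE_CLASSIFICATION` — the same (axis, code) defined twice.
#' * `LEVEL_ORDER` — two codes on one axis share (level, sublevel), so the
#'   within-axis ordering is not total.
#' * `DUPLICATE_GROUPING` — two identical requirement rows anywhere in the
#'   stage array.
#' * `MISSING_QUESTION` — a classification required by some grouping has no
#'   question clauses to prompt with.
#' * `EMPTY_TABLE` — no groupings at all.
#'
#' Lints:
#' * `NEGATIVE_POLARITY` — a question clause is negatively phrased
#'   (contains "no"/"not"/"cannot"/"never"/"none"); such definitions should
#'   be rewritten in the affirmative with the answer mapping inverted
#'   (`affirms: false`), as the bundled lung table does for M0.
#' * `MIXED_BOOLEAN` — a single clause embeds an uppercase ` OR ` / ` AND `
#'   connective, i.e. boolean structure that should have been decomposed
#'   into separate clauses joined by the question's connective.
#' * `OVERLAPPING_GROUPINGS` — two distinct groupings are compatible on
#'   every axis, so one concrete T/N/M combination could match both; the
#'   lookup oracle then takes the first in prognostic order.
#'
#' @param table A [staging_table].
#' @return A tibble with columns `severity`, `code`, `path`, `message`
#'   (zero rows for a fully clean table).
#' @examples
#' validate_staging_table(lung_staging_table())   # 0 issues
#' @export
validate_staging_table <- function(table) {
  stopifnot(inherits(table, "staging_table"))
  issues <- list()
  add <- function(severity, code, path, message) {
    issues[[length(issues) + 1]] <<- tibble(
      severity = severity, code = code, path = path, message = message)
  }
  cls <- table$classifications
  grp <- table$groupings

  # duplicate (axis, code)
  dup <- cls |> count(.data$axis, .data$code) |> filter(.data$n > 1)
  for (i in seq_len(nrow(dup))) {
    add("error", "DUPLICATE_CLASSIFICATION",
        paste0("classifications[", dup$axis[i], " ", dup$code[i], "]"),
        "classification defined more than once")
  }

  # parent integrity
  for (i in seq_len(nrow(cls))) {
    p <- cls$parent[i]
    if (is.na(p)) next
    j <- which(cls$axis == cls$axis[i] & cls$code == p)
    where <- paste0("classifications[", cls$axis[i], " ", cls$code[i], "]")
    if (length(j) == 0) {
      add("error", "UNDEFINED_PARENT", where,
          paste0("parent '", p, "' is undefined on axis ", cls$axis[i]))
    } else if (!is.na(cls$sublevel[j[1]]) ||
               cls$level[j[1]] > cls$level[i]) {
      add("error", "PARENT_NOT_COARSER", where,
          paste0("parent '", p, "' is not strictly coarser"))
    }
  }

  # total (level, sublevel) order within each axis
  lvl_dup <- cls |>
    count(.data$axis, .data$level, .data$sublevel) |>
    filter(.data$n > 1)
  for (i in seq_len(nrow(lvl_dup))) {
    add("error", "LEVEL_ORDER",
        paste0("classifications[axis ", lvl_dup$axis[i], "]"),
        paste0("level ", lvl_dup$level[i],
               if (!is.na(lvl_dup$sublevel[i]))
                 paste0(lvl_dup$sublevel[i]) else "",
               " assigned to more than one code; within-axis order must be total"))
  }

  if (nrow(grp) == 0) {
    add("error", "EMPTY_TABLE", "stages", "the table defines no groupings")
  }

  # grouping reference integrity + question coverage
  used <- unique(stats::na.omit(unlist(lapply(grp$req, function(r) {
    paste(names(r), r, sep = "\r")
  }))))
  used <- used[!grepl("\rNA$", used)]
  for (u in used) {
    parts <- strsplit(u, "\r", fixed = TRUE)[[1]]
    ax <- parts[1]; cd <- parts[2]
    if (is.na(cd)) next
    k <- which(cls$axis == ax & cls$code == cd)
    if (length(k) == 0) {
      add("error", "UNDEFINED_CLASSIFICATION",
          paste0("stages[requirement ", ax, "=", cd, "]"),
          paste0("grouping requires undefined classification '", cd,
                 "' on axis ", ax))
    } else if (length(cls$clauses[[k[1]]]) == 0 ||
               all(!nzchar(cls$clauses[[k[1]]]))) {
      add("error", "MISSING_QUESTION",
          paste0("classifications[", ax, " ", cd, "]"),
          "classification is used in a grouping but has no question clauses")
    }
  }

  # duplicate groupings (identical requirement rows anywhere)
  keys <- vapply(grp$req, function(r) {
    paste(ifelse(is.na(r), "*", r), collapse = "|")
  }, character(1))
  for (k in unique(keys[duplicated(keys)])) {
    at <- grp[keys == k, ]
    add("error", "DUPLICATE_GROUPING",
        paste0("stages[", paste(unique(at$stage), collapse = ","), "]"),
        paste0("identical grouping appears ", nrow(at), " times: ", k))
  }

  # question-phrasing lints
  for (i in seq_len(nrow(cls))) {
    where <- paste0("classifications[", cls$axis[i], " ", cls$code[i],
                    "].question")
    for (cl_txt in cls$clauses[[i]]) {
      if (grepl("(?i)\\b(no|not|cannot|never|none)\\b|n't", cl_txt, perl = TRUE)) {
        add("lint", "NEGATIVE_POLARITY", where,
            paste0("negatively phrased clause: \"", cl_txt,
                   "\"; rewrite in the affirmative and invert 'affirms'"))
      }
      if (grepl(" OR | AND ", cl_txt)) {
        add("lint", "MIXED_BOOLEAN", where,
            paste0("clause embeds an un-decomposed boolean connective: \"",
                   cl_txt, "\""))
      }
    }
  }

  # overlapping groupings: some concrete combination could match both rows
  if (nrow(grp) >= 2 &&
      !any(vapply(issues, function(x)
        x$code %in% c("UNDEFINED_CLASSIFICATION"), logical(1)))) {
    for (i in seq_len(nrow(grp) - 1)) {
      for (j in seq((i + 1), nrow(grp))) {
        ri <- grp$req[[i]]; rj <- grp$req[[j]]
        compatible <- all(vapply(names(ri), function(ax) {
          a <- ri[[ax]]; b <- rj[[ax]]
          if (is.na(a) || is.na(b) || a == b) return(TRUE)
          is_ancestor(table, ax, a, b) || is_ancestor(table, ax, b, a)
        }, logical(1)))
        if (compatible) {
          add("lint", "OVERLAPPING_GROUPINGS",
              paste0("stages[", grp$stage[i], " row ", grp$row[i], " vs ",
                     grp$stage[j], " row ", grp$row[j], "]"),
              "two groupings can match the same concrete combination; lookup takes the first in prognostic order")
        }
      }
    }
  }

  if (length(issues) == 0) {
    tibble(severity = character(), code = character(),
           path = character(), message = character())
  } else {
    bind_rows(issues)
  }
}
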