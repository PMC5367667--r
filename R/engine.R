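#' Start a staging session
#'
#' A session holds the mutable state of one staging exercise: the set of
#' still-viable TNM groupings (initially all of them), the ordered history of
#' prompts and answers (supporting undo/redo), and the stop mode. Sessions
#' are immutable values: [apply_answer()], [select_direct()], [undo_step()]
#' and [redo_step()] return a new session.
#'
#' @param table A [staging_table].
#' @param stop_mode When is the session finished? `"grouping"` (default):
#'   when exactly one TNM grouping survives. `"stage"`: as soon as all
#'   surviving groupings share one stage label, even if several rows remain
#'   (the interactive flow then offers completion to a single grouping).
#' @param rank_policy How classifications are ranked for prompting.
#'   `"frequency-first"` (default): ascending frequency in the surviving
#'   groupings, ties broken by extent of spread (M before N before T), then
#'   by descending level and sublevel. `"axis-first"`: extent of spread is
#'   the primary key and frequency breaks ties — the alternative reading of
#'   the prioritisation rule, kept as a switch.
#' @return An object of class `tnm_session`.
#' @examples
#' s <- staging_session(lung_staging_table())
#' next_prompt(s)
#' @export
staging_session <- function(table,
                            stop_mode = c("grouping", "stage"),
                            rank_policy = c("frequency-first", "axis-first")) {
  stopifnot(inherits(table, "staging_table"))
  structure(
    list(
      table = table,
      candidates = table$groupings$gid,
      asked = character(0),        # "axis\rcode" keys already prompted/selected
      history = list(),
      undone = list(),
      stop_mode = match.arg(stop_mode),
      rank_policy = match.arg(rank_policy)
    ),
    class = "tnm_session"
  )
}

#' @export
print.tnm_session <- function(x, ...) {
  cat("<tnm_session> ", x$table$tumor_type,
      " | ", length(x$candidates), "/", nrow(x$table$groupings),
      " groupings viable | ", length(x$history), " step(s) | stop mode: ",
      x$stop_mode, "\n", sep = "")
  stg <- x$table$groupings$stage[match(x$candidates, x$table$groupings$gid)]
  cat("  surviving stages: ", paste(unique(stg), collapse = ", "), "\n", sep = "")
  invisible(x)
}

candidate_stages <- function(session) {
  session$table$groupings$stage[
    match(session$candidates, session$table$groupings$gid)]
}

ask_key <- function(axis, code) paste(axis, code, sep = "\r")

#' Poll classification frequencies over the surviving groupings
#'
#' The first step of each cycle of the exclusionary algorithm: count, for
#' every classification, how many surviving TNM groupings explicitly require
#' it. Wildcard requirements ("Any T") contribute to no code's count; per
#' axis, the explicit counts plus the number of wildcard rows equal the
#' number of survivors.
#'
#' @param session A `tnm_session`.
#' @return A tibble with columns `axis`, `code`, `n` (one row per
#'   classification that is explicitly required by at least one survivor),
#'   with an attribute `wildcards`: a tibble of per-axis wildcard-row counts.
#' @examples
#' tabulate_frequencies(staging_session(lung_staging_table()))
#' @export
tabulate_frequencies <- function(session) {
  stopifnot(inherits(session, "tnm_session"))
  if (length(session$candidates) == 0) {
    abort("the candidate set is empty; the session is exhausted",
          class = "tnm_exhausted_error")
  }
  f <- freq_core(session)
  ord <- order(f$axis, f$code)
  freq <- tibble(axis = f$axis[ord], code = f$code[ord], n = f$n[ord])
  attr(freq, "wildcards") <- tibble(axis = f$wild_axis,
                                    n_wildcard = f$wild_n)
  freq
}

# plain-vector core of the poll, shared by the tibble surface and the
# per-prompt ranking loop
freq_core <- function(session) {
  tab <- session$table
  idx <- match(session$candidates, tab$groupings$gid)
  n <- colSums(tab$match$exact[idx, , drop = FALSE])
  keep <- n > 0
  nw <- colSums(tab$match$wild[idx, , drop = FALSE])
  list(axis = tab$match$axis[keep], code = tab$match$code[keep],
       n = as.integer(n[keep]), key = tab$match$keys[keep],
       wild_axis = names(nw)[nw > 0], wild_n = as.integer(nw[nw > 0]))
}

#' Rank classifications for prompting
#'
#' The second step of the cycle: sort the polled classifications into the
#' order in which they should be offered as yes/no prompts. Under the
#' default policy the primary key is ascending frequency — the rarest
#' classification is the most exclusionary question to ask — with ties
#' broken by extent of spread (M before N before T), then by level
#' (N3 before N2 before N1 before N0) and sublevel (M1b before M1a). Codes
#' that appear in no surviving grouping are not ranked; they remain
#' reachable through [select_direct()].
#'
#' @inheritParams tabulate_frequencies
#' @return A tibble ordered by rank with columns `axis`, `code`, `n`,
#'   `level`, `sublevel` and `eligible` (`FALSE` for codes a prompt could
#'   not use: already asked, or no answer to them would change the
#'   candidate set).
#' @examples
#' rank_classifications(staging_session(lung_staging_table()))
#' @export
rank_classifications <- function(session) {
  r <- rank_core(session)
  tibble(axis = r$axis, code = r$code, n = r$n, level = r$level,
         sublevel = r$sublevel, eligible = r$eligible)
}

rank_core <- function(session) {
  if (length(session$candidates) == 0) {
    abort("the candidate set is empty; the session is exhausted",
          class = "tnm_exhausted_error")
  }
  f <- freq_core(session)
  tab <- session$table
  cls <- tab$classifications
  i <- match(f$key, tab$match$keys)
  level <- cls$level[i]
  sublevel <- cls$sublevel[i]
  sub_ord <- ifelse(is.na(sublevel), 0L, match(sublevel, letters))
  axis_rank <- tab$axes$rank[match(f$axis, tab$axes$axis)]
  ord <- if (session$rank_policy == "axis-first") {
    order(axis_rank, f$n, -level, -sub_ord)
  } else {
    order(f$n, axis_rank, -level, -sub_ord)
  }
  out <- list(axis = f$axis[ord], code = f$code[ord], n = f$n[ord],
              level = level[ord], sublevel = sublevel[ord])
  out$eligible <- vapply(seq_along(out$axis), function(k) {
    prompt_eligible(session, out$axis[k], out$code[k])
  }, logical(1))
  out
}

# A code is worth prompting iff it has not been asked and at least one answer
# would strictly (and not totally) change the candidate set:
#  - "yes" removes every non-matching survivor, or
#  - "no" removes the survivors explicitly requiring the code (or a
#    descendant), provided that is a non-empty strict subset.
prompt_eligible <- function(session, axis, code) {
  if (ask_key(axis, code) %in% session$asked) return(FALSE)
  gids <- session$candidates
  m <- matching_gids(session$table, gids, axis, code)
  if (any(!m)) return(TRUE)
  ex <- explicit_or_descendant(session$table, gids, axis, code)
  any(ex) && !all(ex)
}

#' Next prompt of the exclusionary cycle
#'
#' The third step of the cycle: either the session has reached its stop
#' condition (all survivors share a stage in `"stage"` mode; a single
#' survivor in `"grouping"` mode) and a terminal marker is returned, or the
#' first-ranked eligible classification is offered as a yes/no prompt.
#' Classifications every survivor matches are never prompted — asking about
#' them could not narrow the set — and are folded into the final report by
#' [resolve_session()] instead. If survivors remain but no classification
#' can distinguish them (possible only when authored rows subsume one
#' another; the validator lints this as `OVERLAPPING_GROUPINGS`), the
#' session is also terminal and resolution falls back to prognostic order.
#'
#' @inheritParams tabulate_frequencies
#' @return A `tnm_prompt` (fields `axis`, `code`, `prompt_text`, `clauses`,
#'   `connective`, `affirms`, `criteria`, `rank_trace`) or a `tnm_terminal`
#'   (fields `stage`, `n_candidates`, `reason`).
#' @examples
#' p <- next_prompt(staging_session(lung_staging_table()))
#' p$code          # "M1b": distant metastasis is asked about first
#' @export
next_prompt <- function(session) {
  stopifnot(inherits(session, "tnm_session"))
  if (length(session$candidates) == 0) {
    abort("the candidate set is empty; the session is exhausted",
          class = "tnm_exhausted_error")
  }
  stages <- candidate_stages(session)
  stopped <-
    (session$stop_mode == "grouping" && length(session$candidates) == 1) ||
    (session$stop_mode == "stage" && length(unique(stages)) == 1)
  if (stopped) {
    return(terminal_marker(session, reason = "stop-condition"))
  }
  ranked <- rank_core(session)
  hit <- which(ranked$eligible)
  if (length(hit) == 0) {
    return(terminal_marker(session, reason = "indistinguishable"))
  }
  i <- hit[1]
  cls <- session$table$classifications
  k <- which(cls$axis == ranked$axis[i] & cls$code == ranked$code[i])[1]
  structure(
    list(
      axis = ranked$axis[i],
      code = ranked$code[i],
      clauses = cls$clauses[[k]],
      connective = cls$connective[k],
      affirms = cls$affirms[k],
      criteria = cls$criteria[k],
      prompt_text = render_question(cls$clauses[[k]], cls$connective[k]),
      rank_trace = tibble(axis = ranked$axis, code = ranked$code,
                          n = ranked$n, level = ranked$level,
                          sublevel = ranked$sublevel,
                          eligible = ranked$eligible)
    ),
    class = "tnm_prompt"
  )
}

terminal_marker <- function(session, reason) {
  stages <- unique(candidate_stages(session))
  structure(
    list(
      stage = if (length(stages) == 1) stages else
        candidate_stages(session)[which.min(session$candidates)],
      stages = stages,
      n_candidates = length(session$candidates),
      reason = reason
    ),
    class = "tnm_terminal"
  )
}

#' @export
print.tnm_prompt <- function(x, ...) {
  cat("<tnm_prompt> ", x$axis, " ", x$code, "\n  ", sep = "")
  cat(paste(x$clauses, collapse = paste0("\n  ",
        if (is.na(x$connective)) "OR" else x$connective, " ")), "\n", sep = "")
  if (!x$affirms) {
    cat("  (a 'yes' answer excludes ", x$code, ")\n", sep = "")
  }
  invisible(x)
}

#' @export
print.tnm_terminal <- function(x, ...) {
  cat("<tnm_terminal> stage ", x$stage, " (", x$n_candidates,
      " grouping(s), ", x$reason, ")\n", sep = "")
  invisible(x)
}

#' Is a prompt object terminal?
#'
#' @param x Result of [next_prompt()].
#' @return Logical scalar.
#' @export
is_terminal <- function(x) inherits(x, "tnm_terminal")

#' Answer a prompt: select or exclude a classification
#'
#' The fourth step of the cycle. `answer = "yes"` *selects* the
#' classification: every surviving grouping that does not include it on its
#' axis is excluded (wildcard rows match everything and always survive;
#' hierarchy is respected, so selecting T1 keeps rows requiring T1, T1a or
#' T1b, and selecting T1a keeps rows requiring T1a or the bare T1).
#' `answer = "no"` *excludes* it: every surviving grouping whose explicit
#' requirement is that classification or one of its descendants is removed.
#' The answer is semantic — "yes" always means the classification applies to
#' the case, regardless of how the question text is phrased; front ends map
#' a literal reply through the question's `affirms` flag (see
#' [staging_session()] and the vignette).
#'
#' An answer that would empty the candidate set is rejected with an
#' `tnm_inconsistent_error` carrying the offending step; the session value
#' is unchanged, so the last consistent state is retained.
#'
#' @param session A `tnm_session`.
#' @param axis Axis code of the answered classification.
#' @param code Classification code.
#' @param answer `"yes"` or `"no"`.
#' @return A new `tnm_session` with the answer appended to its history.
#' @examples
#' s <- staging_session(lung_staging_table())
#' s <- apply_answer(s, "M", "M1b", "yes")
#' resolve_session(s)$stage     # "IV"
#' @export
apply_answer <- function(session, axis, code, answer = c("yes", "no")) {
  record_answer(session, axis, code, match.arg(answer), kind = "prompt")
}

#' Directly select a known classification
#'
#' If a classification is already known at the point of entry it can be
#' selected directly without waiting for it to be prompted; the effect on
#' the candidate set is identical to answering "yes" to its prompt, and the
#' step is recorded in the history as a direct selection.
#'
#' @inheritParams apply_answer
#' @return A new `tnm_session`.
#' @examples
#' s <- select_direct(staging_session(lung_staging_table()), "T", "T3")
#' length(s$candidates)   # 6: four explicit T3 rows plus the two Any-T rows
#' @export
select_direct <- function(session, axis, code) {
  record_answer(session, axis, code, "yes", kind = "direct")
}

record_answer <- function(session, axis, code, answer, kind) {
  stopifnot(inherits(session, "tnm_session"))
  assert_code(session$table, axis, code)
  if (length(session$candidates) == 0) {
    abort("the candidate set is empty; the session is exhausted",
          class = "tnm_exhausted_error")
  }
  gids <- session$candidates
  keep <- if (answer == "yes") {
    gids[matching_gids(session$table, gids, axis, code)]
  } else {
    gids[!explicit_or_descendant(session$table, gids, axis, code)]
  }
  if (length(keep) == 0) {
    abort(
      paste0("answering '", answer, "' to ", axis, " ", code,
             " is inconsistent with the previous answers: it would leave no ",
             "viable TNM grouping"),
      class = "tnm_inconsistent_error",
      step = list(kind = kind, axis = axis, code = code, answer = answer,
                  n_before = length(gids))
    )
  }
  step <- list(
    kind = kind, axis = axis, code = code, answer = answer,
    pre_candidates = gids, post_candidates = keep,
    pre_asked = session$asked,
    post_asked = union(session$asked, ask_key(axis, code))
  )
  session$candidates <- keep
  session$asked <- step$post_asked
  session$history <- c(session$history, list(step))
  session$undone <- list()
  session
}

#' Step backward / forward through the session history
#'
#' `undo_step()` restores the candidate set (and pending prompt) to the
#' state before the most recent answer; `redo_step()` re-applies the most
#' recently undone answer. Taking a new answer after an undo discards the
#' redo trail. Undoing a fresh session (or redoing with nothing undone) is
#' a no-op signalled with a warning of class `tnm_undo_noop`.
#'
#' @param session A `tnm_session`.
#' @return A `tnm_session`.
#' @examples
#' s0 <- staging_session(lung_staging_table())
#' s1 <- apply_answer(s0, "M", "M1b", "no")
#' identical(undo_step(s1)$candidates, s0$candidates)   # TRUE
#' @export
undo_step <- function(session) {
  stopifnot(inherits(session, "tnm_session"))
  if (length(session$history) == 0) {
    warn("nothing to undo: the session has no answered steps",
         class = "tnm_undo_noop")
    return(session)
  }
  step <- session$history[[length(session$history)]]
  session$history <- session$history[-length(session$history)]
  session$undone <- c(list(step), session$undone)
  session$candidates <- step$pre_candidates
  session$asked <- step$pre_asked
  session
}

#' @rdname undo_step
#' @export
redo_step <- function(session) {
  stopifnot(inherits(session, "tnm_session"))
  if (length(session$undone) == 0) {
    warn("nothing to redo", class = "tnm_undo_noop")
    return(session)
  }
  step <- session$undone[[1]]
  session$undone <- session$undone[-1]
  session$candidates <- step$post_candidates
  session$asked <- step$post_asked
  session$history <- c(session$history, list(step))
  session
}

#' Replay a session's history from scratch
#'
#' Re-applies the recorded answers to a fresh session on the same table.
#' Used to verify the history invariant (replay reproduces the candidate
#' set exactly) and by front ends to reconstruct state.
#'
#' @param session A `tnm_session`.
#' @return A `tnm_session` rebuilt by replay.
#' @export
replay_session <- function(session) {
  out <- staging_session(session$table, stop_mode = session$stop_mode,
                         rank_policy = session$rank_policy)
  for (step in session$history) {
    out <- record_answer(out, step$axis, step$code, step$answer, step$kind)
  }
  out
}

#' Resolve a finished session into a staging report
#'
#' The terminal display of a staging exercise: the assigned anatomic stage,
#' the resolved classification on each axis with its criteria text, and the
#' trail of answers that led there. Callable once the session's stop
#' condition holds (see [staging_session()]); calling it earlier raises a
#' `tnm_not_resolved_error`.
#'
#' Per-axis resolution: if the surviving groupings carry explicit
#' requirements on an axis, those are reported (a single code in
#' grouping-resolved mode; possibly alternatives in stage-resolved mode).
#' If only wildcard requirements survive on an axis, the code the user
#' selected on that axis is reported, or `"any"` when the axis was never
#' constrained — stage IV lung disease is stage IV whatever the T and N.
#'
#' @param session A `tnm_session`.
#' @return A `staging_report`: list with `stage`, `ambiguous`,
#'   `resolution` (tibble: `axis`, `codes` list column, `source`
#'   explicit/selected/any, `criteria` list column) and `trail` (tibble of
#'   the answered steps).
#' @examples
#' s <- staging_session(lung_staging_table())
#' s <- apply_answer(s, "M", "M1b", "yes")
#' resolve_session(s)
#' @export
resolve_session <- function(session) {
  stopifnot(inherits(session, "tnm_session"))
  term <- next_prompt(session)
  if (!is_terminal(term)) {
    abort(paste0("the session is not resolved yet: ",
                 length(session$candidates),
                 " groupings spanning stage(s) ",
                 paste(unique(candidate_stages(session)), collapse = ", "),
                 " remain"),
          class = "tnm_not_resolved_error")
  }
  table <- session$table
  ambiguous <- length(term$stages) > 1
  stage <- term$stage
  # survivors contributing to the report: in the ambiguous (subsumed-rows)
  # case, the first grouping in prognostic order — the same tie-break the
  # lookup oracle uses
  surv <- if (session$stop_mode == "grouping" && length(session$candidates) > 1) {
    if (ambiguous) min(session$candidates) else session$candidates
  } else if (ambiguous) {
    gids <- session$candidates
    gids[candidate_stages(session) == stage]
  } else {
    session$candidates
  }
  if (session$stop_mode == "grouping" && length(surv) > 1 &&
      term$reason == "indistinguishable") {
    surv <- min(surv)
  }
  req <- table$groupings$req[match(surv, table$groupings$gid)]

  yes_on <- function(ax) {
    for (step in rev(session$history)) {
      if (step$axis == ax && step$answer == "yes") return(step$code)
    }
    NA_character_
  }
  resolution <- purrr::map_dfr(table$axes$axis, function(ax) {
    explicit <- unique(stats::na.omit(
      vapply(req, function(r) r[[ax]], character(1))))
    if (length(explicit) > 0) {
      codes <- explicit; source <- "explicit"
    } else {
      sel <- yes_on(ax)
      if (!is.na(sel)) {
        codes <- sel; source <- "selected"
      } else {
        codes <- character(0); source <- "any"
      }
    }
    crit <- vapply(codes, function(cd) {
      k <- which(table$classifications$axis == ax &
                   table$classifications$code == cd)
      table$classifications$criteria[k[1]]
    }, character(1))
    tibble(axis = ax, codes = list(codes), source = source,
           criteria = list(unname(crit)))
  })
  trail <- if (length(session$history) == 0) {
    tibble(step = integer(), kind = character(), axis = character(),
           code = character(), answer = character(),
           n_before = integer(), n_after = integer())
  } else {
    purrr::imap_dfr(session$history, function(s, i) {
      tibble(step = i, kind = s$kind, axis = s$axis, code = s$code,
             answer = s$answer, n_before = length(s$pre_candidates),
             n_after = length(s$post_candidates))
    })
  }
  structure(
    list(stage = stage, ambiguous = ambiguous,
         n_groupings = length(surv),
         stop_mode = session$stop_mode,
         resolution = resolution, trail = trail),
    class = "staging_report"
  )
}

#' @export
print.staging_report <- function(x, ...) {
  cat("== Staging report ==\n")
  cat("Anatomic stage: ", x$stage,
      if (x$ambiguous) "  (ambiguous between overlapping groupings)" else "",
      "\n", sep = "")
  for (i in seq_len(nrow(x$resolution))) {
    codes <- x$resolution$codes[[i]]
    lbl <- if (length(codes) == 0) {
      paste0("any ", x$resolution$axis[i])
    } else {
      paste(codes, collapse = " / ")
    }
    cat("  ", x$resolution$axis[i], ": ", lbl, sep = "")
    crit <- x$resolution$criteria[[i]]
    if (length(crit) == 1) cat("  — ", crit, sep = "")
    cat("\n")
  }
  if (nrow(x$trail) > 0) {
    cat("Answer trail:\n")
    for (i in seq_len(nrow(x$trail))) {
      cat(sprintf("  %d. [%s] %s %s -> %s (%d -> %d groupings)\n",
                  x$trail$step[i], x$trail$kind[i], x$trail$axis[i],
                  x$trail$code[i], x$trail$answer[i],
                  x$trail$n_before[i], x$trail$n_after[i]))
    }
  }
  invisible(x)
}
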