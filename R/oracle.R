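#' Stage lookup by exhaustive scan
#'
#' The conventional combinatorial approach, kept as an independent reference:
#' given one concrete classification per axis, scan the stage array in
#' prognostic order and return the stage of the first grouping every axis
#' matches. The exclusionary engine is tested against this oracle; it never
#' shares code with the prompting cycle.
#'
#' @param table A [staging_table].
#' @param codes Named character vector, one concrete classification per axis
#'   (e.g. `c(T = "T2b", N = "N1", M = "M0")`).
#' @return The stage label, or `NA_character_` if no grouping matches (an
#'   unstageable combination); the `NA` case also signals a condition of
#'   class `tnm_unstageable`.
#' @examples
#' lung <- lung_staging_table()
#' lookup_stage(lung, c(T = "T2b", N = "N1", M = "M0"))   # "IIB"
#' lookup_stage(lung, c(T = "T4", N = "N3", M = "M1a"))   # "IV"
#' @export
lookup_stage <- function(table, codes) {
  stopifnot(inherits(table, "staging_table"))
  for (ax in table$axes$axis) {
    if (!ax %in% names(codes)) {
      abort(paste0("codes must name every axis; missing ", ax),
            class = "tnm_vocabulary_error")
    }
    assert_code(table, ax, codes[[ax]])
  }
  for (i in seq_len(nrow(table$groupings))) {
    ok <- all(vapply(table$axes$axis, function(ax) {
      grouping_matches(table, table$groupings$req[[i]], ax, codes[[ax]])
    }, logical(1)))
    if (ok) return(table$groupings$stage[i])
  }
  rlang::signal("no grouping matches this combination of classifications",
                class = "tnm_unstageable")
  NA_character_
}

#' Build truthful-responder scenarios from a staging table
#'
#' One scenario per TNM grouping: the grouping's explicit requirements give
#' the true concrete classification on each axis, and wildcard requirements
#' are filled with a concrete (childless) code drawn from the axis
#' vocabulary under the given seed. Scenarios whose concrete combination
#' matches no grouping are impossible by construction here (each scenario
#' matches at least its source grouping).
#'
#' @param table A [staging_table].
#' @param seed Integer seed for the wildcard draws.
#' @return A tibble with columns `gid`, `stage` (the source grouping) and
#'   `truth` (list column of named code vectors).
#' @export
truthful_scenarios <- function(table, seed = 1L) {
  stopifnot(inherits(table, "staging_table"))
  withr::with_seed(as.integer(seed), {
    purrr::map_dfr(seq_len(nrow(table$groupings)), function(i) {
      req <- table$groupings$req[[i]]
      truth <- vapply(names(req), function(ax) {
        if (!is.na(req[[ax]])) return(req[[ax]])
        pool <- leaf_codes(table, ax)
        pool[sample.int(length(pool), 1)]
      }, character(1))
      tibble(gid = table$groupings$gid[i],
             stage = table$groupings$stage[i],
             truth = list(truth))
    })
  })
}

# Would a truthful responder say the prompted code applies to this case?
# Yes iff the code is the true classification on its axis, or a coarser
# ancestor of it (a T1a tumor is also a T1 tumor).
truth_applies <- function(table, axis, code, truth) {
  t <- truth[[axis]]
  code == t || is_ancestor(table, axis, code, t)
}

#' Run one truthful-responder session
#'
#' Drives the exclusionary engine end-to-end for a fixed true case: every
#' prompt is answered "yes" exactly when the prompted classification applies
#' to the case (equals the true code on its axis or is an ancestor of it).
#' Used to verify that the engine reaches the same stage as [lookup_stage()]
#' and to measure how many questions staging takes.
#'
#' @param table A [staging_table].
#' @param truth Named character vector: the true concrete classification per
#'   axis.
#' @param stop_mode,rank_policy Passed to [staging_session()].
#' @return A list: `report` ([resolve_session()] output), `transcript`
#'   (tibble of prompts and answers with candidate counts), `n_prompts`,
#'   and `stage`.
#' @examples
#' lung <- lung_staging_table()
#' run_truthful_session(lung, c(T = "T1a", N = "N0", M = "M0"))$stage  # "IA"
#' @export
run_truthful_session <- function(table, truth,
                                 stop_mode = c("grouping", "stage"),
                                 rank_policy = c("frequency-first", "axis-first")) {
  stop_mode <- match.arg(stop_mode)
  rank_policy <- match.arg(rank_policy)
  s <- staging_session(table, stop_mode = stop_mode, rank_policy = rank_policy)
  axis <- code <- question <- answer <- character(0)
  n_before <- n_after <- integer(0)
  limit <- nrow(table$classifications) + 1L
  for (i in seq_len(limit)) {
    p <- next_prompt(s)
    if (is_terminal(p)) break
    ans <- if (truth_applies(table, p$axis, p$code, truth)) "yes" else "no"
    nb <- length(s$candidates)
    s <- apply_answer(s, p$axis, p$code, ans)
    axis <- c(axis, p$axis); code <- c(code, p$code)
    question <- c(question, p$prompt_text); answer <- c(answer, ans)
    n_before <- c(n_before, nb); n_after <- c(n_after, length(s$candidates))
  }
  report <- resolve_session(s)
  transcript <- tibble(
    prompt = seq_along(axis), axis = axis, code = code,
    question = question, answer = answer,
    n_before = n_before, n_after = n_after)
  list(report = report, transcript = transcript,
       n_prompts = nrow(transcript), stage = report$stage)
}

#' Prompt-count statistics over all truthful scenarios
#'
#' Runs a truthful-responder session for every grouping of the table and
#' summarises how many prompted questions each took, against the naive
#' baseline of reviewing every distinct explicit classification in the
#' stage array criterion by criterion. The exclusionary approach earns its
#' keep when the mean prompt count sits well below that baseline.
#'
#' @param table A [staging_table].
#' @param stop_mode Stop mode for the sessions (see [staging_session()]).
#' @param seed Seed for the wildcard draws in [truthful_scenarios()].
#' @param rank_policy Ranking policy (see [staging_session()]).
#' @return A `tnm_sim` object: list with `per_scenario` (tibble: `gid`,
#'   `stage`, `truth`, `n_prompts`, `stage_engine`, `stage_lookup`,
#'   `agree`), `mean_prompts`, `max_prompts`, `baseline` (distinct explicit
#'   classification count), `agreement` (fraction of scenarios where engine
#'   and lookup stages coincide), `stop_mode` and `seed`.
#' @examples
#' question_count_stats(lung_staging_table())
#' @export
question_count_stats <- function(table, stop_mode = c("grouping", "stage"),
                                 seed = 1L,
                                 rank_policy = c("frequency-first", "axis-first")) {
  stop_mode <- match.arg(stop_mode)
  rank_policy <- match.arg(rank_policy)
  scen <- truthful_scenarios(table, seed = seed)
  per <- purrr::map_dfr(seq_len(nrow(scen)), function(i) {
    truth <- scen$truth[[i]]
    run <- run_truthful_session(table, truth, stop_mode = stop_mode,
                                rank_policy = rank_policy)
    ref <- suppressWarnings(lookup_stage(table, truth))
    tibble(gid = scen$gid[i], stage = scen$stage[i], truth = list(truth),
           n_prompts = run$n_prompts, stage_engine = run$stage,
           stage_lookup = ref, agree = identical(run$stage, ref))
  })
  structure(
    list(per_scenario = per,
         mean_prompts = mean(per$n_prompts),
         max_prompts = max(per$n_prompts),
         baseline = n_distinct_explicit(table),
         agreement = mean(per$agree),
         stop_mode = stop_mode,
         rank_policy = rank_policy,
         seed = as.integer(seed)),
    class = "tnm_sim"
  )
}

# number of distinct explicit classifications listed anywhere in the stage
# array — the naive criterion-by-criterion review burden
n_distinct_explicit <- function(table) {
  codes <- unlist(lapply(table$groupings$req, function(r) {
    paste(names(r), r, sep = "\r")
  }))
  codes <- codes[!grepl("\rNA$", codes)]
  length(unique(codes))
}

#' @export
print.tnm_sim <- function(x, ...) {
  cat("<tnm_sim> ", nrow(x$per_scenario), " truthful scenarios (",
      x$stop_mode, "-resolved, ", x$rank_policy, ")\n", sep = "")
  cat(sprintf("  prompts per session: mean %.2f, max %d\n",
              x$mean_prompts, x$max_prompts))
  cat("  naive review baseline: ", x$baseline,
      " distinct explicit classifications\n", sep = "")
  cat(sprintf("  engine vs lookup agreement: %.0f%%\n", 100 * x$agreement))
  invisible(x)
}

#' Generate a random small staging table
#'
#' Property-testing workhorse: builds a structurally valid staging table
#' with T/N/M axes, a seeded number of levels per axis (no hierarchy or
#' sublevels — those are exercised by the bundled lung table), a seeded
#' number of stages, and random distinct groupings in which each requirement
#' is a wildcard with probability `wildcard_prob`. Every generated
#' classification carries a trivially phrased question, so the tables load,
#' validate (possibly with `OVERLAPPING_GROUPINGS` lints) and run.
#'
#' @param seed Integer seed; the table is a deterministic function of it.
#' @param max_stages Maximum number of stages (at least 1 is generated).
#' @param max_levels Maximum classification levels per axis (level 0 up to
#'   `max_levels - 1`).
#' @param wildcard_prob Probability that any one requirement is a wildcard.
#' @return A [staging_table].
#' @examples
#' random_staging_table(42)
#' @export
random_staging_table <- function(seed, max_stages = 4L, max_levels = 3L,
                                 wildcard_prob = 0.15) {
  withr::with_seed(as.integer(seed), {
    n_levels <- stats::setNames(
      sample.int(max_levels, 3, replace = TRUE), c("T", "N", "M"))
    classifications <- purrr::map_dfr(c("T", "N", "M"), function(ax) {
      lv <- seq_len(n_levels[[ax]]) - 1L
      tibble(
        axis = ax, code = paste0(ax, lv), level = as.numeric(lv),
        sublevel = NA_character_, parent = NA_character_,
        criteria = paste0("synthetic criterion for ", ax, lv),
        clauses = lapply(lv, function(l)
          paste0("Does classification ", ax, l, " apply?")),
        connective = NA_character_, affirms = TRUE
      )
    })
    n_stages <- sample.int(max_stages, 1)
    # distinct requirement rows, at least one per stage
    combos <- expand.grid(
      T = c(paste0("T", seq_len(n_levels[["T"]]) - 1L), NA),
      N = c(paste0("N", seq_len(n_levels[["N"]]) - 1L), NA),
      M = c(paste0("M", seq_len(n_levels[["M"]]) - 1L), NA),
      stringsAsFactors = FALSE)
    # bias towards explicit rows: keep wildcard rows with wildcard_prob weight
    w <- apply(combos, 1, function(r) {
      k <- sum(is.na(r))
      wildcard_prob^k * (1 - wildcard_prob)^(3 - k)
    })
    n_rows <- min(nrow(combos), n_stages + sample.int(2 * n_stages, 1))
    pick <- sample.int(nrow(combos), n_rows, prob = w)
    stage_of <- sort(c(seq_len(n_stages),
                       sample.int(n_stages, n_rows - n_stages, replace = TRUE)))
    groupings <- tibble(
      stage = paste0("S", stage_of),
      req = lapply(pick, function(i) {
        r <- unlist(combos[i, , drop = TRUE])
        stats::setNames(as.character(r), c("T", "N", "M"))
      })
    )
    staging_table(
      tumor_type = paste0("synthetic-", seed),
      axes = tibble(axis = c("T", "N", "M"), rank = c(3L, 2L, 1L)),
      classifications = classifications,
      groupings = groupings
    )
  })
}
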