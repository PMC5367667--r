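#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a staging session into its answer history
#'
#' One row per answered step, in order: the kind of step (prompted answer or
#' direct selection), the classification, the semantic answer, and the
#' candidate-set sizes before and after.
#'
#' @param x A `tnm_session`.
#' @param ... Unused.
#' @return A tibble with columns `step`, `kind`, `axis`, `code`, `answer`,
#'   `n_before`, `n_after`.
#' @export
tidy.tnm_session <- function(x, ...) {
  if (length(x$history) == 0) {
    return(tibble(step = integer(), kind = character(), axis = character(),
                  code = character(), answer = character(),
                  n_before = integer(), n_after = integer()))
  }
  purrr::imap_dfr(x$history, function(s, i) {
    tibble(step = i, kind = s$kind, axis = s$axis, code = s$code,
           answer = s$answer, n_before = length(s$pre_candidates),
           n_after = length(s$post_candidates))
  })
}

#' One-row summary of a staging session
#'
#' @param x A `tnm_session`.
#' @param ... Unused.
#' @return A one-row tibble: `tumor_type`, `n_candidates`, `n_total`,
#'   `n_steps`, `stop_mode`, `stopped`, `stage` (the resolved stage label,
#'   or `NA` while unresolved).
#' @export
glance.tnm_session <- function(x, ...) {
  term <- next_prompt(x)
  stopped <- is_terminal(term)
  tibble(
    tumor_type = x$table$tumor_type,
    n_candidates = length(x$candidates),
    n_total = nrow(x$table$groupings),
    n_steps = length(x$history),
    stop_mode = x$stop_mode,
    stopped = stopped,
    stage = if (stopped) term$stage else NA_character_
  )
}

#' Tidy a staging report into its per-axis resolution
#'
#' @param x A `staging_report`.
#' @param ... Unused.
#' @return A tibble with one row per (axis, resolved code): columns `axis`,
#'   `code` (`NA` for an unconstrained wildcard axis), `source`
#'   (explicit/selected/any) and `criteria`.
#' @export
tidy.staging_report <- function(x, ...) {
  purrr::map_dfr(seq_len(nrow(x$resolution)), function(i) {
    codes <- x$resolution$codes[[i]]
    if (length(codes) == 0) {
      tibble(axis = x$resolution$axis[i], code = NA_character_,
             source = x$resolution$source[i], criteria = NA_character_)
    } else {
      tibble(axis = x$resolution$axis[i], code = codes,
             source = x$resolution$source[i],
             criteria = x$resolution$criteria[[i]])
    }
  })
}

#' Tidy / summarise a prompt-count simulation
#'
#' `tidy()` returns the per-scenario prompt counts; `glance()` the one-row
#' summary with the naive-review baseline.
#'
#' @param x A `tnm_sim` from [question_count_stats()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.tnm_sim <- function(x, ...) {
  x$per_scenario |>
    mutate(truth = vapply(.data$truth, paste, character(1), collapse = " ")) |>
    select("gid", "stage", "truth", "n_prompts", "stage_engine",
           "stage_lookup", "agree")
}

#' @rdname tidy.tnm_sim
#' @export
glance.tnm_sim <- function(x, ...) {
  tibble(
    n_scenarios = nrow(x$per_scenario),
    mean_prompts = x$mean_prompts,
    max_prompts = x$max_prompts,
    baseline = x$baseline,
    agreement = x$agreement,
    stop_mode = x$stop_mode,
    rank_policy = x$rank_policy,
    seed = x$seed
  )
}

#' Plot the classification frequency profile of a session
#'
#' Bar chart of how often each classification is required by the surviving
#' TNM groupings, faceted by axis — the poll the exclusionary algorithm
#' ranks on (rarest first).
#'
#' @param object A `tnm_session`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tnm_session <- function(object, ...) {
  freq <- tabulate_frequencies(object)
  ggplot2::ggplot(freq,
                  ggplot2::aes(x = stats::reorder(.data$code, .data$n),
                               y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(ggplot2::vars(.data$axis), scales = "free_y") +
    ggplot2::labs(
      x = NULL, y = "groupings explicitly requiring the classification",
      title = paste0("Classification frequencies (",
                     length(object$candidates), " viable groupings)"))
}

#' Plot prompt counts against the naive review baseline
#'
#' Histogram of per-scenario prompted-question counts from a truthful
#' simulation, with the naive criterion-by-criterion baseline (distinct
#' explicit classifications) marked.
#'
#' @param object A `tnm_sim`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tnm_sim <- function(object, ...) {
  ggplot2::ggplot(object$per_scenario,
                  ggplot2::aes(x = .data$n_prompts)) +
    ggplot2::geom_bar() +
    ggplot2::geom_vline(xintercept = object$baseline, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$mean_prompts, colour = "steelblue") +
    ggplot2::labs(
      x = "prompted questions per truthful session",
      y = "scenarios",
      title = "Questions needed by exclusion vs naive review",
      subtitle = sprintf("mean %.2f (solid), naive baseline %d (dashed)",
                         object$mean_prompts, object$baseline))
}

#' @export
ggplot2::autoplot
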