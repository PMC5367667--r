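test_that("polling counts explicit requirements, with wildcards set aside", {
  s <- staging_session(lung_tab())
  freq <- tabulate_frequencies(s)
  get <- function(ax, cd) freq$n[freq$axis == ax & freq$code == cd]
  expect_equal(get("M", "M1a"), 1L)
  expect_equal(get("M", "M1b"), 1L)
  expect_equal(get("T", "Tis"), 1L)
  expect_equal(get("M", "M0"), 26L)
  expect_equal(get("N", "N0"), 8L)
  expect_equal(get("T", "T1a"), 4L)

  # per axis: explicit counts + wildcard rows = candidate-set size
  wild <- attr(freq, "wildcards")
  for (ax in c("T", "N", "M")) {
    nw <- wild$n_wildcard[wild$axis == ax]
    expect_equal(sum(freq$n[freq$axis == ax]) + sum(nw), 28L, info = ax)
  }
})

test_that("ranking is ascending frequency with M>N>T and level tie-breaks", {
  lung <- lung_tab()
  r <- rank_classifications(staging_session(lung))
  # rarest first; among the count-1 ties the M axis wins and M1b outranks M1a
  expect_equal(r$code[1:2], c("M1b", "M1a"))
  expect_equal(r$axis[1], "M")
  expect_true(all(diff(r$n) >= 0))

  # among the stage IIIB rows, ascending count puts N2 (1 row) before N3 (6)
  s2 <- staging_session(lung)
  s2$candidates <- lung$groupings$gid[lung$groupings$stage == "IIIB"]
  r2 <- rank_classifications(s2)
  n_codes <- r2[r2$axis == "N", ]
  expect_equal(n_codes$code[1], "N2")
  expect_equal(n_codes$n[n_codes$code == "N2"], 1L)
  expect_equal(n_codes$n[n_codes$code == "N3"], 6L)

  # single surviving row: every explicit code ranked once, M first
  s3 <- staging_session(lung)
  s3$candidates <- lung$groupings$gid[lung$groupings$stage == "IB"]
  r3 <- rank_classifications(s3)
  expect_equal(nrow(r3), 3L)
  expect_equal(r3$axis[1], "M")
  expect_true(all(r3$n == 1L))

  # the alternative axis-first policy still leads with metastasis codes but
  # orders by axis before frequency
  r4 <- rank_classifications(
    staging_session(lung, rank_policy = "axis-first"))
  expect_equal(unique(r4$axis), c("M", "N", "T"))
})

test_that("prompting asks the first-ranked informative question and stops", {
  lung <- lung_tab()
  p <- next_prompt(staging_session(lung))
  expect_s3_class(p, "tnm_prompt")
  expect_equal(list(p$axis, p$code), list("M", "M1b"))
  expect_match(p$prompt_text, "distant metastasis", ignore.case = TRUE)

  # narrow to the two stage IA rows via hierarchy: select T1, then M0, N0
  base <- staging_session(lung, stop_mode = "stage")
  base <- apply_answer(base, "T", "T1", "yes")
  base <- apply_answer(base, "M", "M0", "yes")
  base <- apply_answer(base, "N", "N0", "yes")
  expect_equal(length(base$candidates), 2L)
  expect_equal(unique(stages_of(base)), "IA")
  term <- next_prompt(base)
  expect_true(is_terminal(term))
  expect_equal(term$stage, "IA")

  # same state, grouping-resolved: a T-axis prompt separates T1a from T1b
  g <- staging_session(lung, stop_mode = "grouping")
  g <- apply_answer(g, "T", "T1", "yes")
  g <- apply_answer(g, "M", "M0", "yes")
  g <- apply_answer(g, "N", "N0", "yes")
  pg <- next_prompt(g)
  expect_false(is_terminal(pg))
  expect_equal(pg$axis, "T")
  expect_true(pg$code %in% c("T1a", "T1b"))

  # universally-matched codes (here M0) are never prompted
  expect_false(any(pg$rank_trace$eligible[pg$rank_trace$code == "M0"]))
})

test_that("selection keeps matching groupings and exclusion removes them", {
  lung <- lung_tab()
  s <- staging_session(lung)

  yes <- apply_answer(s, "M", "M1b", "yes")
  expect_equal(length(yes$candidates), 1L)
  expect_equal(stages_of(yes), "IV")

  no <- apply_answer(s, "M", "M1b", "no")
  expect_equal(length(no$candidates), 27L)

  seqd <- apply_answer(no, "M", "M1a", "no")
  seqd <- apply_answer(seqd, "N", "N3", "yes")
  expect_equal(length(seqd$candidates), 6L)
  expect_equal(unique(stages_of(seqd)), "IIIB")

  # direct selection: T3 keeps the four explicit T3 rows and both Any-T rows
  d <- select_direct(s, "T", "T3")
  expect_equal(length(d$candidates), 6L)
  expect_equal(d$history[[1]]$kind, "direct")

  # excluding a parent removes its descendants' rows too
  noT1 <- apply_answer(s, "T", "T1", "no")
  g <- stage_groupings(lung)
  expect_equal(length(noT1$candidates),
               28L - sum(g$T %in% c("T1a", "T1b")))

  # an answer that would empty the set is rejected, session value unchanged
  one <- apply_answer(s, "M", "M1b", "yes")
  expect_error(apply_answer(one, "M", "M1b", "no"),
               class = "tnm_inconsistent_error")
  expect_equal(length(one$candidates), 1L)

  # direct selection incompatible with every survivor is inconsistent
  m0 <- apply_answer(s, "M", "M0", "yes")   # 26 rows, all explicitly M0
  expect_error(select_direct(m0, "M", "M1"),
               class = "tnm_inconsistent_error")
})

test_that("undo and redo walk the history without loss", {
  lung <- lung_tab()
  s0 <- staging_session(lung)

  s1 <- apply_answer(s0, "M", "M1b", "no")
  expect_equal(length(undo_step(s1)$candidates), 28L)
  expect_equal(undo_step(s1)$candidates, s0$candidates)

  # select then undo restores the original candidate set
  d <- select_direct(s0, "T", "T3")
  expect_equal(undo_step(d)$candidates, s0$candidates)

  # three answers, two undos, one redo -> state after the first two
  s <- apply_answer(s0, "M", "M1b", "no")
  s <- apply_answer(s, "M", "M1a", "no")
  two <- s
  s <- apply_answer(s, "N", "N3", "yes")
  s <- undo_step(undo_step(s))
  s <- redo_step(s)
  expect_equal(s$candidates, two$candidates)
  expect_equal(length(s$history), 2L)

  # a new answer clears the redo trail
  s <- undo_step(s)
  s <- apply_answer(s, "N", "N0", "yes")
  expect_warning(redo_step(s), class = "tnm_undo_noop")

  # undo on a fresh session is a signalled no-op
  expect_warning(out <- undo_step(s0), class = "tnm_undo_noop")
  expect_equal(out$candidates, s0$candidates)

  # replaying the recorded history reproduces the candidate set exactly
  s <- apply_answer(s0, "M", "M1b", "no")
  s <- apply_answer(s, "T", "T4", "yes")
  expect_equal(replay_session(s)$candidates, s$candidates)
})

test_that("resolution reports stage, per-axis classifications and the trail", {
  lung <- lung_tab()
  s <- staging_session(lung)

  expect_error(resolve_session(s), class = "tnm_not_resolved_error")

  # narrow to the single row IIB T2b N1 M0
  s1 <- apply_answer(s, "M", "M0", "yes")
  s1 <- apply_answer(s1, "N", "N1", "yes")
  s1 <- apply_answer(s1, "T", "T2b", "yes")
  rep1 <- resolve_session(s1)
  expect_equal(rep1$stage, "IIB")
  tr <- tidy(rep1)
  expect_equal(tr$code[match(c("T", "N", "M"), tr$axis)],
               c("T2b", "N1", "M0"))
  expect_equal(tr$criteria[tr$axis == "T"],
               "Tumor more than 5 cm but 7 cm or less in greatest dimension")
  expect_equal(nrow(rep1$trail), 3L)

  # both stage IV rows surviving, stage-resolved: M lists alternatives and
  # the wildcard axes are reported as unconstrained
  s2 <- staging_session(lung, stop_mode = "stage")
  s2 <- apply_answer(s2, "M", "M1", "yes")
  rep2 <- resolve_session(s2)
  expect_equal(rep2$stage, "IV")
  expect_setequal(rep2$resolution$codes[[which(rep2$resolution$axis == "M")]],
                  c("M1a", "M1b"))
  expect_equal(rep2$resolution$source[rep2$resolution$axis == "T"], "any")
  expect_equal(rep2$resolution$codes[[which(rep2$resolution$axis == "T")]],
               character(0))

  # wildcard axis with a direct selection on record reports the selection
  s3 <- staging_session(lung)
  s3 <- select_direct(s3, "T", "T2a")
  s3 <- apply_answer(s3, "M", "M1b", "yes")
  rep3 <- resolve_session(s3)
  expect_equal(rep3$stage, "IV")
  expect_equal(rep3$resolution$codes[[which(rep3$resolution$axis == "T")]],
               "T2a")
  expect_equal(rep3$resolution$source[rep3$resolution$axis == "T"],
               "selected")
})

test_that("exhausted and glance/tidy surfaces behave", {
  lung <- lung_tab()
  s <- staging_session(lung)
  s$candidates <- integer(0)
  expect_error(next_prompt(s), class = "tnm_exhausted_error")
  expect_error(tabulate_frequencies(s), class = "tnm_exhausted_error")

  s <- staging_session(lung)
  expect_equal(nrow(tidy(s)), 0L)
  g0 <- glance(s)
  expect_false(g0$stopped)
  s <- apply_answer(s, "M", "M1b", "yes")
  expect_equal(tidy(s)$n_after, 1L)
  g1 <- glance(s)
  expect_true(g1$stopped)
  expect_equal(g1$stage, "IV")
})
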