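---
title: "Methods: exclusionary TNM staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exclusionary TNM staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnmstager)
```

This vignette records the methodological choices behind the package: the
exclusion algorithm and its assumptions, the question-ranking and
prompt-eligibility rules, the polarity model for question authoring, and the
scope of the simulation machinery used to quantify the savings.

## Data model

A staging table has three parts, all stored as tibbles inside a
`staging_table` object:

* **Axes** — T, N, M with an *assessment rank* (M = 1, N = 2, T = 3). The
  rank encodes the clinical intuition that extent of distant spread is the
  cheapest discriminating information, nodal spread next, local tumor
  anatomy last; it is used only to break ties in question ranking.
* **Classifications** — codes with optional hierarchy (T1 is the parent of
  T1a and T1b; M1 of M1a and M1b) and numeric *levels* encoding coarse
  severity order within an axis. The bundled lung table uses
  TX = −1, T0 = 0, Tis = 1, T1 = 2, T2 = 3, T3 = 4, T4 = 5;
  NX = −1 and N0–N3 = 0–3; M0 = 0, M1 = 1, with sublevels `a`/`b` carried
  separately. The X codes ("cannot be assessed") are deliberately placed
  *below* 0 so that level-based tie-breaks prefer more informative codes.
  Each classification carries its diagnostic criteria and one or more
  yes/no question clauses.
* **Groupings** — rows mapping requirement triples to stage labels, in
  *prognostic order* (the order stages appear in the document, best to
  worst). A missing requirement is a wildcard: `Any T` matches every T
  code. Rows for one stage must form a contiguous block.

Tables round-trip through a JSON document format
(`read_staging_table()` / `write_staging_table()`); wildcards serialize as
`"*"`. Code spellings are normalized on load (`Tx` → `TX`, etc.) so that
case variants in source documents do not create spurious codes.

## The exclusion cycle

Given surviving groupings `G`:

1. **Poll.** `tabulate_frequencies()` counts, for each code, the rows in
   `G` that *explicitly* require it. Wildcards contribute to a separate
   per-axis wildcard count, not to any code.
2. **Rank.** `rank_classifications()` orders codes with count ≥ 1 by
   ascending count, then ascending axis rank (M < N < T), then descending
   level, then descending sublevel (`b` > `a` > no sublevel). Codes with
   count 0 are never asked: with no explicitly requiring row, a *no* removes
   nothing and a *yes* can only be decided through other codes' questions,
   so such a question cannot drive exclusion.
3. **Prompt.** `next_prompt()` walks the ranking and returns the first
   *eligible* code (below). *Yes* keeps rows whose requirement on that axis
   matches the code — exactly, as an ancestor of it, or as a wildcard.
   *No* removes rows explicitly requiring the code or a descendant.
4. **Stop.** With `stop_mode = "grouping"` (default) the session terminates
   when one row survives; with `"stage"`, as soon as all survivors share a
   stage label, which can only shorten sessions and never changes the
   reported stage for truthful answers.

Asking rare requirements first maximizes the information from a *yes*
(immediate near-identification) while a *no* is cheap; empirically on the
bundled lung table it also keeps the worst case low (12 questions vs the
15-classification naive review).

### Prompt eligibility and indistinguishable rows

A ranked code is skipped when neither answer can matter. Concretely, a code
is eligible iff at least one surviving row would *not* survive a yes, **or**
a no would remove a non-empty strict subset of `G`. Each code is asked at
most once per session.

Without the second clause a subtle failure appears with *subsumed rows*:
e.g. `{T1 N0 M0 → I, Any-T N0 M0 → II}`. Once T1 has been confirmed, both
rows match every consistent answer, no further question can separate them,
and a naive loop would either stall or ask useless questions forever. The
engine instead reaches a terminal state with reason `"indistinguishable"`
and resolves to the first surviving row in prognostic order. This is the
same tie-break the brute-force `lookup_stage()` oracle uses (first matching
row wins), so engine and oracle remain in exact agreement even on
overlapping tables — a property the test suite checks over hundreds of
random tables.

### Assumptions

* Answers are truthful and consistent with a single underlying (T, N, M).
  Contradictory batch answers raise a classed error identifying the step.
* One grouping applies to every case the table covers; combinations
  matching no row (e.g. Tis with nodal involvement in the lung table) are
  reported as unstageable by the oracle, and in a session surface as an
  inconsistency at the first impossible answer.
* The axis ranks reflect assessment cost order; if they do not, the
  alternative `rank_policy = "axis-first"` ranks by axis before frequency.

## Question polarity and authoring lints

Clinically natural phrasings are sometimes negative ("no distant
metastasis"), which invites double-negative confusion at the prompt. The
package separates two concerns:

* **Semantics.** Each question carries an `affirms` flag: `TRUE` means a
  literal *yes* asserts the classification applies. For M0 the bundled
  question is the affirmative "Is there evidence of distant metastasis?"
  with `affirms = FALSE`, so a literal *no* selects M0. The engine API
  (`apply_answer()`, `batch_stage()`) always takes *semantic* answers
  ("does the classification apply"); only the interactive CLI maps literal
  `y`/`n` through `affirms`.
* **Lints.** `validate_staging_table()` flags negatively phrased clause
  text (`NEGATIVE_POLARITY`: "no", "not", "cannot", "never", "none",
  "n't") and compound clauses (`MIXED_BOOLEAN`: a single clause containing
  ` OR ` / ` AND ` in uppercase — the package's authoring convention for
  marking an un-decomposed boolean, since prose "or" within one criterion
  is often harmless). Multi-clause questions with an explicit connective
  are the supported decomposition.

These are lints, not errors: tables carrying them still stage correctly;
they mark questions likely to be misanswered by humans.

## Simulation and the random-table generator

`truthful_scenarios()` derives one ground-truth triple per grouping,
filling wildcards with seeded concrete leaf codes.
`run_truthful_session()` answers each prompt from the ground truth (a code
applies if it equals the truth or is an ancestor of it) and
`question_count_stats()` aggregates prompt counts, comparing each session's
stage against `lookup_stage()`. The *baseline* is the number of distinct
explicit classifications in the table — the classifications a naive
front-to-back review would have to assess.

`random_staging_table(seed, max_stages, max_levels, wildcard_prob)`
generates small seeded tables for property testing: three axes, flat code
sets (no hierarchy, no sublevels, no multi-clause questions), distinct
requirement rows sampled without replacement, wildcards appearing with the
given probability. It deliberately does *not* emulate hierarchical codes —
those paths are exercised by the hand-built lung table and targeted unit
tests — so the random sweep stresses the combinatorial exclusion logic
(agreement with the oracle, monotone shrinkage of the candidate set,
prompt count bounded by the baseline) rather than hierarchy traversal.

Problem sizes: the default test suite sweeps 40 random tables; the
reproduction script (`scripts/acceptance.R`) sweeps 200 tables
(~1,050–1,100 scenarios depending on seed) plus the 28 lung scenarios, in
about 40 seconds on one CPU.

## Limitations and open questions

* TX/NX ("cannot be assessed") are treated as ordinary classifications at
  level −1. A richer treatment — propagating assessment uncertainty
  through the session rather than asking about X codes — is out of scope.
* The frequency-first ranking is a greedy heuristic, not an optimal
  decision tree; it reproduces the intended clinical behavior (rare,
  distant-spread questions first) and halves the lung question count, but
  no optimality claim is made.
* Stage-mode stopping reports a stage without pinning the grouping, so its
  reports may carry wildcard resolution entries (`source = "any"`) for
  axes the session never needed to determine.
* The generator's flat-table scope means hierarchy-heavy pathologies
  (deeply nested sublevels) rely on the lung fixture and unit tests for
  coverage.
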