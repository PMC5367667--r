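# tnmstager

Exclusionary TNM cancer staging: interrogate a staging table with as few
questions as possible.

## The problem

Anatomic cancer staging under the TNM system assigns a tumor a *stage group*
(0, IA, IB, …, IV) from three classifications: primary tumor extent (T),
regional lymph node involvement (N), and distant metastasis (M). A staging
table is a list of *groupings* — rows such as `T2a N1 M0 → IIA` — possibly
with wildcard requirements (`Any T`, `Any N`). The conventional workflow
asks the clinician to determine T, N and M fully and then look the triple up.
That means reviewing every classification's criteria even when most of them
cannot change the answer.

This package implements the *exclusionary* alternative: treat staging as a
process of elimination over the table's rows. At each step it asks a single
yes/no question about one classification, chosen so that either answer
removes rows, and stops as soon as one grouping (or one stage label)
survives. For the bundled lung table this cuts the work roughly in half: a
truthful session needs on average **8.57** questions (worst case 12) against
a naive baseline of **15** distinct explicit classifications.

## The algorithm

Let `G` be the surviving groupings (initially all rows). Repeat:

1. **Poll** — for every classification code `c` on axis `a`, count
   `n(c) = #{g ∈ G : g` explicitly requires `c}` (wildcards do not count).
2. **Rank** — order codes with `n(c) ≥ 1` by ascending `n(c)`; break ties by
   axis (M before N before T, the order in which spread is cheapest to
   assess), then by descending level, then by descending sublevel.
3. **Prompt** — ask the highest-ranked code whose answer can still
   discriminate: a *yes* restricts `G` to rows matching `c` (wildcards and
   rows requiring `c` or an ancestor of `c` survive); a *no* removes rows
   that explicitly require `c` or a descendant of `c`. Codes whose answer
   could not change the outcome are skipped, and no code is asked twice.
4. **Stop** when one grouping survives (`stop_mode = "grouping"`), or as
   soon as all survivors share a stage label (`stop_mode = "stage"`). If the
   remaining rows are indistinguishable by questioning (one row subsumes
   another through wildcards), the session terminates and resolves to the
   first surviving row in prognostic order — the same row a brute-force
   table lookup returns.

Asking the *rarest* requirement first front-loads the questions with the
largest expected exclusion: on the lung table the opening question is about
M1b (extrathoracic metastasis), required by a single row, and a *yes* stages
the case IV immediately.

## Worked example

```r
library(tnmstager)

lung <- lung_staging_table()
lung
#> <staging_table> lung
#>   axes: M > N > T (extent-of-spread order)
#>   20 classifications, 28 groupings in 9 stages: Occult, 0, IA, IB, IIA, IIB, IIIA, IIIB, IV

s <- staging_session(lung)
next_prompt(s)
#> <tnm_prompt> M M1b
#>   Is there distant metastasis at a site beyond the thorax?
```

Sessions are immutable values; answering returns a new session. A patient
with a mediastinum-invading tumor, contralateral nodal spread and no distant
metastasis:

```r
s <- apply_answer(s, "M", "M1b", "no")
s <- apply_answer(s, "M", "M1a", "no")
s <- apply_answer(s, "N", "N3", "yes")
s <- apply_answer(s, "T", "T4", "yes")
resolve_session(s)
#> == Staging report ==
#> Anatomic stage: IIIB
#>   M: M0  — No distant metastasis
#>   N: N3  — Metastasis in contralateral mediastinal, contralateral hilar, ipsilateral or contralateral scalene, or supraclavicular lymph node(s)
#>   T: T4  — Tumor of any size that invades any of the following: mediastinum, heart, great vessels, trachea, recurrent laryngeal nerve, esophagus, vertebral body, carina, separate tumor nodule(s) in a different ipsilateral lobe
#> Answer trail:
#>   1. [prompt] M M1b -> no (28 -> 27 groupings)
#>   2. [prompt] M M1a -> no (27 -> 26 groupings)
#>   3. [prompt] N N3 -> yes (26 -> 6 groupings)
#>   4. [prompt] T T4 -> yes (6 -> 1 groupings)
```

Four questions, where the naive route reviews 15 classifications. The
answers to the two excluded metastasis codes let the engine *infer* M0 —
note the report's M line despite M0 never being asked. Reports, sessions and
simulations have `tidy()`/`glance()` methods, and `autoplot()` shows the
current frequency poll or the prompt-count distribution.

A brute-force oracle is available for checking:

```r
lookup_stage(lung, c(T = "T2b", N = "N1", M = "M0"))
#> [1] "IIB"
```

## How much does exclusion save?

`question_count_stats()` enumerates one truthful scenario per grouping
(wildcards filled with seeded concrete codes), answers every prompt
according to that ground truth, and compares the result with `lookup_stage`:

```r
question_count_stats(lung, seed = 1)
#> <tnm_sim> 28 truthful scenarios (grouping-resolved, frequency-first)
#>   prompts per session: mean 8.57, max 12
#>   naive review baseline: 15 distinct explicit classifications
#>   engine vs lookup agreement: 100%
```

`random_staging_table(seed)` generates seeded random tables for property
testing; the test suite checks engine/lookup agreement, monotone candidate
shrinkage and the prompt-count bound over hundreds of them.

## Command line

A thin CLI installs with the package:

```sh
tnmstage=$(Rscript -e 'cat(system.file("exec", "tnmstage", package = "tnmstager"))')
Rscript "$tnmstage" stage    --tumor-type lung            # interactive y/n/u/q
Rscript "$tnmstage" stage    --table lung.json --batch answers.csv --json
Rscript "$tnmstage" validate --table lung.json
Rscript "$tnmstage" simulate --tumor-type lung --seed 1
```

Interactive replies are literal: the engine maps `y`/`n` through each
question's polarity, so answering *no* to "Is there evidence of distant
metastasis?" correctly selects M0. Tables are portable JSON documents;
`read_staging_table()` / `write_staging_table()` round-trip them losslessly,
and `validate_staging_table()` reports structural errors (undefined codes,
duplicate rows, level inversions) and authoring lints (negatively phrased
questions, compound boolean clauses, overlapping groupings).

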