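---
title: "Causality assessment of adverse drug reactions: instruments, agreement statistics and the panel simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causality assessment of adverse drug reactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrcat)
library(dplyr)
```

## The problem

When a patient on medication develops a harmful event, someone must judge
how likely it is that the drug caused it. Such causality assessments of
adverse drug reactions (ADRs) are made by clinicians, regulators and
trialists, and unstructured judgement is known to produce wide
disagreement between assessors. Structured instruments exist to narrow
that disagreement; `adrcat` implements two of the most prominent designs
as executable engines, plus the statistical battery used to quantify how
well a panel of raters agrees, plus a simulator so the whole pipeline can
be exercised and tested without access to clinical case data (which is
rarely shareable).

All verdicts live on one four-point ordinal scale:

unlikely < possible < probable < definite.

## The two instruments

### The weighted questionnaire

The Naranjo instrument asks ten fixed questions; each answer (yes / no /
don't know) contributes an integer weight, and the total score is mapped
to the scale by fixed boundaries. The packaged weight matrix is the
original published one; with it, achievable totals span exactly
[-4, 13] (the package verifies this by exhaustive enumeration of all
3^10 sheets). The score boundaries were never formally justified by the
instrument's authors and are therefore configuration, not code: the
packaged default is the original convention (total <= 0 unlikely, 1-4
possible, 5-8 probable, >= 9 definite), and `read_naranjo_weights()`
loads dialect variants from JSON. The original "doubtful" label is
presented as "unlikely" so both instruments share one scale.

```{r}
sheets <- tibble::tibble(
  case_id = "c1", rater_id = "r1",
  Q1 = "yes", Q2 = "yes", Q3 = "yes", Q4 = "no", Q5 = "no",
  Q6 = "unknown", Q7 = "no", Q8 = "no", Q9 = "yes", Q10 = "yes"
)
score_naranjo(sheets)
```

A known weakness motivates the second instrument: heterogeneous real
cases force many "don't know" answers (weight 0), deflating totals so
that clearly drug-related events can fail to reach "definite".

### The decision tree

The Liverpool instrument is a flowchart: mostly dichotomous questions
(timing, alternative cause, de-challenge, re-challenge or previous
reaction to the same drug, supporting evidence) with routing to a leaf
category. The tree is shipped as a JSON document, not hard-coded,
because the instrument itself went through several prototype iterations
and users will want variants; `read_tree()` loads any document that
passes structural validation. The packaged document is a transcription
of the published flowchart; routing choices the published text leaves
open are recorded in the document's `metadata$notes` rather than decided
silently.

Two semantic rules are checked by `validate_tree()` as data-driven
diagnostics:

* **full range** — every one of the four categories labels at least one
  reachable leaf. (An early prototype of the instrument was biased
  towards "definite"; the check guards the opposite failure too.)
* **definite gate** — every root-to-definite path passes through an
  affirmative answer at a node tagged `rechallenge_gate`. This encodes
  the instrument's design rule that a definite verdict requires a
  positive re-challenge or a previous reaction to the same drug; the
  tag makes the rule data-driven instead of matching prompt text.

```{r}
tree <- liverpool_tree()
validate_tree(tree)
enumerate_paths(tree) |> count(category)
```

`assess()` is a pure function of the tree and the answers; only
questions along the taken path are required. `enumerate_paths()` lists
every root-to-leaf path, which supports validation, documentation and
inverse sampling.

## The agreement battery

Panels are summarised with the statistics standard in reliability
studies of ordinal instruments:

* **%EA**, exact agreement: the percentage of cases two raters label
  identically.
* **%ED**, extreme disagreement: the percentage of cases two raters
  place more than one ordinal step apart (e.g. possible vs definite).
  %EA, the one-step percentage and %ED always sum to 100.
* **Linear weighted kappa** per rater pair: chance-corrected agreement
  with weights `w_ij = 1 - |i - j|/3`, so near-misses earn partial
  credit. The standard error is the non-null large-sample form for
  weighted kappa (the classical Fleiss-Cohen-Everitt variance), and the
  95% CI (estimate ± 1.96 SE) is truncated to [-1, 1]. The estimate is
  computed case by case and, as an internal cross-check, again from the
  4x4 contingency table; the two routes agree to 1e-12 in the tests,
  and both are tested against an independent plain-loop evaluation of
  the defining formula.
* **Fleiss' kappa** across the whole panel, treating the categories as
  nominal, with the large-sample category-sum variance. This gives one
  number per study arm.
* **Altman bands** for verbal interpretation: poor (<=0.20), fair
  (<=0.40), moderate (<=0.60), good (<=0.80), very good (<=1.00). The
  published convention leaves gaps such as (0.20, 0.21); the bands here
  are half-open intervals applied to the full-precision estimate, and
  banding always precedes display rounding, so no value falls in a gap.

Missing ratings are handled conservatively: pairwise statistics use all
complete pairs for that pair of raters; Fleiss' kappa uses complete
cases only (so every retained case has the same number of ratings) and
reports the exclusion count. When both raters of a pair are constant on
one category the chance-corrected denominator is zero; the result is
flagged `degenerate` rather than thrown, because a report over many
pairs should not die on one uninformative pair.

```{r}
panel <- simulate_ratings(seed = 42)
rep <- agreement_report(panel$ratings)
rep
glance(rep)
```

`tidy()` returns the pairwise table, `glance()` the global row, and
`autoplot()` draws the pairwise kappa matrix. `write_report()` emits
schema-versioned JSON or a Markdown matrix in the layout reliability
papers print (the %EA/%ED line with the kappa and CI beneath).

## The simulator

No per-case ratings are published for the studies this package's
statistics come from, so the simulator is the package's source of truth
for testing: it generates panels with *known* latent categories.

The generative model is deliberately the simplest one with an ordinal
notion of error and a single agreement knob:

* latent category of each case i.i.d. from `prevalence`;
* each rater reports the latent category with probability `fidelity`,
  otherwise a different category at ordinal distance `d` with
  probability proportional to `spillover_decay^d`, renormalised.

Defaults are fixed at the design of the motivating study and are not
tuning knobs: `n_cases = 40`, `n_raters = 7` (seven investigators
assessing 40 consecutive case reports); `prevalence = (1, 62, 92,
125)/280`, the collated decision-tree category distribution of such a
case mix (suspected-ADR series contain essentially no "unlikely"
cases); `fidelity = 0.8` and `spillover_decay = 0.5`, chosen once so
that simulated panels show the qualitative pattern reliability tables
report — pairwise exact agreement mostly between 55% and 90% and
disagreements predominantly one category apart.

`simulate_study()` extends ratings to the answer-sheet level by inverse
path sampling: for each reported category it draws uniformly one of the
tree's enumerated paths to that category. Re-assessing the emitted
sheets therefore reproduces the ratings *exactly*, which the tests
assert cell for cell. Sampling a path uniformly is a modelling
convenience (real assessors do not choose their evidence route at
random); it is sufficient because the rating, not the route, is the
object of the agreement statistics.

What the simulator does **not** model: rater-specific leniency or bias,
case-difficulty random effects, correlated errors between raters who
share training, and learning over time. Passing tests on simulated
panels therefore demonstrate correctness of the engines and statistics,
not that any instrument achieves a particular reliability on real
cases.

Reproducibility follows R idiom: every simulation entry point takes a
`seed` and evaluates under `withr::with_seed()`, so the same arguments
always give the same panel and the caller's RNG state is untouched.

```{r}
study <- simulate_study(n_cases = 10, n_raters = 3, seed = 7)
all(assess_liverpool(study$sheets)$category ==
      tidyr::pivot_longer(study$ratings, -case_id,
                          names_to = "rater_id",
                          values_to = "category")$category)
```

## Collation and instrument comparison

`collate_categories()` rebuilds the per-assessor count table of a study
arm (counts, totals, percentages to 1 decimal place by default, full
precision retained) from long assessments, wide ratings or pre-counted
rows; the package ships the published per-assessor counts of a
three-arm validation study (`published_category_counts()`,
`development_counts()`) purely as worked inputs for this arithmetic.
`compare_instruments()` aligns two instruments over the same
case-by-rater grid and reports both count tables, both global kappas
and the distribution of per-assessment category shifts. Because the
same case-rater pair assessed with both instruments can be counted
either once or twice, the comparison reports both conventions
(`n_unique_pairs` vs `n_assessments`) explicitly.

## Numerical and design choices

* Category tokens are normalised case-insensitively with whitespace
  stripped; integer codes 1-4 are accepted. Unknown tokens are named in
  the error.
* Ordinal distance uses the fixed integer coding unlikely=1 ... definite=4.
* CI truncation to [-1, 1] happens after the ± 1.96 SE step, never on
  the estimate itself.
* Weighted-kappa variance is the non-null form; a null-variance CI
  (appropriate for testing kappa = 0 rather than for interval
  estimation) is deliberately not offered.
* Structural tree defects (dangling route, duplicate id, cycle,
  unlabeled leaf) abort loading with *all* violations listed; the
  semantic checks (full range, definite gate) are diagnostics so that
  work-in-progress trees can be inspected.
* Displayed tables round kappas to 2 dp and percentages to 1 dp; all
  objects retain full precision.

Test and script problem sizes were chosen to make the checks sharp but
quick: the null-limit check uses 2000 cases x 7 raters (Monte-Carlo SE
of Fleiss kappa ~ 0.003), fidelity-recovery uses a 4-point grid at 500
cases x 7 raters averaged over 3 seeds, and the exhaustive Naranjo
enumeration covers all 59049 sheets in well under a second.

## Limitations

The packaged tree is a transcription of a published figure; wording and
one or two ambiguous routes are recorded in the document metadata and
can be revised without touching code. The agreement battery implements
exactly the statistics named above — quadratic-weight kappa,
Krippendorff's alpha and Gwet's AC are out of scope. Published global
kappas from the motivating validation study cannot be recomputed here
because the underlying per-case ratings were never deposited; what the
package reproduces of that study is its collation arithmetic, and what
it validates statistically it validates against independent brute-force
oracles and degenerate/null limits on simulated data.
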