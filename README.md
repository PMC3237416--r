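# adrcat

Causality assessment of adverse drug reactions (ADRs) and the
inter-rater reliability of causality instruments, in R.

When a patient on medication develops a harmful event, clinicians,
regulators and trialists must judge how likely it is that the drug
caused it. Structured instruments exist to make that judgement
reproducible; `adrcat` is for the methodologists and pharmacovigilance
teams who run and audit multi-rater studies of such instruments. It
provides:

* **Scoring engines** for two instrument designs on the shared ordinal
  scale *unlikely < possible < probable < definite*:
  * the **Naranjo questionnaire** — ten questions, each answer
    (yes/no/don't know) carrying an integer weight; the total score
    maps to a category through configurable boundaries
    (`score_naranjo()`);
  * the **Liverpool decision tree** — a flowchart of mostly dichotomous
    questions (timing, alternative cause, de-challenge,
    re-challenge/previous reaction, supporting evidence) encoded as a
    validated JSON document, with structural checks plus two semantic
    diagnostics: all four categories reachable, and no path to
    *definite* without an affirmative re-challenge/previous-reaction
    answer (`assess_liverpool()`, `validate_tree()`).
* **The agreement battery** used in reliability studies
  (`agreement_report()`): per rater pair the exact-agreement percentage
  (%EA), the extreme-disagreement percentage (%ED: more than one
  ordinal step apart) and the linear weighted kappa

  κ_w = (p_o − p_e)/(1 − p_e),  p_o = Σ w_ij p_ij,  p_e = Σ w_ij p_i. p_.j,
  w_ij = 1 − |i − j|/3,

  with the non-null large-sample standard error and 95% CI; across the
  whole panel, Fleiss' multi-rater kappa with its large-sample CI; and
  Altman's verbal bands (poor/fair/moderate/good/very good) applied to
  the full-precision estimates.
* **A seeded panel simulator** (`simulate_ratings()`,
  `simulate_study()`): latent true categories drawn from a prevalence
  vector, ratings corrupted by an ordinal misclassification kernel
  (correct with probability *fidelity*, otherwise decaying with ordinal
  distance), and — for the decision tree — answer sheets drawn by
  inverse path sampling so that re-assessing them reproduces the
  ratings exactly.
* **Collation and comparison**: per-assessor category count tables with
  totals and percentages (`collate_categories()`), and side-by-side
  instrument comparison with category-shift distributions
  (`compare_instruments()`).

Everything is tibble-in/tibble-out and pipe-friendly; fitted report
objects support `tidy()`, `glance()` and `autoplot()`. A thin CLI over
the same functions ships in `inst/cli/adrcat` (subcommands
`score-naranjo`, `assess-liverpool`, `agree`, `collate`, `compare`,
`simulate`).

## Worked example

Simulate a 7-rater, 40-case panel at the package defaults and run the
full battery:

```r
library(adrcat)
panel <- simulate_ratings(seed = 42)
agreement_report(panel$ratings)
#> Inter-rater agreement: 7 raters, 40 complete cases
#> Global kappa 0.45 (95% CI 0.40, 0.50), moderate agreement
#>
#>   pair   %EA/%ED             kappa
#>  R1-R2 67.5/15.0 0.51 (0.28, 0.74)
#>  R1-R3 67.5/17.5 0.44 (0.20, 0.67)
#>  ...                              (21 pairs in all)
```

Each pairwise line gives the share of cases the two raters labelled
identically, the share more than one category apart, and the
chance-corrected weighted kappa with its CI; the global line condenses
the panel into one Fleiss kappa, here 0.45 — "moderate" on the Altman
scale, which is exactly the range real causality panels tend to occupy.

Collation reproduces published study arithmetic from per-assessor
counts (the package ships the count tables of a published three-arm
validation study as worked inputs):

```r
library(dplyr)
published_category_counts() |>
  filter(case_set == "adric_original", tool == "liverpool") |>
  collate_categories()
#> Causality category assignments (280 assessments)
#>  rater_id unlikely possible probable definite
#>        RG        0        7       23       10
#>        ...
#> Totals: unlikely 1 (0.4), possible 62 (22.1), probable 92 (32.9),
#>         definite 125 (44.6)
```

That is, 125 of 280 assessments (44.6%) in that arm were *definite* —
the decision tree uses the full width of the scale, where the weighted
questionnaire concentrates almost everything in *possible*/*probable*.

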