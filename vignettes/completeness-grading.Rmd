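---
title: "Grading the completeness of veterinary adverse-event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading the completeness of veterinary adverse-event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vetgrade)
```

## The problem

Spontaneous reporting of adverse events (AEs) following the use of
veterinary medicinal products is the backbone of post-marketing safety
surveillance: practitioners and owners submit reports to the national
competent authority, which uses them to detect emerging safety signals
and keep product information accurate. Reports are only useful to the
extent that they are *complete* — a report that omits when the drug was
started relative to the reaction, or basic animal demographics, supports
causality assessment poorly.

vetgrade models the full life cycle of such a report as it moves through
an electronic reporting pipeline integrated with a practice management
system: a structured record mirroring a four-screen reporting form
(animal, drug, reaction, contact), validity checking, completeness
grading, terminology coding, corpus-level statistics, and XML batch
export. Because real spontaneous-report corpora cannot be redistributed,
the package also includes a seeded synthetic generator whose per-element
completeness structure is fully known, so every downstream computation
can be tested end to end.

## Validity: the four minimum reporting criteria

Under veterinary good pharmacovigilance practice, a report is valid only
if it identifies a **reporter**, a **patient**, at least one **suspect
product**, and describes the **reaction**. In a practice-integrated
pipeline the first three are typically satisfied automatically (the
practice identifier stands in for the reporter; species and dispensed
products are pre-populated from the health record), so
`validate_minimum_criteria()` reduces in practice to a check on the
free-text reaction description. Placeholder strings (`"n/a"`, `"na"`,
`"..."`, `"-"`, blank — case-insensitive after trimming) do not count as
a description; the same placeholder set drives the comments-element
penalty of the scorer, which keeps the two notions consistent.

`UNKNOWN` is carried as an explicit enum value distinct from a
structurally absent field; the scorer treats the two identically, so
serialization round trips cannot change a score.

## The completeness score

`assess_report()` implements a multiplicative completeness score adapted
from the vigiGrade family of report-quality measures. Ten elements are
scored; each contributes a factor of 1 when the information is present
and `1 - penalty` when it is not, and the final score is the product of
the ten factors. A report is **well-documented** when the product is at
least 0.8.

| element | penalty | rule sketch |
|---|---|---|
| time-to-onset | 50% | drug start strictly before reaction = 1; same-day needs free text stating the order; any ambiguity or missing date is penalized; with several suspect drugs the worst one counts |
| reaction duration | 10% | duration fields populated, or determinable from free text |
| dose | 10% | daily dose determinable from dosage text; vaccine/pipette doses exempt |
| occupation of administrator | 30% | populated (including "other") = 1; unknown penalized |
| breed | 30% | unknown/absent penalized |
| age | 30% / 10% | unknown = 30%; a bare age of 0 (no months) = 10% |
| sex | 30% | unknown penalized |
| neuter status | 30% | unknown penalized |
| comments | 10% | placeholder description penalized |
| additional comments | 10% | clinical notes attached, or a stated reason (first consult, no relevant history) |

Two numerical consequences are worth knowing. First, the only reachable
element scores are {1, 0.9, 0.7, 0.5}, so the final score lives on a
lattice whose minimum is 0.5 × 0.9⁴ × 0.7⁵ ≈ 0.0551. Second, no product
of values from {0.9, 0.7, 0.5} equals 0.8 exactly, so the classification
boundary can never be hit exactly from a penalized report; we fix the
rule as *score ≥ 0.8 is well-documented* and classify on the unrounded
product (display rounding to two decimals is cosmetic only).

### Free text without NLP: judgments

Several rules hinge on what a human can elucidate from free text ("the
description states the drug came first", "the dose is clear from the
dosage text"). Rather than attempt clinical NLP, the package mechanizes
these as explicit `element_judgment()` records — verdicts of `RESOLVES`,
`AMBIGUOUS` or `ABSENT` from a source (`REPORT_FIELDS`,
`CLINICAL_NOTES`, `REVIEWER`). The conservative default when no judgment
exists is `ABSENT`: the penalty applies. This keeps scoring
deterministic and auditable, and lets two reviewers' judgment sets be
compared (`compare_reviewers()`) and reconciled (`reconcile()`) exactly
as in a manual scoring exercise.

### Dual assessment

`dual_assess()` scores each report twice: `FIELDS_ONLY` ignores
judgments sourced from the clinical notes; `WITH_NOTES` honors them.
Only the three elements with free-text clauses — time-to-onset, reaction
duration and dose — can be lifted by notes; demographics (breed, age,
sex, neuter status, occupation) cannot, which is why an auto-populated
bare age of 0 stays penalized in both passes. Notes can only remove
penalties, never add them, so the with-notes score dominates the
fields-only score report by report; this monotonicity is enforced by a
property test over generated corpora.

## Corpus statistics

`summarize_scores()` reports min/max/mean/median/IQR and the
well-documented proportion. The quantile convention is fixed (type 7,
linear interpolation) because the IQR is otherwise not reproducible
across software; the median uses the usual midpoint convention.

`paired_score_test()` compares the two assessment passes with a
two-sided Wilcoxon signed-rank test. Zero differences are dropped before
ranking (the classic treatment; the count is recorded in the result's
`detail`). Because final scores live on a small lattice, tied absolute
differences are the norm, and the textbook exact distribution does not
apply under ties — so the exact null distribution is computed by dynamic
programming over the (doubled, possibly half-integer) ranks whenever at
most 25 nonzero differences remain, and the normal approximation with
tie correction is used above that. The exact path is verified against
exhaustive enumeration of all sign assignments for n ≤ 10 and against
the classical routine on tie-free data.

`proportion_test()` compares well-documented proportions between two
reporting routes from a 2×2 table, choosing Fisher's exact test when any
cell is below 5 and the chi-squared test otherwise. Two genuinely open
choices are exposed as arguments rather than silently fixed: the
below-5 rule is applied to *observed* counts by default (with
`rule = "expected"` for the conventional expected-count rule), and the
chi-squared test runs *without* Yates continuity correction by default
(`correction = TRUE` enables it). For strongly separated proportions,
e.g. 43/45 vs 19/45, the conclusion (p < 0.001) is identical under
every variant; for borderline tables the variants differ and the caller
should state which was used.

## The synthetic generator

`generator_config()` + `generate_corpus()` draw report corpora with
known completeness structure: each element is complete with probability
θₑ; an incomplete time-to-onset is a same-day case (resolvable from
notes) with probability `p_same_day` and a missing start date otherwise;
clinical notes are attached with probability `p_notes_attached`; an
attached note resolves an incomplete resolvable element with probability
ρₑ; and an animal with known age is under one year (transmitted as a
bare 0) with probability `p_age_zero`. Every generated report passes the
minimum reporting criteria, and each comes with a truth record carrying
the drawn states and the implied final scores in both modes — tests
require the scorer to reproduce these exactly.

Defaults are anchored to the observed structure of a small-animal
practice corpus where such rates are known: time-to-onset complete in
28/45 of reports with every incomplete case same-day and fully
notes-resolvable (ρ = 1), age always known but under-one-year (bare 0)
in 14/45, occupation known in 44/45 with an administrator mix of
33 vet / 22 owner / 3 nurse, and a species mix of 30 dog / 24 cat /
4 rabbit / 1 other. Rates with no observed anchor (reaction-duration
and dose completeness, note attachment, breed/sex/neuter completeness,
the note-resolution probabilities for duration and dose) were chosen
once as plausible values for an EHR-pre-populated form — e.g. notes
attached 90% of the time, demographics nearly always pre-populated —
and are deliberately not tuned to reproduce any published summary
table: real corpora have correlated missingness, reporter-specific
habits, and free text whose interpretability is not a coin flip, none
of which the generator emulates. Passing tests therefore demonstrate
the *internal* consistency of the pipeline, not distributional fidelity
to real reporting data. `theta["COMMENTS"] < 1` is allowed but warns,
since a placeholder description is by construction an invalid report.

The random stream is split per report (a fixed sub-seed per index), so
corpora from the same seed are prefix-stable as `n_reports` grows.
Element states are drawn independently; a correlation structure (e.g. a
copula over element states) is a possible extension but out of scope.

### The closed-form expected score

`expected_score()` gives the analytic expectation of the final score
under a configuration. One subtlety: note attachment couples the
additional-comments element with the resolution events of
time-to-onset, duration and dose, so a naive product of marginal
per-element expectations is wrong whenever `p_notes_attached < 1`. The
expectation is therefore computed by conditioning on attachment —
elements *are* independent given the attachment indicator — and mixing
the two conditional products. Monte-Carlo means over 10 000 generated
reports are required (in the test suite) to fall within three standard
errors of this closed form across a spread of configurations.

## Numerical and design choices, in brief

- Threshold fixed at ≥ 0.8; boundary unreachable from penalized
  lattices, so the ≥ vs > distinction is observationally irrelevant but
  documented.
- Scores carried in double precision; products compared with 1e-12
  tolerances in tests; no rounding before classification.
- Same-day time-to-onset without a resolving judgment is penalized; an
  `AMBIGUOUS` judgment forces the penalty even with clean dates.
- With several suspect drugs the time-to-onset and occupation elements
  take the most pessimistic drug.
- A populated dosage text alone does not clear the dose element — a
  `RESOLVES` judgment that the daily dose is determinable is required,
  mirroring manual review.
- Terminology matching is exact after normalization (lowercase, trim,
  collapse whitespace); no fuzzy matching or synonym expansion, by
  design: determinism over recall. The shipped VeDDRA/ATCvet/SPC tables
  are small synthetic stand-ins (licensed dictionaries cannot be
  redistributed); users supply real tables as TSV.
- Expectedness of a drug-event pair requires *all* of its coded signs to
  be listed in the product's SPC; a product without an SPC entry is
  `UNASSESSABLE`.
- XML export defines its own documented schema (shipped XSD) covering
  the full report model, rather than guessing at any regulator's
  gateway schema; round-trip identity is tested across random corpora.
- Problem sizes in the test suite: property suites run on corpora of
  120–1000 reports; Monte-Carlo recovery uses five configurations of
  10 000 reports; the exhaustive Wilcoxon oracle covers n ≤ 10; the
  score lattice is enumerated in full (1536 combinations).

## Worked example

```{r example, eval = FALSE}
cfg <- generator_config(n_reports = 45, seed = 20200918)
corpus <- generate_corpus(cfg)

fields <- assess_corpus(corpus$reports, corpus$judgments, "FIELDS_ONLY")
notes  <- assess_corpus(corpus$reports, corpus$judgments, "WITH_NOTES")

summarize_scores(fields$final_score)
summarize_scores(notes$final_score)
paired_score_test(fields$final_score, notes$final_score)

# route comparison from two well-documented counts
proportion_test(43, 45, 19, 45)
```

## Known limitations

- Judgments must be supplied; the package ships no NLP to derive them
  from note text.
- The generator's independence assumption and Bernoulli completeness
  states are a deliberate simplification of real reporting behaviour.
- Summary statistics of real published corpora cannot be reproduced
  without the underlying (unpublished) reports; the package's claims
  are about the correctness of its machinery, checked against oracles
  and closed forms.
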