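---
title: "Methods: scoring, compass assembly, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, compass assembly, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rehabcompass)
```

## The measurement model

`rehabcompass` turns item-level answers to six stroke patient-reported
outcome measures (PROMs) into a single, commensurable picture of a person's
rehabilitation needs. The pipeline has four stages:

1. **Item validation** — every answer is checked against the instrument's
   declared admissible levels; an unanswered item is an explicit `NA`,
   never 0 (0 is a valid code in HADS and EAT-10).
2. **Domain scoring** — each functional domain's raw score is an aggregate
   of its member items under the instrument's published rule.
3. **Normalization** — every raw domain score is mapped *linearly* onto a
   common 0–100 scale with 100 = best health. Linearity means the variable's
   ordering and spacing are preserved; nothing about its distribution is
   changed.
4. **Compass assembly** — normalized domains are grouped into seven
   functional areas (life, cognition, emotion, fatigue, sexuality and
   continence, sensory function, motor function); each area is colored by
   the arithmetic mean of its member domains and carries an inner-edge
   marker colored by its *minimum* member, so a single severe problem is
   not averaged away.

### Scoring rules and their rescales

| Instrument | Items | Rule | Raw range (per domain) | Normalized |
|---|---|---|---|---|
| SIS 3.0 (8 ordinal domains) | 59, codes 1–5 | mean-rescale | mean in [1, 5] | $100(\bar{x}-1)/4$ |
| SIS recovery rating | 1, 0–100 | passthrough | [0, 100] | identity |
| SIS+ (sensory, sleep, pain, continence, sexuality) | 8, codes 1–5 | mean-rescale | [1, 5] | $100(\bar{x}-1)/4$ |
| HADS (anxiety, depression) | 7 + 7, codes 0–3 | sum-rescale | [0, 21] | $100(21-s)/21$ |
| FAS | 10, codes 1–5 | sum-rescale | [10, 50] | $100(50-s)/40$ |
| smRSq | 5 yes/no | grade-rescale | grade [0, 5] | $100(5-g)/5$ |
| EQ-5D-3L dimensions | 5, codes 1–3 | per-dimension | [1, 3] | $100(3-\ell)/2$ |
| EQ-5D VAS | 1, 0–100 | passthrough | [0, 100] | identity |
| EAT-10 | 10, codes 0–4 | sum-rescale | [0, 40] | $100(40-s)/40$ |

All of these are instances of one affine map
$100\,(x - x_\mathrm{worst})/(x_\mathrm{best} - x_\mathrm{worst})$, so the
package funnels every rule through a single `normalize_score()` with
per-domain achievable bounds and an orientation flag; scales on which a
higher raw value is worse are reflected. Output is clamped to $[0,100]$ only
against floating-point round-off — a raw value outside its achievable
bounds is an error, never silently truncated.

The item banks are *reconstructions*: the published instruments fix the
counts and level ranges used here, but prompts are placeholders
(questionnaire wording is copyrighted) and the deployed tool's exact SIS+
item set is not public. Banks are data (JSON documents under
`inst/extdata/instruments/`), not code, so a deployment can replace them.
The named instruments' published forms also sum to fewer items than the
~130 the original deployment administered; the difference lies in the
unpublished additional questions, which is precisely why the banks are
configuration.

### Missing answers and proration

A domain is scored when at least half of its member items are answered
(the common PROM half-scale convention; `proration_floor` is a knob).
Sum-scored domains prorate as `mean(answered) * n_total`, which coincides
exactly with the plain sum when everything is answered. Below the floor the
domain is *unscorable* (`missing = TRUE`) and stays visible as such — the
package never imputes: in a triage tool, failing visibly beats guessing.

The smRSq is the one non-prorated instrument: its five yes/no questions
form a decision tree read from the severest question down, and the first
"yes" fixes the disability grade (all "no" is grade 0). If an answer is
missing before any "yes" is reached the grade is unresolvable and the
domain is missing. A "yes" at a severe question with "no"s below it is
tree-consistent (those questions would not have been asked), not a
contradiction.

### Impairment vs. color bands — two different rules

Two thresholds coexist deliberately and must not be conflated:

* **Impairment** (unmet need): normalized score $< 100$. A score of 95 is
  impaired.
* **Color bands** (triage severity): red $[0,30]$, orange $(30,70)$, green
  $[70,100]$. A score of 95 is green.

The band boundaries are closed at 30 and 70 because the printed ranges
("0–30", "70–100") are closed; orange is everything between. The test suite
asserts the coexistence explicitly (a green-yet-impaired score) so a future
refactor cannot merge the rules. Per-domain impairment thresholds and the
two band cut points are configurable; published instrument-specific
clinical cut-offs can thus be layered on, but none are asserted as
defaults because the original deployment's choices are not printed.

### Area aggregation

Areas are *equally weighted* means of their member domains — a domain-level
mean, not an item-count-weighted one — because the area color is defined as
the mean of the included domains, each of which is already on the common
scale. Members that are missing drop out (available-case mean); an area with
no scorable member renders neutral grey and is excluded from impairment
counts. The default domain→area mapping (e.g. ADL/IADL, participation,
global disability grade, health rating and recovery under *Life*) is a
reconstruction from domain semantics; it ships as a JSON document, is
validated against the catalog, and deployments may replace it.

## Longitudinal deltas

`compare_snapshots(earlier, later)` reports, per domain and per area, the
signed change (later − earlier) and the band transition
(`"red->green"`). Domains unscorable at either end are flagged
`newly_missing` / `newly_scored` and never differenced. The comparison is
antisymmetric by construction and the identity comparison is all-zero; both
are asserted as properties.

## Cohort summaries

For every mapped domain the cohort summary reports the median and 25–75%
interquartile range over non-missing scores (percentile convention:
linear interpolation between closest ranks, `stats::quantile` type 7, a
knob), the impaired count, and the frequency with its percent rounded to
the nearest integer, half away from zero — so 20/24 prints as 83%, 18/24 as
75%, 16/24 as 67%. Respondents with a missing domain leave that domain's
denominator, and `n_scored` is always reported next to the frequency so the
denominator is never hidden. The extent/frequency table sorts worst median
first, ties broken by impairment frequency (descending), then domain id —
a total, deterministic order.

## The synthetic cohort: what it emulates, and what it does not

There is no public item-level dataset for this instrument, so the package
carries a seeded generator as a first-class module. Its stated world is a
24-person post-stroke outpatient cohort answering every instrument at
3- and 12-month follow-ups:

* **Prevalence** — per-domain impairment prevalence is planted; the
  packaged default profile uses the published group-level frequencies
  (fatigue 20/24, sleep 18/24, health rating and strength 17/24, anxiety
  16/24) and 0.5 elsewhere, a mid-range burden typical of 12-month cohorts.
* **Assignment** — `exact-count` mode allocates exactly
  `round(p · n)` impaired respondents (needed to reproduce printed
  count/percent pairs); `probabilistic` mode draws per-respondent Bernoulli
  flags (used for distributional property tests).
* **Severity** — an impaired respondent draws each item's shift from the
  best level as $\mathrm{Binomial}(\text{steps},\ \sigma)$ with worseness
  $\sigma = 0.3$ by default (mild-to-moderate impairment); one member item
  per domain is forced off the best level so the planted impairment is
  always recoverable by scoring. Unimpaired respondents answer the best
  level everywhere — the anchor the acceptance tests rely on.
* **Time** — impairments persist across time points while severity shrinks
  by an improvement drift of 0.25 per step, emulating partial recovery
  between 3 and 12 months.

The generator makes no attempt at epidemiological covariate structure
(age, sex, education), item-level correlation within domains, or
instrument-specific response styles. A green test therefore establishes
that the *pipeline arithmetic* is right — scoring, normalization, banding,
aggregation, counting — not that the synthetic answers resemble real
stroke-survivor response patterns.

All randomness flows through a private, seeded RNG stream that saves and
restores the caller's `.Random.seed`; a fixed seed fixes the emitted
records byte-for-byte. One subtlety worth recording: the catalog's
instrument order feeds the RNG consumption order, so the default file list
is sorted in byte order (`method = "radix"`), immune to locale collation
differences between environments.

## Numerical and format choices

* Normalized scores are kept at double precision end to end; nothing is
  rounded except the printed percent.
* Bounds checks use a relative `1e-9` epsilon; monotonicity and oracle
  comparisons use `1e-12` slack on a 0–100 scale.
* Definition documents (instruments, mapping, profiles) are JSON validated
  structurally on load with errors that name the file, item, and field.
  JSON was chosen over YAML as the serialization because the target
  R environment guarantees a JSON parser (`jsonlite`) and no YAML parser;
  the document structure is unchanged by that choice.
* SVG is the canonical rendering: element order, ids
  (`sector-<area>`, `marker-<area>`, `bar-<instr>-<domain>`,
  `freq-<instr>-<domain>`) and fixed three-decimal coordinates make output
  byte-deterministic and parseable, which is how the fidelity tests assert
  that every rendered color and annotation equals the exported number. PNG
  is derived from the same geometry via base graphics devices.
* The compass draws its seven sectors clockwise from 12 o'clock in mapping
  order; sector geometry (equal angles, annular marker width as a fraction
  of the radial extent, default 0.18) is a documented convention of this
  package, not a reproduction of the original tool's layout.

## Known limitations

* Item banks and the domain→area mapping are reconstructions
  (config-overridable); prompts are placeholders.
* No EQ-5D country value-set index is computed — only the dimension
  rescales and the VAS passthrough.
* No inferential statistics: the cohort summary is descriptive
  (median/IQR/frequency), matching the instrument's reporting style.
* The usability study surrounding the original instrument (task
  completion, SUS, satisfaction) concerns human participants and is out of
  scope for a scoring library; none of its numbers are reproduced here.
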