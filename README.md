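# rehabcompass

Stroke survivors carry a wide mix of long-term problems — fatigue, low
mood, pain, disturbed sleep, reduced hand function, participation
restrictions — that routine follow-up visits easily miss. A practical way
to surface them is to let the patient answer a battery of validated
patient-reported outcome measures (PROMs) at home and compress the answers
into one triage picture the clinician can read at a glance.

`rehabcompass` is an R implementation of that pipeline for a six-PROM
stroke battery: **SIS 3.0** (with additional sensory/sleep/pain/
continence/sexuality questions), **HADS**, **FAS**, **smRSq**,
**EQ-5D-3L**, and **EAT-10**. It provides:

* item-level validation and domain scoring for all six instruments,
  with every domain normalized linearly onto a common **0–100 scale
  (100 = best health)**: e.g. FAS total $s \in [10,50]$ maps to
  $100(50-s)/40$, a HADS subscale $s \in [0,21]$ to $100(21-s)/21$,
  an SIS domain mean $\bar{x} \in [1,5]$ to $100(\bar{x}-1)/4$;
* the seven-area **compass graph** (life, cognition, emotion, fatigue,
  sexuality and continence, sensory function, motor function): each sector
  colored by the mean of its member domains on the triage scale
  **red [0,30] / orange (30,70) / green [70,100]**, with an inner-edge
  marker colored by the *lowest* member so single severe problems stay
  visible, rendered as deterministic SVG (or PNG);
* **impairment flagging** (normalized score < 100 = unmet need — distinct
  from the color bands by design), longitudinal **snapshot deltas** with
  band transitions, and **cohort summaries** (median, 25–75% IQR,
  impairment frequency as `k/n, p%`);
* a seeded **synthetic cohort generator** (default: 24 respondents,
  3- and 12-month time points, per-domain plantable impairment prevalence)
  so the whole pipeline is testable without patient data;
* a **CLI** (`simulate`, `score`, `compass`, `compare`, `cohort`,
  `render`) over long-format CSV/JSON responses and JSON
  instrument/mapping/profile documents.

Item banks, the domain→area mapping, and the cohort profile are data
(JSON under `inst/extdata/`), not code; the packaged versions are
documented reconstructions and any deployment can replace them.

## Worked example

Simulate the packaged default cohort (24 respondents; planted prevalences
fatigue 20/24, sleep 18/24, health rating and strength 17/24, anxiety
16/24), score it, and summarize the 12-month follow-up:

```r
library(rehabcompass)

catalog <- load_instrument_catalog()
mapping <- load_area_mapping(catalog = catalog)
profile <- load_cohort_profile()

records <- generate_cohort(profile, catalog, mapping)
scores  <- score_records(records, catalog)

s12   <- scores[scores$timepoint == "12-month", ]
snaps <- lapply(unique(s12$respondent_id), function(r)
  assemble_compass(s12[s12$respondent_id == r, ], mapping))
summ  <- summarize_cohort(snaps)
head(extent_frequency_table(summ)[, c("label", "median", "q25", "q75",
                                      "impaired_n", "n_scored", "percent")], 4)
```

```
            label median  q25   q75 impaired_n n_scored percent
1  sis_plus:sleep   75.0 71.9  90.6         18       24      75
2      eq5d3l:vas   78.5 75.0 100.0         17       24      71
3     fas:fatigue   80.0 76.9  88.1         20       24      83
4   sis3:strength   81.2 75.0 100.0         17       24      71
```

Reading a row: the cohort's median sleep score is 75 points (IQR
71.9–90.6) on the 0–100 best-health scale, and 18 of 24 respondents score
below 100 there — a 75% impairment frequency. The planted 20/24 fatigue
prevalence comes back as exactly `20/24, 83%`.

One respondent's compass:

```r
snaps[[1]]
#> <compass snapshot: respondent R001 @ 12-month>
#>               area_id area_score min_score area_band min_band
#>                  life  100.00000 100.00000     green    green
#>             cognition   92.85714  85.71429     green    green
#>               emotion   85.31746  75.00000     green    green
#>               fatigue   77.50000  75.00000     green    green
#>  sexuality_continence  100.00000 100.00000     green    green
#>               sensory   93.75000  87.50000     green    green
#>                 motor   89.06250  75.00000     green    green
render_compass(snaps[[1]], render_spec(), "compass_R001.svg")
```

The same pipeline from the shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "rehabcompass", package = "rehabcompass"))')
Rscript "$CLI" simulate --out responses.csv
Rscript "$CLI" score    --responses responses.csv --out scores.csv
Rscript "$CLI" cohort   --responses responses.csv --timepoint 12-month --out summary.csv
Rscript "$CLI" render   --responses responses.csv --respondent R001 \
                        --timepoint 12-month --out compass.svg
```

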