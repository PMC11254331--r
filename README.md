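# toxflow

Longitudinal tolerability trajectories, Sankey flows, and the Toxicity
Index for clinical-trial adverse-event (CTCAE) and patient-reported
outcome (PRO) data.

Trials assess toxicity grades and symptom bother at every cycle, but the
usual worst-grade summaries discard the trajectory: whether a grade-3
arthralgia resolved, persisted, or ended in discontinuation. `toxflow` is
for biostatisticians and trialists who want those trajectories as
first-class objects — selectable cohorts, flow graphs, duration tables,
and scalar severity summaries — scriptable from R or the shell.

## What it computes

Given a long-format table of (patient, arm, term, timepoint, level)
records on an ordered severity scale:

* **Cohort selection** — the patients of one arm at a chosen severity
  level at a chosen start cycle, followed over a stage window.
* **Sankey flow graphs** — per-stage node counts and consecutive-stage
  transition counts, with exact conservation (nodes sum to the cohort
  size; outflow and inflow match node counts), rendered to deterministic
  SVG (plus PNG/HTML).
* **Toxicity Index (TI)** — for a patient with per-cycle grades sorted
  descending, w₍₁₎ ≥ w₍₂₎ ≥ … ≥ w₍ₙ₎,

  TI = Σᵢ w₍ᵢ₎ · Π_{j<i} (1 + w₍ⱼ₎)⁻¹,

  so m ≤ TI < m + 1 where m is the maximum grade, and TI ∈ [0, 6) for
  CTCAE grades. Cohort summaries report mean (SD), median (IQR), and a
  fixed-bin histogram.
* **Grade-duration tables** — for each grade, the distribution over
  cycles of the patient-stage cells at that grade.
* **Final-state statements** — plain-language summaries with whole-number
  percents over the initial cohort size.
* **Synthetic trials** — a first-order Markov simulator with a two-arm
  CTCAE-like preset (6-month cycles, 6-60 months) and a three-arm
  PRO-like preset, plus a transition-matrix estimator for parameter
  recovery.

## Worked example

```r
library(toxflow)

trial  <- simulate_trial(preset_b35(), n_per_arm = 200,
                         term = "Arthralgia", seed = 7)
query  <- cohort_query(arm = "Anastrozole", term = "Arthralgia",
                       initial_level = "3",
                       start_stage = "6 mo", end_stage = "30 mo")
cohort <- select_cohort(trial, query)

final_state_summary(collapse_levels(cohort))
#> Of the initial 14 patients, by the final time point (30 mo),
#> 4 (29%) were off treatment, 3 (21%) were at grade 4,
#> 3 (21%) were at grade 0-1, 2 (14%) were at grade 3 and
#> 2 (14%) were at grade 2.

cohort_ti_summary(cohort)
#> <ti_summary> n = 14
#>   mean (SD): 4.45 (0.66)
#>   median [IQR]: 4.39 [3.98-4.96]

gd <- grade_duration(cohort)
gd[gd$state == "3", c("stage", "count", "percent")]
#>   stage count percent
#> 1 6 mo     14      41
#> 2 12 mo     9      26
#> 3 18 mo     5      15
#> 4 24 mo     4      12
#> 5 30 mo     2       6

render_sankey(build_flow_graph(collapse_levels(cohort)),
              title = "Grade 3 arthralgia at 6 mo (Anastrozole)",
              out = "cohort.svg", format = "svg")
```

Reading the output: 14 simulated patients had grade-3 arthralgia at the
6-month cycle on the anastrozole arm. The statement tallies where they
ended up at 30 months (percents use the initial 14 as denominator and are
not forced to sum to 100). Every patient's TI is at least 3 — the cohort
is defined by a grade-3 cycle — and values near 4 or above reflect later
worsening. The grade-duration rows say 41% of this cohort's grade-3
patient-cycles occurred at 6 months, tapering to 6% by 30 months.

The same workflows run from the shell via the bundled CLI
(`inst/cli/toxflow.R`): subcommands `simulate`, `ae-explore`,
`ae-cohort`, `pro-cohort`, and `custom` (which ingests your own
three-column long-format CSV with a JSON mapping config declaring column
names and the orderings of time points and responses). Exit codes:
0 success, 2 validation failure, 3 empty cohort, 4 I/O error.

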