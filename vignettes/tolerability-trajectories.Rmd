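---
title: "Modelling longitudinal tolerability: trajectories, flows, and the Toxicity Index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling longitudinal tolerability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxflow)
```

## The problem

Randomized trials collect adverse-event grades (CTCAE, an ordinal 0-5
clinician rating) and patient-reported symptom bother (e.g. the BCPT
symptom checklist, "Not at all" through "Extremely") at every assessment
cycle, yet tolerability is usually reported as a single worst-grade table.
That collapses the longitudinal structure: two patients with the same
maximum grade may have had very different treatment experiences — one a
transient flare, the other a persistent burden ending in discontinuation.

`toxflow` keeps the trajectories. Its data model is a long-format table of
(patient, arm, term, timepoint, level) records governed by an ordered
severity scale; everything else — cohort selection, Sankey flow graphs,
grade-duration tables, Toxicity Index distributions, plain-language
final-state statements — is derived from that table.

## The data model and its conventions

A `severity_scale` orders its levels from least to most severe and
designates one extra *missing level* ("Off Treatment" for AE scales,
"No Response" for PRO scales). The missing level is a first-class display
category, not an NA: when a patient has no record at a stage inside the
analysis window, the cell is filled with the missing level. The fill
happens at pivot time (`pivot_trajectories()`), so the stored table remains
a faithful record of what was observed.

Two conventions matter downstream:

* **Raw grades are stored; bins are display.** CTCAE tables keep grades
  0-5 individually so the Toxicity Index can use them; the familiar "0-1"
  category is applied at flow/summary time via `collapse_levels()`.
* **Absorbing dropout is policy, not structure.** Whether a patient can
  return after an off-treatment cycle is a property of the trial, so
  `validate_table(check_absorbing = TRUE)` only *flags* non-absorbing
  sequences (severity "warning"); they are never fatal. The synthetic
  generator defaults to absorbing dropout.

Duplicate (patient, term, timepoint) records — common in real extracts —
are rejected in strict mode and resolved to the most severe level, with a
warning, in lenient mode.

The upload schema mirrors the three-column custom-explorer convention:
patient identifier, time point, and one response column whose header names
the term, with the orderings of time points and responses declared
explicitly by the user (never inferred). The format is long — the patient
identifier repeats once per time point — which is how such uploads are
described operationally even where they are loosely called "wide". Because
three columns cannot carry a treatment arm, the writer adds an optional
arm column (declared in the mapping) so multi-arm tables round-trip; a
plain three-column file simply lands in a single arm labelled "All".

## The Toxicity Index

The Toxicity Index (TI) summarises a patient's multiset of per-cycle
grades into one order-preserving number. With grades sorted descending,
$w_{(1)} \ge w_{(2)} \ge \dots \ge w_{(n)}$,

$$\mathrm{TI} = \sum_{i=1}^{n} w_{(i)} \prod_{j<i} \bigl(1 + w_{(j)}\bigr)^{-1}
 = w_{(1)} + \frac{w_{(2)}}{1+w_{(1)}} + \frac{w_{(3)}}{(1+w_{(1)})(1+w_{(2)})} + \dots$$

The leading term is the maximum grade; each further grade contributes a
strictly smaller correction. Hence for any non-empty profile with maximum
grade $m > 0$,

$$m \le \mathrm{TI} < m + 1,$$

so profiles are ranked first by their worst grade and, within the same
worst grade, by the rest of the profile. For CTCAE grades in $[0,5]$ the
TI lies in $[0, 6)$: the supremum 6 is approached, never attained, as
all-grade-5 sequences lengthen.

```{r ti-examples}
toxicity_index(c(3, 2))     # 3 + 2/4
toxicity_index(c(3, 3, 2))  # 3 + 3/4 + 2/16
toxicity_index(rep(5, 6))   # approaches, never reaches, 6
```

Choices made where the convention was open:

* **Per-term TI.** TI is computed over the per-cycle grades of the single
  selected term within the selected window, matching how a cohort is
  defined (one arm, one term, one window). Pooling across terms would be a
  different estimand; `grade_profiles()` exposes the inputs so users can
  build such variants.
* **Missing cycles are skipped**, not imputed as grade 0: an off-treatment
  cycle is absence of information about toxicity, and imputing 0 would
  reward early discontinuation with a lower score.
* **Quartiles** use linear interpolation between order statistics
  (`stats::quantile` type 7, the R default), configurable via
  `quantile_type`.
* **Histogram bins** are width 0.5 over $[0, 6)$, the natural TI range.
* **SD of a single patient** is reported as `NA`, never 0 — a one-patient
  cohort has no dispersion estimate.

## Sankey flow graphs

`build_flow_graph()` reduces a trajectory matrix to node counts (marginal
state frequencies per stage) and link counts (joint frequencies of
consecutive-stage state pairs). Three identities hold exactly, by
construction, and are verified against a brute-force tally in the tests:

* node counts at every stage sum to the cohort size,
* outflow from each non-terminal node equals its count,
* inflow into each non-initial node equals its count.

Rendering conventions: nodes run most-severe at top to least severe at
bottom with the missing level pinned last; zero-count nodes are omitted
from the drawing but retained (count 0) in the serialized JSON; colors
come from a fixed diverging ramp keyed by level index (grey for the
missing level), so the same scale always renders the same way. SVG is the
canonical target — the writer emits fixed-precision coordinates, so
rendering the same graph twice gives byte-identical files, which makes
figures diffable and testable. PNG is rasterised from the same layout and
HTML wraps the SVG.

## Cohorts, statements, and grade duration

`select_cohort()` returns exactly the patients of one arm whose state for
the term at the start stage equals the chosen initial level, clipped to
the window; an empty result is an empty matrix, not an error. The window
must span at least two stages (a single stage defines no trajectory).

`final_state_summary()` tallies last-stage states. Percents are whole
numbers, rounded half away from zero, with the **initial cohort size as
denominator** — patients off treatment by the final stage stay in the
denominator — and are deliberately not force-balanced: 12/18, 5/18 and
1/18 print as 67%, 28% and 6%, which sum to 101. Categories are listed in
descending count order, ties broken most severe first.

`grade_duration()` answers "when did the grade-3 burden occur?": for each
state, the distribution over stages of the patient-stage *cells* at that
state. Cells, not patients: a patient at grade 3 in two cycles contributes
two grade-3 cases. Off-treatment cells are excluded by default
(`include_missing = TRUE` includes them). Unrounded proportions sum to 1
per state; rounded percents may drift from 100 by at most one unit per
stage.

## The synthetic generator

No individual-level data from the motivating trials are public, so the
package ships a first-order Markov simulator whose presets emulate their
*structure*: `preset_b35()` gives two arms on raw CTCAE grades with
"Off Treatment", assessed at 6-month cycles from 6 to 60 months;
`preset_b30()` gives three chemotherapy arms on the five-level bother
scale with "No Response", assessed at baseline, day 1 of cycle 4, and
6-month intervals to 24 months.

Transition kernels are ordinal random walks: from each level, mass goes to
staying, improving one level, worsening one level, and dropping out, with
boundary mass folded into staying; CTCAE grade 5 exits the study and the
missing level is absorbing. The preset parameters — mostly low-grade
initial severity, improvement slightly more likely than worsening, a 5-6%
per-cycle dropout hazard — were chosen once as clinically plausible
magnitudes for adjuvant breast-cancer regimens and are not fitted to any
dataset.

What the simulator does *not* emulate: sojourn-time (semi-Markov)
dynamics, covariate-dependent transitions, between-patient heterogeneity,
informative dropout correlated with grade history beyond the current
state, and visit-level missingness that later resumes. Passing tests
therefore demonstrate the *mechanics* — conservation, round-trips,
estimator consistency — under a clean generative model, not fidelity to
any real trial's dynamics.

`estimate_transitions()` closes the loop: row-normalised consecutive-stage
counts recover the generating matrix as cohorts grow (a row estimated from
$k$ transitions has binomial standard error at most $0.5/\sqrt{k}$), and
rows for never-visited states are reported as `NA` and flagged rather than
fabricated.

## Problem sizes and numerical choices

The test suite exercises: exhaustive TI enumeration over all 55,986 grade
sequences of length 1-6 (the supremum check); 200 random trajectory
matrices up to 20 patients by 5 stages against the brute-force flow
oracle plus a 10,000-patient simulated trial for conservation; transition
recovery at 5,000 patients per arm (where well-supported rows are
recoverable to ±0.03); and 50 randomized CSV round-trips. These sizes were
chosen so every property is checked at a scale where its statistical
guarantee is meaningful.

Numerical details worth knowing: percent rounding is half-away-from-zero
(base R's `round()` is half-to-even); TI computation sorts once and uses a
cumulative product, so it is exact to double precision and
permutation-invariant; simulation uses a single Mersenne-Twister stream
per call, seeded explicitly, and restores the caller's RNG state.

## Limitations

The package deliberately stops at description: no between-arm tests, no
longitudinal models, no TI variants or recalibrations. One scale governs
one table, so mixed AE/PRO analyses require two tables. The statement
generator targets English clinical-report phrasing. And all empirical
claims in this vignette are exactly those computed by the test suite and
the example code above — nothing here reflects real trial data.
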