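---
title: "Model and methods: AI support at the baseline lung-screening scan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: AI support at the baseline lung-screening scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcscreen)
```

## The decision problem

Low-dose CT (LDCT) lung cancer screening of high-risk smokers reduces lung
cancer mortality, but its value is limited by false positives (costly,
invasive follow-up of benign nodules) and false negatives (missed cancers
detected later, at worse stages). Deep-learning readers for the *baseline*
scan — the first screen, where no prior imaging exists — report substantially
better sensitivity and specificity than standalone radiologist reads. The
question this package answers is economic: per screened person, what do those
extra true negatives and true positives buy, and how much may the AI system
cost per screen before it stops being cost-effective?

The package re-implements a published decision-analytic model of this
question as a tested, reusable pipeline: a diagnostic decision tree feeding
an annual-cycle Markov cohort model, incremental cost-effectiveness analysis,
deterministic and probabilistic sensitivity analysis, and a threshold
analysis on the per-screen AI cost.

## Model structure

### Decision tree

A cohort of 60-year-old high-risk smokers with bronchial cancer (BC)
prevalence $p = 0.02635$ is screened once. A strategy is a (sensitivity,
specificity) pair plus acute per-screen costs:

| arm | sensitivity | specificity | screen cost | AI cost |
|-----|------------:|------------:|------------:|--------:|
| CT      | 0.779 | 0.877 | USD 161 | 0 |
| CT + AI | 0.977 | 0.984 | USD 161 | 0 (varied in the threshold analysis) |

`initial_distribution()` splits the cohort into TP $= p \cdot sens$,
FN $= p(1-sens)$, TN $= (1-p)\,spec$, FP $= (1-p)(1-spec)$.
`entry_states()` then resolves the transient "early detection" node within
cycle 0: 75% of true positives are resectable (one-time resection cost
USD 36,305, charged undiscounted at entry) and start in the first
post-resection year; the rest start palliative. False negatives enter the
undetected-BC tunnel, true negatives "no BC", false positives
"no BC, suspicious nodule".

### Markov states

Nine expanded states (`markov_states()`), annual cycles, ages
$60 \dots 60{+}t$ read from a life table:

* **no_bc** — background life-table mortality $q(a)$; utility 1; cost 0.
* **no_bc_suspicious** — the false-positive year: mortality
  $\min(1, q(a) + 0.001)$ (procedural excess from invasive diagnostics);
  survivors are verified benign (100%) and return to no_bc. The follow-up
  work-up (USD 2256) is charged once for this year, and the year is lived at
  utility 0.98.
* **undetected_y1..y3** — tunnel for missed cancers, utility 1 and cost 0 as
  specified by the source analysis (a documented faithfulness choice, however
  counterintuitive); background mortality only; surviving cancers are
  clinically detected with probability 0.15, 0.40, 1.00 in years 1, 2, 3.
  Detected cases resolve through the transient "delayed detection" node: 26%
  resectable (resection cost charged at that cycle, discounted), 74%
  palliative.
* **after_resection_y1 / later** — tunnel for the first post-resection year
  (utility 0.79) versus later years (0.933); annual cost USD 4283; *total*
  state mortality 4.7% per year (not added to the life table); recurrence
  9.8% per year among survivors moves to palliative — the state set offers no
  other recurrence-bearing destination.
* **palliative** — utility 0.63, cost USD 60,000/yr, total mortality 36%/yr.
* **dead** — absorbing, utility and cost 0.

Death is resolved first within a cycle; detection, verification and
recurrence apply to survivors. This event ordering is one of two implemented
options (see *Conventions* below).

### Accrual and discounting

Under the package default (`markov_convention()`): state membership during
cycle $t = 1..20$ accrues that state's annual cost and utility based on the
occupancy *after* the $t$-th transition, discounted by $(1+r)^{-t}$ with
$r = 0.03$; cycle-0 one-time costs (screen, AI, entry resections) are
undiscounted; no half-cycle correction; cycle 0 accrues no state rewards, so
an immortal, utility-1, undiscounted cohort accrues exactly
`horizon_cycles` QALYs. Because the suspicious-nodule state is never occupied
at an accrual point under this convention, its follow-up cost and the
0.02 utility decrement of the follow-up year are charged as one-off events to
the people who spent the year in it — the parameters act even though the
state occupancy at accrual points is zero.

## Conventions: the calibration grid

The source analysis was built in a commercial decision-tree package and does
not state its accrual conventions. Rather than guess silently, the engine
exposes them (`markov_convention()`), and `calibrate_conventions()` scores
every grid member against the published base case — primarily on the four
per-arm totals (the directly printed quantities), secondarily on the
increments —
(`reference_base_case()`: CT USD 4378.44 / 13.75 QALYs, CT+AI USD 4310.82 /
13.76 QALYs):

* accrual timing: end-of-cycle, start-of-cycle, or half-cycle average;
* cycle-0 accrual of state rewards: on/off;
* discount start: first payment discounted ($(1+r)^{-t}$) or not
  ($(1+r)^{-(t-1)}$);
* detection timing: at the cycle boundary (default), or at cycle start with
  the destination state's hazards applying within the detection year.

The winner — `replication_convention()` (end-of-cycle accrual, cycle-0
accrual **on**, discounting from cycle 0, default detection timing) — lands
all four per-arm totals inside tight bands of the published values with the
bundled life table: costs within 0.1%/3.0%, QALYs within 0.6%. These are the
values `scripts/acceptance.R` recomputes. The package default stays the
reference convention above, because the exact-limit invariants (QALY equals
horizon; the geometric closed form for an all-palliative cohort,
$\sum_t 0.63 \cdot 0.64^t$) hold only there.

### What cannot be reproduced, and why

The published totals imply increments of $\Delta C = -67.62$ USD and
$\Delta E = 0.0117$ QALY (the WTP-to-AI-cost table is affine with slope
$\Delta E$ and intercept $-\Delta C$, and its printed row confirms both). No
member of the convention grid reproduces them: across all combinations the
model yields $\Delta C \in [-292, +15]$ and $\Delta E \in [0.004, 0.009]$.
The binding constraint is the false-negative pathway as printed: with
undetected-BC mortality equal to the background life table and undetected
utility 1, a missed cancer loses only about 0.5 QALY and *costs more* than an
early-detected one (its delayed detection is mostly non-resectable, hence
palliative-care-heavy), whereas the published increments require a missed
cancer to be about 1.6 QALYs worse and about USD 31,000 cheaper. Bridging
that gap needs an un-printed structural choice (for instance undetected-BC
mortality near 0.18/yr), which we decline to invent. Consequently the
increment-dependent acceptance checks — the increments themselves, the AI
cost thresholds (published: USD 68 at ICER 0 and USD 1240 at WTP
100,000/QALY; this model: USD 197 and USD 678 under the replication
convention), and the upper end of the specificity robustness claim — fail and
are left failing, with the analysis above as the explanation. The qualitative
headline survives: CT+AI *dominates* CT in the base case under every
convention, and the dominance is robust to ±20% variation of sensitivities
and resectability probabilities.

## Sensitivity analyses

**Tornado (one-way DSA).** `one_way()` re-runs both arms with one parameter
at its low/high value; `tornado()` does this for every continuous parameter
over ±20% relative ranges (clamped to validity ranges; the published
"wide ranges" are not quantified, so the width is explicit and overridable).
Dominant/dominated outcomes are reported as classifications; the signed
ratio is retained only for ranking and plotting.

**Threshold analysis.** The AI cost enters only the cycle-0 acute cost of
the CT+AI arm, so the ICER is affine in it and
`threshold_ai_cost(target)` solves $c^\* = target \cdot \Delta E - \Delta
C_0$ in closed form, cross-checked by bisection on the full model to
USD 0.01. `wtp_cost_table()` applies this across WTP values; its affinity
(residuals $\le$ USD 0.01 against a two-point line, slope $= \Delta E$) is a
tested invariant.

**PSA.** The source analysis ran 30,000 Monte Carlo iterations but states
neither distribution families nor dispersions. Defaults here, chosen once:
beta for probabilities and utilities, gamma for costs, moment-matched with a
10% relative standard error; degenerate means (0 or 1) stay fixed; the two
arms share all cohort parameters per iteration and draw their four
performance parameters independently. All draws are generated up-front from
one seed, so results are order-independent and bit-reproducible; out-of-range
draws are redrawn and counted. One documented consequence: about 6–7% of
iterations are cost-saving but QALY-losing (the CT sensitivity draw can
exceed the CT+AI draw), so the acceptability curve `ceac()` *declines*
slightly with WTP — a monotone CEAC would require the QALY increment to be
almost surely positive, which independent performance sampling does not give.

## Life tables and synthetic data

Background mortality comes from a CSV life table (`load_life_table()`,
columns `age,qx`, integer-age lookup, no interpolation, unisex — the
screened cohort pools sexes and no smoker-specific uplift is applied since
none is stated). The bundled fixture (`default_life_table()`) is
**synthetic**: a log-linear (Gompertz-type) interpolation through
US-magnitude anchor values at five-year ages 55–85 (q(60) = 0.01136 rising
to q(85) = 0.09826), standing in for a published national table and
swappable by the user; every reproduction figure quoted above depends on it.

`make_life_table()` generates flat or Gompertz tables for tests
(flat $q$ gives exact geometric survival; $q \equiv 0$ the immortal limit).
`perturb_parameters()` produces fuzzed but valid parameter sets.
`microsimulate()` is the independent oracle for the cohort engine: a
vectorised per-patient random walk through the same decision tree and
transition rows, accruing the same discounted rewards; the acceptance suite
checks 200,000-patient agreement with the cohort totals within three Monte
Carlo standard errors for the base case and twenty perturbed scenarios. What
passing these tests shows is internal consistency of the two engines and the
generators' invariants — not external validity of the clinical inputs, which
are taken as given.

## Numerical choices and problem sizes

Transition rows are validated to sum to 1 within $10^{-12}$, cycle occupancy
within $10^{-10}$; the dead fraction must be non-decreasing. Ties and
degenerate inputs: a zero discount rate disables discounting exactly;
`detection_schedule` must end in 1 so the undetected tunnel drains; a
perfect test with zero prevalence reduces the model to a pure survival
annuity (tested in closed form). The test suite runs the PSA at the full
30,000 iterations (about 1.5 minutes) and the microsimulation oracle at
200,000 patients per scenario (about 0.5 s each); unit tests use smaller
sizes chosen for sub-second feedback.

## Known limitations

* Single baseline screen only — no annual repeat screening, no stage-shift
  modelling, no per-sex stratification, no Lung-RADS categories (the test is
  binary), and no EVPI or correlated-PSA machinery.
* The undetected-BC state uses background mortality and utility 1 as
  printed; both are clinically generous to late detection and are the main
  reason the published increments cannot be matched (see above).
* The bundled life table is synthetic; users reproducing jurisdiction-
  specific results should supply their own table via `--life-table` /
  `load_life_table()`.
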