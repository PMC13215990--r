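---
title: "Methods: the caries system-dynamics cost-effectiveness model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the caries system-dynamics cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cariescea)
```

## The model and its assumptions

`cariescea` simulates dental caries progression in a closed cohort of Thai
schoolchildren (678,243 children, the 2021 birth cohort) from age 6 to age
12 with a discrete-time stock-and-flow model. Five stocks partition the
cohort — caries-free, untreated caries, filled, endodontically treated,
and missing teeth — and six annual fractions drive the flows between them:
caries incidence out of the caries-free stock; filling, endodontic and
extraction uptake out of the untreated stock; and recurrence out of the
two restored stocks back into untreated caries. Recurrence is the model's
reinforcing feedback: treated teeth can decay again, be re-treated, and
re-enter the cost stream.

Structural assumptions worth stating plainly:

* **Closed cohort.** No entry, exit, or mortality; the five stocks sum to
  the cohort size at every step. This is enforced exactly by the flow
  bookkeeping and checked to 1e-6 relative tolerance in the tests.
* **Homogeneous population.** No age-, region- or risk-stratification;
  fractions are constant over the six years.
* **One-way severity.** Children never return to the caries-free stock;
  "caries-free at 12" therefore means never having left that stock, which
  is the effectiveness measure used throughout.
* **Simultaneous flows.** All flows in a step are computed from the
  time-*t* state (standard stock-flow semantics), which makes the update
  order-independent. A consequence used below: treatment flows lag
  incidence by one step.
* **Extraction is absorbing**; the missing-teeth stock only grows.

The time step defaults to `dt = 1` year, matching the annual resolution of
every published figure for these programmes. The step is forward Euler, so
fractions are per-step transfer proportions rather than continuous-time
hazards; `dt` is configurable (the conservation and decay properties are
tested at `dt = 0.5` too), but all shipped results use the annual step.
Whether the original implementation behind the published aggregates used
a finer internal step is not verifiable from those aggregates.

## Interventions

A programme with per-child effectiveness `e` and cohort coverage `c`
multiplies the incidence fraction by `1 − e·c` (coverage-adjusted
effectiveness: 9.5% for supervised toothbrushing, 15.66% — printed 15.7% —
for sealant). Only the incidence fraction is modified; treatment uptake
and recurrence are intervention-invariant. Effectiveness and coverage are
constant over the six programme years (no waning), matching the constant
annual programme cost in the published accounts.

`intervention()` accepts an `onset_lag` (years before the reduction takes
effect). Its default is 0: because treatment flows respond to the
*previous* step's untreated stock, an immediately effective programme
already produces treatment costs identical to the base case at ages 6–7
and diverging from age 8, which is exactly the pattern in the published
cost table. A positive lag delays the divergence by the same amount; we
found no configuration in which a positive lag improved the overall fit
(calibration deviance is ~15× worse at lag 2 than lag 0), so the lag is
retained purely as a scenario knob.

## Costing

Treatment costs value the *cumulative* counters of delivered fillings,
endodontic treatments and extractions at per-child unit costs (2024 THB:
360.1, 1839.4, 133.6 on average). Counters rather than stock levels are
used because recurrence drains the restored stocks while the published
treatment-cost trajectories are monotone increasing, and because
re-treatment after recurrence is a real repeated expense. Programme cost
is `unit cost × coverage × cohort` per year (57.6 THB/child/yr STB, 203.5
sealant), and the total cost at age *t* adds **one** annual programme cost
to the cumulative treatment cost — not the six-year accumulated programme
spend. That convention is economically unusual but is what the published
total-cost arithmetic does (e.g. 37,113,500 + 67,478,000 = 104,591,500 at
age 12), and we adopt it verbatim so results are comparable.

Unit costs were synthesised from Thai costing studies as unweighted
mean/min/max after rescaling to 2024 prices with the Thai CPI
(`cpi_adjust()`, base 2019 = 100); the CPI series itself is user-supplied
configuration, since only the adjustment rule, not the index values, is
fixed by the method. An optional annual discount rate (default 0 — no
published result is discounted) deflates both cost components. A helper
`display_round()` reproduces the 6-significant-figure display convention
of the published tables; all internal arithmetic is full precision and
rounding happens only at presentation.

USD companions use a configurable exchange rate defaulting to 32 THB/USD,
the ratio implied by every published THB/USD pair; USD output is
presentational only.

## CEA and sensitivity analysis

`cer()` is total cost per caries-free child; `icer()` is the incremental
ratio against a comparator and returns `NA` when the effectiveness
difference is zero (undefined, printed as NA), never an error. Negative
ICERs are reported together with their cost-effectiveness-plane quadrant
(`cea_quadrant()`): dominant, dominated, trade-off, or
cost-saving-less-effective. The evaluation horizon is fixed at age 12.

The deterministic multi-way sensitivity analysis crosses coverage
(current/max), effectiveness (min/max) and unit costs (min/max) in the
standard 2×2×2 row order. Two conventions matter for reproducing the
published grids: the min/max unit-cost level applies to **all five** unit
costs simultaneously (treatments and programme), and the base-case
comparator always keeps mean unit costs and zero programme cost, so its
total cost is identical in every row. STB's current coverage already
equals the national target, so its grid rows 1–4 duplicate rows 5–8 — a
structural identity used as a test. Scenario 7 (max coverage, max
effectiveness, min costs) is the best case and scenario 2 the worst;
`compare_best_worst()` crosses them between programmes. For the STB best
case the published record itself prints two variants of the same CER
(333.1 and 332.9 in different tables); the package computes at full
precision and reports its own value rather than forcing either printing.

## Calibration: reconstructing unpublished parameters

The flow fractions and initial stocks behind the published aggregates were
never released, so the shipped configuration is *calibrated*, not copied.
`calibrate_sdm()` minimises weighted squared relative errors with
Levenberg–Marquardt (`minpack.lm`) over a 13-dimensional parameter vector:
the six fractions, the initial stock composition, and the initial
cumulative counters (the published age-6 treatment cost is nonzero, so the
cohort enters with treatment history). Parameters are transformed to an
unconstrained scale — logits for single fractions, stick-breaking for the
treatment-uptake triple (so `p_f + p_e + p_x ≤ 1` by construction) and for
the stock composition (so conservation holds by construction), bounded
shares for the counters — which keeps every Levenberg–Marquardt iterate
feasible without penalties. The start point is fixed and documented
(`cariescea:::.default_start`), so the fit is deterministic; there is no
stochastic search. The identifiable single-parameter case (only the
incidence fraction free, everyone initially caries-free) is solved by
bisection on the monotone map from fraction to final caries-free count and
agrees with the closed form `1 − (target/cohort)^(1/6)` to 1e-8.

Targets (`cohort_targets()`): the caries-free population at age 12 for the
three scenarios; the treatment-cost trajectory at mean unit costs for the
three scenarios (7 ages each); and the twelve distinct age-12 totals from
the published sensitivity grids. The last group does real identification
work: valuing the same cumulative counters at three different price
vectors (min/mean/max) pins down the split of treatment volume across
filling, endodontic treatment and extraction, which the mean-cost
trajectory alone leaves undetermined. Caries-free targets carry weight 8
(chosen a priori so that the 3 caries-free targets and the 21+ cost points
have comparable aggregate influence); cost points carry weight 1.

The fit residuals are part of the package's claims: all 37 targets are
reproduced within 0.3% relative (caries-free populations within 0.3%,
every cost target within 0.07%), and the test suite asserts these
tolerances. Residual directions are not random — see the limitations
below. Some parameter combinations remain under-determined even with the
extended targets (the optimiser moves on a near-flat manifold trading
recurrence against initial-stock composition at essentially constant
deviance), so the shipped parameter values are one member of a family of
solutions that reproduce the aggregates; they should not be read as
estimates of the true Thai flow rates.

## The synthetic-parameter generator

`synthetic_flow_params()` stands in for the unavailable true parameter
file in property tests: it draws the six fractions uniformly within
documented ranges (incidence 0.05–0.30; each treatment fraction up to
0.3–0.5; recurrence up to 0.3 — spanning the plausible neighbourhood of
the calibrated values), rejecting draws whose treatment fractions sum
above 1, and splits the cohort into a random initial composition with a
60–100% caries-free share. Draws are a pure function of the seed. The
generator emulates the *structure* of realistic parameter sets —
invariants, conservation, magnitudes — not their empirical joint
distribution: real uptake fractions are correlated with incidence and
with service capacity in ways no uniform draw captures. Passing the
property suite therefore demonstrates correctness of the mechanics
(conservation, monotonicity, zero-effect equivalence, closed-form decay,
calibration self-consistency) on a broad parameter family, not validity
of any particular parameter set for Thailand.

Problem sizes used by the tests and the acceptance script — 200–1,000
generator draws for the conservation properties, one 37-target
calibration for parameter recovery — were chosen as the smallest sizes at
which the properties are convincingly exercised.

## Numerical choices

* Conservation tolerance 1e-6 relative (floating accumulation over 6
  steps is ~1e-16; the slack is intentional headroom).
* Closed-form decay comparison at 1e-9 relative.
* A step that would drive any stock negative (outflow fractions summing
  above 1 for the realised `dt`) is an **error**, not a clip: silent
  clipping would mask mis-calibration.
* Relative-error denominators in calibration are floored at a thousandth
  of the largest target in their group, so an exactly-zero observed value
  (a synthetic cohort entering with empty counters) cannot produce an
  infinite residual.
* Zero-valued recurrence and treatment fractions are ordinary parameter
  values, not special cases; the all-zero flow vector is a fixed point and
  is tested as such.
* `icer()` with equal effectiveness returns `NA` (undefined) by design;
  `cer()` with non-positive effectiveness is an error because a CER has no
  meaning there.

## Known limitations

* **The published aggregates are not exactly attainable in this model
  class, and the package does not pretend otherwise.** Two structural
  bounds matter. First, the age-12 treatment-cost savings implied by the
  published cost table have a sealant:STB ratio of 1.59, but with a
  multiplicative incidence reduction every year's incidence deficit is
  proportional to the coverage-adjusted effectiveness, so any weighting of
  years gives a model ratio of at least 0.1566/0.095 ≈ 1.65; the three
  year-12 totals therefore cannot all be matched to 6-significant-figure
  display precision, only to ~0.07%. Second, the published caries-free
  gains (+10.2% STB, +16.4% sealant) are likewise jointly outside the
  reachable set of per-year multiplicative reductions at 9.5%/15.66%,
  which is why the caries-free residuals sit at ~0.3% rather than zero.
  Both gaps presumably reflect additional structure in the original
  (unpublished) implementation.
* Calibration is local least squares from a fixed start; it is
  deterministic but not guaranteed globally optimal, and the recovered
  parameter vector is one of a near-equivalent family.
* No QALYs/DALYs, no willingness-to-pay threshold, no probabilistic
  sensitivity analysis — the analysis mirrors the deterministic
  multi-way design of the source programmes' evaluation.
* Provider perspective only; no patient travel or productivity costs; no
  socioeconomic or behavioural heterogeneity; sealant retention/failure
  over time is not modelled (the multiplicative formula is used exactly).

```{r example}
fx <- reproduction_fixture()
run_cea(fx)
```
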