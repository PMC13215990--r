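# cariescea

Cost-effectiveness analysis of school-based dental caries prevention in
Thailand, built on a system-dynamics (stock-and-flow) simulation of caries
progression in a closed cohort of 678,243 children followed from age 6 to
age 12.

The package is for health-economics and dental-public-health analysts who
want a tested, configuration-driven implementation of the full pipeline:
compartmental disease simulation, provider-perspective costing,
cost-effectiveness ratios with dominance classification, deterministic
multi-way sensitivity analysis, and calibration of the model's flow
parameters to published aggregate outcomes.

## The model

Children occupy one of five stocks: caries-free `S`, untreated caries `C`,
filled `F`, endodontically treated `E`, and missing teeth (extraction) `M`.
Per year (forward Euler, all flows computed simultaneously from the current
state):

```
new caries       = f · S          (caries-incidence fraction f)
fillings         = p_f · C
endodontic       = p_e · C        (p_f + p_e + p_x ≤ 1)
extractions      = p_x · C
recurrent caries = r_F · F + r_E · E   (returns to C; reinforcing loops)
```

The five stocks always sum to the cohort size (closed cohort). Cumulative
counters of fillings, endodontic treatments and extractions — incremented
again on re-treatment after recurrence — drive treatment costs.

A preventive programme with effectiveness `e` and coverage `c` lowers the
incidence fraction multiplicatively by its coverage-adjusted effectiveness:
`f → f · (1 − e·c)`. The national supervised-toothbrushing programme (STB)
has `e` = 10%, `c` = 95% (adjusted 9.5%); the sealant programme has
`e` = 58%, `c` = 27% (adjusted 15.7%).

Costs (2024 Thai baht, provider perspective): an annual programme cost
`unit cost × c × population` plus the cumulative treatment cost
`u_fill·cumF + u_endo·cumE + u_extr·cumX`. Cost-effectiveness at age 12
uses the caries-free population as the effectiveness measure:

```
CER  = total cost / caries-free children
ICER = Δ total cost / Δ caries-free children   (vs a comparator)
```

with the usual dominance quadrants (a strategy that is more effective and
less costly than its comparator is *dominant*).

## Worked example

```r
library(cariescea)

fx <- reproduction_fixture()   # shipped calibrated configuration
run_cea(fx)
```

```
Cost-effectiveness at evaluation horizon (THB; USD at 32 THB/USD)
 scenario  total_cost caries_free           cer icer_vs_base     head_to_head
     base  68,865,700     176,925 389.2 (12.16)            -                -
      stb 104,635,000     194,127 539.0 (16.84)       2079.3                -
  sealant 103,887,000     206,009 504.3 (15.76)       1204.1 -63.0 [dominant]
```

Reading: without intervention, 176,925 of the 678,243 children are still
caries-free at age 12 and treatment costs total 68.9 million THB. STB and
sealant each add roughly 17,000–29,000 caries-free children at ~104 million
THB total cost, so both are more effective *and* more costly than doing
nothing (a trade-off). Head to head, sealant yields more caries-free
children at slightly lower total cost than STB — the negative ICER flags it
as dominant (cost-saving).

The multi-way sensitivity analysis varies coverage, effectiveness and all
five unit costs over a 2×2×2 grid per programme:

```r
sens <- run_sensitivity(fx$config, fx$interventions$sealant,
                        cost_ranges = fx$unit_cost_ranges)
compare_best_worst(run_sensitivity(fx$config, fx$interventions$stb,
                                   cost_ranges = fx$unit_cost_ranges), sens)
```

Calibration itself is exposed through `calibrate_sdm()`, which fits the
flow fractions and initial stocks to aggregate targets
(`cohort_targets()`) by Levenberg–Marquardt on relative errors, and
supports `coef()`, `summary()`, `residuals()`, `predict()`, `plot()` and
`simulate()`. The shipped configuration was produced exactly this way; the
original flow parameters behind the published tables were never released,
so the fixture is a constrained reconstruction (see the methods vignette
for its documented residuals and the parts of the published tables that no
model of this class can reproduce exactly).

A thin command-line wrapper is installed at `inst/cli/cariescea`:

```sh
Rscript inst/cli/cariescea simulate --config inst/extdata/calibrated_config.yaml \
        --scenario stb --out results/
```

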