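# Quality contract of the shipped calibrated configuration: it is a
# constrained reconstruction (the original parameter file was never
# published), so it is held to documented tolerances, not to exact
# replication of the source tables.

fx <- reproduction_fixture()

test_that("the fixture reproduces the caries-free populations to 0.3%", {
  published <- c(base = 176722, stb = 194701, sealant = 205642)
  for (nm in names(published)) {
    spec <- if (nm == "base") NULL else fx$interventions[[nm]]
    traj <- sdm_simulate(fx$config, spec)
    expect_equal(tail(traj$caries_free, 1), published[[nm]],
                 tolerance = 3e-3, ignore_attr = TRUE)
  }
})

test_that("the fixture reproduces every treatment-cost trajectory to 0.2%", {
  published <- cohort_targets()$treatment_cost
  uc <- unit_costs("mean", fx$unit_cost_ranges)
  for (nm in c("base", "stb", "sealant")) {
    spec <- if (nm == "base") NULL else fx$interventions[[nm]]
    traj <- sdm_simulate(fx$config, spec)
    expect_equal(treatment_cost(traj, uc), published[[nm]],
                 tolerance = 2e-3, ignore_attr = TRUE)
  }
})

test_that("the fixture reproduces the sensitivity-scenario totals to 0.2%", {
  sc <- cohort_targets()$scenario_costs
  for (i in seq_len(nrow(sc))) {
    spec <- intervention(sc$intervention[i], sc$effectiveness[i],
                         sc$coverage[i],
                         onset_lag = fx$interventions[[sc$intervention[i]]]$onset_lag)
    traj <- sdm_simulate(fx$config, spec)
    uc <- unit_costs(sc$cost_level[i], fx$unit_cost_ranges)
    total <- intervention_cost(spec, fx$config$total_population,
                               unit_cost = uc[[spec$name]]) +
      treatment_cost(traj[nrow(traj), ], uc)
    expect_equal(total, sc$total_cost[i], tolerance = 2e-3)
  }
})

test_that("zeroing effectiveness collapses both programmes onto the base", {
  base <- sdm_simulate(fx$config)
  for (nm in c("stb", "sealant")) {
    spec <- fx$interventions[[nm]]
    spec$effectiveness <- 0
    traj <- sdm_simulate(fx$config, spec)
    expect_identical(as.matrix(as.data.frame(traj)),
                     as.matrix(as.data.frame(base)))
  }
})

test_that("the fixture CEA ranks the programmes as published", {
  tab <- run_cea(fx)
  expect_equal(tab$scenario, c("base", "stb", "sealant"))
  # sealant dominates STB; both trade off against the base case
  expect_equal(tab$quadrant_vs_previous[3], "dominant")
  expect_equal(tab$quadrant_vs_base[2:3], rep("trade-off", 2))
  expect_true(tab$cer[3] < tab$cer[2])   # sealant is the more efficient
  expect_true(tab$cer[1] < tab$cer[3])   # base case has the lowest CER
})
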