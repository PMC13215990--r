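test_that("the grid enumerates the 2x2x2 levels in table order", {
  grid <- sensitivity_grid(default_interventions()$sealant)
  expect_equal(nrow(grid), 8)
  expect_equal(grid$scenario, 1:8)
  expect_equal(grid$coverage_level,
               rep(c("current", "max"), each = 4))
  expect_equal(grid$effectiveness_level,
               rep(rep(c("min", "max"), each = 2), 2))
  expect_equal(grid$unit_cost_level, rep(c("min", "max"), 4))
  # scenario 7 is the best case: max coverage, max effectiveness, min costs
  expect_equal(grid$coverage[7], 0.472)
  expect_equal(grid$effectiveness[7], 0.82)
  expect_equal(grid$unit_cost_level[7], "min")
  expect_error(sensitivity_grid(default_interventions()$stb,
                                ranges = list(coverage = c(current = 0.95))),
               "incomplete")
})

fx <- reproduction_fixture()
res_stb <- run_sensitivity(fx$config, fx$interventions$stb)
res_seal <- run_sensitivity(fx$config, fx$interventions$sealant)

test_that("STB rows 1-4 duplicate rows 5-8 (current coverage = target)", {
  top <- res_stb[1:4, c("total_cost", "caries_free", "cer", "icer_vs_base")]
  bottom <- res_stb[5:8, c("total_cost", "caries_free", "cer",
                           "icer_vs_base")]
  expect_equal(top, bottom, ignore_attr = TRUE)
})

test_that("zero-effectiveness scenarios tie the base case and print NA", {
  zero <- res_stb[res_stb$effectiveness_level == "min" &
                  !is.na(res_stb$scenario), ]
  base_cf <- res_stb$caries_free[is.na(res_stb$scenario)]
  expect_equal(zero$caries_free, rep(base_cf, 4))
  expect_true(all(is.na(zero$icer_vs_base)))
})

test_that("raising unit costs raises cost and CER but not effectiveness", {
  for (res in list(res_stb, res_seal)) {
    grid <- res[!is.na(res$scenario), ]
    for (cov in unique(grid$coverage_level))
      for (eff in unique(grid$effectiveness_level)) {
        lo <- grid[grid$coverage_level == cov &
                   grid$effectiveness_level == eff &
                   grid$unit_cost_level == "min", ]
        hi <- grid[grid$coverage_level == cov &
                   grid$effectiveness_level == eff &
                   grid$unit_cost_level == "max", ]
        expect_lt(lo$total_cost, hi$total_cost)
        expect_lt(lo$cer, hi$cer)
        expect_equal(lo$caries_free, hi$caries_free)
      }
  }
})

test_that("higher effectiveness never reduces the caries-free population", {
  grid <- res_seal[!is.na(res_seal$scenario), ]
  for (cov in unique(grid$coverage_level)) {
    lo <- grid[grid$coverage_level == cov &
               grid$effectiveness_level == "min", "caries_free"]
    hi <- grid[grid$coverage_level == cov &
               grid$effectiveness_level == "max", "caries_free"]
    expect_true(all(hi >= lo))
  }
})

test_that("the base comparator keeps mean unit costs in every row", {
  # base total cost is the same whatever cost level the scenario uses
  expect_equal(res_stb$total_cost[is.na(res_stb$scenario)],
               res_seal$total_cost[is.na(res_seal$scenario)])
  base_cost <- res_stb$total_cost[is.na(res_stb$scenario)]
  traj <- sdm_simulate(fx$config)
  expect_equal(base_cost,
               tail(cost_trajectory(traj, NULL,
                                    unit_costs("mean",
                                               fx$unit_cost_ranges))$total_cost,
                    1))
})

test_that("best/worst cross-comparison yields the four pairings", {
  cmp <- compare_best_worst(res_stb, res_seal)
  expect_equal(nrow(cmp), 4)
  expect_equal(cmp$comparison,
               c("best/worst", "best/best", "worst/worst", "worst/best"))
  # sealant's best case beats STB's worst case outright
  expect_equal(cmp$quadrant[cmp$comparison == "worst/best"], "dominant")
  # identical arms give an undefined ICER
  self <- compare_best_worst(res_stb, res_stb, best = 3, worst = 3)
  expect_true(all(is.na(self$icer)))
})
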