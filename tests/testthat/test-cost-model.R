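test_that("CPI adjustment follows the index ratio", {
  cpi <- c("2018" = 100, "2020" = 125, "2024" = 112)
  expect_equal(cpi_adjust(100, 2018, cpi), 112)
  expect_equal(cpi_adjust(50, 2020, c("2020" = 125, "2024" = 100)), 40)
  expect_equal(cpi_adjust(77, 2024, cpi), 77)  # same year: unchanged
  expect_error(cpi_adjust(100, 2019, cpi), "2019")
})

test_that("unit-cost synthesis is mean/min/max", {
  expect_equal(summarize_costs(10), c(mean = 10, min = 10, max = 10))
  expect_equal(summarize_costs(c(1, 2, 3)), c(mean = 2, min = 1, max = 3))
  expect_equal(summarize_costs(c(270.2, 471.5)),
               c(mean = 370.85, min = 270.2, max = 471.5))
  expect_error(summarize_costs(numeric(0)), "no cost estimates")
})

test_that("programme costs reproduce the published annual amounts", {
  ivs <- default_interventions()
  expect_equal(display_round(intervention_cost(ivs$stb, 678243)), 37113500)
  expect_equal(display_round(intervention_cost(ivs$sealant, 678243)),
               37266100)
  expect_equal(intervention_cost(ivs$base, 678243), 0)
})

test_that("treatment cost values cumulative counters at unit costs", {
  uc <- unit_costs()
  s0 <- caries_stocks(caries_free = 100)
  expect_equal(treatment_cost(s0, uc), 0)
  s1 <- caries_stocks(caries_free = 100, cum_fillings = 100)
  expect_equal(treatment_cost(s1, uc), 36010)
  s2 <- caries_stocks(caries_free = 100, cum_fillings = 1000,
                      cum_endodontic = 100, cum_extractions = 50)
  expect_equal(treatment_cost(s2, uc), 360100 + 183940 + 6680)  # 550720
})

test_that("cost breakdown is additive and treatment cost is monotone", {
  cfg <- mixed_config()
  spec <- intervention("stb", 0.10, 0.95, unit_cost = 57.6)
  costs <- cost_trajectory(sdm_simulate(cfg, spec), spec)
  expect_equal(costs$total_cost,
               costs$intervention_cost + costs$treatment_cost)
  expect_true(all(diff(costs$treatment_cost) >= 0))
  # programme cost is a constant annual amount, not an accumulation
  expect_equal(costs$intervention_cost,
               rep(costs$intervention_cost[1], nrow(costs)))
})

test_that("costs scale linearly in the unit costs", {
  cfg <- mixed_config()
  traj <- sdm_simulate(cfg)
  ranges <- unit_cost_ranges()
  scaled <- ranges
  scaled[, c("mean", "min", "max")] <- 3 * scaled[, c("mean", "min", "max")]
  expect_equal(cost_trajectory(traj, NULL, unit_costs("mean", scaled))$total_cost,
               3 * cost_trajectory(traj, NULL, unit_costs())$total_cost)
})

test_that("base-case total cost equals its treatment cost", {
  fx <- reproduction_fixture()
  costs <- cost_trajectory(sdm_simulate(fx$config), NULL)
  expect_equal(costs$total_cost, costs$treatment_cost)
})

test_that("currency conversion divides by the exchange rate", {
  expect_equal(thb_to_usd(1985.3), 62.04, tolerance = 1e-4)
  expect_equal(thb_to_usd(505.3), 15.79, tolerance = 1e-3)
  expect_equal(thb_to_usd(0), 0)
  expect_error(thb_to_usd(100, rate = 0), "positive")
})

test_that("display rounding keeps 6 significant figures", {
  expect_equal(display_round(37113457), 37113500)
  expect_equal(display_round(68898123), 68898100)
})

test_that("an optional discount rate deflates later years only", {
  cfg <- mixed_config()
  cfg$discount_rate <- 0.03
  traj <- sdm_simulate(cfg)
  disc <- cost_trajectory(traj, NULL)
  undisc <- cost_trajectory(sdm_simulate(mixed_config()), NULL)
  expect_equal(disc$total_cost[1], undisc$total_cost[1])
  expect_equal(disc$total_cost[-1],
               undisc$total_cost[-1] * 1.03^-(1:6))
})
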