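test_that("all-zero fractions leave the state unchanged", {
  s <- mixed_config()$initial_stocks
  expect_equal(unclass(sdm_step(s, flow_fractions())), unclass(s))
  traj <- sdm_simulate(sdm_config(total_population = 1e5,
                                  initial_stocks = s,
                                  fractions = flow_fractions()))
  for (i in seq_len(nrow(traj)))
    expect_equal(unlist(traj[i, -1]), unclass(s), ignore_attr = TRUE)
})

test_that("population is conserved by every step, whatever the flows", {
  cfg <- mixed_config()
  traj <- sdm_simulate(cfg)
  expect_equal(pop_total(traj), rep(1e5, nrow(traj)), tolerance = 1e-9)
})

test_that("single-flow simulation matches the geometric closed form", {
  # independent oracle: pure exponential decay of the caries-free stock
  cfg <- pure_decay_config(f = 0.2008)
  traj <- sdm_simulate(cfg)
  expect_equal(nrow(traj), 7)
  closed_form <- 678243 * (1 - 0.2008)^(0:6)
  expect_equal(traj$caries_free, closed_form, tolerance = 1e-9)
  expect_equal(tail(traj$caries_free, 1), 176733.2, tolerance = 1e-6)
  # the flow leaving caries-free arrives, untouched, in untreated caries
  expect_equal(traj$caries_untreated, 678243 - closed_form, tolerance = 1e-9)
})

test_that("without recurrence, caries-free declines and missing grows", {
  cfg <- mixed_config()
  cfg$fractions[["recur_filled_fraction"]] <- 0
  cfg$fractions[["recur_endo_fraction"]] <- 0
  traj <- sdm_simulate(cfg)
  expect_true(all(diff(traj$caries_free) <= 0))
  expect_true(all(diff(traj$missing) >= 0))
})

test_that("cumulative treatment counters never decrease", {
  traj <- sdm_simulate(mixed_config())
  for (col in c("cum_fillings", "cum_endodontic", "cum_extractions"))
    expect_true(all(diff(traj[[col]]) >= 0), info = col)
})

test_that("step rejects flows that would overdraw a stock", {
  s <- caries_stocks(caries_free = 100, caries_untreated = 50)
  f <- flow_fractions(caries_fraction = 0.8)
  expect_error(sdm_step(s, f, dt = 2), "negative stock")
  expect_error(flow_fractions(fill_fraction = 0.6, endo_fraction = 0.5),
               "sum to")
  expect_error(flow_fractions(caries_fraction = 1.2), "\\[0, 1\\]")
})

test_that("simulate reports the age at which a step fails", {
  cfg <- sdm_config(total_population = 150,
                    initial_stocks = caries_stocks(caries_free = 100,
                                                   caries_untreated = 50),
                    fractions = flow_fractions(caries_fraction = 0.7),
                    dt = 2, start_age = 6, end_age = 12)
  expect_error(sdm_simulate(cfg), "at age")
})

test_that("configuration invariants are enforced", {
  s <- caries_stocks(caries_free = 100)
  f <- flow_fractions()
  expect_error(sdm_config(total_population = 99, initial_stocks = s,
                          fractions = f), "total_population")
  expect_error(sdm_config(total_population = 100, start_age = 6,
                          end_age = 12, dt = 0.7, initial_stocks = s,
                          fractions = f), "evenly")
  expect_error(caries_stocks(caries_free = -5), "negative")
  expect_silent(sdm_config(total_population = 100, initial_stocks = s,
                           fractions = f, dt = 0.5))
})

test_that("a finer time step yields more records and keeps conservation", {
  cfg <- mixed_config()
  cfg$dt <- 0.5
  traj <- sdm_simulate(cfg)
  expect_equal(nrow(traj), 13)
  expect_equal(pop_total(traj), rep(1e5, 13), tolerance = 1e-9)
})

test_that("conservation holds across many random synthetic parameter sets", {
  draws <- synthetic_flow_params(n = 200, seed = 20260927)
  for (d in draws) {
    cfg <- sdm_config(total_population = 678243,
                      initial_stocks = d$initial_stocks,
                      fractions = d$fractions)
    traj <- sdm_simulate(cfg)
    expect_equal(pop_total(traj), rep(678243, nrow(traj)),
                 tolerance = 1e-6)
  }
})
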