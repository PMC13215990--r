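test_that("single-parameter calibration matches the closed-form solution", {
  fit <- calibrate_sdm(cohort_targets(caries_free = c(base = 176722),
                                      treatment_cost = NULL,
                                      scenario_costs = NULL),
                       free = "caries_fraction")
  # oracle: solve 678243 * (1 - f)^6 = 176722 analytically
  f_star <- 1 - (176722 / 678243)^(1 / 6)
  expect_equal(coef(fit)[["caries_fraction"]], f_star, tolerance = 1e-8)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-7)
})

test_that("a target equal to the initial state needs no flows", {
  fit <- calibrate_sdm(cohort_targets(caries_free = c(base = 678243 - 1e-6),
                                      treatment_cost = NULL,
                                      scenario_costs = NULL),
                       free = "caries_fraction")
  expect_equal(coef(fit)[["caries_fraction"]], 0, tolerance = 1e-7)
})

test_that("infeasible targets are rejected", {
  expect_error(
    calibrate_sdm(cohort_targets(caries_free = c(base = 7e5),
                                 treatment_cost = NULL,
                                 scenario_costs = NULL),
                  free = "caries_fraction"),
    "infeasible")
})

test_that("synthetic parameter draws are a pure function of the seed", {
  a <- synthetic_flow_params(seed = 42)
  b <- synthetic_flow_params(seed = 42)
  expect_identical(a$fractions, b$fractions)
  expect_identical(a$initial_stocks, b$initial_stocks)
  c <- synthetic_flow_params(seed = 43)
  expect_false(identical(a$fractions, c$fractions))
})

test_that("collapsed ranges return exactly the collapsed values", {
  ranges <- lapply(c(caries_fraction = 0.2, fill_fraction = 0.3,
                     endo_fraction = 0.1, extract_fraction = 0.05,
                     recur_filled_fraction = 0.12,
                     recur_endo_fraction = 0.07),
                   function(v) c(v, v))
  p <- synthetic_flow_params(seed = 1, ranges = ranges)
  expect_equal(unclass(p$fractions),
               vapply(ranges, `[`, numeric(1), 1), ignore_attr = TRUE)
})

test_that("every draw satisfies the outflow and conservation invariants", {
  draws <- synthetic_flow_params(n = 1000, seed = 7)
  sums <- vapply(draws, function(d)
    sum(unclass(d$fractions)[c("fill_fraction", "endo_fraction",
                               "extract_fraction")]), numeric(1))
  expect_true(all(sums <= 1))
  pops <- vapply(draws, function(d)
    sum(unclass(d$initial_stocks)[1:5]), numeric(1))
  expect_equal(pops, rep(678243, 1000), tolerance = 1e-9)
})

test_that("impossible sampling ranges are rejected", {
  bad <- synthetic_param_ranges()
  bad$caries_fraction <- c(0.5, 0.2)
  expect_error(synthetic_flow_params(seed = 1, ranges = bad), "impossible")
  bad2 <- synthetic_param_ranges()
  bad2$fill_fraction <- c(0.5, 0.5)
  bad2$endo_fraction <- c(0.4, 0.4)
  bad2$extract_fraction <- c(0.3, 0.3)
  expect_error(synthetic_flow_params(seed = 1, ranges = bad2),
               "unavoidable")
})

test_that("calibration recovers known synthetic parameters", {
  rec <- synthetic_recovery_fit(seed = 314)
  got <- coef(rec$fit)[names(unclass(rec$truth$fractions))]
  expect_equal(unname(got), unname(unclass(rec$truth$fractions)),
               tolerance = 0.01)
  # the fit itself reproduces the targets it was given
  expect_lt(max(abs(residuals(rec$fit))), 1e-3)
})

test_that("the full calibration is deterministic", {
  tg <- cohort_targets()
  f1 <- suppressWarnings(
    calibrate_sdm(tg, control = list(maxiter = 5, maxfev = 200)))
  f2 <- suppressWarnings(
    calibrate_sdm(tg, control = list(maxiter = 5, maxfev = 200)))
  expect_identical(coef(f1), coef(f2))
})

test_that("fit methods expose diagnostics", {
  fit <- calibrate_sdm(cohort_targets(caries_free = c(base = 176722),
                                      treatment_cost = NULL,
                                      scenario_costs = NULL),
                       free = "caries_fraction")
  expect_output(print(fit), "bisection")
  s <- summary(fit)
  expect_s3_class(s, "summary.caries_sdm")
  expect_output(print(s), "caries_free")
  traj <- predict(fit, "stb")
  expect_s3_class(traj, "caries_trajectory")
  expect_error(predict(fit, "nope"), "unknown scenario")
  costs <- predict(fit, "base", type = "costs")
  expect_s3_class(costs, "cost_breakdown")
  sims <- simulate(fit, nsim = 3, seed = 9)
  expect_length(sims, 3)
  expect_s3_class(sims[[1]], "caries_trajectory")
})
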