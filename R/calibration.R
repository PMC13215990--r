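#' Published aggregate targets for the Thai school cohort
#'
#' The aggregate outcomes available for calibrating the model: the
#' caries-free population at age 12 under each scenario and the cumulative
#' treatment-cost trajectory by age (THB, valued at mean unit costs) under
#' each scenario, as published for the Thai 2021 birth cohort of 678,243
#' children. Individual flow parameters and stock levels were never
#' published, so these aggregates are the only constraints available.
#'
#' The published multi-way sensitivity totals also constrain the model:
#' each is the age-12 total cost of the base configuration run with an
#' alternative (coverage, effectiveness, unit-cost level) combination.
#' Valuing the same cumulative counters at three different price vectors
#' (min/mean/max) is what identifies the split of treatment volume across
#' filling, endodontic treatment and extraction, which the mean-cost
#' trajectory alone leaves undetermined.
#'
#' @param caries_free Named vector of caries-free children at age 12 per
#'   scenario.
#' @param treatment_cost Data frame with column `age` and one treatment-cost
#'   column per scenario (valued at mean unit costs).
#' @param scenario_costs Data frame of horizon totals under sensitivity
#'   scenarios: columns `intervention`, `coverage`, `effectiveness`,
#'   `cost_level` (`"min"`/`"mean"`/`"max"`), `age`, `total_cost` (THB,
#'   programme cost included).
#' @param weight_caries_free Relative weight given to each caries-free
#'   target (cost points have weight 1).
#' @return A list of class `"calibration_target"`.
#' @export
cohort_targets <- function(
    caries_free = c(base = 176722, stb = 194701, sealant = 205642),
    treatment_cost = data.frame(
      age     = 6:12,
      base    = c(39857300, 42490200, 46440500, 51330200, 56855600,
                  62775200, 68898100),
      stb     = c(39857300, 42490200, 46277900, 50903900, 56111000,
                  61691200, 67478000),
      sealant = c(39857300, 42490200, 46184900, 50658300, 55678300,
                  61056200, 66639100)),
    scenario_costs = data.frame(
      intervention = c(rep("stb", 4), rep("sealant", 8)),
      coverage = c(rep(0.95, 4), rep(0.27, 4), rep(0.472, 4)),
      effectiveness = c(0, 0, 0.21, 0.21,
                        rep(c(0.52, 0.52, 0.82, 0.82), 2)),
      cost_level = rep(c("min", "max"), 6),
      age = 12,
      total_cost = c(73473400, 142128400, 71316400, 138365700,
                     66436500, 154880800, 65535800, 153309600,
                     77923300, 203137000, 76237400, 200196000)),
    weight_caries_free = 8) {
  stopifnot(all(caries_free > 0), weight_caries_free > 0)
  if (!is.null(treatment_cost))
    stopifnot("age" %in% names(treatment_cost))
  if (!is.null(scenario_costs))
    stopifnot(all(c("intervention", "coverage", "effectiveness",
                    "cost_level", "age", "total_cost") %in%
                  names(scenario_costs)))
  structure(list(caries_free = caries_free,
                 treatment_cost = treatment_cost,
                 scenario_costs = scenario_costs,
                 weight_caries_free = weight_caries_free),
            class = "calibration_target")
}

# Map an unconstrained parameter vector to natural-scale model parameters.
# Treatment fractions use a stick-breaking transform so fill+endo+extract
# can never exceed 1; initial stocks use one so the five stocks always sum
# to the population; cumulative counters are log-transformed.
.par_natural <- function(theta, total_population) {
  p <- stats::plogis(theta[["treat_total"]])
  a <- stats::plogis(theta[["treat_share_fill"]])
  b <- stats::plogis(theta[["treat_share_endo"]])
  q  <- stats::plogis(theta[["init_affected"]])
  u1 <- stats::plogis(theta[["init_share_untreated"]])
  u2 <- stats::plogis(theta[["init_share_filled"]])
  u3 <- stats::plogis(theta[["init_share_endo"]])
  affected <- q * total_population
  c0 <- affected * u1
  f0 <- affected * (1 - u1) * u2
  e0 <- affected * (1 - u1) * (1 - u2) * u3
  m0 <- affected * (1 - u1) * (1 - u2) * (1 - u3)
  list(
    fractions = flow_fractions(
      caries_fraction = stats::plogis(theta[["caries_fraction"]]),
      fill_fraction = p * a,
      endo_fraction = p * (1 - a) * b,
      extract_fraction = p * (1 - a) * (1 - b),
      recur_filled_fraction = stats::plogis(theta[["recur_filled"]]),
      recur_endo_fraction = stats::plogis(theta[["recur_endo"]])),
    initial_stocks = caries_stocks(
      caries_free = total_population - affected,
      caries_untreated = c0, filled = f0, endodontic = e0, missing = m0,
      cum_fillings = total_population *
        stats::plogis(theta[["cum_fillings_share"]]),
      cum_endodontic = total_population *
        stats::plogis(theta[["cum_endodontic_share"]]),
      cum_extractions = total_population *
        stats::plogis(theta[["cum_extractions_share"]])))
}

.default_start <- function() {
  c(caries_fraction = stats::qlogis(0.17),
    treat_total = stats::qlogis(0.15),
    treat_share_fill = stats::qlogis(0.5),
    treat_share_endo = stats::qlogis(0.2),
    recur_filled = stats::qlogis(0.1),
    recur_endo = stats::qlogis(0.1),
    init_affected = stats::qlogis(0.25),
    init_share_untreated = stats::qlogis(0.7),
    init_share_filled = stats::qlogis(0.6),
    init_share_endo = stats::qlogis(0.3),
    cum_fillings_share = stats::qlogis(0.07),
    cum_endodontic_share = stats::qlogis(0.01),
    cum_extractions_share = stats::qlogis(0.02))
}

.scenario_spec <- function(interventions, nm) {
  if (nm == "base") NULL else interventions[[nm]]
}

# Relative-error denominator: |observed|, floored at a thousandth of the
# largest target in its group so that zero-valued observations (e.g. a cost
# trajectory starting from empty counters) stay finite.
.rel_den <- function(obs, group = obs) pmax(abs(obs), 1e-3 * max(abs(group), 1))

# Weighted relative residuals of a candidate parameter vector against the
# calibration target, across all scenarios.
.calib_residuals <- function(theta, target, interventions, ucosts,
                             cost_ranges, total_population, start_age,
                             end_age, dt) {
  nat <- .par_natural(theta, total_population)
  config <- sdm_config(total_population, start_age, end_age, dt,
                       initial_stocks = nat$initial_stocks,
                       fractions = nat$fractions)
  res <- c()
  cost_cols <- if (is.null(target$treatment_cost)) character()
               else setdiff(names(target$treatment_cost), "age")
  for (nm in union(names(target$caries_free), cost_cols)) {
    traj <- sdm_simulate(config, .scenario_spec(interventions, nm))
    horizon <- nrow(traj)
    if (nm %in% names(target$caries_free)) {
      obs <- target$caries_free[[nm]]
      res <- c(res, stats::setNames(
        sqrt(target$weight_caries_free) *
          (traj$caries_free[horizon] - obs) / obs,
        paste0("caries_free.", nm)))
    }
    if (nm %in% cost_cols) {
      idx <- match(target$treatment_cost$age, traj$age)
      if (anyNA(idx))
        stop("treatment-cost target ages outside simulated range")
      obs <- target$treatment_cost[[nm]]
      sim <- treatment_cost(traj[idx, ], ucosts)
      res <- c(res, stats::setNames(
        (sim - obs) / .rel_den(obs),
        paste0("cost.", nm, ".", target$treatment_cost$age)))
    }
  }
  sc <- target$scenario_costs
  if (!is.null(sc) && nrow(sc) > 0) {
    memo <- list()
    for (i in seq_len(nrow(sc))) {
      nm <- sc$intervention[i]
      lag <- if (!is.null(interventions[[nm]]))
        interventions[[nm]]$onset_lag else 0
      spec <- intervention(nm, effectiveness = sc$effectiveness[i],
                           coverage = sc$coverage[i], onset_lag = lag)
      key <- paste(nm, sc$coverage[i], sc$effectiveness[i])
      if (is.null(memo[[key]])) memo[[key]] <- sdm_simulate(config, spec)
      traj <- memo[[key]]
      uc <- unit_costs(sc$cost_level[i], cost_ranges)
      row <- traj[match(sc$age[i], traj$age), ]
      sim <- intervention_cost(spec, total_population,
                               unit_cost = uc[[nm]]) +
        treatment_cost(row, uc)
      res <- c(res, stats::setNames(
        (sim - sc$total_cost[i]) / sc$total_cost[i],
        paste0("scenario_cost.", nm, ".", i)))
    }
  }
  res
}

#' Calibrate the caries model to aggregate cohort targets
#'
#' Estimates the flow fractions, initial stock composition and initial
#' cumulative treatment counters of the stock-and-flow model by weighted
#' least squares on relative errors against published aggregate targets
#' (caries-free population at age 12 per scenario; treatment-cost
#' trajectory per scenario). This is the package's model-fitting entry
#' point; the result carries the fitted [sdm_config()] and supports the
#' usual `coef`, `residuals`, `fitted`, `predict`, `summary`, `plot` and
#' `simulate` methods.
#'
#' With `free = "caries_fraction"` only the caries-incidence fraction is
#' estimated (all other flows fixed at zero, everyone initially
#' caries-free), by bisection on the monotone map from incidence fraction
#' to final caries-free population; this is the identifiable
#' single-parameter case. With `free = "all"` (default) the full parameter
#' set is fitted by Levenberg-Marquardt from a fixed documented starting
#' point, so the fit is deterministic. Because only aggregates were ever
#' published, the split of treatment costs across the three services is not
#' identified: the fitted split is one of a family of solutions that
#' reproduce the cost trajectory.
#'
#' @param target A [cohort_targets()] object.
#' @param total_population Cohort size.
#' @param interventions Named list of [intervention()] objects covering
#'   every non-base scenario named in `target`.
#' @param ucosts Unit costs used to value simulated treatment counters for
#'   the mean-cost trajectory targets.
#' @param cost_ranges Unit-cost ranges used for the min/max-valued
#'   sensitivity-scenario targets.
#' @param start_age,end_age,dt Simulation ages and step (years).
#' @param free `"all"` or `"caries_fraction"`.
#' @param start Optional named starting vector on the transformed scale
#'   (see `cariescea:::.default_start`).
#' @param control List passed to [minpack.lm::nls.lm.control()].
#' @return An object of class `"caries_sdm"`.
#' @examples
#' # single-parameter calibration: pure incidence decay
#' fit <- calibrate_sdm(cohort_targets(caries_free = c(base = 176722)),
#'                      free = "caries_fraction")
#' coef(fit)[["caries_fraction"]]  # ~0.2008
#' @export
calibrate_sdm <- function(target = cohort_targets(),
                          total_population = 678243,
                          interventions = default_interventions(),
                          ucosts = unit_costs(),
                          cost_ranges = unit_cost_ranges(),
                          start_age = 6, end_age = 12, dt = 1,
                          free = c("all", "caries_fraction"),
                          start = NULL,
                          control = list(maxiter = 500, maxfev = 2000,
                                         ftol = 1e-10)) {
  stopifnot(inherits(target, "calibration_target"))
  free <- match.arg(free)
  if (any(target$caries_free >= total_population))
    stop("infeasible target: caries-free target exceeds the population")
  scen <- setdiff(union(names(target$caries_free),
                        c(if (!is.null(target$treatment_cost))
                            setdiff(names(target$treatment_cost), "age"),
                          target$scenario_costs$intervention)), "base")
  absent <- setdiff(scen, names(interventions))
  if (free == "all" && length(absent) > 0)
    stop("no intervention specification for target scenario(s): ",
         paste(absent, collapse = ", "))
  cl <- match.call()

  if (free == "caries_fraction") {
    obs <- target$caries_free[["base"]]
    if (is.null(obs) || is.na(obs))
      stop("single-parameter calibration needs a base-case caries-free target")
    n_steps <- (end_age - start_age) / dt
    final_cf <- function(f) {
      cfg <- sdm_config(total_population, start_age, end_age, dt,
                        initial_stocks = caries_stocks(
                          caries_free = total_population),
                        fractions = flow_fractions(caries_fraction = f))
      traj <- sdm_simulate(cfg)
      traj$caries_free[nrow(traj)]
    }
    # final caries-free is strictly decreasing in f: bracketed bisection
    root <- stats::uniroot(function(f) final_cf(f) - obs,
                           interval = c(0, 1), tol = 1e-12)
    fractions <- flow_fractions(caries_fraction = root$root)
    config <- sdm_config(total_population, start_age, end_age, dt,
                         initial_stocks = caries_stocks(
                           caries_free = total_population),
                         fractions = fractions)
    fit <- list(config = config, interventions = interventions,
                ucosts = ucosts, cost_ranges = cost_ranges,
                target = target, free = free, theta = NULL,
                convergence = list(method = "bisection",
                                   estim.prec = root$estim.prec),
                call = cl)
  } else {
    theta0 <- .default_start()
    if (!is.null(start)) {
      stopifnot(all(names(start) %in% names(theta0)))
      theta0[names(start)] <- start
    }
    lm_fit <- minpack.lm::nls.lm(
      par = theta0,
      fn = .calib_residuals, target = target,
      interventions = interventions, ucosts = ucosts,
      cost_ranges = cost_ranges,
      total_population = total_population, start_age = start_age,
      end_age = end_age, dt = dt,
      control = do.call(minpack.lm::nls.lm.control, control))
    if (lm_fit$info == 0 || lm_fit$info == 9)
      stop("calibration did not converge (nls.lm info = ", lm_fit$info,
           "); final residual sum of squares ", signif(lm_fit$deviance, 4))
    nat <- .par_natural(lm_fit$par, total_population)
    config <- sdm_config(total_population, start_age, end_age, dt,
                         initial_stocks = nat$initial_stocks,
                         fractions = nat$fractions)
    fit <- list(config = config, interventions = interventions,
                ucosts = ucosts, cost_ranges = cost_ranges,
                target = target, free = free, theta = lm_fit$par,
                convergence = list(method = "levenberg-marquardt",
                                   info = lm_fit$info,
                                   message = lm_fit$message,
                                   deviance = lm_fit$deviance,
                                   niter = lm_fit$niter),
                call = cl)
  }
  class(fit) <- "caries_sdm"
  fit
}

#' @export
coef.caries_sdm <- function(object, ...) {
  f <- unclass(object$config$fractions)
  s <- unclass(object$config$initial_stocks)
  c(f, stats::setNames(s, paste0("init_", names(s))))
}

.fit_table <- function(object) {
  target <- object$target
  rows <- list()
  cost_cols <- if (is.null(target$treatment_cost) ||
                   object$free != "all") character()
               else setdiff(names(target$treatment_cost), "age")
  for (nm in union(names(target$caries_free), cost_cols)) {
    traj <- predict(object, scenario = nm)
    horizon <- nrow(traj)
    if (nm %in% names(target$caries_free)) {
      obs <- target$caries_free[[nm]]
      rows[[length(rows) + 1]] <- data.frame(
        quantity = "caries_free", scenario = nm, age = traj$age[horizon],
        observed = obs, fitted = traj$caries_free[horizon])
    }
    if (nm %in% cost_cols) {
      idx <- match(target$treatment_cost$age, traj$age)
      rows[[length(rows) + 1]] <- data.frame(
        quantity = "treatment_cost", scenario = nm,
        age = target$treatment_cost$age,
        observed = target$treatment_cost[[nm]],
        fitted = treatment_cost(traj[idx, ], object$ucosts))
    }
  }
  sc <- target$scenario_costs
  if (!is.null(sc) && nrow(sc) > 0 && object$free == "all") {
    for (i in seq_len(nrow(sc))) {
      nm <- sc$intervention[i]
      lag <- if (!is.null(object$interventions[[nm]]))
        object$interventions[[nm]]$onset_lag else 0
      spec <- intervention(nm, effectiveness = sc$effectiveness[i],
                           coverage = sc$coverage[i], onset_lag = lag)
      traj <- sdm_simulate(object$config, spec)
      uc <- unit_costs(sc$cost_level[i], object$cost_ranges)
      row <- traj[match(sc$age[i], traj$age), ]
      rows[[length(rows) + 1]] <- data.frame(
        quantity = paste0("total_cost_", sc$cost_level[i]),
        scenario = sprintf("%s[c=%g,e=%g]", nm, sc$coverage[i],
                           sc$effectiveness[i]),
        age = sc$age[i], observed = sc$total_cost[i],
        fitted = intervention_cost(spec, object$config$total_population,
                                   unit_cost = uc[[nm]]) +
          treatment_cost(row, uc))
    }
  }
  out <- do.call(rbind, rows)
  out$rel_error <- (out$fitted - out$observed) /
    .rel_den(out$observed, group = out$observed)
  out
}

#' @export
fitted.caries_sdm <- function(object, ...) .fit_table(object)$fitted

#' @export
residuals.caries_sdm <- function(object, ...) {
  tab <- .fit_table(object)
  stats::setNames(tab$rel_error,
                  paste(tab$quantity, tab$scenario, tab$age, sep = "."))
}

#' Predict trajectories or costs from a calibrated model
#'
#' @param object A `"caries_sdm"` fit.
#' @param scenario Scenario name (`"base"` or a name in
#'   `object$interventions`) or an [intervention()] object.
#' @param type `"trajectory"` for the simulated stocks, `"costs"` for the
#'   [cost_trajectory()] breakdown.
#' @param ... Unused.
#' @return A `"caries_trajectory"` or `"cost_breakdown"` data frame.
#' @export
predict.caries_sdm <- function(object, scenario = "base",
                               type = c("trajectory", "costs"), ...) {
  type <- match.arg(type)
  spec <- if (inherits(scenario, "intervention_spec")) scenario
          else if (identical(scenario, "base")) NULL
          else if (scenario %in% names(object$interventions))
            .scenario_spec(object$interventions, scenario)
          else stop("unknown scenario '", scenario, "'; expected one of: ",
                    paste(names(object$interventions), collapse = ", "))
  traj <- sdm_simulate(object$config, spec)
  if (type == "trajectory") traj
  else cost_trajectory(traj, spec, object$ucosts)
}

#' @export
print.caries_sdm <- function(x, ...) {
  cat("Calibrated caries system-dynamics model (", x$convergence$method,
      ")\n", sep = "")
  cat("  cohort:", format(x$config$total_population, big.mark = ","),
      "children, ages", x$config$start_age, "-", x$config$end_age, "\n")
  cat("  fractions:", paste(sprintf("%s=%.4f",
      sub("_fraction$", "", names(x$config$fractions)),
      unclass(x$config$fractions)), collapse = ", "), "\n")
  r <- residuals(x)
  cat(sprintf("  %d targets, max |relative error| %.3g\n",
              length(r), max(abs(r))))
  invisible(x)
}

#' @export
summary.caries_sdm <- function(object, ...) {
  out <- list(fit = .fit_table(object), coef = coef(object),
              convergence = object$convergence)
  class(out) <- "summary.caries_sdm"
  out
}

#' @export
print.summary.caries_sdm <- function(x, ...) {
  cat("Calibration fit (", x$convergence$method, ")\n", sep = "")
  tab <- x$fit
  tab$observed <- format(round(tab$observed), big.mark = ",")
  tab$fitted <- format(round(tab$fitted), big.mark = ",")
  tab$rel_error <- sprintf("%+.2e", tab$rel_error)
  print(tab, row.names = FALSE)
  cat("\nCoefficients:\n")
  print(signif(x$coef, 6))
  invisible(x)
}

#' @export
plot.caries_sdm <- function(x, ...) {
  tab <- .fit_table(x)
  tab <- tab[tab$quantity == "treatment_cost", ]
  scen <- unique(tab$scenario)
  cols <- seq_along(scen)
  graphics::plot(range(tab$age), range(c(tab$observed, tab$fitted)) / 1e6,
                 type = "n", xlab = "age (years)",
                 ylab = "cumulative treatment cost (million THB)", ...)
  for (i in seq_along(scen)) {
    d <- tab[tab$scenario == scen[i], ]
    graphics::lines(d$age, d$fitted / 1e6, col = cols[i])
    graphics::points(d$age, d$observed / 1e6, col = cols[i], pch = 1)
  }
  graphics::legend("topleft", legend = scen, col = cols, lty = 1, pch = 1,
                   bty = "n")
  invisible(x)
}

#' Simulate trajectories under randomly drawn flow parameters
#'
#' Draws `nsim` synthetic parameter sets (see [synthetic_flow_params()])
#' with ranges centred on the fitted fractions and returns the base-case
#' trajectory simulated under each; used for uncertainty exploration and
#' property testing.
#'
#' @param object A `"caries_sdm"` fit.
#' @param nsim Number of parameter draws.
#' @param seed Integer seed for reproducibility.
#' @param spread Half-width of each uniform range, as a fraction of the
#'   fitted value (truncated to `[0, 1]`).
#' @param ... Unused.
#' @return A list of `"caries_trajectory"` data frames with the drawn
#'   parameters attached as attribute `"params"`.
#' @export
simulate.caries_sdm <- function(object, nsim = 1, seed = NULL,
                                spread = 0.1, ...) {
  f <- unclass(object$config$fractions)
  ranges <- lapply(f, function(v) pmin(1, pmax(0, v * c(1 - spread,
                                                        1 + spread))))
  draws <- synthetic_flow_params(n = nsim, seed = seed,
                                 ranges = ranges,
                                 total_population =
                                   object$config$total_population)
  if (nsim == 1) draws <- list(draws)
  lapply(draws, function(d) {
    cfg <- sdm_config(object$config$total_population,
                      object$config$start_age, object$config$end_age,
                      object$config$dt, initial_stocks = d$initial_stocks,
                      fractions = d$fractions)
    traj <- sdm_simulate(cfg)
    attr(traj, "params") <- d
    traj
  })
}

#' Default sampling ranges for synthetic flow parameters
#'
#' @return Named list of `c(min, max)` ranges for the six flow fractions.
#' @export
synthetic_param_ranges <- function() {
  list(caries_fraction = c(0.05, 0.30), fill_fraction = c(0, 0.5),
       endo_fraction = c(0, 0.3), extract_fraction = c(0, 0.3),
       recur_filled_fraction = c(0, 0.3), recur_endo_fraction = c(0, 0.3))
}

#' Generate synthetic model parameters
#'
#' Reproducibly draws flow fractions (uniform within the given ranges,
#' rejecting draws whose treatment outflow fractions sum above 1) and a
#' random initial stock composition that respects the closed-cohort
#' conservation constraint. Used as the stand-in for unpublished true
#' parameter values in property tests and calibration self-consistency
#' checks.
#'
#' @param n Number of parameter sets.
#' @param seed Integer seed; the draw is a pure function of the seed.
#' @param ranges Named list of `c(min, max)` ranges for the six fractions.
#' @param total_population Cohort size for the stock composition.
#' @param caries_free_share Range of the initially caries-free share.
#' @return For `n = 1` a list of class `"synthetic_params"` with components
#'   `fractions`, `initial_stocks`, `seed`, `ranges`; for `n > 1` a list of
#'   such objects.
#' @examples
#' p <- synthetic_flow_params(seed = 42)
#' identical(p$fractions, synthetic_flow_params(seed = 42)$fractions)
#' @export
synthetic_flow_params <- function(n = 1, seed = NULL,
                                  ranges = synthetic_param_ranges(),
                                  total_population = 678243,
                                  caries_free_share = c(0.6, 1)) {
  needed <- .FRACTION_NAMES
  if (!all(needed %in% names(ranges)))
    stop("ranges must cover: ", paste(needed, collapse = ", "))
  for (nm in needed) {
    r <- ranges[[nm]]
    if (length(r) != 2 || r[1] > r[2] || r[1] < 0 || r[2] > 1)
      stop("impossible range for ", nm)
  }
  treat <- c("fill_fraction", "endo_fraction", "extract_fraction")
  if (sum(vapply(ranges[treat], min, numeric(1))) > 1)
    stop("treatment fraction ranges make outflow sum > 1 unavoidable")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  draw_one <- function() {
    repeat {
      f <- vapply(needed,
                  function(nm) stats::runif(1, ranges[[nm]][1],
                                            ranges[[nm]][2]),
                  numeric(1))
      if (sum(f[treat]) <= 1) break
    }
    share_cf <- stats::runif(1, caries_free_share[1], caries_free_share[2])
    rest <- stats::runif(4)
    rest <- (1 - share_cf) * rest / sum(rest)
    structure(list(
      fractions = do.call(flow_fractions, as.list(f)),
      initial_stocks = caries_stocks(
        caries_free = share_cf * total_population,
        caries_untreated = rest[1] * total_population,
        filled = rest[2] * total_population,
        endodontic = rest[3] * total_population,
        missing = rest[4] * total_population),
      seed = seed, ranges = ranges), class = "synthetic_params")
  }
  if (n == 1) draw_one() else replicate(n, draw_one(), simplify = FALSE)
}

#' The shipped calibrated configuration
#'
#' Loads the calibrated model configuration distributed with the package:
#' flow fractions and initial stocks fitted (see [calibrate_sdm()]) to the
#' published aggregate trajectories of the Thai cohort, together with the
#' national programme specifications and unit-cost ranges. Because the
#' original parameter values were never published, this configuration is a
#' constrained reconstruction: it reproduces the published aggregates to
#' the accuracy documented in the methods vignette, not the underlying
#' stock levels.
#'
#' @return A list with components `config` ([sdm_config()]),
#'   `interventions` (named list of [intervention()]), `unit_cost_ranges`
#'   (data frame) and `exchange_rate`.
#' @examples
#' fx <- reproduction_fixture()
#' sdm_simulate(fx$config)
#' @export
reproduction_fixture <- function() {
  path <- system.file("extdata", "calibrated_config.yaml",
                      package = "cariescea")
  if (path == "") stop("shipped configuration not found")
  read_sdm_config(path)
}
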