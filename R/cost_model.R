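#' Unit costs of dental services
#'
#' Per-child unit costs in 2024 Thai baht (THB) for the three caries
#' treatments and the two preventive programmes, synthesised from Thai
#' costing studies (mean across studies for the base case; study minima and
#' maxima for sensitivity analysis).
#'
#' @param level `"mean"`, `"min"` or `"max"`, selecting which column of
#'   [unit_cost_ranges()] to return.
#' @param ranges A data frame in the shape of [unit_cost_ranges()].
#' @return A named numeric vector of class `"unit_costs"` with elements
#'   `filling`, `endodontic`, `extraction`, `stb`, `sealant`.
#' @examples
#' unit_costs()
#' unit_costs("min")
#' @export
unit_costs <- function(level = c("mean", "min", "max"),
                       ranges = unit_cost_ranges()) {
  level <- match.arg(level)
  stopifnot(all(c("service", "mean", "min", "max") %in% names(ranges)),
            all(ranges$min <= ranges$mean), all(ranges$mean <= ranges$max),
            all(ranges$min > 0))
  x <- stats::setNames(ranges[[level]], ranges$service)
  class(x) <- "unit_costs"
  x
}

#' Unit-cost ranges from Thai costing studies
#'
#' Mean, minimum and maximum 2024-price unit costs (THB per child; STB per
#' child per year) used for base-case costing and sensitivity analysis.
#'
#' @return A data frame with columns `service`, `mean`, `min`, `max`.
#' @export
unit_cost_ranges <- function() {
  data.frame(
    service = c("filling", "endodontic", "extraction", "stb", "sealant"),
    mean = c(360.1, 1839.4, 133.6, 57.6, 203.5),
    min  = c(270.2, 1315.7, 100.5, 34.8, 92.2),
    max  = c(471.5, 2619.7, 155.9, 80.4, 366.8))
}

#' Standardise a historical cost to target-year prices
#'
#' Rescales a cost reported in `source_year` prices to `target_year` prices
#' using a consumer price index series:
#' `adjusted = cost * cpi[target_year] / cpi[source_year]`.
#'
#' @param cost Cost in `source_year` THB.
#' @param source_year Year the cost was reported in.
#' @param cpi Named numeric vector mapping years to CPI index values
#'   (e.g. Thai CPI, base year 2019 = 100).
#' @param target_year Year to express the cost in (default 2024).
#' @return The adjusted cost.
#' @examples
#' cpi <- c("2018" = 100, "2024" = 112)
#' cpi_adjust(100, 2018, cpi)  # 112
#' @export
cpi_adjust <- function(cost, source_year, cpi, target_year = 2024) {
  for (yr in c(source_year, target_year))
    if (!as.character(yr) %in% names(cpi))
      stop("CPI series has no value for year ", yr)
  stopifnot(all(cpi > 0))
  cost * cpi[[as.character(target_year)]] / cpi[[as.character(source_year)]]
}

#' Summarise unit-cost estimates across studies
#'
#' Pragmatic synthesis of point estimates from multiple costing studies:
#' unweighted arithmetic mean (used for the base case) plus minimum and
#' maximum (used for sensitivity analysis).
#'
#' @param values Numeric vector of positive cost estimates.
#' @return Named vector `c(mean, min, max)`.
#' @examples
#' summarize_costs(c(270.2, 471.5))
#' @export
summarize_costs <- function(values) {
  if (length(values) == 0) stop("no cost estimates supplied")
  stopifnot(is.numeric(values), all(values > 0))
  c(mean = mean(values), min = min(values), max = max(values))
}

#' Annual programme cost
#'
#' Cost of running a preventive programme for one year: unit cost per
#' covered child times the covered population (`coverage *
#' total_population`). Constant over the simulation; zero for the base case.
#'
#' @param spec An [intervention()] object.
#' @param total_population Cohort size.
#' @param unit_cost Programme unit cost; defaults to the one stored in
#'   `spec`.
#' @return Annual cost in THB.
#' @examples
#' intervention_cost(default_interventions()$stb, 678243)
#' @export
intervention_cost <- function(spec, total_population,
                              unit_cost = spec$unit_cost) {
  stopifnot(inherits(spec, "intervention_spec"), total_population > 0,
            unit_cost >= 0)
  unit_cost * spec$coverage * total_population
}

#' Cumulative treatment cost of a state
#'
#' Values the cumulative treatment-event counters at the given unit costs:
#' `filling * cum_fillings + endodontic * cum_endodontic + extraction *
#' cum_extractions`. Costing uses cumulative events rather than current
#' stock levels so that every delivered treatment (including re-treatment
#' after recurrence) is paid for exactly once.
#'
#' @param stocks A [caries_stocks()] vector, or a `"caries_trajectory"`
#'   data frame (vectorised over rows).
#' @param ucosts A [unit_costs()] vector.
#' @return Treatment cost(s) in THB.
#' @export
treatment_cost <- function(stocks, ucosts = unit_costs()) {
  stopifnot(inherits(ucosts, "unit_costs"))
  if (is.data.frame(stocks)) {
    ucosts[["filling"]] * stocks$cum_fillings +
      ucosts[["endodontic"]] * stocks$cum_endodontic +
      ucosts[["extraction"]] * stocks$cum_extractions
  } else {
    validate_stocks(stocks)
    ucosts[["filling"]] * stocks[["cum_fillings"]] +
      ucosts[["endodontic"]] * stocks[["cum_endodontic"]] +
      ucosts[["extraction"]] * stocks[["cum_extractions"]]
  }
}

#' Cost breakdown along a simulated trajectory
#'
#' Combines programme and treatment costs at every time point. The total at
#' age `t` is one (constant) annual programme cost plus the cumulative
#' treatment cost of the age-`t` state; the programme cost is deliberately
#' not accumulated across years, matching the published accounting
#' convention for these programmes. Costs are optionally discounted from
#' the simulation start at the configured annual rate (default 0).
#'
#' @param traj A `"caries_trajectory"` from [sdm_simulate()].
#' @param spec The [intervention()] under which `traj` was simulated, or
#'   `NULL` for the base case.
#' @param ucosts A [unit_costs()] vector.
#' @param exchange_rate THB per USD used for the companion USD columns.
#' @return A data frame of class `"cost_breakdown"` with columns `age`,
#'   `intervention_cost`, `treatment_cost`, `total_cost` (THB) and
#'   `total_cost_usd`.
#' @examples
#' fx <- reproduction_fixture()
#' traj <- sdm_simulate(fx$config, fx$interventions$stb)
#' cost_trajectory(traj, fx$interventions$stb)
#' @export
cost_trajectory <- function(traj, spec = attr(traj, "intervention"),
                            ucosts = unit_costs(), exchange_rate = 32) {
  stopifnot(inherits(traj, "caries_trajectory"))
  config <- attr(traj, "config")
  iv_cost <- if (is.null(spec) || spec$coverage == 0 ||
                 spec$unit_cost == 0) 0
  else intervention_cost(spec, config$total_population,
                         unit_cost = ucosts[[spec$name]])
  disc <- (1 + config$discount_rate)^-(traj$age - config$start_age)
  out <- data.frame(
    age = traj$age,
    intervention_cost = iv_cost * disc,
    treatment_cost = treatment_cost(traj, ucosts) * disc)
  out$total_cost <- out$intervention_cost + out$treatment_cost
  out$total_cost_usd <- thb_to_usd(out$total_cost, exchange_rate)
  class(out) <- c("cost_breakdown", "data.frame")
  out
}

#' Convert THB to USD
#'
#' @param thb Amount in Thai baht.
#' @param rate Exchange rate in THB per USD (default 32, consistent with
#'   every published THB/USD pair in the source tables).
#' @return Amount in USD.
#' @export
thb_to_usd <- function(thb, rate = 32) {
  if (rate <= 0) stop("exchange rate must be positive")
  thb / rate
}

#' Round to the simulator display convention
#'
#' Published cost tables show values rounded to 6 significant figures (e.g.
#' 37,113,457 is displayed as 37,113,500). Internal arithmetic is always at
#' full precision; use this helper only at presentation or comparison time.
#'
#' @param x Numeric vector.
#' @return `signif(x, 6)`.
#' @examples
#' display_round(37113457)
#' @export
display_round <- function(x) signif(x, 6)
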