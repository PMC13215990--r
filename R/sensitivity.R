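#' Parameter ranges for the multi-way sensitivity analysis
#'
#' Coverage (current and national-target maximum) and effectiveness
#' (meta-analysis lower/upper bounds) levels for each programme. STB's
#' current coverage already equals the national target, so its current and
#' maximum coverage coincide.
#'
#' @param name `"stb"` or `"sealant"`.
#' @return A list with components `coverage` (named `current`, `max`) and
#'   `effectiveness` (named `min`, `max`).
#' @export
default_sensitivity_ranges <- function(name = c("stb", "sealant")) {
  name <- match.arg(name)
  switch(name,
         stb = list(coverage = c(current = 0.95, max = 0.95),
                    effectiveness = c(min = 0, max = 0.21)),
         sealant = list(coverage = c(current = 0.27, max = 0.472),
                        effectiveness = c(min = 0.52, max = 0.82)))
}

#' Build the 2 x 2 x 2 sensitivity grid
#'
#' Enumerates the eight deterministic sensitivity scenarios for one
#' programme in the standard row order (1: current coverage / min
#' effectiveness / min unit costs ... 8: max / max / max), resolving each
#' level to its parameter value.
#'
#' @param spec An [intervention()] for the programme being varied.
#' @param ranges Coverage/effectiveness ranges as returned by
#'   [default_sensitivity_ranges()].
#' @return A data frame with columns `scenario` (1-8), `coverage_level`,
#'   `effectiveness_level`, `unit_cost_level` and the resolved `coverage`
#'   and `effectiveness` values.
#' @examples
#' sensitivity_grid(default_interventions()$sealant)
#' @export
sensitivity_grid <- function(spec,
                             ranges = default_sensitivity_ranges(spec$name)) {
  stopifnot(inherits(spec, "intervention_spec"))
  for (comp in c("coverage", "effectiveness")) {
    if (is.null(ranges[[comp]]) || length(ranges[[comp]]) < 2 ||
        any(is.na(ranges[[comp]])))
      stop("incomplete sensitivity range for ", comp)
  }
  grid <- expand.grid(unit_cost_level = c("min", "max"),
                      effectiveness_level = c("min", "max"),
                      coverage_level = c("current", "max"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("coverage_level", "effectiveness_level",
                   "unit_cost_level")]
  grid <- data.frame(scenario = 1:8, grid)
  grid$coverage <- unname(ranges$coverage[grid$coverage_level])
  grid$effectiveness <- unname(ranges$effectiveness[grid$effectiveness_level])
  grid
}

#' Run the multi-way sensitivity analysis for one programme
#'
#' Simulates each of the eight grid scenarios with its resolved coverage,
#' effectiveness and unit-cost level and compares it with the unchanged
#' base case. The min/max unit-cost level applies to all five unit costs
#' simultaneously (treatments and programme); the base-case comparator
#' always keeps mean unit costs and no programme, so its total cost is
#' identical in every row.
#'
#' @param config A calibrated [sdm_config()] for the base case.
#' @param spec The [intervention()] being varied.
#' @param ranges Coverage/effectiveness ranges
#'   ([default_sensitivity_ranges()]).
#' @param cost_ranges Unit-cost ranges ([unit_cost_ranges()]).
#' @return A data frame of class `"sensitivity_result"`: the grid plus
#'   `total_cost`, `caries_free`, `cer`, `icer_vs_base` (`NA` when the
#'   scenario's effectiveness equals the base case) and `quadrant`, with
#'   the base-case row appended as scenario `"base"`.
#' @examples
#' fx <- reproduction_fixture()
#' run_sensitivity(fx$config, fx$interventions$stb)
#' @export
run_sensitivity <- function(config, spec,
                            ranges = default_sensitivity_ranges(spec$name),
                            cost_ranges = unit_cost_ranges()) {
  stopifnot(inherits(config, "sdm_config"),
            inherits(spec, "intervention_spec"))
  grid <- sensitivity_grid(spec, ranges)
  base_traj <- sdm_simulate(config)
  base_cost <- cost_trajectory(base_traj, NULL,
                               unit_costs("mean", cost_ranges))
  horizon <- nrow(base_traj)
  base_total <- base_cost$total_cost[horizon]
  base_eff <- base_traj$caries_free[horizon]

  res <- lapply(seq_len(nrow(grid)), function(i) {
    row <- grid[i, ]
    sc_spec <- intervention(spec$name, effectiveness = row$effectiveness,
                            coverage = row$coverage,
                            unit_cost = spec$unit_cost,
                            onset_lag = spec$onset_lag)
    uc <- unit_costs(row$unit_cost_level, cost_ranges)
    traj <- tryCatch(sdm_simulate(config, sc_spec),
                     error = function(e) stop("sensitivity scenario ",
                                              row$scenario, ": ",
                                              conditionMessage(e)))
    costs <- cost_trajectory(traj, sc_spec, uc)
    data.frame(total_cost = costs$total_cost[horizon],
               caries_free = traj$caries_free[horizon])
  })
  res <- do.call(rbind, res)
  out <- cbind(grid, res)
  out$cer <- cer(out$total_cost, out$caries_free)
  out$icer_vs_base <- icer(out$total_cost, out$caries_free,
                           base_total, base_eff)
  out$quadrant <- cea_quadrant(out$total_cost - base_total,
                               out$caries_free - base_eff)
  base_row <- data.frame(scenario = NA_integer_, coverage_level = "base",
                         effectiveness_level = "-", unit_cost_level = "-",
                         coverage = 0, effectiveness = 0,
                         total_cost = base_total, caries_free = base_eff,
                         cer = cer(base_total, base_eff),
                         icer_vs_base = NA_real_, quadrant = NA_character_)
  out <- rbind(out, base_row)
  attr(out, "intervention") <- spec$name
  class(out) <- c("sensitivity_result", "data.frame")
  out
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("Multi-way sensitivity analysis:", attr(x, "intervention"), "\n")
  disp <- data.frame(
    scenario = ifelse(is.na(x$scenario), "base", as.character(x$scenario)),
    coverage = x$coverage_level, effectiveness = x$effectiveness_level,
    unit_costs = x$unit_cost_level,
    total_cost = format(display_round(x$total_cost), big.mark = ","),
    caries_free = format(round(x$caries_free), big.mark = ","),
    cer = sprintf("%.1f", x$cer),
    icer_vs_base = ifelse(is.na(x$icer_vs_base), "NA",
                          sprintf("%.1f", x$icer_vs_base)))
  print(disp, row.names = FALSE)
  invisible(x)
}

#' Best-case / worst-case comparison between the two programmes
#'
#' Cross-compares the best (maximum coverage, maximum effectiveness,
#' minimum unit costs; grid scenario 7) and worst (minimum coverage,
#' minimum effectiveness, maximum unit costs; grid scenario 2) sensitivity
#' scenarios of STB and sealant: the sealant-vs-STB ICER and dominance
#' quadrant for the four pairings (best/worst, best/best, worst/worst,
#' worst/best).
#'
#' @param res_stb,res_sealant `"sensitivity_result"` objects from
#'   [run_sensitivity()] for STB and sealant.
#' @param best,worst Grid scenario ids taken as best and worst case.
#' @return A data frame with one row per pairing: the two scenarios'
#'   costs, caries-free counts and CERs, the sealant-vs-STB `icer`, and
#'   `quadrant` (sealant relative to STB).
#' @export
compare_best_worst <- function(res_stb, res_sealant, best = 7, worst = 2) {
  pick <- function(res, id) res[!is.na(res$scenario) & res$scenario == id, ]
  pairs <- list("best/worst"   = list(stb = best,  sealant = worst),
                "best/best"    = list(stb = best,  sealant = best),
                "worst/worst"  = list(stb = worst, sealant = worst),
                "worst/best"   = list(stb = worst, sealant = best))
  out <- lapply(names(pairs), function(nm) {
    a <- pick(res_stb, pairs[[nm]]$stb)       # STB arm
    b <- pick(res_sealant, pairs[[nm]]$sealant)  # sealant arm
    data.frame(comparison = nm,
               stb_scenario = pairs[[nm]]$stb,
               sealant_scenario = pairs[[nm]]$sealant,
               stb_cost = a$total_cost, stb_caries_free = a$caries_free,
               stb_cer = a$cer,
               sealant_cost = b$total_cost,
               sealant_caries_free = b$caries_free, sealant_cer = b$cer,
               icer = icer(b$total_cost, b$caries_free,
                           a$total_cost, a$caries_free),
               quadrant = cea_quadrant(b$total_cost - a$total_cost,
                                       b$caries_free - a$caries_free))
  })
  do.call(rbind, out)
}
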