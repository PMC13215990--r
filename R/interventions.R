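#' Preventive intervention specification
#'
#' Describes a school-based caries preventive programme as a modification of
#' the caries-incidence fraction. The programme's effectiveness is adjusted
#' for coverage (`effectiveness * coverage`) and applied multiplicatively:
#' `caries fraction = base caries fraction * (1 - coverage-adjusted
#' effectiveness)` from age `start_age + onset_lag` onwards.
#'
#' @param name Scenario label, e.g. `"stb"`, `"sealant"` or `"base"`.
#' @param effectiveness Relative caries reduction achieved by the programme
#'   in fully covered children, in `[0, 1]`.
#' @param coverage Fraction of the cohort reached by the programme.
#' @param unit_cost Programme cost in Thai baht (THB) per covered child per
#'   year.
#' @param onset_lag Years after the simulation start before the incidence
#'   reduction takes effect (default 0, i.e. the programme is effective
#'   from its first year). Because treatment flows respond to the untreated
#'   stock of the previous step, a lag-0 programme already leaves costs at
#'   the first two ages unchanged and lets them diverge from the third age
#'   on, which is the pattern observed for the national programmes; a
#'   positive lag delays the divergence further.
#'
#' @return An object of class `"intervention_spec"`.
#' @seealso [default_interventions()] for the national STB and sealant
#'   programmes.
#' @examples
#' stb <- intervention("stb", effectiveness = 0.10, coverage = 0.95,
#'                     unit_cost = 57.6)
#' coverage_effectiveness(stb)  # 0.095
#' @export
intervention <- function(name, effectiveness, coverage, unit_cost = 0,
                         onset_lag = 0) {
  stopifnot(is.character(name), length(name) == 1,
            effectiveness >= 0, effectiveness <= 1,
            coverage >= 0, coverage <= 1, unit_cost >= 0, onset_lag >= 0)
  structure(list(name = name, effectiveness = effectiveness,
                 coverage = coverage, unit_cost = unit_cost,
                 onset_lag = onset_lag),
            class = "intervention_spec")
}

#' @export
print.intervention_spec <- function(x, ...) {
  cat(sprintf(
    "Intervention '%s': effectiveness %.1f%%, coverage %.1f%% (adjusted %.2f%%),\n  unit cost %.1f THB/child/yr, onset lag %g yr\n",
    x$name, 100 * x$effectiveness, 100 * x$coverage,
    100 * coverage_effectiveness(x), x$unit_cost, x$onset_lag))
  invisible(x)
}

#' National programme scenarios
#'
#' The three scenarios evaluated for the Thai cohort: supervised
#' toothbrushing (STB; 10% effective, 95% coverage, 57.6 THB/child/yr),
#' dental sealant (58% effective, 27% coverage, 203.5 THB/child/yr) and the
#' base case without intervention.
#'
#' @param onset_lag Onset lag in years applied to both programmes.
#' @return A named list of [intervention()] objects
#'   (`base`, `stb`, `sealant`).
#' @examples
#' sapply(default_interventions(), coverage_effectiveness)
#' @export
default_interventions <- function(onset_lag = 0) {
  list(base = intervention("base", effectiveness = 0, coverage = 0,
                           unit_cost = 0, onset_lag = onset_lag),
       stb = intervention("stb", effectiveness = 0.10, coverage = 0.95,
                          unit_cost = 57.6, onset_lag = onset_lag),
       sealant = intervention("sealant", effectiveness = 0.58,
                              coverage = 0.27, unit_cost = 203.5,
                              onset_lag = onset_lag))
}

#' Coverage-adjusted effectiveness
#'
#' Effectiveness of a programme at the population level: the per-child
#' effectiveness multiplied by the fraction of the cohort covered. For the
#' national programmes this gives 9.5% for STB (10% x 95%) and 15.66%
#' (printed 15.7%) for sealant (58% x 27%).
#'
#' @param spec An [intervention()] object.
#' @return A fraction in `[0, 1]`.
#' @export
coverage_effectiveness <- function(spec) {
  stopifnot(inherits(spec, "intervention_spec"))
  spec$effectiveness * spec$coverage
}

#' Caries-incidence fraction under an intervention
#'
#' Applies the multiplicative incidence reduction
#' `base_fraction * (1 - coverage-adjusted effectiveness)` once the
#' programme's onset lag has elapsed; before that the base fraction is
#' returned unchanged.
#'
#' @param base_fraction Base-case annual caries-incidence fraction.
#' @param spec An [intervention()] object (or `NULL` for the base case).
#' @param age Current simulation age in years.
#' @param start_age Age at which the simulation (and programme) starts.
#' @return The adjusted caries fraction, in `[0, base_fraction]`.
#' @examples
#' stb <- default_interventions()$stb
#' effective_caries_fraction(0.2008, stb, age = 9)  # 0.2008 * 0.905
#' @export
effective_caries_fraction <- function(base_fraction, spec, age,
                                      start_age = 6) {
  stopifnot(base_fraction >= 0, base_fraction <= 1)
  if (is.null(spec)) return(base_fraction)
  stopifnot(inherits(spec, "intervention_spec"))
  if (age < start_age + spec$onset_lag) return(base_fraction)
  base_fraction * (1 - coverage_effectiveness(spec))
}
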