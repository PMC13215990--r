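#' cariescea: system-dynamics cost-effectiveness of school caries prevention
#'
#' Stock-and-flow simulation of dental caries progression in a closed cohort
#' of Thai schoolchildren (ages 6-12), with provider-perspective costing and
#' cost-effectiveness analysis of supervised toothbrushing (STB) and dental
#' sealant programmes. The central fitting function is [calibrate_sdm()],
#' which estimates flow fractions and initial stocks from aggregate cohort
#' targets; [sdm_simulate()] is the underlying simulator.
#'
#' @keywords internal
"_PACKAGE"

.STOCK_NAMES <- c("caries_free", "caries_untreated", "filled", "endodontic",
                  "missing", "cum_fillings", "cum_endodontic",
                  "cum_extractions")
.POP_STOCKS <- .STOCK_NAMES[1:5]
.FRACTION_NAMES <- c("caries_fraction", "fill_fraction", "endo_fraction",
                     "extract_fraction", "recur_filled_fraction",
                     "recur_endo_fraction")

#' Population stocks of the caries progression model
#'
#' Constructs the state vector of the compartmental model: five population
#' stocks (children per caries/treatment state) plus three cumulative
#' treatment-event counters used for costing. The five population stocks must
#' sum to the (constant) cohort size; the cumulative counters track every
#' filling, endodontic treatment and extraction delivered, including
#' re-treatment of recurrent caries, and are therefore non-decreasing.
#'
#' @param caries_free Children who have never developed caries.
#' @param caries_untreated Children with untreated caries.
#' @param filled Children whose most recent treatment was a filling.
#' @param endodontic Children whose most recent treatment was endodontic.
#' @param missing Children with teeth extracted for caries (absorbing state).
#' @param cum_fillings,cum_endodontic,cum_extractions Cumulative counts of
#'   treatment events delivered up to this time point.
#'
#' @return A named numeric vector of class `"caries_stocks"`.
#' @examples
#' caries_stocks(caries_free = 678243)
#' @export
caries_stocks <- function(caries_free, caries_untreated = 0, filled = 0,
                          endodontic = 0, missing = 0, cum_fillings = 0,
                          cum_endodontic = 0, cum_extractions = 0) {
  x <- c(caries_free = caries_free, caries_untreated = caries_untreated,
         filled = filled, endodontic = endodontic, missing = missing,
         cum_fillings = cum_fillings, cum_endodontic = cum_endodontic,
         cum_extractions = cum_extractions)
  validate_stocks(x)
  class(x) <- "caries_stocks"
  x
}

validate_stocks <- function(x) {
  stopifnot(is.numeric(x), length(x) == length(.STOCK_NAMES))
  if (!identical(names(x), .STOCK_NAMES))
    stop("stocks must be named ", paste(.STOCK_NAMES, collapse = ", "))
  if (any(!is.finite(x))) stop("stocks must be finite")
  if (any(x < -1e-9)) {
    bad <- names(x)[x < -1e-9]
    stop("negative stock value(s): ", paste(bad, collapse = ", "))
  }
  invisible(x)
}

#' @export
print.caries_stocks <- function(x, ...) {
  cat("Caries model stocks (persons):\n")
  print(unclass(x), ...)
  cat("Population total:", format(sum(x[.POP_STOCKS]), big.mark = ","), "\n")
  invisible(x)
}

#' Annual flow fractions of the caries model
#'
#' The per-time-step transition fractions that drive the stock-and-flow
#' model. Each flow is the fraction times its source stock: caries incidence
#' drains `caries_free`; filling, endodontic treatment and extraction drain
#' `caries_untreated` (their fractions must sum to at most 1); recurrence
#' drains the `filled` and `endodontic` stocks back into `caries_untreated`,
#' the reinforcing feedback through which treated teeth develop new caries.
#'
#' @param caries_fraction Annual caries incidence fraction of the
#'   caries-free stock, in `[0, 1]`.
#' @param fill_fraction,endo_fraction,extract_fraction Annual treatment
#'   uptake fractions of the untreated-caries stock.
#' @param recur_filled_fraction,recur_endo_fraction Annual recurrent-caries
#'   fractions of the filled and endodontically treated stocks.
#'
#' @return A named numeric vector of class `"flow_fractions"`.
#' @examples
#' flow_fractions(caries_fraction = 0.2008)
#' @export
flow_fractions <- function(caries_fraction = 0, fill_fraction = 0,
                           endo_fraction = 0, extract_fraction = 0,
                           recur_filled_fraction = 0,
                           recur_endo_fraction = 0) {
  x <- c(caries_fraction = caries_fraction, fill_fraction = fill_fraction,
         endo_fraction = endo_fraction, extract_fraction = extract_fraction,
         recur_filled_fraction = recur_filled_fraction,
         recur_endo_fraction = recur_endo_fraction)
  validate_fractions(x)
  class(x) <- "flow_fractions"
  x
}

validate_fractions <- function(x) {
  stopifnot(is.numeric(x), length(x) == length(.FRACTION_NAMES))
  if (!identical(names(x), .FRACTION_NAMES))
    stop("fractions must be named ", paste(.FRACTION_NAMES, collapse = ", "))
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("each flow fraction must lie in [0, 1]")
  out <- x[["fill_fraction"]] + x[["endo_fraction"]] + x[["extract_fraction"]]
  if (out > 1 + 1e-12)
    stop("treatment outflow fractions sum to ", signif(out, 6),
         " > 1; the untreated-caries stock would go negative")
  invisible(x)
}

#' Simulation configuration for the caries cohort model
#'
#' Bundles the closed-cohort size, simulation ages, time step, initial
#' stocks and flow fractions. The five population stocks must sum exactly to
#' `total_population` (closed cohort: no births, deaths or migration).
#'
#' @param total_population Cohort size in persons. The default is the Thai
#'   2021 birth cohort registered with the National Statistical Office.
#' @param start_age,end_age Simulation age range in years (default 6 to 12,
#'   the age band in which the school programmes operate).
#' @param dt Time step in years; must divide `end_age - start_age` evenly.
#' @param initial_stocks A [caries_stocks()] vector at `start_age`.
#' @param fractions A [flow_fractions()] vector.
#' @param discount_rate Optional annual discount rate applied to costs
#'   (default 0, i.e. undiscounted).
#'
#' @return An object of class `"sdm_config"`.
#' @examples
#' cfg <- sdm_config(initial_stocks = caries_stocks(caries_free = 678243),
#'                   fractions = flow_fractions(caries_fraction = 0.2008))
#' @export
sdm_config <- function(total_population = 678243, start_age = 6,
                       end_age = 12, dt = 1, initial_stocks, fractions,
                       discount_rate = 0) {
  stopifnot(total_population > 0, start_age < end_age, dt > 0,
            discount_rate >= 0)
  n_steps <- (end_age - start_age) / dt
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stop("dt must divide end_age - start_age evenly")
  validate_stocks(initial_stocks)
  validate_fractions(fractions)
  pop <- sum(initial_stocks[.POP_STOCKS])
  if (abs(pop - total_population) > 1e-6 * total_population)
    stop("initial stocks sum to ", format(pop, big.mark = ","),
         ", not total_population = ",
         format(total_population, big.mark = ","))
  structure(list(total_population = total_population, start_age = start_age,
                 end_age = end_age, dt = dt,
                 initial_stocks = initial_stocks, fractions = fractions,
                 discount_rate = discount_rate),
            class = "sdm_config")
}

#' @export
print.sdm_config <- function(x, ...) {
  cat("Caries SDM configuration\n")
  cat("  cohort:", format(x$total_population, big.mark = ","),
      "children, ages", x$start_age, "to", x$end_age,
      sprintf("(dt = %g yr)\n", x$dt))
  cat("  fractions:\n")
  f <- unclass(x$fractions)
  for (nm in names(f)) cat(sprintf("    %-22s %.6g\n", nm, f[[nm]]))
  cat("  initial stocks:\n")
  s <- unclass(x$initial_stocks)
  for (nm in names(s)) cat(sprintf("    %-22s %.6g\n", nm, s[[nm]]))
  invisible(x)
}

#' Advance the stock vector by one time step
#'
#' Forward-Euler update of the stock-and-flow model. All flows are computed
#' simultaneously from the current state (standard stock-flow semantics, so
#' the update is independent of the order in which flows are written):
#' new caries drains the caries-free stock; filling, endodontic treatment and
#' extraction drain untreated caries into their treatment stocks; recurrent
#' caries returns treated children to the untreated stock, where they are
#' again eligible for (re-)treatment. Cumulative treatment counters are
#' incremented by the treatment flows, so re-treatment is counted again.
#' The five population stocks are conserved exactly by construction.
#'
#' @param stocks A [caries_stocks()] state vector.
#' @param fractions A [flow_fractions()] vector of per-year fractions.
#' @param dt Time step in years.
#'
#' @return The updated `"caries_stocks"` vector.
#' @examples
#' s <- caries_stocks(caries_free = 678243)
#' sdm_step(s, flow_fractions(caries_fraction = 0.2008))
#' @export
sdm_step <- function(stocks, fractions, dt = 1) {
  validate_stocks(stocks)
  validate_fractions(fractions)
  s <- unclass(stocks)
  f <- unclass(fractions)

  new_caries  <- f[["caries_fraction"]] * s[["caries_free"]] * dt
  fillings    <- f[["fill_fraction"]] * s[["caries_untreated"]] * dt
  endo        <- f[["endo_fraction"]] * s[["caries_untreated"]] * dt
  extractions <- f[["extract_fraction"]] * s[["caries_untreated"]] * dt
  recur       <- (f[["recur_filled_fraction"]] * s[["filled"]] +
                  f[["recur_endo_fraction"]] * s[["endodontic"]]) * dt

  out <- s
  out[["caries_free"]]      <- s[["caries_free"]] - new_caries
  out[["caries_untreated"]] <- s[["caries_untreated"]] + new_caries + recur -
                               (fillings + endo + extractions)
  out[["filled"]]     <- s[["filled"]] + fillings -
                         f[["recur_filled_fraction"]] * s[["filled"]] * dt
  out[["endodontic"]] <- s[["endodontic"]] + endo -
                         f[["recur_endo_fraction"]] * s[["endodontic"]] * dt
  out[["missing"]]    <- s[["missing"]] + extractions
  out[["cum_fillings"]]    <- s[["cum_fillings"]] + fillings
  out[["cum_endodontic"]]  <- s[["cum_endodontic"]] + endo
  out[["cum_extractions"]] <- s[["cum_extractions"]] + extractions

  if (any(out < -1e-9 * max(1, sum(s[.POP_STOCKS]))))
    stop("step produced a negative stock; flow fractions are inconsistent ",
         "with dt = ", dt, " (outflows exceed a stock)")
  out[out < 0] <- 0
  class(out) <- "caries_stocks"
  out
}

#' Simulate the caries cohort from start age to end age
#'
#' Runs [sdm_step()] from the initial stocks over the configured age range,
#' optionally under a preventive intervention. The intervention lowers the
#' caries-incidence fraction multiplicatively by its coverage-adjusted
#' effectiveness (see [intervention()]) from `start_age + onset_lag`
#' onwards; all other fractions are untouched.
#'
#' @param config An [sdm_config()] object.
#' @param intervention An [intervention()] specification, or `NULL` for the
#'   base case (no programme).
#'
#' @return A data frame of class `"caries_trajectory"` with one row per time
#'   point (`age` column plus the eight stock columns), and the config and
#'   intervention attached as attributes.
#' @examples
#' cfg <- sdm_config(initial_stocks = caries_stocks(caries_free = 678243),
#'                   fractions = flow_fractions(caries_fraction = 0.2008))
#' traj <- sdm_simulate(cfg)
#' tail(traj, 1)
#' @export
sdm_simulate <- function(config, intervention = NULL) {
  stopifnot(inherits(config, "sdm_config"))
  ages <- seq(config$start_age, config$end_age, by = config$dt)
  n <- length(ages)
  rec <- matrix(NA_real_, nrow = n, ncol = length(.STOCK_NAMES),
                dimnames = list(NULL, .STOCK_NAMES))
  s <- config$initial_stocks
  rec[1, ] <- unclass(s)
  base_f <- config$fractions
  for (i in seq_len(n - 1)) {
    f <- base_f
    if (!is.null(intervention))
      f[["caries_fraction"]] <- effective_caries_fraction(
        base_f[["caries_fraction"]], intervention, age = ages[i],
        start_age = config$start_age)
    s <- tryCatch(sdm_step(s, f, dt = config$dt),
                  error = function(e) stop("at age ", ages[i], ": ",
                                           conditionMessage(e)))
    rec[i + 1, ] <- unclass(s)
  }
  traj <- data.frame(age = ages, rec)
  class(traj) <- c("caries_trajectory", "data.frame")
  attr(traj, "config") <- config
  attr(traj, "intervention") <- intervention
  traj
}

#' @export
print.caries_trajectory <- function(x, ...) {
  iv <- attr(x, "intervention")
  cat("Caries cohort trajectory (",
      if (is.null(iv)) "base case" else iv$name, "), ages ",
      x$age[1], "-", x$age[nrow(x)], "\n", sep = "")
  print(as.data.frame(lapply(x, function(col) round(col, 1))), row.names = FALSE)
  invisible(x)
}

#' @export
plot.caries_trajectory <- function(x, which = .POP_STOCKS, ...) {
  graphics::matplot(x$age, as.matrix(x[, which, drop = FALSE]), type = "b",
                    pch = 1, lty = 1, xlab = "age (years)",
                    ylab = "children", ...)
  graphics::legend("right", legend = which, col = seq_along(which),
                   lty = 1, pch = 1, bty = "n", cex = 0.8)
  invisible(x)
}
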