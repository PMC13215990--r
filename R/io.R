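.require_field <- function(x, field, where) {
  if (is.null(x[[field]]))
    stop("configuration field missing: ", where, "$", field, call. = FALSE)
  x[[field]]
}

.num_field <- function(x, field, where) {
  v <- .require_field(x, field, where)
  if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
    stop("configuration field ", where, "$", field,
         " must be a single finite number", call. = FALSE)
  v
}

#' Read a model configuration file
#'
#' Parses and validates a YAML (or JSON) configuration describing the
#' simulation (cohort size, ages, time step, initial stocks, flow
#' fractions), the intervention scenarios, the unit-cost ranges and the
#' exchange rate. Validation failures name the offending field.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with components `config` ([sdm_config()]),
#'   `interventions` (named list of [intervention()], always including
#'   `base`), `unit_cost_ranges` (data frame) and `exchange_rate`.
#' @seealso [write_sdm_config()] for the inverse, [reproduction_fixture()]
#'   for the shipped calibrated configuration.
#' @export
read_sdm_config <- function(path) {
  if (!file.exists(path)) stop("no such configuration file: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)

  stocks_raw <- .require_field(raw, "initial_stocks", "")
  stocks <- do.call(caries_stocks, lapply(
    stats::setNames(.STOCK_NAMES, .STOCK_NAMES),
    function(nm) if (is.null(stocks_raw[[nm]])) 0
                 else .num_field(stocks_raw, nm, "initial_stocks")))
  frac_raw <- .require_field(raw, "fractions", "")
  fractions <- do.call(flow_fractions, lapply(
    stats::setNames(.FRACTION_NAMES, .FRACTION_NAMES),
    function(nm) if (is.null(frac_raw[[nm]])) 0
                 else .num_field(frac_raw, nm, "fractions")))
  config <- sdm_config(
    total_population = .num_field(raw, "total_population", ""),
    start_age = .num_field(raw, "start_age", ""),
    end_age = .num_field(raw, "end_age", ""),
    dt = if (is.null(raw$dt)) 1 else .num_field(raw, "dt", ""),
    initial_stocks = stocks, fractions = fractions,
    discount_rate = if (is.null(raw$discount_rate)) 0
                    else .num_field(raw, "discount_rate", ""))

  interventions <- list(base = intervention("base", 0, 0, 0))
  for (nm in names(raw$interventions)) {
    iv <- raw$interventions[[nm]]
    where <- paste0("interventions$", nm)
    interventions[[nm]] <- intervention(
      name = nm,
      effectiveness = .num_field(iv, "effectiveness", where),
      coverage = .num_field(iv, "coverage", where),
      unit_cost = .num_field(iv, "unit_cost", where),
      onset_lag = if (is.null(iv$onset_lag)) 0
                  else .num_field(iv, "onset_lag", where))
  }

  ucr <- unit_cost_ranges()
  if (!is.null(raw$unit_costs)) {
    ucr <- do.call(rbind, lapply(names(raw$unit_costs), function(sv) {
      u <- raw$unit_costs[[sv]]
      where <- paste0("unit_costs$", sv)
      data.frame(service = sv,
                 mean = .num_field(u, "mean", where),
                 min = .num_field(u, "min", where),
                 max = .num_field(u, "max", where))
    }))
    if (any(ucr$min > ucr$mean) || any(ucr$mean > ucr$max))
      stop("unit_costs must satisfy min <= mean <= max for every service")
  }
  list(config = config, interventions = interventions,
       unit_cost_ranges = ucr,
       exchange_rate = if (is.null(raw$exchange_rate)) 32
                       else .num_field(raw, "exchange_rate", ""))
}

#' Write a model configuration file
#'
#' Serialises a configuration bundle (as returned by [read_sdm_config()] or
#' [reproduction_fixture()]) to YAML or JSON. Reading the file back yields
#' an identical configuration.
#'
#' @param bundle List with `config`, `interventions`, `unit_cost_ranges`,
#'   `exchange_rate`.
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_sdm_config <- function(bundle, path) {
  cfg <- bundle$config
  stopifnot(inherits(cfg, "sdm_config"))
  ivs <- bundle$interventions
  ivs <- ivs[setdiff(names(ivs), "base")]
  ucr <- bundle$unit_cost_ranges
  raw <- list(
    total_population = cfg$total_population, start_age = cfg$start_age,
    end_age = cfg$end_age, dt = cfg$dt,
    discount_rate = cfg$discount_rate,
    initial_stocks = as.list(unclass(cfg$initial_stocks)),
    fractions = as.list(unclass(cfg$fractions)),
    interventions = lapply(ivs, function(iv)
      list(effectiveness = iv$effectiveness, coverage = iv$coverage,
           unit_cost = iv$unit_cost, onset_lag = iv$onset_lag)),
    unit_costs = stats::setNames(lapply(seq_len(nrow(ucr)), function(i)
      list(mean = ucr$mean[i], min = ucr$min[i], max = ucr$max[i])),
      ucr$service),
    exchange_rate = bundle$exchange_rate)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(raw, path, precision = 15)
  invisible(path)
}

#' Published-table-shaped cost comparison across the three scenarios
#'
#' Simulates base case, STB and sealant from one configuration and tabulates
#' annual programme cost, cumulative treatment cost and total cost per
#' scenario and age, in THB at mean unit costs.
#'
#' @param bundle Configuration bundle (see [reproduction_fixture()]).
#' @return A data frame with one row per age and one column per
#'   scenario/cost component.
#' @examples
#' scenario_costs(reproduction_fixture())
#' @export
scenario_costs <- function(bundle = reproduction_fixture()) {
  uc <- unit_costs("mean", bundle$unit_cost_ranges)
  out <- NULL
  for (nm in names(bundle$interventions)) {
    spec <- if (nm == "base") NULL else bundle$interventions[[nm]]
    traj <- sdm_simulate(bundle$config, spec)
    costs <- cost_trajectory(traj, spec, uc, bundle$exchange_rate)
    block <- costs[, c("intervention_cost", "treatment_cost", "total_cost")]
    names(block) <- paste0(nm, "_", names(block))
    out <- if (is.null(out)) data.frame(age = costs$age, block)
           else cbind(out, block)
  }
  out
}

#' Cost-effectiveness analysis of the three scenarios
#'
#' Simulates every scenario in the bundle to the evaluation horizon and
#' builds the [cea_table()]: CER per scenario, ICER of each programme
#' against the base case, head-to-head sealant-vs-STB ICER and dominance
#' quadrants.
#'
#' @param bundle Configuration bundle (see [reproduction_fixture()]).
#' @return A `"cea_table"` data frame.
#' @examples
#' run_cea(reproduction_fixture())
#' @export
run_cea <- function(bundle = reproduction_fixture()) {
  uc <- unit_costs("mean", bundle$unit_cost_ranges)
  rows <- lapply(names(bundle$interventions), function(nm) {
    spec <- if (nm == "base") NULL else bundle$interventions[[nm]]
    traj <- sdm_simulate(bundle$config, spec)
    costs <- cost_trajectory(traj, spec, uc, bundle$exchange_rate)
    horizon <- nrow(traj)
    data.frame(scenario = nm, total_cost = costs$total_cost[horizon],
               effectiveness = traj$caries_free[horizon])
  })
  cea_table(do.call(rbind, rows), comparator = "base",
            exchange_rate = bundle$exchange_rate)
}

#' Write a trajectory, cost table or CEA table to CSV
#'
#' Plain UTF-8 comma-separated output with a header row; numeric columns
#' are written at full precision.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Command-line entry point
#'
#' Dispatches the `simulate`, `cea` and `sensitivity` subcommands used by
#' the `inst/cli/cariescea` script. Results go to CSV files under `--out`;
#' a JSON run manifest listing every output file is written alongside.
#'
#' @param args Character vector of command-line arguments, e.g.
#'   `c("simulate", "--config", "cfg.yaml", "--scenario", "stb",
#'   "--out", "results")`.
#' @return Invisibly, the manifest list.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: cariescea <simulate|cea|sensitivity> --config <file>",
    "[--scenario <name>] [--intervention <name>] --out <dir>")
  if (length(args) < 1) stop(usage, call. = FALSE)
  cmd <- args[1]
  opts <- list(scenario = "base", intervention = "stb")
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% c("config", "scenario", "intervention", "out"))
      stop("unknown option ", args[i], "\n", usage, call. = FALSE)
    if (i + 1 > length(args)) stop("missing value for --", key, call. = FALSE)
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  if (is.null(opts$config) || is.null(opts$out))
    stop("--config and --out are required\n", usage, call. = FALSE)
  bundle <- read_sdm_config(opts$config)
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  emit <- function(x, name) {
    p <- file.path(opts$out, name)
    write_result_csv(x, p)
    outputs <<- c(outputs, p)
  }
  if (cmd == "simulate") {
    valid <- names(bundle$interventions)
    if (!opts$scenario %in% valid)
      stop("unknown scenario '", opts$scenario, "'; valid choices: ",
           paste(valid, collapse = ", "), call. = FALSE)
    spec <- if (opts$scenario == "base") NULL
            else bundle$interventions[[opts$scenario]]
    traj <- sdm_simulate(bundle$config, spec)
    emit(traj, paste0("trajectory_", opts$scenario, ".csv"))
    emit(cost_trajectory(traj, spec,
                         unit_costs("mean", bundle$unit_cost_ranges),
                         bundle$exchange_rate),
         paste0("costs_", opts$scenario, ".csv"))
  } else if (cmd == "cea") {
    emit(run_cea(bundle), "cea.csv")
  } else if (cmd == "sensitivity") {
    specs <- bundle$interventions[setdiff(names(bundle$interventions),
                                          "base")]
    res <- list()
    for (nm in names(specs)) {
      res[[nm]] <- run_sensitivity(bundle$config, specs[[nm]],
                                   cost_ranges = bundle$unit_cost_ranges)
      emit(res[[nm]], paste0("sensitivity_", nm, ".csv"))
    }
    if (all(c("stb", "sealant") %in% names(res)))
      emit(compare_best_worst(res$stb, res$sealant),
           "sensitivity_best_worst.csv")
  } else stop("unknown command '", cmd, "'\n", usage, call. = FALSE)
  manifest <- list(command = cmd, config = opts$config,
                   version = as.character(utils::packageVersion("cariescea")),
                   timestamp = format(Sys.time(), tz = "UTC",
                                      "%Y-%m-%dT%H:%M:%SZ"),
                   outputs = outputs)
  jsonlite::write_json(manifest, file.path(opts$out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
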