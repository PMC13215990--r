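# Small configurations used across tests; built in code, no stored fixtures.

pure_decay_config <- function(f = 0.2008, pop = 678243) {
  sdm_config(total_population = pop,
             initial_stocks = caries_stocks(caries_free = pop),
             fractions = flow_fractions(caries_fraction = f))
}

mixed_config <- function(pop = 1e5) {
  sdm_config(
    total_population = pop,
    initial_stocks = caries_stocks(
      caries_free = 0.7 * pop, caries_untreated = 0.15 * pop,
      filled = 0.08 * pop, endodontic = 0.04 * pop, missing = 0.03 * pop,
      cum_fillings = 0.1 * pop, cum_endodontic = 0.02 * pop,
      cum_extractions = 0.03 * pop),
    fractions = flow_fractions(
      caries_fraction = 0.18, fill_fraction = 0.25, endo_fraction = 0.1,
      extract_fraction = 0.05, recur_filled_fraction = 0.12,
      recur_endo_fraction = 0.08))
}

pop_total <- function(traj) {
  rowSums(traj[, c("caries_free", "caries_untreated", "filled",
                   "endodontic", "missing")])
}

# Self-consistency oracle: simulate a known synthetic configuration,
# rebuild the aggregate calibration targets from its own output, refit
# from a perturbed start, and return truth and fit for comparison.
synthetic_recovery_fit <- function(seed = 314, perturb = 0.25) {
  truth <- synthetic_flow_params(seed = seed)
  cfg <- sdm_config(total_population = 678243,
                    initial_stocks = truth$initial_stocks,
                    fractions = truth$fractions)
  ivs <- default_interventions()
  uc <- unit_costs()
  trajs <- list(base = sdm_simulate(cfg),
                stb = sdm_simulate(cfg, ivs$stb),
                sealant = sdm_simulate(cfg, ivs$sealant))
  tc <- data.frame(age = trajs$base$age,
                   base = treatment_cost(trajs$base, uc),
                   stb = treatment_cost(trajs$stb, uc),
                   sealant = treatment_cost(trajs$sealant, uc))
  sc <- cohort_targets()$scenario_costs
  for (i in seq_len(nrow(sc))) {
    spec <- intervention(sc$intervention[i], sc$effectiveness[i],
                         sc$coverage[i], onset_lag = 0)
    traj <- sdm_simulate(cfg, spec)
    uci <- unit_costs(sc$cost_level[i])
    sc$total_cost[i] <- intervention_cost(spec, 678243,
                                          unit_cost = uci[[spec$name]]) +
      treatment_cost(traj[nrow(traj), ], uci)
  }
  target <- cohort_targets(
    caries_free = vapply(trajs, function(t) tail(t$caries_free, 1),
                         numeric(1)),
    treatment_cost = tc, scenario_costs = sc)
  start_true <- with(as.list(unclass(truth$fractions)), c(
    caries_fraction = qlogis(caries_fraction),
    treat_total = qlogis(fill_fraction + endo_fraction + extract_fraction),
    treat_share_fill = qlogis(fill_fraction /
      (fill_fraction + endo_fraction + extract_fraction)),
    treat_share_endo = qlogis(endo_fraction /
      (endo_fraction + extract_fraction)),
    recur_filled = qlogis(recur_filled_fraction),
    recur_endo = qlogis(recur_endo_fraction)))
  s <- unclass(truth$initial_stocks)
  affected <- sum(s[2:5])
  start_true <- c(start_true,
    init_affected = qlogis(affected / 678243),
    init_share_untreated = qlogis(s[["caries_untreated"]] / affected),
    init_share_filled = qlogis(s[["filled"]] /
      (affected - s[["caries_untreated"]])),
    init_share_endo = qlogis(s[["endodontic"]] /
      (s[["endodontic"]] + s[["missing"]])),
    cum_fillings_share = qlogis(1e-6), cum_endodontic_share = qlogis(1e-6),
    cum_extractions_share = qlogis(1e-6))
  fit <- calibrate_sdm(target, interventions = ivs,
                       start = start_true + perturb)
  list(truth = truth, fit = fit)
}
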