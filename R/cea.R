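#' Cost-effectiveness ratio
#'
#' Total cost divided by effectiveness; here THB per caries-free child.
#'
#' @param total_cost Total cost in THB.
#' @param effectiveness Effectiveness in persons (caries-free children);
#'   must be positive.
#' @return THB per caries-free child.
#' @examples
#' cer(68898100, 176722)  # base case, ~389.9
#' @export
cer <- function(total_cost, effectiveness) {
  if (any(effectiveness <= 0))
    stop("effectiveness must be positive to form a CER")
  total_cost / effectiveness
}

#' Incremental cost-effectiveness ratio
#'
#' Difference in total costs divided by difference in effectiveness between
#' a strategy and its comparator. When the two strategies are equally
#' effective the ratio is undefined and `NA` is returned (not an error);
#' negative values are meaningful and should be read together with their
#' dominance quadrant from [cea_quadrant()].
#'
#' @param cost_a,eff_a Total cost and effectiveness of the strategy.
#' @param cost_b,eff_b Total cost and effectiveness of the comparator.
#' @return THB per additional caries-free child, or `NA` when
#'   `eff_a == eff_b`.
#' @examples
#' icer(104591500, 194701, 68898100, 176722)  # STB vs base, ~1985.3
#' @export
icer <- function(cost_a, eff_a, cost_b, eff_b) {
  d_eff <- eff_a - eff_b
  ifelse(d_eff == 0, NA_real_, (cost_a - cost_b) / d_eff)
}

#' Dominance quadrant of an incremental comparison
#'
#' Classifies the cost-effectiveness plane position of a strategy relative
#' to its comparator: `"dominant"` (more effective, less costly),
#' `"dominated"` (less effective, more costly), `"trade-off"` (more
#' effective and more costly), `"cost-saving-less-effective"`, or
#' `"undefined"` when the effectiveness difference is zero.
#'
#' @param delta_cost Cost difference (strategy minus comparator), THB.
#' @param delta_eff Effectiveness difference, persons.
#' @return A character label.
#' @examples
#' cea_quadrant(-686300, 10941)  # sealant vs STB: "dominant"
#' @export
cea_quadrant <- function(delta_cost, delta_eff) {
  q <- function(dc, de) {
    if (de == 0) "undefined"
    else if (de > 0 && dc < 0) "dominant"
    else if (de < 0 && dc > 0) "dominated"
    else if (de > 0) "trade-off"
    else "cost-saving-less-effective"
  }
  mapply(q, delta_cost, delta_eff)
}

#' Cost-effectiveness table for a set of scenarios
#'
#' Builds the scenario comparison table: CER per scenario, ICER of each
#' intervention against the comparator, the head-to-head ICER between the
#' two interventions, and dominance quadrants.
#'
#' @param scenarios Data frame with columns `scenario`, `total_cost`,
#'   `effectiveness` (one row per strategy at the evaluation horizon).
#' @param comparator Name of the reference scenario (default `"base"`).
#' @param exchange_rate THB per USD for the companion USD columns.
#' @return A data frame of class `"cea_table"` with columns `scenario`,
#'   `total_cost`, `effectiveness`, `cer`, `icer_vs_base`,
#'   `quadrant_vs_base`, `icer_vs_previous`, `quadrant_vs_previous`, where
#'   "previous" is the preceding non-comparator row (the head-to-head
#'   comparison between interventions).
#' @examples
#' tab <- cea_table(data.frame(
#'   scenario = c("base", "stb", "sealant"),
#'   total_cost = c(68898100, 104591500, 103905200),
#'   effectiveness = c(176722, 194701, 205642)))
#' tab
#' @export
cea_table <- function(scenarios, comparator = "base", exchange_rate = 32) {
  stopifnot(all(c("scenario", "total_cost", "effectiveness") %in%
                names(scenarios)))
  if (!comparator %in% scenarios$scenario)
    stop("comparator '", comparator, "' not among scenarios")
  sc <- scenarios
  ref <- sc[sc$scenario == comparator, ]
  sc$cer <- cer(sc$total_cost, sc$effectiveness)
  sc$icer_vs_base <- ifelse(
    sc$scenario == comparator, NA_real_,
    icer(sc$total_cost, sc$effectiveness, ref$total_cost, ref$effectiveness))
  sc$quadrant_vs_base <- ifelse(
    sc$scenario == comparator, NA_character_,
    cea_quadrant(sc$total_cost - ref$total_cost,
                 sc$effectiveness - ref$effectiveness))
  iv <- which(sc$scenario != comparator)
  sc$icer_vs_previous <- NA_real_
  sc$quadrant_vs_previous <- NA_character_
  if (length(iv) >= 2) {
    for (k in 2:length(iv)) {
      a <- iv[k]; b <- iv[k - 1]
      sc$icer_vs_previous[a] <- icer(sc$total_cost[a], sc$effectiveness[a],
                                     sc$total_cost[b], sc$effectiveness[b])
      sc$quadrant_vs_previous[a] <- cea_quadrant(
        sc$total_cost[a] - sc$total_cost[b],
        sc$effectiveness[a] - sc$effectiveness[b])
    }
  }
  attr(sc, "exchange_rate") <- exchange_rate
  class(sc) <- c("cea_table", "data.frame")
  sc
}

#' @export
print.cea_table <- function(x, ...) {
  rate <- attr(x, "exchange_rate")
  cat("Cost-effectiveness at evaluation horizon (THB; USD at",
      rate, "THB/USD)\n")
  disp <- data.frame(
    scenario = x$scenario,
    total_cost = format(display_round(x$total_cost), big.mark = ","),
    caries_free = format(round(x$effectiveness), big.mark = ","),
    cer = sprintf("%.1f (%.2f)", x$cer, thb_to_usd(x$cer, rate)),
    icer_vs_base = ifelse(is.na(x$icer_vs_base), "-",
                          sprintf("%.1f", x$icer_vs_base)),
    head_to_head = ifelse(is.na(x$icer_vs_previous), "-",
                          sprintf("%.1f [%s]", x$icer_vs_previous,
                                  x$quadrant_vs_previous)))
  print(disp, row.names = FALSE)
  invisible(x)
}
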