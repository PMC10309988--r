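# Annual cost accounting for dairy farms under a farm-system approach.
#
# Variable costs: VC = E1+E2+E3+E4+E5+E6+E7+E8+E10+E11+E12+E17, with E5 taken
# as the paid amount (scenario A) or the opportunity value of subsidised
# veterinary services (scenario B).
# Fixed costs:    FC = E9+E13+E14+E15+E16+E18.
# Total cost TC = VC + FC per scenario; milk production cost TCM excludes calf
# feeding (E2), mortality (E14, E15) and theft (E16) from TC_A; CPM = TCM per
# litre produced; revenues TR = R1+R2+R3; profit P = TR - TC.

VC_CODES <- c("e1", "e2", "e3", "e4", "e6", "e7", "e8", "e10", "e11", "e12", "e17")
FC_CODES <- c("e9", "e13", "e14", "e15", "e16", "e18")

ledger_cols <- function(ledger, cols) {
  missing <- setdiff(cols, names(ledger))
  if (length(missing) > 0) {
    abort(paste0("ledger is missing column(s): ", paste(missing, collapse = ", ")),
          class = "acarecon_schema_error")
  }
  m <- as.matrix(as.data.frame(ledger)[, cols, drop = FALSE])
  if (any(!is.finite(m))) {
    abort("ledger amounts must be finite", class = "acarecon_input_error")
  }
  if (any(m < 0)) {
    abort("ledger amounts must be non-negative", class = "acarecon_input_error")
  }
  m
}

scenario_e5 <- function(ledger, scenario) {
  col <- if (scenario == "A") "e5_real" else "e5_opportunity"
  as.numeric(ledger_cols(ledger, col))
}

#' Annual variable costs
#'
#' Sum of the twelve variable-cost codes E1-E8, E10-E12 and E17, with the E5
#' term resolved by scenario: A uses the veterinary services actually paid,
#' B uses the opportunity value of state-subsidised services.
#'
#' @param ledger A data frame with one row per farm holding the expense
#'   columns `e1`..`e4`, `e5_real`, `e5_opportunity`, `e6`..`e18` (USD/yr).
#' @param scenario `"A"` (paid veterinary services) or `"B"` (subsidised
#'   services valued at opportunity cost).
#' @return Numeric vector of variable costs, USD/yr.
#' @export
#' @examples
#' led <- data.frame(t(setNames(rep(1, 19), acarecon:::expense_columns())))
#' variable_costs(led, "A")  # 12 one-dollar terms
variable_costs <- function(ledger, scenario = c("A", "B")) {
  scenario <- match.arg(scenario)
  rowSums(ledger_cols(ledger, VC_CODES)) + scenario_e5(ledger, scenario)
}

#' Annual fixed costs
#'
#' Sum of the six fixed-cost codes E9, E13-E16 and E18.
#'
#' @inheritParams variable_costs
#' @return Numeric vector of fixed costs, USD/yr.
#' @export
fixed_costs <- function(ledger) {
  rowSums(ledger_cols(ledger, FC_CODES))
}

#' Total annual livestock production cost
#'
#' `TC = VC + FC` under the chosen veterinary-service scenario. The two
#' scenarios differ exactly by the E5 gap:
#' `TC_B - TC_A = e5_opportunity - e5_real`.
#'
#' @inheritParams variable_costs
#' @return Numeric vector of total costs, USD/yr.
#' @export
total_cost <- function(ledger, scenario = c("A", "B")) {
  scenario <- match.arg(scenario)
  variable_costs(ledger, scenario) + fixed_costs(ledger)
}

#' Total cost of milk production and cost per litre
#'
#' The milk production cost excludes from the scenario-A total cost the calf
#' feeding (E2), mortality (E14, E15) and cattle theft (E16) components, since
#' replacement-animal purchases are costed instead:
#' `TCM = TC_A - E2 - E14 - E15 - E16`. The per-litre cost is
#' `CPM = TCM / annual_litres`; with zero litres TCM is still returned and CPM
#' is `NA` (undefined).
#'
#' @inheritParams variable_costs
#' @param annual_litres Litres of milk produced per year (>= 0).
#' @return A tibble with columns `tcm` (USD/yr) and `cpm` (USD/litre).
#' @export
milk_production_cost <- function(ledger, annual_litres) {
  if (any(!is.finite(annual_litres)) || any(annual_litres < 0)) {
    abort("annual_litres must be finite and non-negative",
          class = "acarecon_input_error")
  }
  excl <- rowSums(ledger_cols(ledger, c("e2", "e14", "e15", "e16")))
  tcm <- total_cost(ledger, "A") - excl
  cpm <- ifelse(annual_litres > 0, tcm / annual_litres, NA_real_)
  tibble::tibble(tcm = tcm, cpm = cpm)
}

#' Total annual revenue
#'
#' `TR = R1 + R2 + R3`: milk delivered or sold, on-farm milk consumption
#' valued at opportunity cost, and cattle sales.
#'
#' @param rev A data frame with non-negative columns `r1`, `r2`, `r3` (USD/yr).
#' @return Numeric vector of total revenues, USD/yr.
#' @export
total_revenue <- function(rev) {
  rowSums(ledger_cols(rev, revenue_columns()))
}

#' Annual milk revenue
#'
#' Cows in production times the mean of dry- and rainy-season daily yields
#' times the milk price over `days` days.
#'
#' @param cows_in_production Number of cows in production.
#' @param daily_litres_dry,daily_litres_rainy Litres per cow per day in each
#'   season.
#' @param price Milk price, USD/litre.
#' @param days Days per year (default 365).
#' @return Numeric vector, USD/yr.
#' @export
#' @examples
#' milk_revenue(10, 10, 10, 0.37)  # 13505
milk_revenue <- function(cows_in_production, daily_litres_dry,
                         daily_litres_rainy, price, days = 365) {
  args <- cbind(cows_in_production, daily_litres_dry, daily_litres_rainy,
                price, days)
  if (any(!is.finite(args)) || any(args < 0)) {
    abort("milk_revenue inputs must be finite and non-negative",
          class = "acarecon_input_error")
  }
  cows_in_production * (daily_litres_dry + daily_litres_rainy) / 2 * price * days
}

#' Annual profit
#'
#' `P = TR - TC`; may be negative.
#'
#' @param tr Total revenue, USD/yr.
#' @param tc Total livestock production cost for the chosen scenario, USD/yr.
#' @return Numeric vector, USD/yr.
#' @export
annual_profit <- function(tr, tc) tr - tc

#' Depreciation rule for an asset class
#'
#' Default useful lives: infrastructure 20 years, equipment 11 years, cows 9
#' years, bulls 5 years; residual value 0.
#'
#' @param asset_class One of `"infrastructure"`, `"equipment"`, `"cow"`,
#'   `"bull"`.
#' @param useful_life_years Override of the default useful life (> 0).
#' @param residual_value Residual value at end of life, USD (default 0).
#' @return A list of class `depreciation_rule`.
#' @export
depreciation_rule <- function(asset_class = c("infrastructure", "equipment",
                                              "cow", "bull"),
                              useful_life_years = NULL,
                              residual_value = 0) {
  asset_class <- match.arg(asset_class)
  default_life <- c(infrastructure = 20, equipment = 11, cow = 9, bull = 5)
  life <- useful_life_years %||% default_life[[asset_class]]
  if (!is.finite(life) || life <= 0) {
    abort("useful_life_years must be > 0", class = "acarecon_input_error")
  }
  structure(list(asset_class = asset_class, useful_life_years = life,
                 residual_value = residual_value),
            class = "depreciation_rule")
}

#' Straight-line annual depreciation
#'
#' `(purchase_value - residual) / useful_life_years`.
#'
#' @param purchase_value Purchase value, USD (>= 0).
#' @param rule A [depreciation_rule()] (or an asset-class name).
#' @return Annual depreciation, USD/yr.
#' @export
#' @examples
#' straight_line_depreciation(10000, depreciation_rule("infrastructure"))  # 500
straight_line_depreciation <- function(purchase_value, rule = depreciation_rule()) {
  if (is.character(rule)) rule <- depreciation_rule(rule)
  if (any(purchase_value < 0)) {
    abort("purchase_value must be non-negative", class = "acarecon_input_error")
  }
  (purchase_value - rule$residual_value) / rule$useful_life_years
}

#' Annual replacement cost of an animal
#'
#' The animal's price spread over its average useful life (the E17
#' contribution per animal): cows over 9 years, bulls over 5 by default.
#'
#' @param animal_price Price of the animal, USD (>= 0).
#' @param rule A [depreciation_rule()] for `"cow"` or `"bull"`.
#' @return USD/yr per animal.
#' @export
replacement_cost <- function(animal_price, rule = depreciation_rule("cow")) {
  if (is.character(rule)) rule <- depreciation_rule(rule)
  if (any(animal_price < 0)) {
    abort("animal_price must be non-negative", class = "acarecon_input_error")
  }
  animal_price / rule$useful_life_years
}

#' Family labour requirement for milking
#'
#' One worker milks 18 animals by hand or 25 with mechanical milking; partial
#' workers are impossible, so the requirement is the ceiling of the ratio
#' (0 when there are no milking cows).
#'
#' @param milking_cows Number of cows milked.
#' @param milking_type `"manual"` or `"mechanical"`.
#' @return Integer number of workers.
#' @export
#' @examples
#' family_labor_requirement(19, "manual")  # 2
family_labor_requirement <- function(milking_cows,
                                     milking_type = c("manual", "mechanical")) {
  milking_type <- match.arg(milking_type)
  if (any(milking_cows < 0)) {
    abort("milking_cows must be non-negative", class = "acarecon_input_error")
  }
  per_worker <- if (milking_type == "manual") 18 else 25
  as.integer(ceiling(milking_cows / per_worker))
}

#' Deflate an observed price by one year of inflation
#'
#' Drug prices collected a year after the fiscal period are brought back by
#' one multiplicative period: `price * (1 - annual_inflation)`. The default
#' rate is 2.56%/yr.
#'
#' @param observed_price Observed price, USD (>= 0).
#' @param annual_inflation Annual inflation as a proportion in `[0, 1)`.
#' @return Deflated price, USD.
#' @export
#' @examples
#' deflate_price(100)  # 97.44
deflate_price <- function(observed_price, annual_inflation = 0.0256) {
  if (any(observed_price < 0)) {
    abort("observed_price must be non-negative", class = "acarecon_input_error")
  }
  if (any(annual_inflation < 0) || any(annual_inflation >= 1)) {
    abort("annual_inflation must lie in [0, 1)", class = "acarecon_input_error")
  }
  observed_price * (1 - annual_inflation)
}

#' Mortality rule
#'
#' @param cap_fraction Maximum fraction of the herd whose deaths are costed
#'   per year (default 0.03, the area's average mortality).
#' @return A list of class `mortality_rule`.
#' @export
mortality_rule <- function(cap_fraction = 0.03) {
  if (cap_fraction < 0 || cap_fraction > 1) {
    abort("cap_fraction must lie in [0, 1]", class = "acarecon_input_error")
  }
  structure(list(cap_fraction = cap_fraction), class = "mortality_rule")
}

#' Annual mortality cost with a herd-level cap
#'
#' Reported deaths are costed per animal class at the class's unit cost
#' (annual depreciation value, plus - for cows - the lost annual milk
#' remuneration and the value of a newborn calf, already folded into the unit
#' cost by the caller). The number of costed deaths is capped at the floor of
#' `cap_fraction * herd_size`; when the cap binds, the cheapest deaths are
#' costed first.
#'
#' @param herd_size Total herd size (> 0).
#' @param deaths Named integer vector of reported deaths per animal class.
#' @param unit_costs Named numeric vector of per-death cost (USD) per class;
#'   names must match `deaths`.
#' @param rule A [mortality_rule()].
#' @return A list with `n_costed` (deaths actually costed) and `cost`
#'   (USD/yr).
#' @export
#' @examples
#' mortality_cost(100, c(cow = 5), c(cow = 1650.5))  # 3 deaths costed
mortality_cost <- function(herd_size, deaths, unit_costs,
                           rule = mortality_rule()) {
  if (length(herd_size) != 1 || !is.finite(herd_size) || herd_size <= 0) {
    abort("herd_size must be a single positive count",
          class = "acarecon_input_error")
  }
  if (any(deaths < 0) || any(deaths != round(deaths))) {
    abort("deaths must be non-negative integers", class = "acarecon_input_error")
  }
  if (!setequal(names(deaths), names(unit_costs)) || is.null(names(deaths))) {
    abort("deaths and unit_costs must share class names",
          class = "acarecon_input_error")
  }
  cap <- floor(rule$cap_fraction * herd_size)
  n_costed <- min(sum(deaths), cap)
  # cost cheapest deaths first when the cap binds
  unit_costs <- unit_costs[names(deaths)]
  expanded <- sort(rep(unname(unit_costs), times = deaths))
  costed <- head(expanded, n_costed)
  list(n_costed = as.integer(n_costed), cost = sum(costed))
}

# Resolve the E8-into-E5 merge: when a professional performs insemination the
# insemination outlay belongs with veterinary services (scenario A side) and
# E8 is zeroed, so the amount is never counted twice.
resolve_insemination <- function(farms) {
  flag <- farms$insemination_by_professional %||% rep(FALSE, nrow(farms))
  flag[is.na(flag)] <- FALSE
  farms$e5_real <- farms$e5_real + ifelse(flag, farms$e8, 0)
  farms$e8 <- ifelse(flag, 0, farms$e8)
  farms
}

#' Per-farm economic summary
#'
#' Computes, for every farm: variable and fixed costs, total cost under both
#' veterinary-service scenarios, total milk production cost and cost per
#' litre, annual milk production, total revenue and profit under both
#' scenarios. Farms flagged `insemination_by_professional` have their E8
#' amount moved into E5 (scenario A side) before summation.
#'
#' @param farms A farm-record tibble (see [farm_schema()]).
#' @param days Days per year used for annual milk production (default 365).
#' @return A tibble with columns `farm_id`, `vc_a`, `vc_b`, `fc`, `tc_a`,
#'   `tc_b`, `tcm`, `cpm`, `amp`, `tr`, `p_a`, `p_b` (USD/yr; `cpm` in
#'   USD/litre, `amp` in litres/yr).
#' @export
economic_summary <- function(farms, days = 365) {
  farms <- resolve_insemination(farms)
  amp <- farms$cows_in_production *
    (farms$daily_litres_dry + farms$daily_litres_rainy) / 2 * days
  milk <- milk_production_cost(farms, amp)
  tc_a <- total_cost(farms, "A")
  tc_b <- total_cost(farms, "B")
  tr <- total_revenue(farms)
  tibble::tibble(
    farm_id = farms$farm_id,
    vc_a = variable_costs(farms, "A"),
    vc_b = variable_costs(farms, "B"),
    fc = fixed_costs(farms),
    tc_a = tc_a, tc_b = tc_b,
    tcm = milk$tcm, cpm = milk$cpm, amp = amp,
    tr = tr,
    p_a = annual_profit(tr, tc_a),
    p_b = annual_profit(tr, tc_b)
  )
}

#' Acaricide-treatment cost metrics (Models 1-4 responses)
#'
#' Per farm:
#' * `model1_pct_of_tc`: acaricide treatment cost (drugs + application
#'   labour) as a percentage of the total production cost;
#' * `model2_usd_per_adult`: treatment cost in USD per adult animal (> 1
#'   year old);
#' * `model3_pct_of_e6`: tick-control drug cost (acaricides,
#'   hemo-parasiticides, repellents) as a percentage of the veterinary drugs
#'   and inputs ledger E6;
#' * `model4_pct_of_sanitary`: treatment cost as a percentage of the sanitary
#'   cost (E6 + scenario E5 + sanitary labour).
#'
#' Metrics with a zero denominator are returned as `NA` while the others are
#' still computed.
#'
#' @param farms A farm-record tibble.
#' @param summary Optional precomputed [economic_summary()] for `farms`.
#' @param scenario Scenario used for the total-cost and sanitary denominators
#'   (default `"A"`).
#' @param sanitary_labor_fraction Fraction of total labour (E3 + E4) counted
#'   as sanitary-task labour on top of the acaricide application labour
#'   (default 0; task-level labour data are rarely available).
#' @return A tibble with the four model responses plus `treatment_cost`,
#'   `tick_drug_cost` and `sanitary_cost` (USD/yr).
#' @export
acaricide_cost_metrics <- function(farms, summary = economic_summary(farms),
                                   scenario = c("A", "B"),
                                   sanitary_labor_fraction = 0) {
  scenario <- match.arg(scenario)
  farms0 <- resolve_insemination(farms)
  treatment_cost <- farms$acaricide_drug_cost + farms$treatment_labor_cost
  tick_drug_cost <- farms$acaricide_drug_cost +
    (farms$hemo_repellent_drug_cost %||% rep(0, nrow(farms)))
  tc <- if (scenario == "A") summary$tc_a else summary$tc_b
  e5 <- scenario_e5(farms0, scenario)
  sanitary_labor <- farms$treatment_labor_cost +
    sanitary_labor_fraction * (farms$e3 + farms$e4)
  sanitary_cost <- farms$e6 + e5 + sanitary_labor
  pct <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  tibble::tibble(
    farm_id = farms$farm_id,
    treatment_cost = treatment_cost,
    tick_drug_cost = tick_drug_cost,
    sanitary_cost = sanitary_cost,
    model1_pct_of_tc = pct(treatment_cost, tc),
    model2_usd_per_adult = ifelse(farms$herd_size_adults > 0,
                                  treatment_cost / farms$herd_size_adults,
                                  NA_real_),
    model3_pct_of_e6 = pct(tick_drug_cost, farms$e6),
    model4_pct_of_sanitary = pct(treatment_cost, sanitary_cost)
  )
}
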