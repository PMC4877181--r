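# Tax scenarios: revised cost per drink, elasticity-driven consumption
# response, and each respondent's net cost.

#' Define a tax scenario
#'
#' A scenario either adds a fixed dollar amount of tax per drink
#' (`per_drink_tax`) or raises the retail cost per drink by a fraction
#' (`percent_of_price`). Pass-through is the fraction of a per-drink tax that
#' reaches the retail price; the conventional incidence assumption is full
#' (100%) pass-through.
#'
#' @param mode `"per_drink_tax"` or `"percent_of_price"`.
#' @param amount Dollars per drink (per_drink_tax) or a fraction
#'   (percent_of_price); non-negative.
#' @param pass_through Fraction in (0, 1], default 1.
#' @param label Optional display label; defaults to a compact description.
#' @return A `tax_scenario` list.
#' @export
#' @examples
#' tax_scenario("per_drink_tax", 0.05)
#' tax_scenario("percent_of_price", 0.05)
tax_scenario <- function(mode = c("per_drink_tax", "percent_of_price"),
                         amount, pass_through = 1, label = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(amount) || length(amount) != 1 || amount < 0) {
    stop("scenario amount must be a single non-negative number", call. = FALSE)
  }
  if (pass_through <= 0 || pass_through > 1) {
    stop("pass_through must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(label)) {
    label <- if (mode == "per_drink_tax") {
      sprintf("$%.2f per drink", amount)
    } else {
      sprintf("%g%% of drink price", 100 * amount)
    }
  }
  structure(
    list(mode = mode, amount = amount, pass_through = pass_through, label = label),
    class = "tax_scenario"
  )
}

#' The standard scenario battery
#'
#' Per-drink tax increases of $0.05, $0.10, and $0.25, plus a 5% increase in
#' the retail price of a drink, all at 100% pass-through.
#'
#' @return A named list of [tax_scenario()] objects.
#' @export
default_scenarios <- function() {
  scens <- list(
    tax_scenario("per_drink_tax", 0.05),
    tax_scenario("per_drink_tax", 0.10),
    tax_scenario("per_drink_tax", 0.25),
    tax_scenario("percent_of_price", 0.05)
  )
  stats::setNames(scens, vapply(scens, `[[`, character(1), "label"))
}

#' Default beverage price elasticities
#'
#' Meta-analytic beverage-specific price elasticities of demand: beer -0.46,
#' wine -0.69, spirits -0.80. These are parameters of the model, not
#' constants; every analysis states the values it uses.
#'
#' @return Named numeric vector of elasticities.
#' @export
default_elasticities <- function() {
  c(beer = -0.46, wine = -0.69, spirits = -0.80)
}

check_elasticities <- function(eps, allow_out_of_range = FALSE) {
  if (is.null(names(eps)) || !setequal(names(eps), beverages)) {
    stop("elasticities must be named beer, wine, spirits", call. = FALSE)
  }
  if (!allow_out_of_range && any(eps < -2 | eps > 0)) {
    stop("elasticities outside [-2, 0]; pass allow_out_of_range = TRUE to override",
      call. = FALSE
    )
  }
  eps[beverages]
}

#' Revised cost per drink under a scenario
#'
#' Fixed per-drink tax: `c' = c + pass_through * amount`. Percent scenario:
#' `c' = c * (1 + amount)`.
#'
#' @param cost_per_drink Baseline total cost per drink (product plus tax), $.
#' @param scenario A [tax_scenario()].
#' @return New cost per drink, $.
#' @export
new_cost_per_drink <- function(cost_per_drink, scenario) {
  stopifnot(inherits(scenario, "tax_scenario"))
  if (scenario$mode == "per_drink_tax") {
    cost_per_drink + scenario$pass_through * scenario$amount
  } else {
    cost_per_drink * (1 + scenario$amount)
  }
}

#' Share-weighted price elasticity
#'
#' Collapses beverage-specific elasticities to a single state-level value by
#' weighting with the state's beverage consumption shares.
#'
#' @param elasticities Named vector (`beer`, `wine`, `spirits`).
#' @param shares Named beverage shares summing to 1.
#' @param allow_out_of_range Permit elasticities outside `[-2, 0]`.
#' @return A single elasticity.
#' @export
weighted_elasticity <- function(elasticities, shares,
                                allow_out_of_range = FALSE) {
  eps <- check_elasticities(elasticities, allow_out_of_range)
  shares <- check_shares(shares)
  sum(shares * eps)
}

#' Consumption response to a price change
#'
#' Applies the elasticity as a proportional response to the relative change
#' in the total cost per drink: `D' = D * (1 + eps * (c' - c) / c)`, floored
#' at zero. The base is the tax-inclusive cost, since that is the price
#' consumers face.
#'
#' @param annual Baseline annual drinks, non-negative.
#' @param cost Baseline cost per drink, must be positive.
#' @param new_cost Revised cost per drink.
#' @param elasticity Price elasticity (typically negative).
#' @return Adjusted annual drinks.
#' @export
#' @examples
#' consumption_response(128, 1.60, 1.65, -0.5) # 126
consumption_response <- function(annual, cost, new_cost, elasticity) {
  if (any(cost <= 0)) stop("baseline cost per drink must be positive", call. = FALSE)
  if (any(annual < 0)) stop("annual drinks must be non-negative", call. = FALSE)
  pmax(0, annual * (1 + elasticity * (new_cost - cost) / cost))
}

#' Net cost of a price change for one consumption level
#'
#' New annual expenditure at the reduced consumption, minus baseline annual
#' expenditure: `net = D' * c' - D * c`.
#'
#' @inheritParams consumption_response
#' @return A tibble with `baseline_annual_drinks`, `adjusted_annual_drinks`,
#'   `baseline_spend`, `new_spend`, `net_cost` (all vectorized).
#' @export
#' @examples
#' net_cost(128, 1.60, 1.65, -0.5)$net_cost # 3.10
net_cost <- function(annual, cost, new_cost, elasticity) {
  adjusted <- consumption_response(annual, cost, new_cost, elasticity)
  baseline_spend <- annual * cost
  new_spend <- adjusted * new_cost
  tibble::tibble(
    baseline_annual_drinks = annual,
    adjusted_annual_drinks = adjusted,
    baseline_spend = baseline_spend,
    new_spend = new_spend,
    net_cost = new_spend - baseline_spend
  )
}

#' Per-respondent net costs across a scenario battery
#'
#' Joins classified microdata with state cost profiles, computes each
#' respondent's baseline annual drinks, and evaluates every scenario:
#' revised cost per drink, elasticity-adjusted consumption, and net cost.
#'
#' @param microdata Classified microdata (see [classify_drinker()]).
#' @param profiles State cost profiles from [build_state_cost_profiles()].
#' @param scenarios List of [tax_scenario()] objects, default
#'   [default_scenarios()].
#' @param elasticities Named beverage elasticities, default
#'   [default_elasticities()]; collapsed per state with the state's beverage
#'   shares.
#' @return A tibble with one row per respondent per scenario: identifiers,
#'   stratifiers, survey weight, `scenario`, the [net_cost()] columns, and
#'   the state's baseline/new cost per drink.
#' @export
compute_cost_results <- function(microdata, profiles,
                                 scenarios = default_scenarios(),
                                 elasticities = default_elasticities()) {
  if (!"category" %in% names(microdata)) {
    stop("microdata must be classified first (see classify_drinker())",
      call. = FALSE
    )
  }
  missing_states <- setdiff(unique(microdata$state), profiles$state)
  if (length(missing_states) > 0) {
    stop("no cost profile for state(s): ",
      paste(missing_states, collapse = ", "),
      call. = FALSE
    )
  }
  if (inherits(scenarios, "tax_scenario")) scenarios <- list(scenarios)
  if (is.null(names(scenarios))) {
    names(scenarios) <- vapply(scenarios, `[[`, character(1), "label")
  }

  profiles <- dplyr::mutate(
    profiles,
    state_elasticity = weighted_elasticity_vec(
      elasticities, .data$share_beer, .data$share_wine, .data$share_spirits
    )
  )
  base <- dplyr::left_join(
    microdata,
    profiles[c("state", "cost_per_drink", "state_elasticity")],
    by = "state"
  )
  base$baseline_annual_drinks <- annual_drinks(
    average_daily_consumption(base$drinking_days_30, base$usual_drinks)
  )

  purrr::map_dfr(names(scenarios), function(label) {
    scen <- scenarios[[label]]
    res <- net_cost(
      base$baseline_annual_drinks,
      base$cost_per_drink,
      new_cost_per_drink(base$cost_per_drink, scen),
      base$state_elasticity
    )
    dplyr::bind_cols(
      base[c(
        "respondent_id", "state", "weight", "category",
        "income_bracket", "employment", "race_eth"
      )],
      tibble::tibble(
        scenario = label,
        cost_per_drink = base$cost_per_drink,
        new_cost_per_drink = new_cost_per_drink(base$cost_per_drink, scen)
      ),
      res
    )
  })
}

weighted_elasticity_vec <- function(elasticities, share_beer, share_wine,
                                    share_spirits) {
  eps <- check_elasticities(elasticities)
  share_beer * eps[["beer"]] + share_wine * eps[["wine"]] +
    share_spirits * eps[["spirits"]]
}

#' Write per-respondent cost results to CSV
#'
#' @param results Tibble from [compute_cost_results()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cost_results <- function(results, path) {
  readr::write_csv(results, path, na = "")
  invisible(path)
}
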