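# Shared fixtures built in code.

# Flat national price table whose blended price equals the off-premise price
# regardless of the off-premise weight (off = on), handy for arithmetic
# checks.
flat_price_table <- function(beer = 1.5, wine = 2.0, spirits = 2.5) {
  tibble::tibble(
    beverage = c("beer", "wine", "spirits"),
    price_off = c(beer, wine, spirits),
    price_on = c(beer, wine, spirits)
  )
}

beer_only_shares <- c(beer = 1, wine = 0, spirits = 0)

# One respondent row with sensible defaults; override any field.
make_respondent <- function(id = "R1", state = "XX", age = 40L, sex = "male",
                            weight = 1, days = 0L, usual = 0, maxocc = 0,
                            income = NA_character_, employment = NA_character_,
                            race = NA_character_) {
  tibble::tibble(
    respondent_id = id, state = state, age = as.integer(age), sex = sex,
    weight = weight, drinking_days_30 = as.integer(days),
    usual_drinks = usual, max_drinks_occasion = maxocc,
    income_bracket = income, employment = employment, race_eth = race
  )
}

# A drinker whose annual consumption is exactly `annual` drinks and whose
# classification is forced to `category` (nonexcessive: quiet woman aged 40;
# excessive: man aged 40 with a forced binge occasion).
make_drinker <- function(annual, category, id, state = "XX", weight = 1,
                         income = NA_character_, employment = NA_character_,
                         race = NA_character_) {
  usual <- annual / 365
  if (category == "nonexcessive") {
    stopifnot(usual * 30 <= 30, usual < 4)
    make_respondent(
      id = id, state = state, sex = "female", weight = weight,
      days = 30L, usual = usual, maxocc = usual,
      income = income, employment = employment, race = race
    )
  } else {
    make_respondent(
      id = id, state = state, sex = "male", weight = weight,
      days = 30L, usual = usual, maxocc = max(usual, 5),
      income = income, employment = employment, race = race
    )
  }
}

# A one-state cost profile table with everything sold as beer, so the
# share-weighted elasticity equals the supplied scalar elasticity.
homogeneous_profile <- function(cost = 2.00, state = "XX") {
  tibble::tibble(
    state = state,
    price_per_drink = cost - 0.20,
    tax_per_drink = 0.20,
    cost_per_drink = cost,
    control = FALSE,
    share_beer = 1, share_wine = 0, share_spirits = 0
  )
}

scalar_elasticities <- function(eps) c(beer = eps, wine = eps, spirits = eps)

# Homogeneous single-state population with the published group means:
# every drinker faces the same cost per drink and elasticity, so group
# cost ratios equal ratios of group mean annual drinks.
published <- national_marginals_2011()

homogeneous_microdata <- function(weights = c(
                                    nonexcessive = unname(published$counts["nonexcessive"]),
                                    excessive = unname(published$counts["excessive"])
                                  )) {
  dplyr::bind_rows(
    make_drinker(published$mean_annual[["nonexcessive"]], "nonexcessive",
      id = "NE1", weight = weights[["nonexcessive"]]
    ),
    make_drinker(published$mean_annual[["excessive"]], "excessive",
      id = "EX1", weight = weights[["excessive"]]
    )
  )
}

# Stratified homogeneous population: one nonexcessive and one excessive row
# per sociodemographic stratum, weighted by the published group count times
# the stratum proportion, consuming the stratum mean.
stratified_homogeneous_microdata <- function() {
  rows <- list()
  for (i in seq_len(nrow(published$strata))) {
    s <- published$strata[i, ]
    lv <- list(
      income = NA_character_, employment = NA_character_,
      race = NA_character_
    )
    key <- switch(s$dimension,
      income = "income", employment = "employment", race_eth = "race"
    )
    lv[[key]] <- s$level
    rows[[length(rows) + 1]] <- make_drinker(
      s$nonexcessive_mean, "nonexcessive",
      id = sprintf("NE%02d", i),
      weight = unname(published$counts["nonexcessive"]) * s$nonexcessive_prop,
      income = lv$income, employment = lv$employment, race = lv$race
    )
    rows[[length(rows) + 1]] <- make_drinker(
      s$excessive_mean, "excessive",
      id = sprintf("EX%02d", i),
      weight = unname(published$counts["excessive"]) * s$excessive_prop,
      income = lv$income, employment = lv$employment, race = lv$race
    )
  }
  dplyr::bind_rows(rows)
}

# Run the engine on a homogeneous state and return the per-respondent
# results for the default scenario battery.
homogeneous_results <- function(microdata = homogeneous_microdata(),
                                cost = 2.00, eps = -0.65,
                                scenarios = default_scenarios()) {
  classified <- classify_drinker(validate_microdata(microdata))
  compute_cost_results(
    classified, homogeneous_profile(cost),
    scenarios = scenarios,
    elasticities = scalar_elasticities(eps)
  )
}
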