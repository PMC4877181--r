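# State-level price, tax, and total cost per standard drink, including the
# regression interpolator that fills in taxes for monopoly ("control") states.

beverages <- c("beer", "wine", "spirits")

#' Standard-drink serving sizes
#'
#' US standard-drink convention: a drink is about 0.6 oz of pure ethanol,
#' i.e. 12 oz of beer, 5 oz of wine, or 1.5 oz of spirits. Used to convert
#' volume-based excise taxes ($/gallon) to $/drink.
#'
#' @return Named numeric vector of fluid ounces per standard drink.
#' @export
default_serving_oz <- function() {
  c(beer = 12, wine = 5, spirits = 1.5)
}

GALLON_OZ <- 128

check_shares <- function(shares) {
  if (is.null(names(shares)) || !setequal(names(shares), beverages)) {
    stop("beverage shares must be named beer, wine, spirits", call. = FALSE)
  }
  shares <- shares[beverages]
  if (any(shares < 0)) stop("beverage shares must be non-negative", call. = FALSE)
  if (abs(sum(shares) - 1) > 1e-9) {
    stop("beverage shares must sum to 1", call. = FALSE)
  }
  shares
}

check_price_table <- function(prices) {
  prices <- tibble::as_tibble(prices)
  need <- c("beverage", "price_off", "price_on")
  if (!all(need %in% names(prices))) {
    stop("price table needs columns beverage, price_off, price_on", call. = FALSE)
  }
  if (!setequal(prices$beverage, beverages)) {
    stop("price table must cover exactly beer, wine, spirits", call. = FALSE)
  }
  if (any(prices$price_off <= 0) || any(prices$price_on <= 0)) {
    stop("prices must be positive", call. = FALSE)
  }
  if (any(prices$price_on < prices$price_off)) {
    warning("on-premise price below off-premise price for some beverage",
      call. = FALSE
    )
  }
  prices[match(beverages, prices$beverage), ]
}

blended_price <- function(prices, off_premise_weight = 0.75) {
  prices <- check_price_table(prices)
  stats::setNames(
    off_premise_weight * prices$price_off +
      (1 - off_premise_weight) * prices$price_on,
    prices$beverage
  )
}

#' Average price per drink in a state
#'
#' Blends each beverage's off- and on-premise price per standard drink (by
#' default 75% off-premise, reflecting the share of US alcohol sold through
#' retail rather than bars and restaurants), then weights the blended prices
#' by the state's beverage consumption shares.
#'
#' @param prices Price table: tibble with columns `beverage`, `price_off`,
#'   `price_on` ($ per standard drink).
#' @param shares Named numeric vector of beverage consumption shares
#'   (`beer`, `wine`, `spirits`) summing to 1.
#' @param off_premise_weight Fraction of volume purchased off-premise,
#'   default 0.75.
#' @return Price per drink in dollars.
#' @export
#' @examples
#' prices <- tibble::tibble(
#'   beverage = c("beer", "wine", "spirits"),
#'   price_off = c(1.00, 1.50, 1.20), price_on = c(3.00, 4.00, 4.50)
#' )
#' price_per_drink(prices, c(beer = 0.5, wine = 0.3, spirits = 0.2))
price_per_drink <- function(prices, shares, off_premise_weight = 0.75) {
  if (off_premise_weight < 0 || off_premise_weight > 1) {
    stop("off_premise_weight must lie in [0, 1]", call. = FALSE)
  }
  shares <- check_shares(shares)
  sum(shares * blended_price(prices, off_premise_weight))
}

#' Convert a volume-based excise tax to dollars per standard drink
#'
#' @param excise_per_gallon Excise tax in $/gallon of beverage.
#' @param beverage One of `"beer"`, `"wine"`, `"spirits"`.
#' @param serving_oz Named vector of serving sizes in fluid ounces, default
#'   [default_serving_oz()].
#' @return Tax in $ per standard drink.
#' @export
excise_to_per_drink <- function(excise_per_gallon, beverage,
                                serving_oz = default_serving_oz()) {
  if (!all(beverage %in% names(serving_oz))) {
    stop("unknown beverage: ", paste(setdiff(beverage, names(serving_oz)),
      collapse = ", "
    ), call. = FALSE)
  }
  if (any(excise_per_gallon < 0, na.rm = TRUE)) {
    stop("excise must be non-negative", call. = FALSE)
  }
  unname(excise_per_gallon * serving_oz[beverage] / GALLON_OZ)
}

check_tax_schedule <- function(schedule) {
  schedule <- tibble::as_tibble(schedule)
  need <- c(
    "state", "beverage", "excise_per_gallon", "ad_valorem_rate",
    "sales_tax_rate", "control"
  )
  if (!all(need %in% names(schedule))) {
    stop("tax schedule needs columns ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(schedule$beverage %in% beverages)) {
    stop("unknown beverage in tax schedule", call. = FALSE)
  }
  rates <- c(schedule$ad_valorem_rate, schedule$sales_tax_rate)
  if (any(rates < 0 | rates >= 1)) {
    stop("tax rates must lie in [0, 1)", call. = FALSE)
  }
  if (any(schedule$control & schedule$beverage == "beer")) {
    stop("beer is never a monopolized beverage", call. = FALSE)
  }
  if (any(schedule$control & !is.na(schedule$excise_per_gallon))) {
    stop("monopolized beverages must not carry an excise figure", call. = FALSE)
  }
  if (any(!schedule$control & is.na(schedule$excise_per_gallon))) {
    stop("non-monopolized beverages need an excise figure", call. = FALSE)
  }
  if (any(schedule$excise_per_gallon < 0, na.rm = TRUE)) {
    stop("excise must be non-negative", call. = FALSE)
  }
  schedule
}

# Per-beverage tax per drink for one state's schedule rows (statutory
# beverages only; monopolized rows come back NA).
beverage_tax_per_drink <- function(schedule, prices,
                                   off_premise_weight = 0.75,
                                   serving_oz = default_serving_oz()) {
  blended <- blended_price(prices, off_premise_weight)
  tax <- ifelse(
    schedule$control,
    NA_real_,
    excise_to_per_drink(
      ifelse(schedule$control, 0, schedule$excise_per_gallon),
      schedule$beverage, serving_oz
    ) +
      (schedule$ad_valorem_rate + schedule$sales_tax_rate) *
        blended[schedule$beverage]
  )
  stats::setNames(as.numeric(tax), schedule$beverage)
}

#' Weighted-average state tax per drink
#'
#' For each beverage taxed through statute, tax per drink is the excise
#' converted to $/drink plus the ad valorem and sales-tax rates applied to
#' the blended (off/on-premise) pre-tax price. The per-beverage taxes are
#' then weighted by the state's beverage shares. Beverages sold through a
#' state monopoly carry no statutory rate; their per-drink tax is predicted
#' from the state's beer tax with the control-state interpolator (see
#' [fit_control_state_interpolator()]), which must be supplied whenever the
#' schedule contains a monopolized beverage.
#'
#' @param schedule One state's rows of the tax schedule (one row per
#'   beverage): columns `state`, `beverage`, `excise_per_gallon`,
#'   `ad_valorem_rate`, `sales_tax_rate`, logical `control`.
#' @param prices Price table (see [price_per_drink()]).
#' @param shares Named beverage shares summing to 1.
#' @param interpolator Fitted interpolator, or `NULL` if no beverage is
#'   monopolized.
#' @param off_premise_weight,serving_oz Passed through to the price blend and
#'   excise conversion.
#' @return Tax per drink in dollars.
#' @export
tax_per_drink <- function(schedule, prices, shares, interpolator = NULL,
                          off_premise_weight = 0.75,
                          serving_oz = default_serving_oz()) {
  schedule <- check_tax_schedule(schedule)
  if (length(unique(schedule$state)) != 1 ||
    !setequal(schedule$beverage, beverages)) {
    stop("schedule must hold one state's rows, one per beverage", call. = FALSE)
  }
  shares <- check_shares(shares)
  tax <- beverage_tax_per_drink(schedule, prices, off_premise_weight, serving_oz)
  if (any(is.na(tax))) {
    if (is.null(interpolator)) {
      stop("monopolized beverage present but no interpolation model supplied",
        call. = FALSE
      )
    }
    tax[is.na(tax)] <- predict_control_state_tax(interpolator, tax[["beer"]])
  }
  sum(shares * tax[beverages])
}

#' Fit the control-state tax interpolator
#'
#' In states that tax wine and spirits through statute ("noncontrol" states)
#' the beer tax per drink correlates strongly with the overall weighted tax
#' per drink. This ordinary-least-squares fit of overall tax on beer tax is
#' used to impute a per-drink tax for monopolized beverages in control
#' states, where markups replace transparent taxes.
#'
#' @param beer_tax Numeric vector, beer tax per drink in noncontrol states.
#' @param overall_tax Numeric vector, overall weighted tax per drink in the
#'   same states.
#' @return An object of class `control_state_interpolator`: a list with
#'   `intercept`, `slope`, `r_squared`, `n`, and the underlying `lm` fit.
#' @export
fit_control_state_interpolator <- function(beer_tax, overall_tax) {
  if (length(beer_tax) != length(overall_tax)) {
    stop("beer_tax and overall_tax must have equal length", call. = FALSE)
  }
  if (length(beer_tax) < 3) {
    stop("need at least 3 noncontrol states to fit the interpolator",
      call. = FALSE
    )
  }
  if (stats::sd(beer_tax) == 0) {
    stop("degenerate design: beer taxes are all identical", call. = FALSE)
  }
  fit <- stats::lm(overall_tax ~ beer_tax)
  structure(
    list(
      intercept = unname(stats::coef(fit)[1]),
      slope = unname(stats::coef(fit)[2]),
      r_squared = suppressWarnings(summary(fit)$r.squared),
      n = length(beer_tax),
      fit = fit
    ),
    class = "control_state_interpolator"
  )
}

#' @export
print.control_state_interpolator <- function(x, ...) {
  cat(sprintf(
    "Control-state tax interpolator (n = %d):\n  tax = %.4f + %.4f x beer tax  (R^2 = %.3f)\n",
    x$n, x$intercept, x$slope, x$r_squared
  ))
  invisible(x)
}

#' Predict the tax per drink for a control state's monopolized beverages
#'
#' @param model Fitted [fit_control_state_interpolator()] object.
#' @param beer_tax Beer tax per drink in the control state ($/drink).
#' @return Predicted tax per drink, floored at zero (with a warning if the
#'   linear prediction was negative).
#' @export
predict_control_state_tax <- function(model, beer_tax) {
  if (!inherits(model, "control_state_interpolator")) {
    stop("model must come from fit_control_state_interpolator()", call. = FALSE)
  }
  pred <- model$intercept + model$slope * beer_tax
  if (any(pred < 0)) {
    warning("negative interpolated tax floored at 0", call. = FALSE)
    pred <- pmax(pred, 0)
  }
  pred
}

#' Build cost-per-drink profiles for every state
#'
#' Orchestrates the per-state arithmetic: blends national prices with each
#' state's beverage shares to get a price per drink, computes the weighted
#' tax per drink (fitting the control-state interpolator on noncontrol
#' states and imputing monopolized beverages), and sums the two into the
#' total cost per drink consumers face.
#'
#' @param tax_schedules Tax schedule tibble, one row per state-beverage.
#' @param prices National price table (see [price_per_drink()]).
#' @param shares_table Tibble with columns `state`, `beverage`, `share`;
#'   shares sum to 1 within each state.
#' @param off_premise_weight,serving_oz Conversion settings.
#' @return A tibble with one row per state: `state`, `price_per_drink`,
#'   `tax_per_drink`, `cost_per_drink`, logical `control`, and the beverage
#'   shares as `share_beer`, `share_wine`, `share_spirits`. The attribute
#'   `"interpolator"` carries the fitted model when any state is a control
#'   state.
#' @export
build_state_cost_profiles <- function(tax_schedules, prices, shares_table,
                                      off_premise_weight = 0.75,
                                      serving_oz = default_serving_oz()) {
  tax_schedules <- check_tax_schedule(tax_schedules)
  shares_table <- tibble::as_tibble(shares_table)
  if (!all(c("state", "beverage", "share") %in% names(shares_table))) {
    stop("shares table needs columns state, beverage, share", call. = FALSE)
  }
  states <- sort(unique(tax_schedules$state))
  if (!setequal(states, unique(shares_table$state))) {
    stop("tax schedules and beverage shares cover different states",
      call. = FALSE
    )
  }

  share_vec <- function(st) {
    rows <- shares_table[shares_table$state == st, ]
    check_shares(stats::setNames(rows$share, rows$beverage))
  }
  state_rows <- function(st) tax_schedules[tax_schedules$state == st, ]

  # Per-beverage statutory taxes; control states show NA for monopolized rows.
  tax_by_bev <- lapply(states, function(st) {
    beverage_tax_per_drink(
      check_tax_schedule(state_rows(st)), prices,
      off_premise_weight, serving_oz
    )
  })
  names(tax_by_bev) <- states
  is_control <- vapply(tax_by_bev, function(x) any(is.na(x)), logical(1))

  interpolator <- NULL
  if (any(is_control)) {
    noncontrol <- states[!is_control]
    if (length(noncontrol) < 3) {
      stop("need at least 3 noncontrol states to interpolate control-state taxes",
        call. = FALSE
      )
    }
    beer_tax <- vapply(tax_by_bev[noncontrol], `[[`, numeric(1), "beer")
    overall <- vapply(noncontrol, function(st) {
      sum(share_vec(st) * tax_by_bev[[st]][beverages])
    }, numeric(1))
    interpolator <- fit_control_state_interpolator(beer_tax, overall)
  }

  profiles <- purrr::map_dfr(states, function(st) {
    shares <- share_vec(st)
    tax <- tax_per_drink(
      state_rows(st), prices, shares, interpolator,
      off_premise_weight, serving_oz
    )
    price <- price_per_drink(prices, shares, off_premise_weight)
    tibble::tibble(
      state = st,
      price_per_drink = price,
      tax_per_drink = tax,
      cost_per_drink = price + tax,
      control = is_control[[st]],
      share_beer = shares[["beer"]],
      share_wine = shares[["wine"]],
      share_spirits = shares[["spirits"]]
    )
  })
  attr(profiles, "interpolator") <- interpolator
  profiles
}

#' Read state tax schedules from CSV
#'
#' Headered CSV with one row per state-beverage: `state`, `beverage`,
#' `excise_per_gallon` (empty for monopolized beverages), `ad_valorem_rate`,
#' `sales_tax_rate` (decimal fractions), and logical `control`.
#'
#' @param path Path to the CSV file.
#' @return A validated tax schedule tibble.
#' @export
read_tax_schedules <- function(path) {
  check_tax_schedule(readr::read_csv(
    path,
    col_types = readr::cols(
      state = readr::col_character(),
      beverage = readr::col_character(),
      excise_per_gallon = readr::col_double(),
      ad_valorem_rate = readr::col_double(),
      sales_tax_rate = readr::col_double(),
      control = readr::col_logical()
    ),
    na = c("", "NA"), progress = FALSE
  ))
}

#' Read the national beverage price table from CSV
#'
#' Columns `beverage`, `price_off`, `price_on` in $ per standard drink.
#'
#' @param path Path to the CSV file.
#' @return A validated price tibble.
#' @export
read_price_table <- function(path) {
  check_price_table(readr::read_csv(
    path,
    col_types = readr::cols(
      beverage = readr::col_character(),
      price_off = readr::col_double(),
      price_on = readr::col_double()
    ),
    progress = FALSE
  ))
}

#' Read per-state beverage consumption shares from CSV
#'
#' Columns `state`, `beverage`, `share`; shares must sum to 1 within each
#' state.
#'
#' @param path Path to the CSV file.
#' @return A tibble of shares.
#' @export
read_beverage_shares <- function(path) {
  shares <- readr::read_csv(
    path,
    col_types = readr::cols(
      state = readr::col_character(),
      beverage = readr::col_character(),
      share = readr::col_double()
    ),
    progress = FALSE
  )
  for (st in unique(shares$state)) {
    rows <- shares[shares$state == st, ]
    check_shares(stats::setNames(rows$share, rows$beverage))
  }
  shares
}
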