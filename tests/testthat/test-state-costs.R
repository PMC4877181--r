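test_that("price per drink blends off/on-premise prices and beverage shares", {
  # single beverage: 0.75 * 1.00 + 0.25 * 3.00
  tbl <- tibble::tibble(
    beverage = c("beer", "wine", "spirits"),
    price_off = c(1, 1, 1), price_on = c(3, 3, 3)
  )
  expect_equal(price_per_drink(tbl, beer_only_shares), 1.50)

  # degenerate shares: wine/spirits prices are irrelevant
  tbl2 <- tbl
  tbl2$price_off[2:3] <- c(9, 11)
  tbl2$price_on[2:3] <- c(20, 30)
  expect_equal(
    price_per_drink(tbl2, beer_only_shares),
    price_per_drink(tbl, beer_only_shares)
  )

  # hand-computed share-weighted sum over blended prices
  expect_equal(
    price_per_drink(flat_price_table(), c(beer = 0.5, wine = 0.3, spirits = 0.2)),
    0.5 * 1.5 + 0.3 * 2.0 + 0.2 * 2.5
  )
  expect_error(
    price_per_drink(flat_price_table(), c(beer = 0.5, wine = 0.5, spirits = 0.2)),
    "sum to 1"
  )
})

test_that("price per drink is monotone in prices and ignores on-premise at weight 1", {
  shares <- c(beer = 0.5, wine = 0.3, spirits = 0.2)
  base <- flat_price_table()
  base$price_on <- base$price_on + 5 # headroom so bumps keep on >= off
  p0 <- price_per_drink(base, shares)
  for (col in c("price_off", "price_on")) {
    for (i in 1:3) {
      bumped <- base
      bumped[[col]][i] <- bumped[[col]][i] + 0.5
      expect_gte(price_per_drink(bumped, shares), p0)
    }
  }
  on_changed <- base
  on_changed$price_on <- base$price_on + 5
  expect_equal(
    price_per_drink(on_changed, shares, off_premise_weight = 1),
    price_per_drink(base, shares, off_premise_weight = 1)
  )
})

test_that("excise converts from $/gallon to $/drink by serving size", {
  expect_equal(excise_to_per_drink(0.64, "beer"), 0.64 * 12 / 128)
  expect_equal(unname(excise_to_per_drink(0, "wine")), 0)
  expect_equal(excise_to_per_drink(8.533, "spirits"), 8.533 * 1.5 / 128)
  expect_equal(excise_to_per_drink(8.533, "spirits"), 0.10, tolerance = 1e-3)
  expect_error(excise_to_per_drink(1, "cider"), "unknown beverage")
  expect_error(excise_to_per_drink(-1, "beer"), "non-negative")
})

one_state_schedule <- function(beer_excise = 0, sales = 0, adval = 0,
                               control_spirits = FALSE) {
  tibble::tibble(
    state = "XX",
    beverage = c("beer", "wine", "spirits"),
    excise_per_gallon = c(beer_excise, 0, if (control_spirits) NA_real_ else 0),
    ad_valorem_rate = adval,
    sales_tax_rate = sales,
    control = c(FALSE, FALSE, control_spirits)
  )
}

test_that("tax per drink combines excise, ad valorem, and sales taxes", {
  # excise-only, all beer: reduces to the unit conversion
  expect_equal(
    tax_per_drink(one_state_schedule(beer_excise = 0.64), flat_price_table(),
      beer_only_shares
    ),
    0.64 * 12 / 128
  )
  # no taxes at all
  expect_equal(
    tax_per_drink(one_state_schedule(), flat_price_table(), beer_only_shares),
    0
  )
  # beer excise plus 10% sales tax on the $1.50 blended beer price
  expect_equal(
    tax_per_drink(one_state_schedule(beer_excise = 0.64, sales = 0.10),
      flat_price_table(), beer_only_shares
    ),
    0.06 + 0.15
  )
})

test_that("monopolized beverages require and use the interpolator", {
  sched <- one_state_schedule(beer_excise = 0.64, control_spirits = TRUE)
  shares <- c(beer = 0.5, wine = 0.2, spirits = 0.3)
  expect_error(
    tax_per_drink(sched, flat_price_table(), shares),
    "no interpolation model"
  )
  model <- fit_control_state_interpolator(
    c(0.05, 0.10, 0.15), c(0.10, 0.20, 0.30)
  )
  got <- tax_per_drink(sched, flat_price_table(), shares, model)
  beer_tax <- 0.64 * 12 / 128
  expect_equal(got, 0.5 * beer_tax + 0.2 * 0 + 0.3 * (2 * beer_tax))
})

test_that("OLS interpolator handles exact, constant, and noisy data", {
  exact <- fit_control_state_interpolator(
    c(0.05, 0.10, 0.15), c(0.10, 0.20, 0.30)
  )
  expect_equal(exact$intercept, 0, tolerance = 1e-12)
  expect_equal(exact$slope, 2, tolerance = 1e-12)
  expect_equal(exact$r_squared, 1)

  flat <- fit_control_state_interpolator(
    c(0.05, 0.10, 0.15), c(0.12, 0.12, 0.12)
  )
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$intercept, 0.12, tolerance = 1e-12)

  # independent normal-equations oracle on noisy data
  withr::with_seed(42, {
    x <- runif(20, 0.02, 0.2)
    y <- 0.03 + 1.4 * x + rnorm(20, 0, 0.01)
  })
  fit <- fit_control_state_interpolator(x, y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-8)
  expect_equal(fit$slope, beta[2], tolerance = 1e-8)
  expect_equal(
    predict_control_state_tax(fit, 0.10),
    beta[1] + beta[2] * 0.10,
    tolerance = 1e-8
  )

  expect_error(
    fit_control_state_interpolator(rep(0.1, 5), runif(5)),
    "degenerate"
  )
  expect_error(fit_control_state_interpolator(c(1, 2), c(1, 2)), "at least 3")
})

test_that("OLS recovers planted coefficients within 3 SE on simulated states", {
  withr::with_seed(7, {
    x <- runif(200, 0.02, 0.25)
    y <- 0.04 + 1.3 * x + rnorm(200, 0, 0.02)
  })
  fit <- fit_control_state_interpolator(x, y)
  se <- summary(fit$fit)$coefficients[, "Std. Error"]
  expect_lt(abs(fit$intercept - 0.04), 3 * se[1])
  expect_lt(abs(fit$slope - 1.3), 3 * se[2])
})

test_that("negative interpolated taxes are floored at zero with a warning", {
  model <- fit_control_state_interpolator(
    c(0.05, 0.10, 0.15), c(0.10, 0.20, 0.30)
  )
  model$intercept <- -0.5
  expect_warning(out <- predict_control_state_tax(model, 0.01), "floored")
  expect_equal(out, 0)
})

test_that("state cost profiles satisfy the cost identity and reader contracts", {
  s <- generate_states(state_spec(n_states = 12, seed = 11))
  profiles <- build_state_cost_profiles(s$tax_schedules, s$prices, s$shares)
  expect_equal(
    profiles$cost_per_drink,
    profiles$price_per_drink + profiles$tax_per_drink
  )
  expect_true(all(profiles$price_per_drink > 0))
  expect_true(all(profiles$tax_per_drink >= 0))

  # CSV round trips through the readers
  dir <- withr::local_tempdir()
  readr::write_csv(s$tax_schedules, file.path(dir, "tax.csv"), na = "")
  readr::write_csv(s$prices, file.path(dir, "prices.csv"))
  readr::write_csv(s$shares, file.path(dir, "shares.csv"))
  expect_equal(
    as.data.frame(read_tax_schedules(file.path(dir, "tax.csv"))),
    as.data.frame(s$tax_schedules)
  )
  expect_equal(
    as.data.frame(read_price_table(file.path(dir, "prices.csv"))),
    as.data.frame(s$prices)
  )
  expect_equal(
    as.data.frame(read_beverage_shares(file.path(dir, "shares.csv"))),
    as.data.frame(s$shares)
  )
})

test_that("tax schedule validation rejects malformed inputs", {
  sched <- one_state_schedule()
  bad_rate <- dplyr::mutate(sched, sales_tax_rate = 1.2)
  expect_error(tax_per_drink(bad_rate, flat_price_table(), beer_only_shares), "rates")
  bad_beer <- sched
  bad_beer$control[1] <- TRUE
  bad_beer$excise_per_gallon[1] <- NA
  expect_error(
    tax_per_drink(bad_beer, flat_price_table(), beer_only_shares),
    "beer is never"
  )
  bad_excise <- one_state_schedule(control_spirits = TRUE)
  bad_excise$excise_per_gallon[3] <- 1
  expect_error(
    tax_per_drink(bad_excise, flat_price_table(), beer_only_shares),
    "must not carry"
  )
})
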