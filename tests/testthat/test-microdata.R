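test_that("drinking classification matches the surveillance definitions", {
  cases <- dplyr::bind_rows(
    make_respondent("a", sex = "male", age = 35, days = 2, usual = 2, maxocc = 5),
    make_respondent("b", sex = "female", age = 45, days = 20, usual = 1, maxocc = 2),
    make_respondent("c", sex = "male", age = 19, days = 1, usual = 1, maxocc = 1),
    make_respondent("d", sex = "female", age = 50, days = 0),
    # heavy without binge: 30 days x 2.5 drinks = 2.5/day for a man
    make_respondent("e", sex = "male", age = 40, days = 30, usual = 2.5, maxocc = 3),
    # female binge cutoff is 4, male is 5
    make_respondent("f", sex = "female", age = 40, days = 1, usual = 4, maxocc = 4),
    make_respondent("g", sex = "male", age = 40, days = 1, usual = 4, maxocc = 4)
  )
  out <- classify_drinker(cases)
  expect_equal(
    as.character(out$category),
    c(
      "excessive", "nonexcessive", "excessive", "nondrinker",
      "excessive", "excessive", "nonexcessive"
    )
  )
  expect_true(out$binge[1] && !out$heavy[1] && !out$underage[1])
  expect_true(out$underage[3] && !out$binge[3])
  expect_true(out$heavy[5] && !out$binge[5])
  expect_true(out$binge[6])
})

test_that("classification errors on missing age or decisive missing sex", {
  expect_error(
    classify_drinker(make_respondent(age = NA, days = 5, usual = 1, maxocc = 2)),
    "missing age"
  )
  # sex decides: largest occasion in [4, 5)
  expect_error(
    classify_drinker(make_respondent(sex = NA, days = 5, usual = 1, maxocc = 4.5)),
    "missing sex"
  )
  # sex decides: daily average in (1, 2]
  expect_error(
    classify_drinker(make_respondent(sex = NA, days = 30, usual = 1.5, maxocc = 2)),
    "missing sex"
  )
  # sex not decisive: binge for either sex
  out <- classify_drinker(make_respondent(sex = NA, days = 2, usual = 3, maxocc = 6))
  expect_equal(as.character(out$category), "excessive")
})

test_that("heavy classification by daily average equals the monthly-total rule", {
  grid <- expand.grid(
    days = 0:30, usual = 0:30, sex = c("male", "female"),
    stringsAsFactors = FALSE
  )
  daily <- average_daily_consumption(grid$days, grid$usual)
  monthly <- grid$days * grid$usual
  cut_daily <- ifelse(grid$sex == "male", 2, 1)
  expect_equal(daily > cut_daily, monthly > 30 * cut_daily)
})

test_that("raising the largest-occasion count never de-escalates a drinker", {
  grid <- expand.grid(
    days = c(1L, 10L, 30L), usual = c(0.5, 2, 4), maxocc = c(1, 3, 4, 5, 8),
    sex = c("male", "female"), stringsAsFactors = FALSE
  )
  grid$maxocc <- pmax(grid$maxocc, grid$usual)
  rank_of <- function(maxocc) {
    recs <- dplyr::bind_rows(purrr::pmap(
      grid[c("days", "usual", "sex")],
      function(days, usual, sex) {
        make_respondent(sex = sex, days = days, usual = usual, maxocc = maxocc)
      }
    ))
    as.integer(classify_drinker(recs)$category)
  }
  r1 <- rank_of(grid$maxocc)
  r2 <- rank_of(grid$maxocc + 1)
  expect_true(all(r2 >= r1))
})

test_that("consumption arithmetic follows the 30-day and annualization formulas", {
  expect_equal(average_daily_consumption(15, 2), 1.0)
  expect_equal(average_daily_consumption(0, 0), 0)
  expect_equal(average_daily_consumption(30, 2.5), 2.5)
  expect_equal(annual_drinks(1.0), 365)
  expect_equal(annual_drinks(0), 0)
  expect_equal(annual_drinks(128 / 365), 128)
  expect_error(annual_drinks(-0.1), "non-negative")
  expect_error(average_daily_consumption(31, 1), "0..30")
})

test_that("microdata validation enforces invariants and coerces nondrinker quantities", {
  good <- make_respondent(days = 0, usual = NA_real_, maxocc = NA_real_)
  out <- validate_microdata(good)
  expect_equal(out$usual_drinks, 0)
  expect_equal(out$max_drinks_occasion, 0)

  expect_error(validate_microdata(make_respondent(weight = 0)), "positive")
  expect_error(validate_microdata(make_respondent(age = 17)), "18")
  expect_error(
    validate_microdata(make_respondent(days = 0, usual = 2, maxocc = 2)),
    "zero quantities"
  )
  expect_warning(
    validate_microdata(make_respondent(days = 5, usual = 3, maxocc = 2)),
    "largest-occasion"
  )
  expect_error(
    validate_microdata(dplyr::mutate(make_respondent(), sex = "unknown")),
    "invalid sex"
  )
})

test_that("microdata CSV round-trips, with missing values as empty strings", {
  md <- dplyr::bind_rows(
    make_respondent("r1",
      days = 5, usual = 1.5, maxocc = 3,
      income = "<25k", employment = "nonemployed", race = "nh_white"
    ),
    make_respondent("r2", sex = "female", days = 0)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_microdata(md, path)
  expect_false(any(grepl("NA", readLines(path))))
  back <- read_microdata(path)
  expect_equal(as.data.frame(back), as.data.frame(md))
})
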