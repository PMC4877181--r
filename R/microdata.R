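# Respondent-level drinking microdata: validation, consumption arithmetic,
# and drinking-pattern classification.

#' Categorical levels used in respondent microdata
#'
#' Levels for the sociodemographic stratifiers carried on each respondent
#' record. Missing values are encoded as `NA` internally and as empty strings
#' on disk.
#'
#' @return A named list of character vectors with elements `sex`,
#'   `income_bracket`, `employment`, and `race_eth`.
#' @export
microdata_levels <- function() {
  list(
    sex = c("male", "female"),
    income_bracket = c("<25k", "25-<50k", "50-<75k", ">=75k"),
    employment = c("employed_for_wages", "nonemployed"),
    race_eth = c("nh_white", "other")
  )
}

microdata_columns <- c(
  "respondent_id", "state", "age", "sex", "weight",
  "drinking_days_30", "usual_drinks", "max_drinks_occasion",
  "income_bracket", "employment", "race_eth"
)

#' Validate respondent microdata
#'
#' Checks the structural invariants every downstream step relies on: survey
#' weights are positive, ages are 18 or older, drinking days lie in 0--30,
#' quantities are non-negative, categorical fields use known levels, and
#' respondents reporting zero drinking days carry zero (or absent, coerced to
#' zero) quantity fields. A largest-occasion count below the usual quantity is
#' internally inconsistent but occurs in self-reported data, so it raises a
#' warning rather than an error.
#'
#' @param data A data frame with the columns returned by
#'   [microdata_levels()] plus identifiers, weight, and the three past-30-day
#'   consumption questions (see [read_microdata()] for the full schema).
#' @return The validated tibble, with quantity fields for nondrinkers coerced
#'   to zero.
#' @export
validate_microdata <- function(data) {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(microdata_columns, names(data))
  if (length(missing_cols) > 0) {
    stop("microdata is missing columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  lv <- microdata_levels()
  for (col in names(lv)) {
    bad <- !is.na(data[[col]]) & !(data[[col]] %in% lv[[col]])
    if (any(bad)) {
      stop(
        "invalid ", col, " value(s): ",
        paste(unique(data[[col]][bad]), collapse = ", "),
        call. = FALSE
      )
    }
  }
  if (any(is.na(data$weight)) || any(data$weight <= 0)) {
    stop("survey weights must be positive", call. = FALSE)
  }
  if (any(!is.na(data$age) & data$age < 18)) {
    stop("ages below 18 are outside the adult survey frame", call. = FALSE)
  }
  if (any(is.na(data$drinking_days_30)) ||
    any(data$drinking_days_30 < 0 | data$drinking_days_30 > 30)) {
    stop("drinking_days_30 must lie in 0..30", call. = FALSE)
  }

  nondrinker <- data$drinking_days_30 == 0
  data$usual_drinks[nondrinker & is.na(data$usual_drinks)] <- 0
  data$max_drinks_occasion[nondrinker & is.na(data$max_drinks_occasion)] <- 0
  if (any(nondrinker &
    (data$usual_drinks != 0 | data$max_drinks_occasion != 0))) {
    stop("respondents with zero drinking days must report zero quantities",
      call. = FALSE
    )
  }
  drinker <- !nondrinker
  if (any(drinker & (is.na(data$usual_drinks) | is.na(data$max_drinks_occasion)))) {
    stop("drinkers must report usual_drinks and max_drinks_occasion",
      call. = FALSE
    )
  }
  if (any(data$usual_drinks < 0) || any(data$max_drinks_occasion < 0)) {
    stop("drink quantities must be non-negative", call. = FALSE)
  }
  n_inconsistent <- sum(drinker & data$max_drinks_occasion < data$usual_drinks)
  if (n_inconsistent > 0) {
    warning(
      n_inconsistent, " record(s) report a largest-occasion count below the ",
      "usual quantity; retained as reported",
      call. = FALSE
    )
  }
  data
}

#' Average daily alcohol consumption
#'
#' Past-30-day average daily volume: drinking days times usual drinks per
#' drinking day, divided by 30.
#'
#' @param drinking_days_30 Integer vector, days drank in the past 30 days.
#' @param usual_drinks Numeric vector, usual drinks per drinking day.
#' @return Numeric vector of drinks per day.
#' @export
#' @examples
#' average_daily_consumption(15, 2) # 1 drink/day
average_daily_consumption <- function(drinking_days_30, usual_drinks) {
  if (any(drinking_days_30 < 0 | drinking_days_30 > 30, na.rm = TRUE)) {
    stop("drinking_days_30 must lie in 0..30", call. = FALSE)
  }
  if (any(usual_drinks < 0, na.rm = TRUE)) {
    stop("usual_drinks must be non-negative", call. = FALSE)
  }
  drinking_days_30 * usual_drinks / 30
}

#' Annualize daily consumption
#'
#' @param daily Numeric vector of drinks per day.
#' @return Drinks per year (`daily * 365`).
#' @export
annual_drinks <- function(daily) {
  if (any(daily < 0, na.rm = TRUE)) {
    stop("daily consumption must be non-negative", call. = FALSE)
  }
  daily * 365
}

#' Classify respondents by drinking pattern
#'
#' Applies the standard US surveillance definitions. A respondent with zero
#' drinking days in the past 30 days is a *nondrinker*. A drinker is
#' *excessive* if any of three criteria holds: binge drinking (largest number
#' of drinks on one occasion at least 5 for men, 4 for women), heavy drinking
#' (average daily consumption strictly above 2 drinks/day for men, 1 for
#' women -- equivalently above 60/30 drinks per month), or any drinking while
#' aged 18--20, under the minimum legal drinking age. All remaining drinkers
#' (necessarily aged 21 or older) are *nonexcessive*.
#'
#' Binge status is determined from the largest-occasion count alone; a binge
#' frequency column, if present in the data, is not consulted.
#'
#' Records with drinking but a missing age cannot be classified (the underage
#' criterion needs age). A missing sex is an error only when it is decisive:
#' a largest-occasion count in `[4, 5)` or an average daily consumption in
#' `(1, 2]`, where the male and female cutoffs disagree.
#'
#' @param data Validated microdata tibble (see [validate_microdata()]).
#' @return The input with four columns added: logical `binge`, `heavy`,
#'   `underage`, and `category`, a factor with levels `nondrinker`,
#'   `nonexcessive`, `excessive`.
#' @export
classify_drinker <- function(data) {
  data <- tibble::as_tibble(data)
  days <- data$drinking_days_30
  drinks <- data$usual_drinks
  maxocc <- data$max_drinks_occasion
  sex <- data$sex
  age <- data$age

  drinker <- days > 0
  if (any(drinker & is.na(age))) {
    stop("cannot classify drinkers with missing age", call. = FALSE)
  }
  daily <- average_daily_consumption(days, drinks)
  sex_decisive <- drinker & is.na(sex) &
    ((maxocc >= 4 & maxocc < 5) | (daily > 1 & daily <= 2))
  if (any(sex_decisive)) {
    stop(
      "cannot classify ", sum(sex_decisive), " record(s): missing sex where ",
      "the male and female binge/heavy cutoffs disagree",
      call. = FALSE
    )
  }

  binge_cut <- ifelse(!is.na(sex) & sex == "female", 4, 5)
  heavy_cut <- ifelse(!is.na(sex) & sex == "female", 1, 2)
  binge <- drinker & maxocc >= binge_cut
  heavy <- drinker & daily > heavy_cut
  underage <- drinker & age >= 18 & age <= 20

  category <- ifelse(
    !drinker, "nondrinker",
    ifelse(binge | heavy | underage, "excessive", "nonexcessive")
  )
  data$binge <- binge
  data$heavy <- heavy
  data$underage <- underage
  data$category <- factor(category,
    levels = c("nondrinker", "nonexcessive", "excessive")
  )
  data
}

#' Read respondent microdata from CSV
#'
#' Expects a headered UTF-8 CSV with one row per respondent and columns
#' `respondent_id`, `state`, `age`, `sex`, `weight`, `drinking_days_30`,
#' `usual_drinks`, `max_drinks_occasion`, `income_bracket`, `employment`,
#' `race_eth`. Empty strings are read as missing.
#'
#' @param path Path to the CSV file.
#' @return A validated microdata tibble.
#' @export
read_microdata <- function(path) {
  data <- readr::read_csv(
    path,
    col_types = readr::cols(
      respondent_id = readr::col_character(),
      state = readr::col_character(),
      age = readr::col_integer(),
      sex = readr::col_character(),
      weight = readr::col_double(),
      drinking_days_30 = readr::col_integer(),
      usual_drinks = readr::col_double(),
      max_drinks_occasion = readr::col_double(),
      income_bracket = readr::col_character(),
      employment = readr::col_character(),
      race_eth = readr::col_character()
    ),
    na = c("", "NA"),
    progress = FALSE
  )
  validate_microdata(data)
}

#' Write respondent microdata to CSV
#'
#' Inverse of [read_microdata()]; missing values are written as empty strings.
#'
#' @param data Microdata tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_microdata <- function(data, path) {
  readr::write_csv(data[microdata_columns], path, na = "")
  invisible(path)
}
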