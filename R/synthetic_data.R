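# Synthetic respondent microdata and state tax/price/share schedules with the
# statistical structure the incidence analysis assumes, calibrated to the
# published 2011 US adult drinking marginals. Stands in for the restricted
# survey microdata and proprietary price/tax extracts.

#' Published national drinking marginals (US adults, 2011)
#'
#' The national marginal structure the synthetic-population generator is
#' calibrated to: weighted group counts, population proportions, mean annual
#' drinks per drinking group, and the per-group distributions and means over
#' household income, employment status, and race/ethnicity.
#'
#' @return A list with elements `counts` (weighted persons per drinking
#'   group), `category_probs` (population proportions of nondrinkers,
#'   nonexcessive, and excessive drinkers), `mean_annual` (mean annual drinks
#'   for the two drinking groups), and `strata` (a tibble of per-group
#'   stratum proportions and mean annual drinks).
#' @export
national_marginals_2011 <- function() {
  strata <- tibble::tribble(
    ~dimension, ~level, ~nonexcessive_prop, ~nonexcessive_mean,
    ~excessive_prop, ~excessive_mean, ~nondrinker_prop,
    "income", "<25k", 0.195, 102.1, 0.238, 689.5, 0.410,
    "income", "25-<50k", 0.253, 124.6, 0.251, 722.1, 0.273,
    "income", "50-<75k", 0.184, 128.7, 0.169, 678.6, 0.133,
    "income", ">=75k", 0.370, 144.5, 0.341, 689.4, 0.184,
    "employment", "employed_for_wages", 0.573, 125.9, 0.665, 696.3, 0.446,
    "employment", "nonemployed", 0.427, 131.6, 0.335, 674.0, 0.554,
    "race_eth", "nh_white", 0.878, 133.4, 0.853, 703.8, 0.734,
    "race_eth", "other", 0.122, 105.8, 0.147, 632.8, 0.266
  )
  list(
    counts = c(
      nondrinker = 98262571,
      nonexcessive = 73480718,
      excessive = 47200442
    ),
    category_probs = c(
      nondrinker = 0.449,
      nonexcessive = 0.336,
      excessive = 0.215
    ),
    mean_annual = c(nonexcessive = 128.0, excessive = 689.1),
    strata = strata
  )
}

#' Specify a synthetic respondent population
#'
#' Defaults reproduce the published national marginal structure: 44.9%
#' nondrinkers, 33.6% nonexcessive drinkers, 21.5% excessive drinkers, with
#' group mean annual consumption of 128.0 and 689.1 drinks and per-group
#' sociodemographic distributions from [national_marginals_2011()].
#'
#' @param n_respondents Number of records to generate.
#' @param category_probs Named probabilities over `nondrinker`,
#'   `nonexcessive`, `excessive`; must sum to 1.
#' @param target_mean_annual Named target mean annual drinks for
#'   `nonexcessive` and `excessive`.
#' @param strata Per-group stratum distributions, as in
#'   [national_marginals_2011()]`$strata`.
#' @param underage_fraction Fraction of excessive drinkers drawn from the
#'   18--20 age band (excessive by virtue of underage drinking).
#' @param missing_rate Fraction of records with each sociodemographic field
#'   missing, emulating item nonresponse.
#' @param states Character vector of state codes respondents are spread over.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   spec.
#' @return A `population_spec` list.
#' @export
population_spec <- function(n_respondents,
                            category_probs = national_marginals_2011()$category_probs,
                            target_mean_annual = national_marginals_2011()$mean_annual,
                            strata = national_marginals_2011()$strata,
                            underage_fraction = 0.05,
                            missing_rate = 0.02,
                            states = "XX",
                            seed = 1L) {
  if (n_respondents < 1) stop("n_respondents must be at least 1", call. = FALSE)
  if (abs(sum(category_probs) - 1) > 1e-9) {
    stop("category_probs must sum to 1", call. = FALSE)
  }
  if (!setequal(
    names(category_probs),
    c("nondrinker", "nonexcessive", "excessive")
  )) {
    stop("category_probs must be named nondrinker, nonexcessive, excessive",
      call. = FALSE
    )
  }
  # Nonexcessive consumption is capped by the heavy-drinking thresholds:
  # at most 30 drinks/month for women and 60 for men, i.e. an annual mean
  # no higher than the sex-composite cap under a 50/50 sex split.
  cap_annual <- 0.5 * (30 + 60) * 365 / 30
  if (category_probs[["nonexcessive"]] > 0 &&
    target_mean_annual[["nonexcessive"]] >= cap_annual) {
    stop("nonexcessive target mean exceeds the heavy-drinking cap",
      call. = FALSE
    )
  }
  if (any(target_mean_annual <= 0)) {
    stop("target means must be positive", call. = FALSE)
  }
  if (underage_fraction < 0 || underage_fraction > 1 ||
    missing_rate < 0 || missing_rate >= 1) {
    stop("underage_fraction and missing_rate must be fractions", call. = FALSE)
  }
  structure(
    list(
      n_respondents = as.integer(n_respondents),
      category_probs = category_probs,
      target_mean_annual = target_mean_annual,
      strata = strata,
      underage_fraction = underage_fraction,
      missing_rate = missing_rate,
      states = states,
      seed = as.integer(seed)
    ),
    class = "population_spec"
  )
}

# Mean of a gamma(shape, scale) truncated to [0, cap].
truncated_gamma_mean <- function(shape, scale, cap) {
  p <- stats::pgamma(cap, shape, scale = scale)
  if (p <= 0) {
    return(0)
  }
  # E[X; X <= cap] = shape*scale * P(Gamma(shape+1) <= cap)
  shape * scale * stats::pgamma(cap, shape + 1, scale = scale) / p
}

# Scale such that the cap-truncated gamma has the requested mean.
calibrate_truncated_gamma <- function(shape, target_mean, cap) {
  if (target_mean >= cap) {
    stop("target mean must be below the truncation cap", call. = FALSE)
  }
  f <- function(s) truncated_gamma_mean(shape, s, cap) - target_mean
  stats::uniroot(f,
    lower = target_mean / shape * 1e-3,
    upper = target_mean / shape * 1e3, tol = 1e-12
  )$root
}

r_truncated_gamma <- function(n, shape, scale, cap) {
  u <- stats::runif(n) * stats::pgamma(cap, shape, scale = scale)
  stats::qgamma(u, shape, scale = scale)
}

sample_level <- function(n, levels, probs, missing_rate) {
  x <- sample(levels, n, replace = TRUE, prob = probs)
  x[stats::runif(n) < missing_rate] <- NA_character_
  x
}

#' Generate synthetic respondent microdata
#'
#' Samples a drinking category for each respondent, then draws past-30-day
#' consumption so that [classify_drinker()] reproduces the sampled category
#' by construction:
#'
#' * *Nondrinkers* report zero drinking days and quantities.
#' * *Nonexcessive* drinkers draw a monthly volume from a gamma distribution
#'   truncated at the sex-specific heavy-drinking cap (30 drinks/month for
#'   women, 60 for men) and rescaled so the truncated mean hits the group
#'   target; drinking days and usual quantity are factored from the volume
#'   with the usual quantity kept below the binge cutoff, and the largest
#'   occasion equals the usual quantity. All are aged 21 or older.
#' * *Excessive* drinkers draw an untruncated gamma monthly volume with the
#'   group target mean; a binge occasion at or above the sex cutoff is
#'   forced, except for the underage subgroup (aged 18--20), whose any
#'   drinking already qualifies.
#'
#' Monthly volume factors exactly into days times usual drinks, so group
#' mean annual consumption is calibrated up to sampling error only.
#' Sociodemographic strata are sampled independently within category from
#' the per-group marginal distributions (the joint distribution is not
#' published and is deliberately not invented). Survey weights are mildly
#' dispersed log-normal draws; the survey's raking methodology is not
#' emulated.
#'
#' @param spec A [population_spec()].
#' @return A validated microdata tibble (see [read_microdata()] for schema).
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_respondents
  withr::with_seed(spec$seed, {
    category <- sample(
      names(spec$category_probs), n,
      replace = TRUE, prob = spec$category_probs
    )
    sex <- sample(c("male", "female"), n, replace = TRUE)
    weight <- stats::rlnorm(n, meanlog = 0, sdlog = 0.3)
    state <- sample(spec$states, n, replace = TRUE)

    age <- integer(n)
    is_nd <- category == "nondrinker"
    is_ne <- category == "nonexcessive"
    is_ex <- category == "excessive"
    age[is_nd] <- sample(18:84, sum(is_nd), replace = TRUE)
    age[is_ne] <- sample(21:84, sum(is_ne), replace = TRUE)
    underage <- is_ex & stats::runif(n) < spec$underage_fraction
    age[is_ex & !underage] <- sample(21:84, sum(is_ex & !underage), replace = TRUE)
    age[underage] <- sample(18:20, sum(underage), replace = TRUE)

    days <- integer(n)
    usual <- numeric(n)
    maxocc <- numeric(n)

    # Nonexcessive: truncated gamma monthly volume below the heavy cap.
    ne_shape <- 1.5
    target_month_ne <- spec$target_mean_annual[["nonexcessive"]] * 30 / 365
    for (sx in c("male", "female")) {
      idx <- which(is_ne & sex == sx)
      if (length(idx) == 0) next
      cap <- if (sx == "male") 60 else 30
      binge_cut <- if (sx == "male") 5 else 4
      scale <- calibrate_truncated_gamma(ne_shape, target_month_ne, cap)
      vol <- r_truncated_gamma(length(idx), ne_shape, scale, cap)
      # factor volume into days x usual with usual below the binge cutoff
      d_min <- pmax(1L, as.integer(ceiling(vol / (binge_cut - 0.05))))
      d <- d_min + as.integer(floor(stats::runif(length(idx)) * (31 - d_min)))
      days[idx] <- d
      usual[idx] <- vol / d
      maxocc[idx] <- usual[idx]
    }

    # Excessive: untruncated gamma volume; binge forced unless underage.
    ex_shape <- 1.2
    target_month_ex <- spec$target_mean_annual[["excessive"]] * 30 / 365
    idx <- which(is_ex)
    if (length(idx) > 0) {
      vol <- stats::rgamma(length(idx), ex_shape,
        scale = target_month_ex / ex_shape
      )
      vol <- pmax(vol, 0.05) # a drinker reports at least a sip of volume
      d_min <- pmax(1L, as.integer(ceiling(vol / 15)))
      d_min <- pmin(d_min, 30L)
      d <- d_min + as.integer(floor(stats::runif(length(idx)) * (31 - d_min)))
      days[idx] <- d
      usual[idx] <- vol / d
      binge_cut <- ifelse(sex[idx] == "male", 5, 4)
      maxocc[idx] <- ifelse(
        underage[idx], usual[idx], pmax(usual[idx], binge_cut)
      )
    }

    strata <- spec$strata
    pick <- function(dim) {
      rows <- strata[strata$dimension == dim, ]
      out <- character(n)
      for (cat in c("nondrinker", "nonexcessive", "excessive")) {
        sel <- category == cat
        probs <- rows[[paste0(
          if (cat == "nondrinker") "nondrinker" else cat, "_prop"
        )]]
        out[sel] <- sample_level(sum(sel), rows$level, probs, spec$missing_rate)
      }
      out
    }
    income <- pick("income")
    employment <- pick("employment")
    race <- pick("race_eth")

    data <- tibble::tibble(
      respondent_id = sprintf("R%06d", seq_len(n)),
      state = state,
      age = as.integer(age),
      sex = sex,
      weight = weight,
      drinking_days_30 = as.integer(days),
      usual_drinks = usual,
      max_drinks_occasion = maxocc,
      income_bracket = income,
      employment = employment,
      race_eth = race
    )
  })
  validate_microdata(data)
}

#' Specify synthetic state tax, price, and share schedules
#'
#' Ranges default to plausible US magnitudes: off-premise prices near $1 per
#' standard drink with on-premise markups of 2.5--4x, beer excises of
#' $0.15--$1.20 per gallon, sales taxes of 0--8%, and a national beverage mix
#' of roughly half beer, one-sixth wine, one-third spirits. A planted linear
#' relation (`tax_intercept`, `tax_slope`, Gaussian noise `tax_noise_sd`)
#' links each noncontrol state's beer tax per drink to its overall tax per
#' drink, so the control-state interpolator has a recoverable target.
#'
#' @param n_states Number of states.
#' @param control_fraction Fraction of states operating a spirits (and
#'   possibly wine) monopoly.
#' @param price_off_range Named list of `c(min, max)` off-premise $/drink per
#'   beverage.
#' @param on_markup_range Multiplier range from off- to on-premise price.
#' @param beer_excise_range $/gallon range for beer excises.
#' @param wine_excise_range,spirits_excise_range $/gallon ranges used where
#'   those beverages are taxed through statute.
#' @param sales_tax_range Sales-tax fraction range (applied to all
#'   beverages in a state).
#' @param tax_intercept,tax_slope,tax_noise_sd The planted overall-on-beer
#'   tax relation ($/drink scale).
#' @param share_concentration Dirichlet concentration for state beverage
#'   shares around the national mix; larger is less dispersed.
#' @param seed Integer seed.
#' @return A `state_spec` list.
#' @export
state_spec <- function(n_states = 51,
                       control_fraction = 1 / 3,
                       price_off_range = list(
                         beer = c(0.80, 1.10),
                         wine = c(0.95, 1.30),
                         spirits = c(0.85, 1.20)
                       ),
                       on_markup_range = c(2.5, 4),
                       beer_excise_range = c(0.15, 1.20),
                       wine_excise_range = c(0.30, 2.50),
                       spirits_excise_range = c(1.50, 12.00),
                       sales_tax_range = c(0, 0.08),
                       tax_intercept = 0.05,
                       tax_slope = 1.2,
                       tax_noise_sd = 0.01,
                       share_concentration = 60,
                       seed = 1L) {
  ranges <- c(
    price_off_range, list(
      on_markup_range, beer_excise_range, wine_excise_range,
      spirits_excise_range, sales_tax_range
    )
  )
  ok <- vapply(
    ranges,
    function(r) length(r) == 2 && r[1] >= 0 && r[2] >= r[1],
    logical(1)
  )
  if (!all(ok)) stop("ranges must be ordered non-negative pairs", call. = FALSE)
  if (n_states < 1) stop("need at least one state", call. = FALSE)
  if (control_fraction < 0 || control_fraction > 1) {
    stop("control_fraction must be a fraction", call. = FALSE)
  }
  structure(
    list(
      n_states = as.integer(n_states),
      control_fraction = control_fraction,
      price_off_range = price_off_range,
      on_markup_range = on_markup_range,
      beer_excise_range = beer_excise_range,
      wine_excise_range = wine_excise_range,
      spirits_excise_range = spirits_excise_range,
      sales_tax_range = sales_tax_range,
      tax_intercept = tax_intercept,
      tax_slope = tax_slope,
      tax_noise_sd = tax_noise_sd,
      share_concentration = share_concentration,
      seed = as.integer(seed)
    ),
    class = "state_spec"
  )
}

r_dirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
    nrow = n, byrow = TRUE
  )
  x / rowSums(x)
}

#' Generate synthetic state schedules
#'
#' Emits a national beverage price table, per-state beverage shares, and a
#' per-state-beverage tax schedule satisfying all the reader invariants.
#' Noncontrol states' wine and spirits taxes are reverse-engineered from the
#' planted overall-on-beer linear relation (see [state_spec()]), so with
#' `tax_noise_sd = 0` the control-state interpolator recovers the planted
#' intercept and slope exactly. Control states monopolize spirits, and wine
#' with probability one half; monopolized beverages carry no excise figure.
#'
#' @param spec A [state_spec()].
#' @return A list with `tax_schedules`, `prices`, and `shares` tibbles, ready
#'   for [build_state_cost_profiles()].
#' @export
generate_states <- function(spec) {
  stopifnot(inherits(spec, "state_spec"))
  n <- spec$n_states
  withr::with_seed(spec$seed, {
    states <- sprintf("S%02d", seq_len(n))
    n_control <- round(spec$control_fraction * n)
    control_states <- if (n_control > 0) {
      sample(states, n_control)
    } else {
      character(0)
    }
    wine_controlled <- stats::setNames(
      states %in% control_states & stats::runif(n) < 0.5, states
    )

    runifr <- function(k, r) stats::runif(k, r[1], r[2])
    prices <- tibble::tibble(
      beverage = beverages,
      price_off = vapply(beverages, function(b) {
        runifr(1, spec$price_off_range[[b]])
      }, numeric(1))
    )
    prices$price_on <- prices$price_off * runifr(3, spec$on_markup_range)

    national_mix <- c(beer = 0.50, wine = 0.17, spirits = 0.33)
    share_mat <- r_dirichlet(n, spec$share_concentration * national_mix)
    colnames(share_mat) <- beverages
    shares <- tibble::tibble(
      state = rep(states, each = 3),
      beverage = rep(beverages, n),
      share = as.numeric(t(share_mat))
    )

    sales <- runifr(n, spec$sales_tax_range)
    beer_excise <- runifr(n, spec$beer_excise_range)
    blended <- blended_price(prices)
    serving <- default_serving_oz()
    beer_tax_pd <- beer_excise * serving[["beer"]] / GALLON_OZ +
      sales * blended[["beer"]]

    # Plant the linear overall-on-beer tax relation in noncontrol states by
    # back-solving wine and spirits excises from the target overall tax.
    target_overall <- spec$tax_intercept + spec$tax_slope * beer_tax_pd +
      stats::rnorm(n, 0, spec$tax_noise_sd)

    schedule <- purrr::map_dfr(seq_len(n), function(i) {
      st <- states[i]
      is_ctl <- st %in% control_states
      sh <- share_mat[i, ]
      excise <- c(beer = beer_excise[i], wine = NA_real_, spirits = NA_real_)
      ctl_flags <- c(
        beer = FALSE,
        wine = is_ctl && wine_controlled[[st]],
        spirits = is_ctl
      )
      if (!is_ctl) {
        rest <- target_overall[i] - sh[["beer"]] * beer_tax_pd[i]
        t_other <- max(0, rest / (sh[["wine"]] + sh[["spirits"]]))
        for (b in c("wine", "spirits")) {
          excise_pd <- max(0, t_other - sales[i] * blended[[b]])
          excise[[b]] <- excise_pd * GALLON_OZ / serving[[b]]
        }
      } else {
        for (b in c("wine", "spirits")) {
          if (!ctl_flags[[b]]) {
            excise[[b]] <- runifr(1, spec[[paste0(b, "_excise_range")]])
          }
        }
      }
      tibble::tibble(
        state = st,
        beverage = beverages,
        excise_per_gallon = ifelse(ctl_flags[beverages], NA_real_,
          excise[beverages]
        ),
        ad_valorem_rate = 0,
        sales_tax_rate = sales[i],
        control = unname(ctl_flags[beverages])
      )
    })
  })
  list(
    tax_schedules = check_tax_schedule(schedule),
    prices = check_price_table(prices),
    shares = shares
  )
}
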