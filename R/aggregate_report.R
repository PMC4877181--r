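# Survey-weighted aggregation of per-respondent net costs into stratified
# per-capita costs, aggregate shares, cost ratios, and across-state summaries.

#' Weighted per-capita cost
#'
#' Survey-weighted mean net cost over a member set. The choice of member set
#' is the denominator policy: passing all adults in a stratum (drinkers and
#' nondrinkers) yields population per-capita costs; passing only the drinkers
#' of a named drinking group yields group per-capita costs.
#'
#' @param net_costs Numeric vector of net costs for the members.
#' @param weights Positive survey weights, same length.
#' @return Dollars per person per year.
#' @export
per_capita <- function(net_costs, weights) {
  if (length(net_costs) != length(weights)) {
    stop("net_costs and weights must have equal length", call. = FALSE)
  }
  total_w <- sum(weights)
  if (length(weights) == 0 || total_w <= 0) {
    stop("member set must have positive total weight", call. = FALSE)
  }
  sum(weights * net_costs) / total_w
}

#' Share of combined aggregate cost paid by one group
#'
#' @param net_a,weights_a Net costs and weights of group A.
#' @param net_b,weights_b Net costs and weights of group B (disjoint from A).
#' @return Fraction of the combined aggregate cost paid by group A.
#' @export
aggregate_share <- function(net_a, weights_a, net_b, weights_b) {
  agg_a <- sum(weights_a * net_a)
  agg_b <- sum(weights_b * net_b)
  if (agg_a + agg_b <= 0) {
    stop("combined aggregate cost must be positive", call. = FALSE)
  }
  agg_a / (agg_a + agg_b)
}

#' Ratio of per-capita costs between two groups
#'
#' @param net_num,weights_num Numerator group (e.g. excessive drinkers).
#' @param net_den,weights_den Denominator group (e.g. nonexcessive drinkers).
#' @return `per_capita(numerator) / per_capita(denominator)`.
#' @export
cost_ratio <- function(net_num, weights_num, net_den, weights_den) {
  den <- per_capita(net_den, weights_den)
  if (den <= 0) {
    stop("denominator group per-capita cost must be positive", call. = FALSE)
  }
  per_capita(net_num, weights_num) / den
}

#' Across-state summary of a per-state quantity
#'
#' The mean is weighted by each state's stratum population; the minimum and
#' maximum are unweighted, matching the "mean (state minimum, state maximum)"
#' presentation convention.
#'
#' @param values Per-state values.
#' @param populations Per-state stratum populations (weights for the mean);
#'   defaults to equal weights.
#' @return Named numeric vector `c(mean, min, max)`.
#' @export
state_summary <- function(values, populations = rep(1, length(values))) {
  if (length(values) == 0) stop("need at least one state value", call. = FALSE)
  c(
    mean = sum(values * populations) / sum(populations),
    min = min(values),
    max = max(values)
  )
}

# Long view of the stratifiers: one block of rows per (dimension, level),
# dropping respondents whose value for that dimension is missing.
stratum_long <- function(results) {
  dims <- list(
    consumption = "category",
    income = "income_bracket",
    employment = "employment",
    race_eth = "race_eth"
  )
  purrr::map_dfr(names(dims), function(dim) {
    col <- dims[[dim]]
    rows <- results[!is.na(results[[col]]), ]
    rows$dimension <- dim
    rows$level <- as.character(rows[[col]])
    rows
  })
}

#' Build the stratified incidence report
#'
#' Collapses per-respondent, per-scenario net costs into the three incidence
#' surfaces reported by the analysis:
#'
#' * `population` -- per-capita net cost among *all adults* (drinkers and
#'   nondrinkers) in each stratum of drinking pattern, income, employment,
#'   and race/ethnicity, summarized across states (population-weighted mean,
#'   state minimum, state maximum).
#' * `drinkers` -- among current drinkers in each sociodemographic stratum:
#'   per-capita net cost for nonexcessive drinkers, the
#'   excessive:nonexcessive per-capita cost ratio, and the nonexcessive share
#'   of the stratum's aggregate cost, summarized across states.
#' * `states` -- the same three quantities per state, unstratified.
#'
#' Within a state, every drinker shares the same cost per drink and
#' elasticity, so net cost is proportional to baseline consumption and the
#' ratio and share columns do not depend on the scenario; they are reported
#' per scenario nonetheless, computed from each scenario's costs.
#'
#' @param results Per-respondent results from [compute_cost_results()].
#' @return A list of class `incidence_report` with tibbles `population`,
#'   `drinkers`, `states`, and `state_cells` (the per-state population
#'   cells backing `population`).
#' @export
build_incidence_report <- function(results) {
  results <- tibble::as_tibble(results)

  # Per-state population cells: all-adults denominator within the stratum.
  long <- stratum_long(results)
  state_cells <- long |>
    dplyr::group_by(.data$scenario, .data$dimension, .data$level, .data$state) |>
    dplyr::summarise(
      per_capita_cost = per_capita(.data$net_cost, .data$weight),
      aggregate_cost = sum(.data$weight * .data$net_cost),
      n_weighted = sum(.data$weight),
      .groups = "drop"
    )
  population <- state_cells |>
    dplyr::group_by(.data$scenario, .data$dimension, .data$level) |>
    dplyr::summarise(
      state_min = min(.data$per_capita_cost),
      state_max = max(.data$per_capita_cost),
      per_capita_cost = state_summary(.data$per_capita_cost, .data$n_weighted)[["mean"]],
      aggregate_cost = sum(.data$aggregate_cost),
      n_weighted = sum(.data$n_weighted),
      .groups = "drop"
    ) |>
    dplyr::relocate("per_capita_cost", .before = "state_min")

  drinkers <- results[results$category != "nondrinker", ]
  socio_long <- stratum_long(drinkers)
  socio_long <- socio_long[socio_long$dimension != "consumption", ]
  per_state_socio <- socio_long |>
    dplyr::group_by(.data$scenario, .data$dimension, .data$level, .data$state) |>
    dplyr::summarise(drinker_cells(dplyr::pick(dplyr::everything())), .groups = "drop")
  drinkers_tbl <- if (nrow(per_state_socio) == 0) {
    tibble::tibble(
      scenario = character(), dimension = character(), level = character(),
      nonexcessive_per_capita = numeric(), nonexcessive_min = numeric(),
      nonexcessive_max = numeric(), cost_ratio = numeric(),
      ratio_min = numeric(), ratio_max = numeric(),
      nonexcessive_share = numeric(), share_min = numeric(),
      share_max = numeric()
    )
  } else per_state_socio |>
    dplyr::group_by(.data$scenario, .data$dimension, .data$level) |>
    dplyr::summarise(
      nonexcessive_min = min(.data$nonexcessive_per_capita),
      nonexcessive_max = max(.data$nonexcessive_per_capita),
      nonexcessive_per_capita = state_summary(
        .data$nonexcessive_per_capita, .data$n_weighted_nonexcessive
      )[["mean"]],
      ratio_min = min(.data$cost_ratio),
      ratio_max = max(.data$cost_ratio),
      cost_ratio = state_summary(.data$cost_ratio, .data$n_weighted)[["mean"]],
      share_min = min(.data$nonexcessive_share),
      share_max = max(.data$nonexcessive_share),
      nonexcessive_share = state_summary(.data$nonexcessive_share, .data$n_weighted)[["mean"]],
      .groups = "drop"
    ) |>
    dplyr::relocate("nonexcessive_per_capita", .before = "nonexcessive_min") |>
    dplyr::relocate("cost_ratio", .before = "ratio_min") |>
    dplyr::relocate("nonexcessive_share", .before = "share_min")

  states_tbl <- drinkers |>
    dplyr::group_by(.data$scenario, .data$state) |>
    dplyr::summarise(drinker_cells(dplyr::pick(dplyr::everything())), .groups = "drop")

  structure(
    list(
      population = population,
      drinkers = drinkers_tbl,
      states = states_tbl,
      state_cells = state_cells
    ),
    class = "incidence_report"
  )
}

# Nonexcessive per-capita cost, excessive:nonexcessive ratio, and
# nonexcessive aggregate share for one cell of drinkers.
drinker_cells <- function(rows) {
  ne <- rows[rows$category == "nonexcessive", ]
  ex <- rows[rows$category == "excessive", ]
  has_both <- nrow(ne) > 0 && nrow(ex) > 0
  tibble::tibble(
    nonexcessive_per_capita = if (nrow(ne) > 0) {
      per_capita(ne$net_cost, ne$weight)
    } else {
      NA_real_
    },
    cost_ratio = if (has_both && sum(ne$weight * ne$net_cost) > 0) {
      cost_ratio(ex$net_cost, ex$weight, ne$net_cost, ne$weight)
    } else {
      NA_real_
    },
    nonexcessive_share = if (has_both &&
      sum(ne$weight * ne$net_cost) + sum(ex$weight * ex$net_cost) > 0) {
      aggregate_share(ne$net_cost, ne$weight, ex$net_cost, ex$weight)
    } else {
      NA_real_
    },
    n_weighted_nonexcessive = sum(ne$weight),
    n_weighted = sum(rows$weight)
  )
}

#' @export
print.incidence_report <- function(x, ...) {
  cat("Incidence report:\n")
  cat("  population cells:", nrow(x$population), "\n")
  cat("  drinker strata cells:", nrow(x$drinkers), "\n")
  cat("  state cells:", nrow(x$states), "\n")
  invisible(x)
}

round_cols <- function(tbl, cols, digits) {
  for (col in intersect(cols, names(tbl))) {
    tbl[[col]] <- round(tbl[[col]], digits)
  }
  tbl
}

#' Render the incidence report to disk
#'
#' Writes three CSV tables plus a machine-readable JSON of all cells:
#'
#' * `table2.csv` -- population per-capita costs (all adults) by scenario and
#'   stratum, with state minimum and maximum.
#' * `table3.csv` -- nonexcessive per-capita costs, cost ratios, and
#'   nonexcessive aggregate shares (as percentages) by sociodemographic
#'   stratum.
#' * `table4.csv` -- the same three quantities per state.
#' * `report.json` -- all cells at full precision.
#'
#' Dollar cells are rounded to 2 decimals and ratios/percentages to 1
#' decimal in the CSVs; the JSON retains full precision.
#'
#' @param report An [build_incidence_report()] object.
#' @param dir Output directory, created if needed.
#' @return Named character vector of the files written, invisibly.
#' @export
render_tables <- function(report, dir) {
  stopifnot(inherits(report, "incidence_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  t2 <- round_cols(
    report$population,
    c("per_capita_cost", "state_min", "state_max", "aggregate_cost"), 2
  )
  t3 <- report$drinkers
  t3$nonexcessive_share <- 100 * t3$nonexcessive_share
  t3$share_min <- 100 * t3$share_min
  t3$share_max <- 100 * t3$share_max
  t3 <- round_cols(t3, c("nonexcessive_per_capita", "nonexcessive_min", "nonexcessive_max"), 2)
  t3 <- round_cols(t3, c(
    "cost_ratio", "ratio_min", "ratio_max",
    "nonexcessive_share", "share_min", "share_max"
  ), 1)
  t4 <- report$states
  t4$nonexcessive_share <- 100 * t4$nonexcessive_share
  t4 <- round_cols(t4, c("nonexcessive_per_capita"), 2)
  t4 <- round_cols(t4, c("cost_ratio", "nonexcessive_share"), 1)
  t4 <- t4[c("scenario", "state", "nonexcessive_per_capita", "cost_ratio", "nonexcessive_share")]

  paths <- c(
    table2 = file.path(dir, "table2.csv"),
    table3 = file.path(dir, "table3.csv"),
    table4 = file.path(dir, "table4.csv"),
    json = file.path(dir, "report.json")
  )
  readr::write_csv(t2, paths[["table2"]], na = "")
  readr::write_csv(t3, paths[["table3"]], na = "")
  readr::write_csv(t4, paths[["table4"]], na = "")
  jsonlite::write_json(
    lapply(report[c("population", "drinkers", "states", "state_cells")], as.data.frame),
    paths[["json"]],
    dataframe = "rows", digits = NA
  )
  invisible(paths)
}
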