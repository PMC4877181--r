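test_that("per-capita cost is the survey-weighted mean over the member set", {
  expect_equal(per_capita(c(4, 0), c(1, 1)), 2)
  # one drinker with net 9 among ten equally weighted adults
  expect_equal(per_capita(c(9, rep(0, 9)), rep(1, 10)), 0.9)
  # splitting every record in two at half weight changes nothing
  net <- c(3, 7, 0)
  w <- c(2, 1, 5)
  expect_equal(
    per_capita(rep(net, each = 2), rep(w / 2, each = 2)),
    per_capita(net, w)
  )
  expect_error(per_capita(numeric(0), numeric(0)), "positive total weight")
})

test_that("aggregate shares and cost ratios behave as ratios of weighted sums", {
  expect_equal(aggregate_share(c(5), c(1), c(1, 4), c(1, 1)), 0.5)
  expect_equal(aggregate_share(c(0), c(1), c(5), c(1)), 0)
  expect_error(aggregate_share(c(0), c(1), c(0), c(1)), "positive")

  expect_equal(cost_ratio(c(2, 4), c(1, 1), c(4, 2), c(1, 1)), 1)
  expect_equal(
    cost_ratio(c(10), c(3), c(2), c(5)),
    cost_ratio(c(10), c(6), c(2), c(10))
  )
  expect_error(cost_ratio(c(1), c(1), c(0), c(1)), "positive")
})

test_that("state summaries weight the mean by population but not min/max", {
  expect_equal(state_summary(c(2, 2, 2)), c(mean = 2, min = 2, max = 2))
  expect_equal(state_summary(c(1, 2, 3)), c(mean = 2, min = 1, max = 3))
  expect_equal(
    state_summary(c(1, 2, 3), c(1, 1, 8)),
    c(mean = 2.7, min = 1, max = 3)
  )
  expect_error(state_summary(numeric(0)), "at least one")
})

test_that("homogeneous-state cost ratios equal ratios of group mean drinks", {
  res <- homogeneous_results()
  for (scen in unique(res$scenario)) {
    rows <- res[res$scenario == scen, ]
    ne <- rows[rows$category == "nonexcessive", ]
    ex <- rows[rows$category == "excessive", ]
    expect_equal(
      cost_ratio(ex$net_cost, ex$weight, ne$net_cost, ne$weight),
      689.1 / 128.0,
      tolerance = 1e-12
    )
  }
})

test_that("stratum aggregates conserve the grand total within each partition", {
  md <- generate_population(population_spec(4000,
    states = sprintf("S%02d", 1:4),
    missing_rate = 0, seed = 19
  ))
  states <- generate_states(state_spec(n_states = 4, seed = 20))
  profiles <- build_state_cost_profiles(
    states$tax_schedules, states$prices, states$shares
  )
  res <- compute_cost_results(classify_drinker(md), profiles)
  report <- build_incidence_report(res)

  totals <- res |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(total = sum(.data$weight * .data$net_cost))
  for (dim in unique(report$population$dimension)) {
    cells <- report$population[report$population$dimension == dim, ]
    sums <- cells |>
      dplyr::group_by(.data$scenario) |>
      dplyr::summarise(total = sum(.data$aggregate_cost))
    expect_equal(sums$total, totals$total, tolerance = 1e-6)
  }
})

test_that("reported cells are invariant to splitting survey weights", {
  md <- homogeneous_microdata(weights = c(nonexcessive = 10, excessive = 4))
  split_md <- dplyr::bind_rows(md, md)
  split_md$weight <- split_md$weight / 2
  split_md$respondent_id <- sprintf("R%d", seq_len(nrow(split_md)))
  r1 <- build_incidence_report(homogeneous_results(md))
  r2 <- build_incidence_report(homogeneous_results(split_md))
  expect_equal(r1$population, r2$population)
  expect_equal(r1$drinkers, r2$drinkers)
  expect_equal(r1$states, r2$states)
})

test_that("rendered tables parse, respect report invariants, and are deterministic", {
  md <- generate_population(population_spec(1500,
    states = sprintf("S%02d", 1:2), seed = 23
  ))
  states <- generate_states(state_spec(n_states = 2, control_fraction = 0, seed = 24))
  profiles <- build_state_cost_profiles(
    states$tax_schedules, states$prices, states$shares
  )
  res <- compute_cost_results(classify_drinker(md), profiles)
  report <- build_incidence_report(res)

  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  files1 <- render_tables(report, dir1)
  files2 <- render_tables(report, dir2)
  for (f in c("table2", "table3", "table4", "json")) {
    expect_true(file.exists(files1[[f]]))
    expect_identical(readLines(files1[[f]]), readLines(files2[[f]]))
  }
  t2 <- readr::read_csv(files1[["table2"]], show_col_types = FALSE)
  expect_true(all(c("scenario", "dimension", "level", "per_capita_cost") %in% names(t2)))
  expect_true(all(t2$state_min <= t2$per_capita_cost + 0.01))
  expect_true(all(t2$state_max >= t2$per_capita_cost - 0.01))
  t3 <- readr::read_csv(files1[["table3"]], show_col_types = FALSE)
  expect_true(all(t3$nonexcessive_share >= 0 & t3$nonexcessive_share <= 100))
  t4 <- readr::read_csv(files1[["table4"]], show_col_types = FALSE)
  expect_equal(sort(unique(t4$state)), c("S01", "S02"))
})
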