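test_that("toy ration matches the grid oracle and the program rules", {
  db <- toy_instances()$thr_toy_5
  g <- default_guidelines("child_1_3y")
  cfg <- small_thr_config()
  sols <- optimize_thr(db, g, cfg)
  s <- sols[[1]]
  expect_true(s$status %in% c("optimal", "over_budget"))

  decisions <- rationplan:::thr_decisions(db, cfg)
  constraints <- rationplan:::thr_constraints(g, cfg)
  oracle <- brute_force_oracle(decisions, constraints, grid_step = 1)
  expect_equal(oracle$status, "optimal")
  expect_lte(s$total_cost, oracle$total_cost + 1e-9)
  expect_lte(
    oracle$total_cost,
    s$total_cost + sum(decisions$unit_cost) + 1e-9
  )

  # one food from each mandatory group
  sel <- s$quantities[s$quantities$selected, ]
  for (grp in rationplan:::thr_mandatory_groups()) {
    expect_true(grp %in% sel$group, info = grp)
  }
  # cereal mass is twice pulse mass within the 2% tolerance
  cer <- sum(sel$weight[sel$group == "cereals_and_millets"])
  pul <- sum(sel$weight[sel$group == "pulses_and_legumes"])
  expect_lte(abs(cer - 2 * pul), 0.02 * 2 * pul + 1e-9)
  # macros inside the guideline bands
  tot <- s$nutrient_totals
  expect_gte(tot[["energy"]], 400 - 1e-6)
  expect_lte(tot[["energy"]], 408 + 1e-6)
  expect_gte(tot[["protein"]], 13.5 - 1e-6)
  expect_gte(tot[["fat"]], 13.5 - 1e-6)
  expect_no_violations(s, decisions, constraints)
})

test_that("subsidising a price never increases the optimal cost", {
  db <- toy_instances()$thr_toy_5
  g <- default_guidelines("child_1_3y")
  base <- optimize_thr(db, g, thr_config(use_subsidy = FALSE))[[1]]
  # halve the oil price through a subsidy
  db2 <- db
  db2$foods$subsidized_price_per_kg[db2$foods$id == "toy_oil"] <- 6
  sub <- optimize_thr(db2, g, thr_config(use_subsidy = TRUE))[[1]]
  expect_lte(sub$total_cost, base$total_cost + 1e-9)
  # milk powder's packaged subsidy also helps
  sub2 <- optimize_thr(db, g, thr_config(use_subsidy = TRUE))[[1]]
  expect_lte(sub2$total_cost, base$total_cost + 1e-9)
})

test_that("preconditions are enforced with informative errors", {
  db <- toy_instances()$thr_toy_5
  g <- default_guidelines("child_1_3y")
  nopulse <- db
  nopulse$foods <- nopulse$foods[nopulse$foods$group != "pulses_and_legumes", ]
  expect_error(
    optimize_thr(food_db(nopulse$foods), g),
    "pulses_and_legumes"
  )
  expect_error(
    optimize_thr(db, g, thr_config(must_include_food = "ragi_millet")),
    "ragi_millet"
  )
  expect_error(
    optimize_thr(db, g, thr_config(must_include_food = "toy_oil")),
    "cereal or millet"
  )
})

test_that("a compulsory cereal is selected when requested", {
  db <- toy_instances()$thr_toy_5
  g <- default_guidelines("child_1_3y")
  s <- optimize_thr(db, g, thr_config(must_include_food = "toy_cereal"))[[1]]
  expect_true(
    s$quantities$selected[s$quantities$id == "toy_cereal"]
  )
})

test_that("dropping the cereal:pulse rule never increases cost; tol 0 is exact", {
  db <- toy_instances()$thr_toy_5
  g <- default_guidelines("child_1_3y")
  cfg <- small_thr_config()
  with_rule <- optimize_thr(db, g, cfg)[[1]]
  decisions <- rationplan:::thr_decisions(db, cfg)
  free <- rationplan:::thr_constraints(g, cfg)
  free$ratio <- NULL
  without <- solve_min_cost(decisions, free)
  expect_lte(without$total_cost, with_rule$total_cost + 1e-9)

  exact <- optimize_thr(db, g, small_thr_config(ratio_tol = 0))[[1]]
  sel <- exact$quantities[exact$quantities$selected, ]
  cer <- sum(sel$weight[sel$group == "cereals_and_millets"])
  pul <- sum(sel$weight[sel$group == "pulses_and_legumes"])
  expect_equal(cer, 2 * pul, tolerance = 1e-6)
})

test_that("product summary extrapolates costs and recomputes totals", {
  db <- toy_instances()$thr_toy_5
  g <- default_guidelines("child_1_3y")
  s <- optimize_thr(db, g)[[1]]
  summ <- thr_product_summary(s, g)
  expect_equal(summ$costs$cost, s$total_cost * c(1, 7, 30, 365))
  expect_equal(sum(summ$ingredients$grams), sum(s$quantities$weight),
    tolerance = 1e-9
  )
  # adequacy content column equals the solver's nutrient totals
  expect_equal(
    stats::setNames(summ$adequacy$content, summ$adequacy$nutrient),
    s$nutrient_totals[summ$adequacy$nutrient]
  )
  # a daily cost of 8 extrapolates to 56 / 240 / 2920
  fake <- s
  fake$total_cost <- 8
  expect_equal(
    thr_product_summary(fake, g)$costs$cost,
    c(8, 56, 240, 2920)
  )
  bad <- s
  bad$status <- "infeasible"
  expect_error(thr_product_summary(bad, g), "infeasible")
})

test_that("enforced micronutrients become binding lower bounds", {
  db <- toy_instances()$thr_toy_5
  g <- default_guidelines("child_1_3y")
  base <- optimize_thr(db, g)[[1]]
  # iron target 2 mg: enforcing it must keep iron above target
  s <- optimize_thr(db, g, thr_config(enforce_micros = "iron"))[[1]]
  expect_gte(s$nutrient_totals[["iron"]], 2 - 1e-6)
  expect_gte(s$total_cost, base$total_cost - 1e-9)
})
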