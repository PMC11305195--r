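test_that("single-food instance solves to the closed form", {
  d <- decision_spec("grain", "continuous_grams",
    min = 0, max = 200,
    unit_cost = 0.01, unit_nutrients = c(energy = 4),
    group = "cereals_and_millets"
  )
  s <- solve_min_cost(d, constraint_set(nutrient_lower = c(energy = 400)))
  expect_equal(s$status, "optimal")
  expect_equal(s$quantities$amount, 100, tolerance = 1e-9)
  expect_equal(s$total_cost, 1.0, tolerance = 1e-9)
  expect_true("energy_lower" %in% s$binding_constraints)

  # oracle agrees where the optimum lies on the grid
  o <- brute_force_oracle(d, constraint_set(nutrient_lower = c(energy = 400)),
    grid_step = 1
  )
  expect_equal(o$total_cost, s$total_cost, tolerance = 1e-9)
})

test_that("four-food instance matches the grid oracle within one step", {
  d <- toy4_decisions()
  cs <- toy4_constraints()
  milp <- solve_min_cost(d, cs)
  expect_equal(milp$status, "optimal")
  oracle <- brute_force_oracle(d, cs, grid_step = 1)
  expect_equal(oracle$status, "optimal")
  # relaxation dominance and grid-resolution sandwich
  expect_lte(milp$total_cost, oracle$total_cost + 1e-9)
  expect_lte(oracle$total_cost, milp$total_cost + sum(d$unit_cost) + 1e-9)
  expect_no_violations(milp, d, cs)
})

test_that("solution invariants hold: totals recompute, bounds respected", {
  d <- toy4_decisions()
  cs <- toy4_constraints()
  s <- solve_min_cost(d, cs)
  nut <- as.matrix(d[, nutrient_names()])
  recomputed <- as.numeric(s$quantities$amount %*% nut)
  expect_equal(unname(s$nutrient_totals), recomputed, tolerance = 1e-9)
  expect_equal(s$total_cost, sum(s$quantities$amount * d$unit_cost),
    tolerance = 1e-9
  )
  qs <- s$quantities
  expect_true(all(qs$amount[!qs$selected] == 0))
  expect_true(all(qs$amount[qs$selected] >= d$min[qs$selected] - 1e-9))
  expect_true(all(qs$amount[qs$selected] <= d$max[qs$selected] + 1e-9))
})

test_that("vacuously infeasible model names the offending family", {
  d <- decision_spec("chalk", "continuous_grams",
    min = 0, max = 100,
    unit_cost = 0.01, unit_nutrients = c(protein = 0.1), group = "sugars"
  )
  s <- solve_min_cost(d, constraint_set(nutrient_lower = c(energy = 400)))
  expect_equal(s$status, "infeasible")
  expect_true("nutrient_lower" %in% s$infeasible_hint)
})

test_that("k-best enumerates distinct supports in nondecreasing cost order", {
  db <- toy_instances()$hcm_toy
  cfg <- meal_config(compulsory_recipe_ids = "boiled_egg", k_alternatives = 1)
  decisions <- rationplan:::hcm_decisions(db, db$recipes$id, cfg)
  constraints <- rationplan:::hcm_constraints(
    default_guidelines("child_3_6y"), cfg, unique(db$recipes$category)
  )

  # k = 1 reproduces the plain solve
  k1 <- enumerate_k_best(decisions, constraints, k = 1)
  s1 <- solve_min_cost(decisions, constraints)
  expect_length(k1, 1)
  expect_equal(k1[[1]]$total_cost, s1$total_cost, tolerance = 1e-9)
  expect_equal(
    sort(k1[[1]]$quantities$id[k1[[1]]$quantities$selected]),
    sort(s1$quantities$id[s1$quantities$selected])
  )

  ks <- enumerate_k_best(decisions, constraints, k = 8)
  expect_gte(length(ks), 3)
  costs <- vapply(ks, function(s) s$total_cost, numeric(1))
  expect_true(all(diff(costs) >= -1e-9))
  supports <- lapply(ks, function(s) {
    sort(s$quantities$id[s$quantities$selected])
  })
  expect_equal(length(unique(supports)), length(supports))

  # support-enumeration oracle: the k-best costs are exactly the sorted
  # costs of the feasible supports (each solved with its support forced)
  all_supports <- ks_oracle_costs(decisions, constraints)
  expect_equal(costs, head(all_supports, length(costs)), tolerance = 1e-6)

  # infeasible base model yields an empty list flagged infeasible
  bad <- constraint_set(nutrient_lower = c(energy = 10000))
  empty <- enumerate_k_best(decisions, bad, k = 3)
  expect_length(empty, 0)
  expect_equal(attr(empty, "status"), "infeasible")
})

test_that("price scaling scales the optimum; subsidies never hurt", {
  d <- toy4_decisions()
  cs <- toy4_constraints()
  base <- solve_min_cost(d, cs)
  for (lambda in c(0.5, 2, 10)) {
    d2 <- d
    d2$unit_cost <- d$unit_cost * lambda
    s2 <- solve_min_cost(d2, cs)
    expect_equal(s2$total_cost, base$total_cost * lambda, tolerance = 1e-6)
  }
  # lowering any single unit cost never increases the optimum
  for (i in seq_len(nrow(d))) {
    d3 <- d
    d3$unit_cost[i] <- d$unit_cost[i] * 0.5
    s3 <- solve_min_cost(d3, cs)
    expect_lte(s3$total_cost, base$total_cost + 1e-9)
  }
})

test_that("enlarging the food set never increases the optimal cost", {
  d <- toy4_decisions()
  cs <- toy4_constraints()
  base <- solve_min_cost(d, cs)
  extra <- decision_spec("cheap_cereal", "continuous_grams",
    min = 0, max = 90,
    unit_cost = 0.001,
    unit_nutrients = c(energy = 3.6, protein = 0.11, fat = 0.01),
    group = "cereals_and_millets"
  )
  s2 <- solve_min_cost(dplyr::bind_rows(d, extra), cs)
  expect_lte(s2$total_cost, base$total_cost + 1e-9)
})

test_that("oracle refuses oversized instances and reports empty grids", {
  d <- toy4_decisions()
  d$max <- c(5000, 5000, 5000, 5000)
  expect_error(
    brute_force_oracle(d, toy4_constraints(), grid_step = 1),
    "exceed the 1e7 cap"
  )
  d2 <- decision_spec("x", "continuous_grams",
    min = 0, max = 10,
    unit_cost = 0.01, unit_nutrients = c(energy = 1), group = "sugars"
  )
  o <- brute_force_oracle(
    d2, constraint_set(nutrient_lower = c(energy = 400)),
    grid_step = 1
  )
  expect_equal(o$status, "infeasible")
})

test_that("identical inputs give identical solutions and JSON bytes", {
  d <- toy4_decisions()
  cs <- toy4_constraints()
  s1 <- solve_min_cost(d, cs)
  s2 <- solve_min_cost(d, cs)
  expect_identical(s1$quantities$amount, s2$quantities$amount)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_solution_json(s1, p1)
  write_solution_json(s2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("LP text export writes a well-formed model", {
  d <- toy4_decisions()
  path <- withr::local_tempfile(fileext = ".lp")
  export_lp_format(d, toy4_constraints(), path)
  txt <- readLines(path)
  expect_equal(txt[1], "Minimize")
  expect_true(any(grepl("ratio", txt)))
  expect_equal(txt[length(txt)], "End")
})
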