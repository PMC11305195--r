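test_that("percent of guideline matches hand-checked ratios", {
  g13 <- default_guidelines("child_1_3y")
  tab <- percent_of_guideline(
    c(energy = 400, protein = 13.7, iron = 3.4), g13
  )
  get <- function(n) tab$percent[tab$nutrient == n]
  expect_equal(get("iron"), 170.0) # 3.4 / 2.0
  expect_equal(get("protein"), 91.3) # 13.7 / 15, one decimal
  expect_equal(get("energy"), 100.0)
  # content equal to target is exactly 100 for every defined nutrient
  tab2 <- percent_of_guideline(g13$targets, g13)
  expect_true(all(tab2$percent[tab2$defined] == 100.0))
  # zero-target rows are flagged, not divided
  expect_true(is.na(tab$percent[!tab$defined][1]))
})

test_that("rounding is one decimal, half away from zero", {
  g <- guideline_set("child_1_3y", nutrient_vector(protein = 400))
  # 91.25% must print as 91.3, not banker's 91.2
  tab <- percent_of_guideline(c(protein = 365), g)
  expect_equal(tab$percent[tab$nutrient == "protein"], 91.3)
})

test_that("adequacy colours follow the two threshold schemes", {
  # meal scheme: green above 60, orange 30-60 inclusive, red below 30
  expect_equal(adequacy_color(53, "hcm"), "orange")
  expect_equal(adequacy_color(60, "hcm"), "orange")
  expect_equal(adequacy_color(60.0001, "hcm"), "green")
  expect_equal(adequacy_color(30, "hcm"), "orange")
  expect_equal(adequacy_color(29.999, "hcm"), "red")
  # ration scheme: green above 80, orange 50-80, red below 50
  expect_equal(adequacy_color(85, "thr"), "green")
  expect_equal(adequacy_color(80, "thr"), "orange")
  expect_equal(adequacy_color(50, "thr"), "orange")
  expect_equal(adequacy_color(49.9, "thr"), "red")
  # monotone step function of percent alone
  for (mode in c("hcm", "thr")) {
    p <- seq(0, 130, by = 0.5)
    rank <- c(red = 1, orange = 2, green = 3)[adequacy_color(p, mode)]
    expect_true(all(diff(rank) >= 0))
  }
  expect_true(is.na(adequacy_color(NA_real_, "hcm")))
})

test_that("published meal percentages are all green except vitamin B2", {
  hcm <- worked_example("hcm_3_6y")
  cols <- adequacy_color(hcm$percent_printed, mode = "hcm")
  expect_equal(hcm$nutrient[cols != "green"], "vitamin_b2")
  expect_equal(cols[hcm$nutrient == "vitamin_b2"], "orange")
})

test_that("food-group allocation shares sum to 100", {
  db <- toy_instances()$thr_toy_5
  g <- default_guidelines("child_1_3y")
  s <- optimize_thr(db, g)[[1]]
  alloc <- food_group_allocation(s)
  expect_equal(sum(alloc$share_pct), 100, tolerance = 1e-9)
  # independent regrouped summation
  sel <- s$quantities[s$quantities$selected, ]
  byhand <- tapply(sel$weight, sel$group, sum)
  expect_equal(
    stats::setNames(alloc$weight_g, alloc$group)[names(byhand)],
    byhand,
    tolerance = 1e-9, ignore_attr = TRUE
  )

  # degenerate cases
  one <- s
  keep <- which(one$quantities$id == "toy_cereal")
  one$quantities$selected[-keep] <- FALSE
  one$quantities$weight[-keep] <- 0
  a1 <- food_group_allocation(one)
  expect_equal(a1$share_pct, 100)
  expect_equal(a1$group, "cereals_and_millets")

  two <- one
  j <- which(two$quantities$id == "toy_pulse")
  two$quantities$selected[j] <- TRUE
  two$quantities$weight[keep] <- 60
  two$quantities$weight[j] <- 30
  a2 <- food_group_allocation(two)
  expect_equal(sort(round(a2$share_pct, 1)), c(33.3, 66.7))

  zero <- s
  zero$quantities$weight[] <- 0
  expect_error(food_group_allocation(zero), "zero total weight")
})

test_that("radar ratios are unrounded content/target", {
  g13 <- default_guidelines("child_1_3y")
  rad <- nutrient_ratio_radar(c(iron = 3.4), g13)
  expect_equal(rad$ratio[rad$nutrient == "iron"], 1.70, tolerance = 1e-12)
  # all content equal to target: unit radar
  rad2 <- nutrient_ratio_radar(g13$targets, g13)
  expect_true(all(rad2$ratio[rad2$defined] == 1))
  # zero content: zero ratios
  rad3 <- nutrient_ratio_radar(nutrient_vector(), g13)
  expect_true(all(rad3$ratio[rad3$defined] == 0))
  expect_true(all(is.na(rad3$ratio[!rad3$defined])))
})

test_that("contribution breakdown conserves totals and cost shares", {
  db <- toy_instances()$thr_toy_5
  g <- default_guidelines("child_1_3y")
  s <- optimize_thr(db, g)[[1]]
  bd <- contribution_breakdown(s)
  sums <- tapply(bd$nutrients$contribution, bd$nutrients$nutrient, sum)
  expect_equal(sums[names(s$nutrient_totals)],
    s$nutrient_totals,
    tolerance = 1e-9, ignore_attr = TRUE
  )
  expect_equal(sum(bd$cost$share_pct), 100, tolerance = 1e-9)
  expect_false(bd$zero_cost)

  # independent per-item recomputation on a two-food slice
  sel <- s$quantities[s$quantities$selected, ]
  f <- db$foods[match(sel$id, db$foods$id), ]
  iron_byhand <- tapply(sel$amount * f$iron / 100, sel$group, sum)
  iron_bd <- bd$nutrients[bd$nutrients$nutrient == "iron", ]
  got <- stats::setNames(iron_bd$contribution, iron_bd$group)[names(iron_byhand)]
  expect_equal(got, iron_byhand, tolerance = 1e-9, ignore_attr = TRUE)

  # zero-cost solution is flagged with zero shares
  z <- s
  z$quantities$cost[] <- 0
  bz <- contribution_breakdown(z)
  expect_true(bz$zero_cost)
  expect_true(all(bz$cost$share_pct == 0))
})
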