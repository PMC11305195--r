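test_that("compulsory recipes appear in every returned meal", {
  db <- toy_instances()$hcm_toy
  g <- default_guidelines("child_3_6y")
  cfg <- meal_config(compulsory_recipe_ids = "boiled_egg", k_alternatives = 4)
  sols <- optimize_meal(db, g, db$recipes$id, cfg)
  expect_gte(length(sols), 2)
  for (s in sols) {
    expect_true(s$quantities$selected[s$quantities$id == "boiled_egg"])
    # category structure: exactly one main and one curry, at most one side
    sel <- s$quantities[s$quantities$selected, ]
    expect_equal(sum(sel$group == "main_dish"), 1)
    expect_equal(sum(sel$group == "curry"), 1)
    expect_lte(sum(sel$group == "side_dish"), 1)
    # serving multipliers stay inside [alpha, 1.5]
    expect_true(all(sel$amount >= 0.5 - 1e-9))
    expect_true(all(sel$amount <= 1.5 + 1e-9))
  }
  # dropping the compulsory egg can only help the objective
  free <- optimize_meal(db, g, db$recipes$id, meal_config())[[1]]
  expect_lte(free$total_cost, sols[[1]]$total_cost + 1e-9)
})

test_that("meal optimum equals the support-enumeration oracle", {
  db <- toy_instances()$hcm_toy
  g <- default_guidelines("child_3_6y")
  cfg <- meal_config(compulsory_recipe_ids = "boiled_egg")
  s <- optimize_meal(db, g, db$recipes$id, cfg)[[1]]
  decisions <- rationplan:::hcm_decisions(db, db$recipes$id, cfg)
  constraints <- rationplan:::hcm_constraints(
    g, cfg, unique(db$recipes$category)
  )
  best <- Inf
  n <- nrow(decisions)
  for (mask in 1:(2^n - 1)) {
    on <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    d2 <- decisions[on, ]
    if (!"boiled_egg" %in% d2$id) next
    d2$required <- TRUE
    sub <- try(solve_min_cost(d2, constraints, lp_config(hint = FALSE)),
      silent = TRUE
    )
    if (!inherits(sub, "try-error") &&
      sub$status %in% c("optimal", "over_budget")) {
      best <- min(best, sub$total_cost)
    }
  }
  expect_equal(s$total_cost, best, tolerance = 1e-6)
})

test_that("missing required categories and bad compulsory ids error", {
  db <- toy_instances()$hcm_toy
  g <- default_guidelines("child_3_6y")
  mains_only <- db$recipes$id[db$recipes$category == "main_dish"]
  expect_error(optimize_meal(db, g, mains_only, meal_config()), "curry")
  expect_error(
    optimize_meal(db, g, db$recipes$id,
      config = meal_config(compulsory_recipe_ids = "salad")
    ),
    "not compulsory-eligible"
  )
  expect_error(optimize_meal(db, g, character(), meal_config()), "nonempty")
  expect_error(
    optimize_meal(db, g, c("steamed_rice", "ghost_dish"), meal_config()),
    "ghost_dish"
  )
})

test_that("SAM augmentation reaches the elevated bands or reports shortfall", {
  db <- hcm_db_with_snacks()
  g36 <- default_guidelines("child_3_6y")
  cfg <- meal_config(compulsory_recipe_ids = "boiled_egg")
  base <- optimize_meal(db, g36, toy_instances()$hcm_toy$recipes$id, cfg)[[1]]

  gsam <- default_guidelines("sam_child_1_3y") # 700 kcal / 25 g / 25 g
  aug <- augment_for_sam(base, db, gsam, cfg)
  # energy never decreases and the augmentation is explicit
  expect_gte(
    aug$nutrient_totals[["energy"]],
    base$nutrient_totals[["energy"]] - 1e-9
  )
  if (isTRUE(aug$best_effort)) {
    expect_gt(nrow(aug$shortfall), 0)
  } else {
    expect_gte(aug$nutrient_totals[["energy"]], 700 - 1e-6)
    expect_gte(aug$nutrient_totals[["protein"]], 22.5 - 1e-6)
    expect_gte(aug$nutrient_totals[["fat"]], 22.5 - 1e-6)
  }
  # snack servings stay at one serving each, scaling within the cap
  expect_lte(aug$sam_scale, 1.25 + 1e-9)
  sel <- aug$quantities[aug$quantities$selected, ]
  expect_true(all(sel$amount <= 1.5 + 1e-9))

  # same targets as the base category: a no-op
  same <- augment_for_sam(base, db, g36, cfg)
  expect_identical(same, base)

  # no snacks available and insufficient scaling: explicit shortfall
  nosnack <- toy_instances()$hcm_toy
  aug2 <- augment_for_sam(base, nosnack, gsam, cfg)
  expect_true(aug2$best_effort)
  expect_gt(nrow(aug2$shortfall), 0)
})

test_that("weekly menu statistics follow the sample conventions", {
  db <- toy_instances()$hcm_toy
  g <- default_guidelines("child_3_6y")
  s <- optimize_meal(db, g, db$recipes$id,
    meal_config(compulsory_recipe_ids = "boiled_egg")
  )[[1]]

  # six identical days: zero variance
  wm <- build_weekly_menu(rep(list(s), 6))
  expect_equal(wm$mean_cost, s$total_cost, tolerance = 1e-12)
  expect_equal(wm$sd_cost, 0)

  # synthetic costs 9.0 / 9.6 / 10.2: mean 9.6, sample SD 0.6
  mk <- function(cost) {
    x <- s
    x$total_cost <- cost
    x
  }
  wm2 <- build_weekly_menu(list(mk(9.0), mk(9.6), mk(10.2)))
  expect_equal(wm2$mean_cost, 9.6, tolerance = 1e-12)
  expect_equal(wm2$sd_cost, 0.6, tolerance = 1e-12)

  # protein:energy via Atwater 4 kcal/g: 17 g in 400 kcal is 17%
  x <- s
  x$nutrient_totals[["protein"]] <- 17
  x$nutrient_totals[["energy"]] <- 400
  x$nutrient_totals[["fat"]] <- 14
  wm3 <- build_weekly_menu(list(x))
  expect_equal(wm3$days$protein_energy_pct, 17.0, tolerance = 1e-12)
  expect_equal(wm3$days$fat_energy_pct, 100 * 9 * 14 / 400, tolerance = 1e-12)

  expect_error(build_weekly_menu(list()), "at least one")
})

test_that("tidiers return the documented shapes", {
  db <- toy_instances()$hcm_toy
  g <- default_guidelines("child_3_6y")
  s <- optimize_meal(db, g, db$recipes$id,
    meal_config(compulsory_recipe_ids = "boiled_egg")
  )[[1]]
  td <- tidy(s)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), nrow(db$recipes))
  gl <- glance(s)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$total_cost, s$total_cost)
  wm <- build_weekly_menu(list(s, s))
  expect_equal(nrow(tidy(wm)), 2)
  expect_equal(glance(wm)$mean_cost, s$total_cost)
  # plots build without evaluation errors
  expect_s3_class(autoplot(s, "allocation"), "ggplot")
  expect_s3_class(autoplot(s, "adequacy", guidelines = g), "ggplot")
  expect_s3_class(autoplot(wm), "ggplot")
})
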