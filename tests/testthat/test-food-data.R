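test_that("CSV schema round-trips and validates with row locations", {
  db <- toy_instances()$thr_toy_5
  path <- withr::local_tempfile(fileext = ".csv")
  write_food_database(db, path)
  db2 <- load_food_database(path)
  expect_equal(nrow(db2$foods), 5)
  expect_equal(nrow(db2$recipes), 0)
  expect_equal(db2$foods$id, db$foods$id)
  for (nm in nutrient_names()) {
    expect_equal(db2$foods[[nm]], db$foods[[nm]], tolerance = 1e-12)
  }
  expect_equal(db2$foods$retail_price_per_kg, db$foods$retail_price_per_kg,
    tolerance = 1e-12
  )

  # negative price in a specific row is reported with row and field
  bad <- readr::read_csv(path, show_col_types = FALSE)
  bad$retail_price_per_kg[3] <- -2
  badpath <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, badpath)
  expect_error(
    load_food_database(badpath),
    "retail_price_per_kg.*row\\(s\\) 3"
  )

  # negative nutrient likewise
  bad2 <- readr::read_csv(path, show_col_types = FALSE)
  bad2$iron_mg[2] <- -1
  badpath2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad2, badpath2)
  expect_error(load_food_database(badpath2), "iron.*row\\(s\\) 2")

  # missing required column
  bad3 <- readr::read_csv(path, show_col_types = FALSE)
  bad3$protein_g <- NULL
  badpath3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad3, badpath3)
  expect_error(load_food_database(badpath3), "protein_g")
})

test_that("JSON round-trip preserves recipes, overlays and prices", {
  db <- toy_instances()$hcm_toy
  db$foods$fortified[4] <- TRUE # the oil
  db$foods$fortification_overlay[[4]] <- nutrient_vector(vitamin_a = 750)
  db <- rationplan:::validate_food_db(db)
  path <- withr::local_tempfile(fileext = ".json")
  write_food_database(db, path)
  db2 <- load_food_database(path)
  expect_equal(db2$foods$id, db$foods$id)
  expect_equal(nrow(db2$recipes), nrow(db$recipes))
  expect_equal(
    db2$foods$fortification_overlay[[4]][["vitamin_a"]], 750
  )
  expect_equal(
    db2$recipes$ingredients[[3]]$grams,
    db$recipes$ingredients[[3]]$grams,
    tolerance = 1e-12
  )
  # referential integrity is enforced on load
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  doc$recipes[[1]]$ingredients[[1]]$food_id <- "xyz"
  badpath <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, badpath, auto_unbox = TRUE, digits = NA)
  expect_error(load_food_database(badpath), "unknown food id.*xyz")
})

test_that("database invariants are enforced at construction", {
  foods <- toy_instances()$thr_toy_5$foods
  dup <- dplyr::bind_rows(foods, foods[1, ])
  expect_error(food_db(dup), "duplicate food id")
  badgroup <- foods
  badgroup$group[2] <- "junk_food"
  expect_error(food_db(badgroup), "invalid food group")
  overlay <- foods
  overlay$fortification_overlay[[1]] <- nutrient_vector(iron = 5)
  expect_error(food_db(overlay), "unfortified")
})

test_that("effective price honours subsidy flag and per-kg storage", {
  food <- tibble::tibble(
    retail_price_per_kg = 5, subsidized_price_per_kg = 2.5
  )
  expect_equal(effective_price_per_gram(food, use_subsidy = FALSE), 0.005)
  expect_equal(effective_price_per_gram(food, use_subsidy = TRUE), 0.0025)
  nosub <- tibble::tibble(
    retail_price_per_kg = 5, subsidized_price_per_kg = NA_real_
  )
  expect_equal(effective_price_per_gram(nosub, use_subsidy = TRUE), 0.005)
})

test_that("fortification overlay is additive and toggleable", {
  db <- toy_instances()$thr_toy_5
  db$foods$fortified[3] <- TRUE
  db$foods$fortification_overlay[[3]] <- nutrient_vector(vitamin_a = 750)
  oil <- db$foods[3, ]
  base <- effective_nutrients_per_100g(oil, apply_fortification = FALSE)
  fort <- effective_nutrients_per_100g(oil, apply_fortification = TRUE)
  expect_equal(fort[["vitamin_a"]], base[["vitamin_a"]] + 750)
  expect_equal(fort[setdiff(nutrient_names(), "vitamin_a")],
    base[setdiff(nutrient_names(), "vitamin_a")],
    tolerance = 1e-12
  )
  plain <- effective_nutrients_per_100g(db$foods[1, ])
  expect_equal(plain[["energy"]], 350)
})

test_that("recipe profile equals independent summation and is linear", {
  db <- toy_instances()$hcm_toy
  # independent spreadsheet-style oracle for the 3-ingredient gravy
  gravy <- db$recipes[db$recipes$id == "lentil_gravy", ]
  ing <- gravy$ingredients[[1]]
  expect_3 <- rep(0, 16)
  cost_3 <- 0
  for (i in seq_len(nrow(ing))) {
    f <- db$foods[db$foods$id == ing$food_id[i], ]
    expect_3 <- expect_3 + ing$grams[i] / 100 *
      as.numeric(f[1, nutrient_names()])
    cost_3 <- cost_3 + ing$grams[i] * f$retail_price_per_kg / 1000
  }
  prof <- recipe_profile("lentil_gravy", db)
  expect_equal(unname(prof$nutrients), expect_3, tolerance = 1e-12)
  expect_equal(prof$cost_per_serving, cost_3, tolerance = 1e-12)
  expect_equal(prof$weight_g, sum(ing$grams))

  # doubling all grams doubles everything
  db2 <- db
  idx <- which(db2$recipes$id == "lentil_gravy")
  db2$recipes$ingredients[[idx]]$grams <- ing$grams * 2
  prof2 <- recipe_profile("lentil_gravy", db2)
  expect_equal(prof2$nutrients, prof$nutrients * 2, tolerance = 1e-12)
  expect_equal(prof2$cost_per_serving, prof$cost_per_serving * 2,
    tolerance = 1e-12
  )
  expect_equal(prof2$weight_g, prof$weight_g * 2)

  # subsidies never make a recipe dearer
  for (id in db$recipes$id) {
    expect_lte(
      recipe_profile(id, db, use_subsidy = TRUE)$cost_per_serving,
      recipe_profile(id, db, use_subsidy = FALSE)$cost_per_serving
    )
  }

  # empty ingredient list: zero vector, zero cost, zero weight
  db3 <- db
  db3$recipes$ingredients[[1]] <- tibble::tibble(
    food_id = character(), grams = numeric()
  )
  prof0 <- recipe_profile(db3$recipes[1, ], db3)
  expect_equal(sum(prof0$nutrients), 0)
  expect_equal(prof0$cost_per_serving, 0)
  expect_equal(prof0$weight_g, 0)

  expect_error(
    recipe_profile("no_such_dish", db),
    "unknown recipe id"
  )
})

test_that("nutrient vector constructor validates and fills", {
  v <- nutrient_vector(energy = 350, protein = 10)
  expect_length(v, 16)
  expect_equal(v[["vitamin_c"]], 0)
  expect_error(nutrient_vector(unobtainium = 1), "unknown nutrient")
  expect_error(nutrient_vector(energy = -5), "negative")
  expect_warning(nutrient_vector(energy = NA), "treated as 0")
})
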