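# Shared builders for test instances. Everything is generated in code;
# no fixture files.

# The four-food ration instance used for oracle comparisons: one food
# per mandatory group, lower-bound macro constraints, 2:1 cereal:pulse.
toy4_decisions <- function() {
  dplyr::bind_rows(
    decision_spec("cereal", "continuous_grams",
      min = 0, max = 90,
      unit_cost = 0.003, unit_nutrients = c(energy = 3.5, protein = 0.10, fat = 0.01),
      group = "cereals_and_millets"
    ),
    decision_spec("pulse", "continuous_grams",
      min = 0, max = 45,
      unit_cost = 0.008, unit_nutrients = c(energy = 3.4, protein = 0.22, fat = 0.015),
      group = "pulses_and_legumes"
    ),
    decision_spec("oil", "continuous_grams",
      min = 0, max = 18,
      unit_cost = 0.012, unit_nutrients = c(energy = 9, fat = 1),
      group = "edible_oils_and_fats"
    ),
    decision_spec("sugar", "continuous_grams",
      min = 0, max = 30,
      unit_cost = 0.004, unit_nutrients = c(energy = 4),
      group = "sugars"
    )
  )
}

toy4_constraints <- function(ratio_tol = 0.02) {
  constraint_set(
    nutrient_lower = c(energy = 400, protein = 15, fat = 15),
    ratio = list(
      num_group = "cereals_and_millets",
      den_group = "pulses_and_legumes", ratio = 2, tol = ratio_tol
    )
  )
}

# THR config with windows small enough for the 1 g grid oracle.
small_thr_config <- function(...) {
  thr_config(
    default_item_window = c(5, 30),
    class_windows = list(
      edible_oils_and_fats = c(5, 15),
      sugars = c(5, 30),
      milk_and_milk_products = c(5, 30)
    ),
    ...
  )
}

# Random small lp_engine instance (lower-bound constraints plus one
# group-count rule), grid-compatible: integer bounds, min = 0.
random_lp_instance <- function(seed) {
  set.seed(seed)
  n <- sample(3:5, 1)
  maxs <- if (n <= 3) {
    sample(15:30, n, replace = TRUE)
  } else if (n == 4) {
    sample(10:15, n, replace = TRUE)
  } else {
    sample(8:10, n, replace = TRUE)
  }
  groups <- sample(c("cereals_and_millets", "pulses_and_legumes", "sugars"),
    n,
    replace = TRUE
  )
  decisions <- purrr::map_dfr(seq_len(n), function(i) {
    decision_spec(
      id = sprintf("item%02d", i), kind = "continuous_grams",
      min = 1, max = maxs[i], # selection means at least 1 g
      unit_cost = round(stats::runif(1, 0.002, 0.03), 5),
      unit_nutrients = c(
        energy = round(stats::runif(1, 0.5, 9), 3),
        protein = round(stats::runif(1, 0, 0.25), 4),
        fat = round(stats::runif(1, 0, 1) * stats::rbinom(1, 1, 0.5), 4)
      ),
      group = groups[i]
    )
  })
  cap <- as.numeric(maxs %*% as.matrix(decisions[, c("energy", "protein")]))
  constraints <- constraint_set(
    nutrient_lower = c(
      energy = round(0.5 * cap[1], 1),
      protein = round(0.4 * cap[2], 2)
    ),
    group_min_count = stats::setNames(1, groups[1])
  )
  list(decisions = decisions, constraints = constraints)
}

# hcm_toy plus snack recipes, for SAM augmentation tests.
hcm_db_with_snacks <- function() {
  db <- toy_instances()$hcm_toy
  snacks <- tibble::tibble(
    id = c("rice_laddu", "veg_fritter"),
    name = c("rice laddu", "vegetable fritter"),
    category = "snack",
    serving_size_g = c(40, 45),
    compulsory_eligible = FALSE,
    ingredients = list(
      tibble::tibble(food_id = c("rice", "oil"), grams = c(30, 10)),
      tibble::tibble(food_id = c("vegetable", "rice", "oil"), grams = c(25, 15, 5))
    )
  )
  db$recipes <- dplyr::bind_rows(db$recipes, snacks)
  rationplan:::validate_food_db(db)
}

# Jitter all retail prices of a database multiplicatively (seeded).
jitter_prices <- function(db, seed, range = c(0.7, 1.3)) {
  set.seed(seed)
  db$foods$retail_price_per_kg <- db$foods$retail_price_per_kg *
    stats::runif(nrow(db$foods), range[1], range[2])
  db
}

# exhaustive support enumeration: for every subset of items, force that
# exact support and solve; return the sorted costs of feasible supports
ks_oracle_costs <- function(decisions, constraints) {
  n <- nrow(decisions)
  costs <- c()
  for (mask in 1:(2^n - 1)) {
    on <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    d2 <- decisions[on, ]
    d2$required <- TRUE
    cs2 <- constraints
    cs2$force_ids <- intersect(cs2$force_ids, d2$id)
    if (!setequal(cs2$force_ids, constraints$force_ids)) next
    s <- try(solve_min_cost(d2, cs2, lp_config(hint = FALSE)), silent = TRUE)
    if (!inherits(s, "try-error") && s$status %in% c("optimal", "over_budget")) {
      costs <- c(costs, s$total_cost)
    }
  }
  sort(costs)
}

expect_no_violations <- function(solution, decisions, constraints) {
  v <- check_solution(solution, decisions, constraints)
  expect_identical(nrow(v), 0L, info = paste(
    "violations:", paste(v$constraint, collapse = ", ")
  ))
}
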