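#' Specification for a synthetic food database
#'
#' Controls the deterministic generator of synthetic food databases used
#' in tests, examples and documentation. Nutrient and price ranges are
#' composition-table-plausible per food group; no real food list or
#' price survey is mimicked.
#'
#' @param seed Integer seed; the same spec always generates the same
#'   database.
#' @param n_foods_per_group Named integer vector: how many foods to
#'   generate per food group.
#' @param mode `"guaranteed_feasible"` (the generated database is
#'   verified, by solving, to admit a feasible take-home ration for the
#'   child-1-3y defaults), `"guaranteed_infeasible"` (an arithmetic
#'   certificate of infeasibility is constructed), or `"unconstrained"`.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L,
                         n_foods_per_group = c(
                           cereals_and_millets = 2,
                           pulses_and_legumes = 2,
                           sugars = 1,
                           edible_oils_and_fats = 1,
                           milk_and_milk_products = 1
                         ),
                         mode = c(
                           "guaranteed_feasible",
                           "guaranteed_infeasible",
                           "unconstrained"
                         )) {
  mode <- match.arg(mode)
  stopifnot(all(names(n_foods_per_group) %in% food_groups()))
  structure(
    list(
      seed = as.integer(seed),
      n_foods_per_group = n_foods_per_group,
      mode = mode
    ),
    class = "fixture_spec"
  )
}

# Composition-table-plausible per-100 g ranges by group, plus price
# ranges per kg. Values are uniform-sampling bounds, not real foods.
fixture_group_ranges <- function(group) {
  switch(group,
    cereals_and_millets = list(
      energy = c(330, 365), protein = c(8, 12), fat = c(0.5, 2.5),
      dietary_fiber = c(2, 11), calcium = c(10, 40), zinc = c(1, 3),
      iron = c(2, 5), magnesium = c(40, 140), vitamin_a = c(0, 5),
      folate = c(10, 45), vitamin_b1 = c(0.2, 0.5),
      vitamin_b2 = c(0.05, 0.2), vitamin_b3 = c(1, 4.5),
      vitamin_b6 = c(0.1, 0.4), vitamin_b12 = c(0, 0),
      vitamin_c = c(0, 0), price = c(20, 45)
    ),
    pulses_and_legumes = list(
      energy = c(315, 350), protein = c(20, 25), fat = c(1, 6),
      dietary_fiber = c(9, 17), calcium = c(40, 150), zinc = c(2, 4),
      iron = c(3, 8), magnesium = c(90, 200), vitamin_a = c(0, 10),
      folate = c(100, 350), vitamin_b1 = c(0.3, 0.7),
      vitamin_b2 = c(0.1, 0.3), vitamin_b3 = c(1.5, 3),
      vitamin_b6 = c(0.2, 0.5), vitamin_b12 = c(0, 0),
      vitamin_c = c(0, 2), price = c(60, 130)
    ),
    sugars = list(
      energy = c(375, 400), protein = c(0, 0.4), fat = c(0, 0.1),
      dietary_fiber = c(0, 0.5), calcium = c(0, 80), zinc = c(0, 0.4),
      iron = c(0, 3), magnesium = c(0, 70), vitamin_a = c(0, 0),
      folate = c(0, 3), vitamin_b1 = c(0, 0.02),
      vitamin_b2 = c(0, 0.05), vitamin_b3 = c(0, 0.5),
      vitamin_b6 = c(0, 0.1), vitamin_b12 = c(0, 0),
      vitamin_c = c(0, 0), price = c(35, 50)
    ),
    edible_oils_and_fats = list(
      energy = c(880, 900), protein = c(0, 0), fat = c(98, 100),
      dietary_fiber = c(0, 0), calcium = c(0, 1), zinc = c(0, 0.1),
      iron = c(0, 0.5), magnesium = c(0, 1), vitamin_a = c(0, 100),
      folate = c(0, 0), vitamin_b1 = c(0, 0), vitamin_b2 = c(0, 0),
      vitamin_b3 = c(0, 0), vitamin_b6 = c(0, 0), vitamin_b12 = c(0, 0),
      vitamin_c = c(0, 0), price = c(100, 170)
    ),
    milk_and_milk_products = list(
      energy = c(480, 510), protein = c(24, 27), fat = c(24, 28),
      dietary_fiber = c(0, 0), calcium = c(900, 1300), zinc = c(3, 4.5),
      iron = c(0.2, 0.8), magnesium = c(80, 120), vitamin_a = c(200, 400),
      folate = c(20, 40), vitamin_b1 = c(0.2, 0.4),
      vitamin_b2 = c(1, 1.6), vitamin_b3 = c(0.5, 1),
      vitamin_b6 = c(0.2, 0.4), vitamin_b12 = c(1, 3),
      vitamin_c = c(0, 6), price = c(250, 420)
    ),
    # generic vegetable-like profile for any other group
    list(
      energy = c(25, 90), protein = c(1, 4), fat = c(0.1, 1),
      dietary_fiber = c(1, 5), calcium = c(20, 200), zinc = c(0.2, 1),
      iron = c(0.5, 4), magnesium = c(10, 80), vitamin_a = c(10, 600),
      folate = c(10, 150), vitamin_b1 = c(0.02, 0.1),
      vitamin_b2 = c(0.02, 0.2), vitamin_b3 = c(0.2, 1),
      vitamin_b6 = c(0.05, 0.3), vitamin_b12 = c(0, 0),
      vitamin_c = c(5, 120), price = c(20, 80)
    )
  )
}

# Sample one synthetic food row.
sample_food <- function(id, group, rng_protein_cap = NULL) {
  rg <- fixture_group_ranges(group)
  vals <- vapply(nutrient_names(), function(nm) {
    stats::runif(1, rg[[nm]][1], rg[[nm]][2])
  }, numeric(1))
  if (!is.null(rng_protein_cap)) {
    vals["protein"] <- stats::runif(1, 0.1, rng_protein_cap)
  }
  tibble::tibble(
    id = id, name = gsub("_", " ", id), group = group,
    !!!as.list(round(vals, 3)),
    retail_price_per_kg = round(stats::runif(1, rg$price[1], rg$price[2]), 2),
    subsidized_price_per_kg = NA_real_,
    fortified = FALSE, premix_eligible = FALSE
  )
}

#' Generate a deterministic synthetic food database
#'
#' Draws one food database from a [fixture_spec()]: reproducible for a
#' given seed. In `guaranteed_feasible` mode the take-home-ration model
#' for the child-1-3y defaults is verified feasible by actually solving
#' it (re-drawing with a derived seed up to 5 times); in
#' `guaranteed_infeasible` mode every food's protein density is drawn so
#' low that the protein requirement is unreachable even at every item's
#' maximum quantity, and this certificate is checked arithmetically.
#'
#' @param spec A [fixture_spec()].
#' @return A [food_db()]; in `guaranteed_infeasible` mode it carries an
#'   attribute `"certificate"` describing the arithmetic witness.
#' @export
#' @examples
#' db <- generate_food_db(fixture_spec(seed = 42))
#' nrow(db$foods)
generate_food_db <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(
    if (!is.null(old)) assign(".Random.seed", old, globalenv()),
    add = TRUE
  )

  draw <- function(seed) {
    set.seed(seed)
    protein_cap <- if (spec$mode == "guaranteed_infeasible") 0.5 else NULL
    rows <- list()
    for (g in names(spec$n_foods_per_group)) {
      for (i in seq_len(spec$n_foods_per_group[[g]])) {
        rows[[length(rows) + 1]] <- sample_food(
          paste0(g, "_", i), g,
          rng_protein_cap = protein_cap
        )
      }
    }
    food_db(dplyr::bind_rows(rows))
  }

  if (spec$mode == "guaranteed_infeasible") {
    db <- draw(spec$seed)
    cfg <- thr_config()
    caps <- vapply(seq_len(nrow(db$foods)), function(i) {
      resolve_item_window(db$foods$id[i], db$foods$group[i], cfg)[2]
    }, numeric(1))
    max_protein <- sum(caps * db$foods$protein / 100)
    need <- default_guidelines("child_1_3y")$targets[["protein"]] * 0.9
    if (max_protein >= need) {
      stop(
        "infeasibility certificate failed: maximum attainable protein ",
        round(max_protein, 2), " g is not below the requirement ",
        need, " g",
        call. = FALSE
      )
    }
    attr(db, "certificate") <- sprintf(
      "max attainable protein %.2f g < required %.2f g", max_protein, need
    )
    return(db)
  }

  db <- draw(spec$seed)
  if (spec$mode == "guaranteed_feasible") {
    guide <- default_guidelines("child_1_3y")
    for (attempt in 0:5) {
      if (attempt > 0) db <- draw(spec$seed + 100000L * attempt)
      sol <- optimize_thr(db, guide,
        thr_config(),
        lp = lp_config(hint = FALSE)
      )[[1]]
      if (sol$status %in% c("optimal", "over_budget")) {
        return(db)
      }
    }
    stop("could not construct a feasible database within 5 redraws",
      call. = FALSE
    )
  }
  db
}

#' Hand-printed toy instances
#'
#' Two small, fully documented instances used across tests and examples:
#' `thr_toy_5`, five raw foods (one in each mandatory take-home-ration
#' group plus a subsidizable milk powder), and `hcm_toy`, a recipe
#' database with two main dishes, two curries, one side dish and one
#' compulsory-eligible egg dish. Small enough for the brute-force grid
#' oracle.
#'
#' @return Named list of [food_db()] objects.
#' @export
#' @examples
#' toy_instances()$thr_toy_5$foods[, 1:5]
toy_instances <- function() {
  thr_foods <- dplyr::bind_rows(
    decorate_toy_food("toy_cereal", "cereals_and_millets",
      energy = 350, protein = 10, fat = 1, iron = 3, price = 3
    ),
    decorate_toy_food("toy_pulse", "pulses_and_legumes",
      energy = 340, protein = 22, fat = 1.5, iron = 5, price = 8
    ),
    decorate_toy_food("toy_oil", "edible_oils_and_fats",
      energy = 900, protein = 0, fat = 100, price = 12
    ),
    decorate_toy_food("toy_sugar", "sugars",
      energy = 400, protein = 0, fat = 0, price = 4
    ),
    decorate_toy_food("toy_milk_powder", "milk_and_milk_products",
      energy = 496, protein = 25.8, fat = 26.7, calcium = 950,
      price = 25.9, subsidized = 12.95
    )
  )

  hcm_foods <- dplyr::bind_rows(
    decorate_toy_food("rice", "cereals_and_millets",
      energy = 345, protein = 6.8, fat = 0.6, price = 40
    ),
    decorate_toy_food("lentil", "pulses_and_legumes",
      energy = 340, protein = 22, fat = 1.5, iron = 5, price = 90
    ),
    decorate_toy_food("vegetable", "other_vegetables",
      energy = 40, protein = 2, fat = 0.2, vitamin_c = 30, price = 30
    ),
    decorate_toy_food("oil", "edible_oils_and_fats",
      energy = 900, protein = 0, fat = 100, price = 120
    ),
    decorate_toy_food("egg", "egg",
      energy = 140, protein = 12.5, fat = 10, vitamin_b12 = 1.1,
      price = 100, subsidized = 50
    )
  )
  ing <- function(...) {
    x <- list(...)
    tibble::tibble(
      food_id = names(x),
      grams = as.numeric(unlist(x))
    )
  }
  hcm_recipes <- tibble::tribble(
    ~id, ~name, ~category, ~serving_size_g, ~compulsory_eligible, ~ingredients,
    "steamed_rice", "steamed rice", "main_dish", 60, FALSE,
    list(ing(rice = 60)),
    "veg_pulao", "vegetable pulao", "main_dish", 85, FALSE,
    list(ing(rice = 50, vegetable = 30, oil = 5)),
    "lentil_gravy", "lentil gravy", "curry", 58, FALSE,
    list(ing(lentil = 30, vegetable = 20, oil = 8)),
    "veg_curry", "vegetable curry", "curry", 84, FALSE,
    list(ing(vegetable = 80, oil = 4)),
    "salad", "salad", "side_dish", 50, FALSE,
    list(ing(vegetable = 50)),
    "boiled_egg", "boiled egg", "additional", 50, TRUE,
    list(ing(egg = 50))
  )
  hcm_recipes$ingredients <- lapply(hcm_recipes$ingredients, `[[`, 1)

  list(
    thr_toy_5 = food_db(thr_foods),
    hcm_toy = food_db(hcm_foods, hcm_recipes)
  )
}

decorate_toy_food <- function(id, group, energy = 0, protein = 0, fat = 0,
                              iron = 0, calcium = 0, vitamin_c = 0,
                              vitamin_b12 = 0, price, subsidized = NA_real_) {
  tibble::tibble(
    id = id, name = gsub("_", " ", id), group = group,
    !!!as.list(nutrient_vector(
      energy = energy, protein = protein, fat = fat, iron = iron,
      calcium = calcium, vitamin_c = vitamin_c, vitamin_b12 = vitamin_b12
    )),
    retail_price_per_kg = price,
    subsidized_price_per_kg = subsidized,
    fortified = FALSE, premix_eligible = FALSE
  )
}
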