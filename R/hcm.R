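#' Hot-cooked-meal configuration
#'
#' Rules for composing one day's hot cooked meal from categorized
#' recipes. A meal takes one main dish and one curry, optionally a side
#' dish and up to two "additional" accompaniments; each selected
#' recipe's quantity is a multiple of its predetermined serving size,
#' between `serving_fraction_low` (default 0.5, the smallest portion
#' worth serving) and `serving_fraction_high` (1.5, the most a child can
#' reasonably be served). Compulsory recipes (egg/milk/milk-powder
#' dishes chosen before optimization) are forced into the solution.
#'
#' @param category_counts Data frame (`category`, `min`, `max`) of how
#'   many recipes of each category a meal selects.
#' @param serving_fraction_low,serving_fraction_high Multiplier window
#'   applied to each recipe's serving size; `0 < low <= 1 <= high`.
#' @param compulsory_recipe_ids Recipe ids forced into the solution;
#'   each must be flagged `compulsory_eligible` in the database.
#' @param budget Daily budget (soft unless `hard_budget`).
#' @param hard_budget Enforce the budget as a hard cap.
#' @param use_subsidy,apply_fortification Pricing/fortification toggles,
#'   as in [thr_config()].
#' @param enforce_micros Micronutrients whose targets become hard lower
#'   bounds (macros are always enforced through their bands).
#' @param k_alternatives Number of alternative menus to return.
#' @param sam_scale_cap Maximum uniform up-scaling of a meal during SAM
#'   augmentation (never beyond `serving_fraction_high`).
#' @return A `meal_config` list.
#' @export
meal_config <- function(category_counts = default_category_counts(),
                        serving_fraction_low = 0.5,
                        serving_fraction_high = 1.5,
                        compulsory_recipe_ids = character(),
                        budget = 8, hard_budget = FALSE,
                        use_subsidy = FALSE, apply_fortification = TRUE,
                        enforce_micros = character(),
                        k_alternatives = 1, sam_scale_cap = 1.25) {
  stopifnot(
    serving_fraction_low > 0, serving_fraction_low <= 1,
    serving_fraction_high >= 1, budget > 0, k_alternatives >= 1,
    sam_scale_cap >= 1
  )
  category_counts <- tibble::as_tibble(category_counts)
  stopifnot(all(c("category", "min", "max") %in% names(category_counts)))
  structure(
    list(
      category_counts = category_counts,
      serving_fraction_low = serving_fraction_low,
      serving_fraction_high = serving_fraction_high,
      compulsory_recipe_ids = compulsory_recipe_ids,
      budget = budget, hard_budget = hard_budget,
      use_subsidy = use_subsidy, apply_fortification = apply_fortification,
      enforce_micros = enforce_micros,
      k_alternatives = k_alternatives, sam_scale_cap = sam_scale_cap
    ),
    class = "meal_config"
  )
}

#' Default recipe-category counts per meal
#'
#' One main dish and one curry, at most one side dish, up to two
#' additional accompaniments, no snacks in the base meal (snacks enter
#' through SAM augmentation).
#'
#' @return Tibble with columns `category`, `min`, `max`.
#' @export
default_category_counts <- function() {
  tibble::tribble(
    ~category, ~min, ~max,
    "main_dish", 1, 1,
    "curry", 1, 1,
    "side_dish", 0, 1,
    "additional", 0, 2,
    "snack", 0, 0
  )
}

# Decision table for a set of recipe ids (quantities in serving
# multipliers).
hcm_decisions <- function(db, ids, config) {
  idx <- match(ids, db$recipes$id)
  if (anyNA(idx)) {
    stop("unknown recipe id(s): ", paste(ids[is.na(idx)], collapse = ", "),
      call. = FALSE
    )
  }
  purrr::map_dfr(idx, function(i) {
    r <- db$recipes[i, ]
    prof <- recipe_profile(r, db,
      use_subsidy = config$use_subsidy,
      apply_fortification = config$apply_fortification
    )
    decision_spec(
      id = r$id, kind = "semi_continuous_servings",
      min = config$serving_fraction_low,
      max = config$serving_fraction_high,
      unit_cost = prof$cost_per_serving,
      unit_nutrients = prof$nutrients,
      unit_weight = prof$weight_g,
      group = r$category,
      required = r$id %in% config$compulsory_recipe_ids
    )
  })
}

hcm_constraints <- function(guidelines, config, categories_present) {
  band <- guidelines$macro_band
  lower <- stats::setNames(
    guidelines$targets[band$nutrient] * band$low, band$nutrient
  )
  upper <- stats::setNames(
    guidelines$targets[band$nutrient] * band$high, band$nutrient
  )
  for (nut in config$enforce_micros) {
    if (guidelines$targets[[nut]] > 0) lower[[nut]] <- guidelines$targets[[nut]]
  }
  if (!is.null(guidelines$upper_limits)) {
    tul <- guidelines$upper_limits[guidelines$upper_limits > 0]
    for (nut in names(tul)) {
      upper[[nut]] <- min(upper[[nut]] %||% Inf, tul[[nut]], na.rm = TRUE)
    }
  }
  cc <- config$category_counts
  cc <- cc[cc$category %in% categories_present | cc$min > 0, ]
  constraint_set(
    nutrient_lower = lower, nutrient_upper = upper,
    group_min_count = stats::setNames(cc$min, cc$category),
    group_max_count = stats::setNames(cc$max, cc$category),
    force_ids = config$compulsory_recipe_ids,
    budget = config$budget, hard_budget = config$hard_budget
  )
}

#' Optimize one day's hot cooked meal
#'
#' Selects recipes from the user's shortlist and sizes their servings to
#' minimize cost while meeting the guideline macro bands (and any
#' enforced micronutrient floors), respecting the per-category recipe
#' counts, the serving-multiplier window, and compulsory recipes.
#'
#' @param db A [food_db()] with recipes.
#' @param guidelines A [guideline_set()].
#' @param selection Character vector of candidate recipe ids (the foods
#'   the user is willing to cook); compulsory ids are added
#'   automatically.
#' @param config A [meal_config()].
#' @param lp Solver settings ([lp_config()]).
#' @return A list of `ration_solution`s ordered by cost; quantities are
#'   serving multipliers. On infeasibility, a single `infeasible`
#'   solution with a relaxation hint.
#' @export
#' @examples
#' db <- toy_instances()$hcm_toy
#' cfg <- meal_config(compulsory_recipe_ids = "boiled_egg")
#' sols <- optimize_meal(db, default_guidelines("child_3_6y"),
#'   selection = db$recipes$id, config = cfg
#' )
#' sols[[1]]$total_cost
optimize_meal <- function(db, guidelines, selection,
                          config = meal_config(), lp = lp_config()) {
  stopifnot(inherits(db, "food_db"), inherits(guidelines, "guideline_set"))
  if (!length(selection)) stop("selection must be nonempty", call. = FALSE)
  selection <- union(selection, config$compulsory_recipe_ids)
  idx <- match(selection, db$recipes$id)
  if (anyNA(idx)) {
    stop("unknown recipe id(s): ",
      paste(selection[is.na(idx)], collapse = ", "),
      call. = FALSE
    )
  }
  for (cid in config$compulsory_recipe_ids) {
    i <- match(cid, db$recipes$id)
    if (!db$recipes$compulsory_eligible[i]) {
      stop("recipe '", cid, "' is not compulsory-eligible ",
        "(only egg/milk/milk-powder dishes may be compulsory)",
        call. = FALSE
      )
    }
  }
  cats <- db$recipes$category[idx]
  need <- config$category_counts
  lacking <- need$category[need$min > 0 & !need$category %in% cats]
  if (length(lacking)) {
    stop("selection has no recipe of required category: ",
      paste(lacking, collapse = ", "),
      call. = FALSE
    )
  }
  decisions <- hcm_decisions(db, selection, config)
  constraints <- hcm_constraints(guidelines, config, unique(cats))
  sols <- enumerate_k_best(decisions, constraints,
    k = config$k_alternatives, config = lp
  )
  if (!length(sols)) {
    return(list(solve_min_cost(decisions, constraints, lp)))
  }
  lapply(sols, function(s) {
    s$meta <- list(
      mode = "hcm", category = guidelines$category,
      use_subsidy = config$use_subsidy
    )
    s
  })
}

#' Augment a meal for a severely malnourished child
#'
#' SAM beneficiaries have elevated macro targets. Starting from a meal
#' optimized for the non-SAM sibling category, this adds one or two
#' snack servings, uniformly scales the meal's serving multipliers (up
#' to `sam_scale_cap`, never beyond the serving-multiplier ceiling), or
#' both, choosing the cheapest combination that brings energy, protein
#' and fat into the SAM guideline bands. If no combination suffices, the
#' best-effort augmentation is returned with an explicit per-nutrient
#' shortfall report, never silently.
#'
#' @param solution A feasible meal (`ration_solution`) for the non-SAM
#'   category.
#' @param db The [food_db()] (supplies snack recipes).
#' @param guidelines_sam The SAM [guideline_set()].
#' @param config The [meal_config()] used for the base meal.
#' @return A `ration_solution` with extra fields `sam_scale` (the
#'   applied multiplier), `added_snacks` (ids), `best_effort` (logical)
#'   and `shortfall` (tibble; zero rows when all bands are met). Energy
#'   never decreases relative to the input.
#' @export
augment_for_sam <- function(solution, db, guidelines_sam,
                            config = meal_config()) {
  if (solution$status == "infeasible") {
    stop("base solution is infeasible", call. = FALSE)
  }
  band <- guidelines_sam$macro_band
  lower <- guidelines_sam$targets[band$nutrient] * band$low
  upper <- guidelines_sam$targets[band$nutrient] * band$high
  macros <- band$nutrient

  base_sel <- dplyr::filter(solution$quantities, .data$selected)
  base_tot <- solution$nutrient_totals
  lam_max <- min(
    config$sam_scale_cap,
    if (nrow(base_sel)) config$serving_fraction_high / max(base_sel$amount) else 1
  )
  lam_max <- max(1, lam_max)

  snack_ids <- setdiff(
    db$recipes$id[db$recipes$category == "snack"], base_sel$id
  )
  snack_prof <- lapply(snack_ids, function(id) {
    recipe_profile(id, db,
      use_subsidy = config$use_subsidy,
      apply_fortification = config$apply_fortification
    )
  })
  names(snack_prof) <- snack_ids
  # snack sets: none, each single snack, each pair of distinct snacks
  # (a snack enters at one serving, keeping multipliers within bounds)
  snack_sets <- list(character(0))
  for (s in snack_ids) snack_sets <- c(snack_sets, list(s))
  if (length(snack_ids) >= 2) {
    pairs <- utils::combn(snack_ids, 2, simplify = FALSE)
    snack_sets <- c(snack_sets, pairs)
  }

  evaluate <- function(set, lam) {
    snack_nut <- nutrient_vector()
    snack_cost <- 0
    for (s in set) {
      snack_nut <- snack_nut + snack_prof[[s]]$nutrients
      snack_cost <- snack_cost + snack_prof[[s]]$cost_per_serving
    }
    tot <- lam * base_tot + snack_nut
    short <- pmax(lower - tot[macros], 0)
    over <- pmax(tot[macros] - upper, 0)
    list(
      totals = tot, shortfall = short, overflow = over,
      cost = lam * solution$total_cost + snack_cost
    )
  }

  candidates <- list()
  for (set in snack_sets) {
    # minimal lambda that closes all macro gaps with this snack set
    snack_nut <- nutrient_vector()
    for (s in set) snack_nut <- snack_nut + snack_prof[[s]]$nutrients
    need <- (lower - snack_nut[macros]) / pmax(base_tot[macros], 1e-12)
    lam <- max(1, max(need))
    lam <- min(lam, lam_max)
    ev <- evaluate(set, lam)
    candidates[[length(candidates) + 1]] <- list(
      set = set, lam = lam, ev = ev,
      feasible = all(ev$shortfall <= 1e-9) && all(ev$overflow <= 1e-9)
    )
  }
  feas <- Filter(function(c) c$feasible, candidates)
  pick <- if (length(feas)) {
    feas[[which.min(vapply(feas, function(c) c$ev$cost, numeric(1)))]]
  } else {
    # best effort: minimize total relative shortfall, then cost
    score <- vapply(candidates, function(c) {
      sum(c$ev$shortfall / pmax(lower, 1e-12))
    }, numeric(1))
    best <- which(score <= min(score) + 1e-12)
    cands <- candidates[best]
    cands[[which.min(vapply(cands, function(c) c$ev$cost, numeric(1)))]]
  }

  if (length(pick$set) == 0 && abs(pick$lam - 1) < 1e-12 && pick$feasible) {
    return(solution) # SAM bands already met: no-op
  }

  # rebuild a solution over the meal recipes + added snacks
  ids <- c(base_sel$id, unique(pick$set))
  cfg2 <- config
  cfg2$compulsory_recipe_ids <- character()
  decisions <- hcm_decisions(db, ids, cfg2)
  amounts <- stats::setNames(rep(0, length(ids)), ids)
  amounts[base_sel$id] <- base_sel$amount * pick$lam
  for (s in pick$set) amounts[s] <- amounts[s] + 1
  constraints <- constraint_set(
    nutrient_lower = stats::setNames(lower, macros),
    nutrient_upper = stats::setNames(upper, macros),
    budget = config$budget
  )
  out <- new_ration_solution(
    decisions, unname(amounts[decisions$id]), constraints,
    status = "optimal"
  )
  short <- pick$ev$shortfall
  out$sam_scale <- pick$lam
  out$added_snacks <- pick$set
  out$best_effort <- !pick$feasible
  out$shortfall <- tibble::tibble(
    nutrient = macros[short > 1e-9],
    required = unname(lower[short > 1e-9]),
    achieved = unname(pick$ev$totals[macros][short > 1e-9]),
    shortfall = unname(short[short > 1e-9])
  )
  out$meta <- list(mode = "hcm_sam", category = guidelines_sam$category)
  out
}

#' Assemble a weekly menu
#'
#' Bundles per-day meal solutions into a weekly menu with the mean and
#' sample standard deviation of the daily cost and the daily macro
#' series. Protein:energy and fat:energy are expressed as percent of
#' energy via the Atwater factors (4 kcal/g protein, 9 kcal/g fat).
#'
#' @param day_solutions List of `ration_solution`s, one per day.
#' @param labels Optional day labels (default `day_1`, `day_2`, ...).
#' @return A `weekly_menu`: `days` tibble (label, cost, energy, protein,
#'   fat, protein_energy_pct, fat_energy_pct), `solutions` list,
#'   `mean_cost`, `sd_cost`.
#' @export
build_weekly_menu <- function(day_solutions, labels = NULL) {
  if (!length(day_solutions)) {
    stop("need at least one day's solution", call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("day_", seq_along(day_solutions))
  stopifnot(length(labels) == length(day_solutions))
  days <- purrr::map2_dfr(day_solutions, labels, function(s, lab) {
    tot <- s$nutrient_totals
    tibble::tibble(
      label = lab, cost = s$total_cost,
      energy = tot[["energy"]], protein = tot[["protein"]],
      fat = tot[["fat"]],
      protein_energy_pct = 100 * 4 * tot[["protein"]] / tot[["energy"]],
      fat_energy_pct = 100 * 9 * tot[["fat"]] / tot[["energy"]]
    )
  })
  structure(
    list(
      days = days, solutions = day_solutions,
      mean_cost = mean(days$cost),
      sd_cost = stats::sd(days$cost)
    ),
    class = "weekly_menu"
  )
}

#' @export
print.weekly_menu <- function(x, ...) {
  cat(
    "<weekly_menu> ", nrow(x$days), " days; mean (SD) cost per day: ",
    format(x$mean_cost, digits = 4), " (",
    format(x$sd_cost, digits = 3), ")\n",
    sep = ""
  )
  print(x$days)
  invisible(x)
}
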