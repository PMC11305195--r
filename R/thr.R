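#' Take-home-ration configuration
#'
#' Tunable rules for the take-home-ration (THR) optimizer. Defaults
#' encode the program rules: a 2:1 cereal-to-pulse ratio, inclusion of
#' at least one food from each of the four mandatory groups, and
#' per-item daily quantity windows with tighter caps on the restricted
#' classes (oils, sugars, nuts, milk products, egg). The published rules
#' name the restricted classes without printing caps, so the caps here
#' are program-plausible defaults and fully user-overridable.
#'
#' @param use_subsidy Price foods at their subsidised price when one
#'   exists.
#' @param apply_fortification Apply fortification overlays of fortified
#'   foods.
#' @param budget Daily budget per beneficiary (soft by default: costlier
#'   optima are flagged `over_budget`, not suppressed).
#' @param hard_budget Enforce the budget as a hard cap instead.
#' @param cereal_pulse_ratio Required ratio of cereal grams to pulse
#'   grams (default 2).
#' @param ratio_tol Relative tolerance on the ratio (default 0.02).
#' @param group_windows Optional data frame (`group`, `premix`, `min_g`,
#'   `max_g`) of quantity windows per food group, separately for whole
#'   foods and premixes; empty (unconstrained) by default.
#' @param item_windows Named list mapping food ids to `c(min, max)`
#'   grams/day, overriding the class defaults.
#' @param default_item_window `c(min, max)` grams/day applied to foods
#'   with no class or item override. The min is the smallest meaningful
#'   inclusion when a food is selected.
#' @param class_windows Named list of `c(min, max)` per food group for
#'   the restricted classes.
#' @param must_include_food Optional id of a cereal or millet that must
#'   appear in the ration.
#' @param enforce_micros Character vector of micronutrients whose
#'   guideline targets become hard lower bounds. By default
#'   micronutrients are reported against, not enforced (program practice:
#'   macros are mandated, micronutrient provision is displayed).
#' @param k_alternatives Number of alternative (next least expensive)
#'   baskets to return.
#' @return A `thr_config` list.
#' @export
thr_config <- function(use_subsidy = FALSE, apply_fortification = TRUE,
                       budget = 8, hard_budget = FALSE,
                       cereal_pulse_ratio = 2, ratio_tol = 0.02,
                       group_windows = NULL, item_windows = list(),
                       default_item_window = c(5, 250),
                       class_windows = list(
                         edible_oils_and_fats = c(5, 15),
                         sugars = c(5, 30),
                         nuts_and_dry_fruits = c(5, 30),
                         milk_and_milk_products = c(5, 60),
                         egg = c(5, 60)
                       ),
                       must_include_food = NULL,
                       enforce_micros = character(),
                       k_alternatives = 1) {
  stopifnot(
    cereal_pulse_ratio > 0, ratio_tol >= 0, budget > 0,
    k_alternatives >= 1, length(default_item_window) == 2,
    default_item_window[1] <= default_item_window[2]
  )
  structure(
    list(
      use_subsidy = use_subsidy, apply_fortification = apply_fortification,
      budget = budget, hard_budget = hard_budget,
      cereal_pulse_ratio = cereal_pulse_ratio, ratio_tol = ratio_tol,
      group_windows = group_windows, item_windows = item_windows,
      default_item_window = default_item_window,
      class_windows = class_windows,
      must_include_food = must_include_food,
      enforce_micros = enforce_micros,
      k_alternatives = k_alternatives
    ),
    class = "thr_config"
  )
}

thr_mandatory_groups <- function() {
  c(
    "cereals_and_millets", "pulses_and_legumes", "sugars",
    "edible_oils_and_fats"
  )
}

# Resolve the (min, max) window for one food.
resolve_item_window <- function(id, group, config) {
  if (!is.null(config$item_windows[[id]])) {
    return(config$item_windows[[id]])
  }
  if (!is.null(config$class_windows[[group]])) {
    return(config$class_windows[[group]])
  }
  config$default_item_window
}

# Decision table for a THR instance.
thr_decisions <- function(db, config) {
  foods <- db$foods
  per_g <- effective_nutrients_per_g(foods, config$apply_fortification)
  price <- effective_price_per_gram(foods, config$use_subsidy)
  purrr::map_dfr(seq_len(nrow(foods)), function(i) {
    win <- resolve_item_window(foods$id[i], foods$group[i], config)
    decision_spec(
      id = foods$id[i], kind = "continuous_grams",
      min = win[1], max = win[2],
      unit_cost = price[i], unit_nutrients = per_g[i, ],
      unit_weight = 1, group = foods$group[i],
      required = identical(foods$id[i], config$must_include_food),
      premix = foods$premix_eligible[i]
    )
  })
}

# Constraint set implied by a guideline set + THR config.
thr_constraints <- function(guidelines, config) {
  band <- guidelines$macro_band
  lower <- stats::setNames(
    guidelines$targets[band$nutrient] * band$low, band$nutrient
  )
  upper <- stats::setNames(
    guidelines$targets[band$nutrient] * band$high, band$nutrient
  )
  for (nut in config$enforce_micros) {
    if (!nut %in% nutrient_names()) {
      stop("enforce_micros names unknown nutrient: ", nut, call. = FALSE)
    }
    if (guidelines$targets[[nut]] > 0) lower[[nut]] <- guidelines$targets[[nut]]
  }
  if (!is.null(guidelines$upper_limits)) {
    tul <- guidelines$upper_limits[guidelines$upper_limits > 0]
    for (nut in names(tul)) {
      upper[[nut]] <- min(upper[[nut]] %||% Inf, tul[[nut]], na.rm = TRUE)
    }
  }
  constraint_set(
    nutrient_lower = lower,
    nutrient_upper = upper,
    group_min_count = stats::setNames(
      rep(1, length(thr_mandatory_groups())), thr_mandatory_groups()
    ),
    group_windows = config$group_windows,
    ratio = list(
      num_group = "cereals_and_millets",
      den_group = "pulses_and_legumes",
      ratio = config$cereal_pulse_ratio, tol = config$ratio_tol
    ),
    force_ids = if (!is.null(config$must_include_food)) {
      config$must_include_food
    } else {
      character()
    },
    budget = config$budget, hard_budget = config$hard_budget
  )
}

#' Optimize a take-home ration
#'
#' Formulates and solves the least-cost raw-food basket (grams per
#' beneficiary per day) that satisfies the program rules: at least one
#' food from each of the cereal, pulse, sugar and oil groups; total
#' energy, protein and fat within the guideline bands; optional
#' micronutrient floors and tolerable upper limits; the cereal-to-pulse
#' ratio; and all group/item quantity windows. Returns the optimum and,
#' when requested, the next least expensive alternative baskets.
#'
#' @param db A [food_db()] with at least one food in each mandatory
#'   group.
#' @param guidelines A [guideline_set()].
#' @param config A [thr_config()].
#' @param lp Solver settings ([lp_config()]).
#' @return A list of `ration_solution`s ordered by cost (length up to
#'   `config$k_alternatives`). If the model is infeasible the list holds
#'   a single solution with status `infeasible` and a relaxation hint.
#' @export
#' @examples
#' db <- toy_instances()$thr_toy_5
#' sols <- optimize_thr(db, default_guidelines("child_1_3y"))
#' sols[[1]]$total_cost
optimize_thr <- function(db, guidelines, config = thr_config(),
                         lp = lp_config()) {
  stopifnot(inherits(db, "food_db"), inherits(guidelines, "guideline_set"))
  missing_groups <- setdiff(thr_mandatory_groups(), unique(db$foods$group))
  if (length(missing_groups)) {
    stop("database lacks foods in mandatory group(s): ",
      paste(missing_groups, collapse = ", "),
      call. = FALSE
    )
  }
  if (!is.null(config$must_include_food)) {
    i <- match(config$must_include_food, db$foods$id)
    if (is.na(i)) {
      stop("must_include_food id not in database: ",
        config$must_include_food,
        call. = FALSE
      )
    }
    if (db$foods$group[i] != "cereals_and_millets") {
      stop(
        "must_include_food must be a cereal or millet; '",
        config$must_include_food, "' is in group ", db$foods$group[i],
        call. = FALSE
      )
    }
  }
  decisions <- thr_decisions(db, config)
  constraints <- thr_constraints(guidelines, config)
  sols <- enumerate_k_best(decisions, constraints,
    k = config$k_alternatives, config = lp
  )
  if (!length(sols)) {
    return(list(solve_min_cost(decisions, constraints, lp)))
  }
  lapply(sols, function(s) {
    s$meta <- list(
      mode = "thr", category = guidelines$category,
      use_subsidy = config$use_subsidy
    )
    s
  })
}

#' Summarize a take-home-ration solution
#'
#' Cost extrapolations for a beneficiary's daily, weekly (x7), monthly
#' (x30) and yearly (x365) requirement, the ingredient grams, and the
#' percent-of-guideline adequacy table with take-home-ration colour
#' coding.
#'
#' @param solution An optimal or over-budget `ration_solution`.
#' @param guidelines The [guideline_set()] it was optimized against.
#' @return A list with `costs` (tibble period/days/cost), `ingredients`
#'   (tibble id/group/grams) and `adequacy` (see [adequacy_table()]).
#' @export
thr_product_summary <- function(solution, guidelines) {
  if (solution$status == "infeasible") {
    stop("cannot summarize an infeasible solution", call. = FALSE)
  }
  days <- c(day = 1, week = 7, month = 30, year = 365)
  costs <- tibble::tibble(
    period = names(days), days = unname(days),
    cost = solution$total_cost * unname(days)
  )
  ingredients <- solution$quantities |>
    dplyr::filter(.data$selected) |>
    dplyr::transmute(.data$id, .data$group, grams = .data$weight)
  list(
    costs = costs,
    ingredients = ingredients,
    adequacy = adequacy_table(solution, guidelines, mode = "thr")
  )
}
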