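#' Tracked nutrients
#'
#' The sixteen nutrients tracked throughout the package, in canonical
#' order, with the fixed unit each is expressed in. All nutrient columns
#' in food tables, guideline sets and solutions use these names.
#'
#' @return A tibble with columns `nutrient` and `unit`.
#' @export
#' @examples
#' nutrient_info()
nutrient_info <- function() {
  tibble::tibble(
    nutrient = c(
      "energy", "protein", "fat", "dietary_fiber",
      "calcium", "zinc", "iron", "magnesium",
      "vitamin_a", "folate", "vitamin_b12", "vitamin_b1",
      "vitamin_b2", "vitamin_b3", "vitamin_b6", "vitamin_c"
    ),
    unit = c(
      "kcal", "g", "g", "g",
      "mg", "mg", "mg", "mg",
      "ug", "ug", "ug", "mg",
      "mg", "mg", "mg", "mg"
    )
  )
}

#' Canonical nutrient names
#'
#' @return Character vector of the sixteen tracked nutrient names, in
#'   canonical order.
#' @export
nutrient_names <- function() nutrient_info()$nutrient

# Column names used in food CSV files, in schema order, paired with the
# canonical nutrient each maps to.
food_csv_nutrient_cols <- function() {
  c(
    energy_kcal = "energy", protein_g = "protein", fat_g = "fat",
    fiber_g = "dietary_fiber", calcium_mg = "calcium", zinc_mg = "zinc",
    iron_mg = "iron", magnesium_mg = "magnesium", vitamin_a_ug = "vitamin_a",
    folate_ug = "folate", vitamin_b12_ug = "vitamin_b12",
    vitamin_b1_mg = "vitamin_b1", vitamin_b2_mg = "vitamin_b2",
    vitamin_b3_mg = "vitamin_b3", vitamin_b6_mg = "vitamin_b6",
    vitamin_c_mg = "vitamin_c"
  )
}

#' Construct a nutrient vector
#'
#' Builds a named numeric vector over the sixteen tracked nutrients.
#' Unspecified nutrients default to 0; `NA` values are replaced by 0
#' with a warning (composition tables are sparse, and zero is the
#' conservative choice for a lower-bound constraint).
#'
#' @param ... Named nutrient amounts, e.g. `energy = 350, protein = 10`.
#' @param .values Optionally, a named numeric vector or list instead of
#'   `...`.
#' @return Named numeric vector of length 16 in canonical order.
#' @export
#' @examples
#' nutrient_vector(energy = 350, protein = 10, fat = 1)
nutrient_vector <- function(..., .values = NULL) {
  vals <- if (is.null(.values)) list(...) else as.list(.values)
  out <- stats::setNames(rep(0, 16), nutrient_names())
  if (length(vals)) {
    nm <- names(vals)
    if (is.null(nm) || any(nm == "")) {
      stop("all nutrient amounts must be named", call. = FALSE)
    }
    unknown <- setdiff(nm, nutrient_names())
    if (length(unknown)) {
      stop("unknown nutrient name(s): ", paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
    v <- vapply(vals, function(x) as.numeric(x)[1], numeric(1))
    if (anyNA(v)) {
      warning("missing nutrient values treated as 0", call. = FALSE)
      v[is.na(v)] <- 0
    }
    out[nm] <- v
  }
  validate_nutrient_vector(out)
  out
}

validate_nutrient_vector <- function(x, what = "nutrient vector") {
  if (!is.numeric(x) || !all(nutrient_names() %in% names(x))) {
    stop(what, " must be numeric and named over all tracked nutrients",
      call. = FALSE
    )
  }
  bad <- !is.finite(x[nutrient_names()]) | x[nutrient_names()] < 0
  if (any(bad)) {
    stop(what, " has negative or non-finite component(s): ",
      paste(nutrient_names()[bad], collapse = ", "),
      call. = FALSE
    )
  }
  invisible(x)
}

# Coerce any object carrying nutrient totals to a canonical named vector.
as_nutrient_vector <- function(x) {
  if (inherits(x, "ration_solution")) {
    return(x$nutrient_totals)
  }
  if (is.data.frame(x)) {
    miss <- setdiff(nutrient_names(), names(x))
    if (length(miss)) {
      stop("data frame lacks nutrient column(s): ",
        paste(miss, collapse = ", "),
        call. = FALSE
      )
    }
    if (nrow(x) != 1) stop("expected a single-row nutrient table", call. = FALSE)
    return(stats::setNames(
      as.numeric(x[1, nutrient_names()]),
      nutrient_names()
    ))
  }
  v <- stats::setNames(rep(0, 16), nutrient_names())
  keep <- intersect(names(x), nutrient_names())
  v[keep] <- as.numeric(x[keep])
  v
}

# Round half away from zero (adequacy tables print one decimal with this
# convention; base round() uses banker's rounding).
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Food groups
#'
#' The closed enumeration of food groups used for raw foods and for the
#' group-level rules of take-home rations (group inclusion, quantity
#' windows, the cereal-to-pulse ratio).
#'
#' @return Character vector of valid food group labels.
#' @export
food_groups <- function() {
  c(
    "cereals_and_millets", "pulses_and_legumes", "green_leafy_vegetables",
    "other_vegetables", "roots_and_tubers", "fruits", "egg",
    "milk_and_milk_products", "nuts_and_dry_fruits", "sugars",
    "edible_oils_and_fats"
  )
}

#' Recipe categories
#'
#' Categories a cooked-meal recipe may belong to. A daily meal is built
#' from a main dish, a curry to accompany it, optionally a side dish and
#' "additional" accompaniments (chutneys, salads); snacks are used for
#' augmenting meals of severely malnourished children.
#'
#' @return Character vector of valid recipe categories.
#' @export
recipe_categories <- function() {
  c("main_dish", "curry", "side_dish", "snack", "additional")
}
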