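#' Construct a food database
#'
#' Bundles a table of raw foods, an optional table of recipes, and a
#' currency label into a validated `food_db` object, the container every
#' optimizer in the package consumes.
#'
#' @param foods A data frame with one row per raw food: columns `id`,
#'   `name`, `group` (see [food_groups()]), one column per tracked
#'   nutrient (per 100 g edible portion; see [nutrient_names()]),
#'   `retail_price_per_kg`, `subsidized_price_per_kg` (`NA` when no
#'   subsidy exists), `fortified` (logical), `premix_eligible`
#'   (logical), and optionally `fortification_overlay` (a list column of
#'   named nutrient vectors added per 100 g when fortification is
#'   applied).
#' @param recipes Optional data frame with one row per recipe: `id`,
#'   `name`, `category` (see [recipe_categories()]), `serving_size_g`,
#'   `compulsory_eligible` (logical; only egg/milk/milk-powder dishes),
#'   and `ingredients`, a list column of data frames with columns
#'   `food_id` and `grams` (grams per serving).
#' @param currency_label Uninterpreted currency tag (default `"INR"`).
#' @return A validated `food_db` object.
#' @export
#' @examples
#' db <- toy_instances()$thr_toy_5
#' db$foods
food_db <- function(foods, recipes = NULL, currency_label = "INR") {
  foods <- tibble::as_tibble(foods)
  if (!"fortification_overlay" %in% names(foods)) {
    foods$fortification_overlay <- vector("list", nrow(foods))
  }
  if (!"subsidized_price_per_kg" %in% names(foods)) {
    foods$subsidized_price_per_kg <- NA_real_
  }
  if (is.null(recipes)) {
    recipes <- tibble::tibble(
      id = character(), name = character(), category = character(),
      serving_size_g = numeric(), compulsory_eligible = logical(),
      ingredients = list()
    )
  }
  recipes <- tibble::as_tibble(recipes)
  db <- structure(
    list(
      foods = foods, recipes = recipes,
      currency_label = currency_label
    ),
    class = "food_db"
  )
  validate_food_db(db)
}

#' @export
print.food_db <- function(x, ...) {
  cat(
    "<food_db> ", nrow(x$foods), " foods, ", nrow(x$recipes),
    " recipes (currency: ", x$currency_label, ")\n",
    sep = ""
  )
  print(dplyr::count(x$foods, .data$group))
  invisible(x)
}

validate_food_db <- function(db) {
  f <- db$foods
  req <- c(
    "id", "name", "group", nutrient_names(),
    "retail_price_per_kg", "fortified", "premix_eligible"
  )
  miss <- setdiff(req, names(f))
  if (length(miss)) {
    stop("foods table lacks required column(s): ",
      paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(f$id)) {
    dup <- unique(f$id[duplicated(f$id)])
    stop("duplicate food id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  badg <- !f$group %in% food_groups()
  if (any(badg)) {
    stop(
      "invalid food group in row(s) ",
      paste(which(badg), collapse = ", "), ": ",
      paste(unique(f$group[badg]), collapse = ", "),
      call. = FALSE
    )
  }
  for (nm in nutrient_names()) {
    v <- f[[nm]]
    if (anyNA(v)) {
      warning(
        "missing values in nutrient column '", nm,
        "' treated as 0 (rows ",
        paste(which(is.na(v)), collapse = ", "), ")",
        call. = FALSE
      )
      f[[nm]][is.na(v)] <- 0
    }
    bad <- !is.finite(f[[nm]]) | f[[nm]] < 0
    if (any(bad)) {
      stop("negative or non-finite '", nm, "' in row(s) ",
        paste(which(bad), collapse = ", "),
        call. = FALSE
      )
    }
  }
  bad <- !is.finite(f$retail_price_per_kg) | f$retail_price_per_kg <= 0
  if (any(bad)) {
    stop("retail_price_per_kg must be > 0; violated in row(s) ",
      paste(which(bad), collapse = ", "),
      call. = FALSE
    )
  }
  sp <- f$subsidized_price_per_kg
  bad <- !is.na(sp) & (!is.finite(sp) | sp <= 0)
  if (any(bad)) {
    stop("subsidized_price_per_kg must be > 0 when present; row(s) ",
      paste(which(bad), collapse = ", "),
      call. = FALSE
    )
  }
  has_overlay <- !vapply(f$fortification_overlay, is.null, logical(1))
  bad <- has_overlay & !f$fortified
  if (any(bad)) {
    stop("fortification_overlay present for unfortified food(s): ",
      paste(f$id[bad], collapse = ", "),
      call. = FALSE
    )
  }
  for (i in which(has_overlay)) {
    validate_nutrient_vector(
      as_nutrient_vector(f$fortification_overlay[[i]]),
      what = paste0("fortification overlay of '", f$id[i], "'")
    )
  }
  db$foods <- f

  r <- db$recipes
  if (nrow(r)) {
    reqr <- c(
      "id", "name", "category", "serving_size_g",
      "compulsory_eligible", "ingredients"
    )
    miss <- setdiff(reqr, names(r))
    if (length(miss)) {
      stop("recipes table lacks required column(s): ",
        paste(miss, collapse = ", "),
        call. = FALSE
      )
    }
    if (anyDuplicated(r$id)) {
      stop("duplicate recipe id(s): ",
        paste(unique(r$id[duplicated(r$id)]), collapse = ", "),
        call. = FALSE
      )
    }
    bad <- !r$category %in% recipe_categories()
    if (any(bad)) {
      stop("invalid recipe category in row(s) ",
        paste(which(bad), collapse = ", "),
        call. = FALSE
      )
    }
    bad <- !is.finite(r$serving_size_g) | r$serving_size_g <= 0
    if (any(bad)) {
      stop("serving_size_g must be > 0; violated in row(s) ",
        paste(which(bad), collapse = ", "),
        call. = FALSE
      )
    }
    for (i in seq_len(nrow(r))) {
      ing <- tibble::as_tibble(r$ingredients[[i]])
      if (!all(c("food_id", "grams") %in% names(ing))) {
        stop("recipe '", r$id[i],
          "': ingredients need columns food_id and grams",
          call. = FALSE
        )
      }
      unknown <- setdiff(ing$food_id, f$id)
      if (length(unknown)) {
        stop("recipe '", r$id[i], "' references unknown food id(s): ",
          paste(unknown, collapse = ", "),
          call. = FALSE
        )
      }
      if (any(!is.finite(ing$grams) | ing$grams <= 0)) {
        stop("recipe '", r$id[i], "': ingredient grams must be > 0",
          call. = FALSE
        )
      }
      r$ingredients[[i]] <- ing
    }
    db$recipes <- r
  }
  db
}

#' Load a food database from disk
#'
#' CSV files carry the foods table only (one row per raw food, exact
#' header names as documented below); JSON documents carry foods,
#' recipes and fortification overlays. All content is validated and
#' violations are reported with their row or record location.
#'
#' CSV headers: `id,name,group,energy_kcal,protein_g,fat_g,fiber_g,
#' calcium_mg,zinc_mg,iron_mg,magnesium_mg,vitamin_a_ug,folate_ug,
#' vitamin_b12_ug,vitamin_b1_mg,vitamin_b2_mg,vitamin_b3_mg,
#' vitamin_b6_mg,vitamin_c_mg,retail_price_per_kg,
#' subsidized_price_per_kg,fortified,premix_eligible`.
#'
#' @param path File to read.
#' @param format `"csv"` or `"json"`; guessed from the extension when
#'   omitted.
#' @return A validated [food_db()] object.
#' @export
load_food_database <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    csv_cols <- c(
      "id", "name", "group", names(food_csv_nutrient_cols()),
      "retail_price_per_kg", "subsidized_price_per_kg",
      "fortified", "premix_eligible"
    )
    miss <- setdiff(csv_cols, names(raw))
    if (length(miss)) {
      stop("missing required column(s): ", paste(miss, collapse = ", "),
        call. = FALSE
      )
    }
    foods <- raw
    names(foods)[match(
      names(food_csv_nutrient_cols()),
      names(foods)
    )] <- unname(food_csv_nutrient_cols())
    foods$fortified <- as.logical(foods$fortified)
    foods$premix_eligible <- as.logical(foods$premix_eligible)
    food_db(foods)
  } else {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
    foods <- purrr::map_dfr(doc$foods, function(x) {
      nut <- as_nutrient_vector(unlist(x$nutrients_per_100g))
      tibble::tibble(
        id = x$id, name = x$name %||% x$id, group = x$group,
        !!!as.list(nut),
        retail_price_per_kg = as.numeric(x$retail_price_per_kg),
        subsidized_price_per_kg = as.numeric(
          x$subsidized_price_per_kg %||% NA_real_
        ),
        fortified = isTRUE(x$fortified),
        premix_eligible = isTRUE(x$premix_eligible),
        fortification_overlay = list(
          if (!is.null(x$fortification_overlay)) {
            as_nutrient_vector(unlist(x$fortification_overlay))
          }
        )
      )
    })
    recipes <- NULL
    if (length(doc$recipes)) {
      recipes <- purrr::map_dfr(doc$recipes, function(x) {
        tibble::tibble(
          id = x$id, name = x$name %||% x$id, category = x$category,
          serving_size_g = as.numeric(x$serving_size_g),
          compulsory_eligible = isTRUE(x$compulsory_eligible),
          ingredients = list(purrr::map_dfr(x$ingredients, function(g) {
            tibble::tibble(
              food_id = g$food_id,
              grams = as.numeric(g$grams)
            )
          }))
        )
      })
    }
    food_db(foods, recipes,
      currency_label = doc$currency_label %||% "INR"
    )
  }
}

#' Write a food database to disk
#'
#' Inverse of [load_food_database()]: CSV writes the foods table with the
#' documented headers, JSON writes the full database (foods, overlays,
#' recipes). Numeric fields round-trip to full double precision.
#'
#' @param db A [food_db()] object.
#' @param path Output file.
#' @param format `"csv"` or `"json"`; guessed from the extension when
#'   omitted.
#' @return `path`, invisibly.
#' @export
write_food_database <- function(db, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    out <- db$foods
    nut_map <- food_csv_nutrient_cols()
    names(out)[match(unname(nut_map), names(out))] <- names(nut_map)
    out <- out[, c(
      "id", "name", "group", names(nut_map),
      "retail_price_per_kg", "subsidized_price_per_kg",
      "fortified", "premix_eligible"
    )]
    readr::write_csv(out, path, progress = FALSE)
  } else {
    foods <- purrr::pmap(db$foods, function(...) {
      row <- list(...)
      rec <- list(
        id = row$id, name = row$name, group = row$group,
        nutrients_per_100g = as.list(
          stats::setNames(
            vapply(nutrient_names(), function(n) row[[n]], numeric(1)),
            nutrient_names()
          )
        ),
        retail_price_per_kg = row$retail_price_per_kg,
        fortified = row$fortified,
        premix_eligible = row$premix_eligible
      )
      if (!is.na(row$subsidized_price_per_kg)) {
        rec$subsidized_price_per_kg <- row$subsidized_price_per_kg
      }
      if (!is.null(row$fortification_overlay)) {
        rec$fortification_overlay <- as.list(row$fortification_overlay)
      }
      rec
    })
    recipes <- purrr::pmap(db$recipes, function(...) {
      row <- list(...)
      list(
        id = row$id, name = row$name, category = row$category,
        serving_size_g = row$serving_size_g,
        compulsory_eligible = row$compulsory_eligible,
        ingredients = purrr::pmap(
          row$ingredients,
          function(food_id, grams) list(food_id = food_id, grams = grams)
        )
      )
    })
    jsonlite::write_json(
      list(
        currency_label = db$currency_label,
        foods = foods, recipes = recipes
      ),
      path,
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(path)
}

#' Effective price per gram of a raw food
#'
#' Prices are stored per kg; the optimizer works per gram. When a
#' subsidy is in force and the food has a subsidised price, that price
#' is used, otherwise the retail price.
#'
#' @param food One row of a foods table (data frame with
#'   `retail_price_per_kg` and `subsidized_price_per_kg`).
#' @param use_subsidy Use the subsidised price when available?
#' @return Price per gram (currency/g), vectorised over rows of `food`.
#' @export
#' @examples
#' db <- toy_instances()$thr_toy_5
#' effective_price_per_gram(db$foods, use_subsidy = TRUE)
effective_price_per_gram <- function(food, use_subsidy = FALSE) {
  p <- food$retail_price_per_kg
  if (use_subsidy) {
    s <- food$subsidized_price_per_kg
    p <- ifelse(!is.na(s), s, p)
  }
  p / 1000
}

#' Effective nutrient content per 100 g
#'
#' Returns the base per-100 g nutrient values, plus the fortification
#' overlay for foods flagged as fortified when `apply_fortification` is
#' on (mandatorily fortified commodities such as oil or salt carry extra
#' micronutrients; the toggle lets users model unfortified procurement).
#'
#' @param food One row of a foods table.
#' @param apply_fortification Add the overlay for fortified foods?
#' @return A named nutrient vector (per 100 g).
#' @export
effective_nutrients_per_100g <- function(food, apply_fortification = TRUE) {
  if (nrow(food) != 1) stop("expected a single food row", call. = FALSE)
  base <- as_nutrient_vector(food[1, ])
  ov <- food$fortification_overlay[[1]]
  if (apply_fortification && isTRUE(food$fortified[1]) && !is.null(ov)) {
    base <- base + as_nutrient_vector(ov)
  }
  base
}

# Per-gram effective nutrient matrix for a whole foods table
# (rows = foods, cols = nutrients).
effective_nutrients_per_g <- function(foods, apply_fortification = TRUE) {
  m <- as.matrix(foods[, nutrient_names()])
  if (apply_fortification && any(foods$fortified)) {
    for (i in which(foods$fortified)) {
      ov <- foods$fortification_overlay[[i]]
      if (!is.null(ov)) m[i, ] <- m[i, ] + as_nutrient_vector(ov)
    }
  }
  rownames(m) <- foods$id
  m / 100
}

#' Per-serving nutrient profile, cost and weight of a recipe
#'
#' Recomputes (never caches) the per-serving totals of a recipe from its
#' raw ingredients: nutrients are the gram-weighted sum of the
#' ingredients' effective per-100 g values, cost is grams times the
#' effective per-gram price, weight is total raw grams.
#'
#' @param recipe A recipe id, or one row of a recipes table.
#' @param db A [food_db()] providing the ingredient foods.
#' @param use_subsidy,apply_fortification Passed to
#'   [effective_price_per_gram()] / [effective_nutrients_per_100g()].
#' @return A list with `nutrients` (named vector per serving),
#'   `cost_per_serving` and `weight_g`.
#' @export
recipe_profile <- function(recipe, db, use_subsidy = FALSE,
                           apply_fortification = TRUE) {
  if (is.character(recipe)) {
    i <- match(recipe, db$recipes$id)
    if (is.na(i)) stop("unknown recipe id: ", recipe, call. = FALSE)
    recipe <- db$recipes[i, ]
  }
  ing <- recipe$ingredients[[1]]
  if (is.null(ing) || nrow(ing) == 0) {
    return(list(
      nutrients = nutrient_vector(), cost_per_serving = 0, weight_g = 0
    ))
  }
  idx <- match(ing$food_id, db$foods$id)
  if (anyNA(idx)) {
    stop("unknown ingredient id(s): ",
      paste(ing$food_id[is.na(idx)], collapse = ", "),
      call. = FALSE
    )
  }
  foods <- db$foods[idx, ]
  per_g <- effective_nutrients_per_g(foods, apply_fortification)
  nutrients <- as.vector(ing$grams %*% per_g)
  names(nutrients) <- nutrient_names()
  cost <- sum(ing$grams * effective_price_per_gram(foods, use_subsidy))
  list(
    nutrients = nutrients,
    cost_per_serving = cost,
    weight_g = sum(ing$grams)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
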