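#' Beneficiary categories
#'
#' The supplementary-nutrition-program beneficiary categories the
#' packaged guideline defaults cover: children by age band, severely
#' acutely malnourished (SAM) children, and pregnant and lactating
#' women.
#'
#' @return Character vector of valid category labels.
#' @export
beneficiary_categories <- function() {
  c(
    "child_6_12m", "child_1_3y", "child_3_6y",
    "sam_child_6_12m", "sam_child_1_3y", "sam_child_3_6y",
    "pregnant_woman", "lactating_woman"
  )
}

# ICDS-SNP macronutrient guideline matrix (kcal, g, g per beneficiary
# per day). The program's published age-band matrix; SAM categories
# carry elevated targets.
icds_macro_matrix <- function() {
  tibble::tribble(
    ~category, ~energy, ~protein, ~fat,
    "child_6_12m", 200, 8, 10,
    "child_1_3y", 400, 15, 15,
    "child_3_6y", 400, 15, 15,
    "sam_child_6_12m", 400, 15, 15,
    "sam_child_1_3y", 700, 25, 25,
    "sam_child_3_6y", 800, 25, 25,
    "pregnant_woman", 600, 22, 22,
    "lactating_woman", 600, 22, 22
  )
}

# Per-meal micronutrient guideline values. Values flagged one_third_ear
# represent one-third of the estimated average requirement (the share
# of the daily requirement one supplemental meal is expected to cover).
icds_micro_defaults <- function(category) {
  if (category == "child_3_6y") {
    tibble::tribble(
      ~nutrient, ~target, ~one_third_ear,
      "calcium", 150.0, FALSE,
      "dietary_fiber", 6.8, TRUE,
      "folate", 40.0, FALSE,
      "iron", 3.0, FALSE,
      "magnesium", 34.7, TRUE,
      "vitamin_b3", 2.7, TRUE,
      "vitamin_b6", 0.3, FALSE,
      "vitamin_b2", 0.4, TRUE,
      "vitamin_b1", 0.3, TRUE,
      "vitamin_a", 80.0, FALSE,
      "vitamin_b12", 0.7, FALSE,
      "vitamin_c", 9.0, TRUE,
      "zinc", 1.5, FALSE
    )
  } else if (category == "child_1_3y") {
    tibble::tribble(
      ~nutrient, ~target, ~one_third_ear,
      "calcium", 135.0, FALSE,
      "dietary_fiber", 5.6, TRUE,
      "folate", 35.0, FALSE,
      "iron", 2.0, FALSE,
      "magnesium", 24.3, TRUE,
      "vitamin_a", 60.0, FALSE,
      "vitamin_b1", 0.2, TRUE,
      "vitamin_b12", 0.3, FALSE,
      "vitamin_b2", 0.3, TRUE,
      "vitamin_b3", 2.0, TRUE,
      "vitamin_b6", 0.3, FALSE,
      "vitamin_c", 8.0, TRUE,
      "zinc", 1.0, FALSE
    )
  } else {
    NULL
  }
}

#' Construct a guideline set
#'
#' A guideline set holds, for one beneficiary category, the per-day
#' nutrient targets, which of them are one-third-of-EAR single-meal
#' shares, optional tolerable upper limits, and the macronutrient bands
#' the optimizer enforces relative to the energy/protein/fat targets.
#' A target of 0 means "no lower-bound constraint for this nutrient",
#' not "force zero intake".
#'
#' @param category One of [beneficiary_categories()].
#' @param targets Named nutrient vector of guideline amounts per day.
#' @param one_third_ear Named logical vector flagging nutrients whose
#'   target is one-third of the estimated average requirement.
#' @param upper_limits Optional named nutrient vector of tolerable upper
#'   limits; where given, each must be at least the target.
#' @param macro_band Data frame with columns `nutrient`
#'   (energy/protein/fat), `low`, `high`: multiplicative band applied to
#'   the macro targets (low <= 1 <= high).
#' @return A `guideline_set` object.
#' @export
guideline_set <- function(category, targets,
                          one_third_ear = NULL,
                          upper_limits = NULL,
                          macro_band = default_macro_band()) {
  if (!category %in% beneficiary_categories()) {
    stop(
      "unknown beneficiary category '", category, "'; valid: ",
      paste(beneficiary_categories(), collapse = ", "),
      call. = FALSE
    )
  }
  targets <- as_nutrient_vector(targets)
  validate_nutrient_vector(targets, "targets")
  flags <- stats::setNames(rep(FALSE, 16), nutrient_names())
  if (!is.null(one_third_ear)) {
    flags[intersect(names(one_third_ear), nutrient_names())] <-
      as.logical(one_third_ear[intersect(names(one_third_ear), nutrient_names())])
  }
  if (!is.null(upper_limits)) {
    upper_limits <- as_nutrient_vector(upper_limits)
    bad <- upper_limits > 0 & upper_limits < targets
    if (any(bad)) {
      stop("upper_limit below target for: ",
        paste(nutrient_names()[bad], collapse = ", "),
        call. = FALSE
      )
    }
  }
  macro_band <- tibble::as_tibble(macro_band)
  stopifnot(all(c("nutrient", "low", "high") %in% names(macro_band)))
  bad <- macro_band$low > 1 | macro_band$high < 1 | macro_band$low > macro_band$high
  if (any(bad)) {
    stop("macro_band must satisfy low <= 1 <= high; violated for: ",
      paste(macro_band$nutrient[bad], collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      category = category, targets = targets, one_third_ear = flags,
      upper_limits = upper_limits, macro_band = macro_band
    ),
    class = "guideline_set"
  )
}

#' @export
print.guideline_set <- function(x, ...) {
  cat("<guideline_set> category:", x$category, "\n")
  nz <- x$targets[x$targets > 0]
  cat(
    " targets:",
    paste(names(nz), signif(nz, 4), sep = "=", collapse = ", "), "\n"
  )
  invisible(x)
}

#' Default macronutrient band
#'
#' The multiplicative window, relative to each macro target, within
#' which an optimized ration must fall: energy is pinned tightly at the
#' guideline (100-102%), while protein and fat may range 90-135% of
#' target, reflecting how program rules are applied in practice (energy
#' exactly budgeted, protein/fat allowed to float upward when cheap
#' protein sources overshoot).
#'
#' @return Tibble with columns `nutrient`, `low`, `high`.
#' @export
default_macro_band <- function() {
  tibble::tribble(
    ~nutrient, ~low, ~high,
    "energy", 1.00, 1.02,
    "protein", 0.90, 1.35,
    "fat", 0.90, 1.35
  )
}

#' Packaged default guidelines per beneficiary category
#'
#' Returns the packaged program defaults: the ICDS-SNP macronutrient
#' matrix for every category, plus per-meal micronutrient guideline
#' values for `child_3_6y` and `child_1_3y` (the two categories with
#' published worked examples). Other categories carry macros only until
#' the user supplies micronutrient values. Tolerable upper limits ship
#' empty (unconstrained); users provide them via [load_guidelines()].
#'
#' @param category One of [beneficiary_categories()].
#' @return A [guideline_set()].
#' @export
#' @examples
#' default_guidelines("child_1_3y")
default_guidelines <- function(category) {
  mac <- icds_macro_matrix()
  i <- match(category, mac$category)
  if (is.na(i)) {
    stop(
      "unknown beneficiary category '", category, "'; valid: ",
      paste(beneficiary_categories(), collapse = ", "),
      call. = FALSE
    )
  }
  targets <- nutrient_vector(
    energy = mac$energy[i], protein = mac$protein[i], fat = mac$fat[i]
  )
  micro <- icds_micro_defaults(category)
  flags <- NULL
  if (!is.null(micro)) {
    targets[micro$nutrient] <- micro$target
    flags <- stats::setNames(micro$one_third_ear, micro$nutrient)
  }
  guideline_set(category, targets, one_third_ear = flags)
}

#' Save / load guideline sets
#'
#' Guideline documents are JSON (or YAML, by extension) mirroring the
#' guideline-set fields, so program officers can edit targets, add
#' tolerable upper limits, or adjust macro bands and feed the result
#' back to the optimizers. Loading re-validates all invariants and a
#' save/load round trip reproduces the set exactly.
#'
#' @param set A [guideline_set()].
#' @param path File path (`.json`, `.yaml`/`.yml`).
#' @return `load_guidelines()` returns a [guideline_set()];
#'   `save_guidelines()` returns `path` invisibly.
#' @export
save_guidelines <- function(set, path) {
  doc <- list(
    category = set$category,
    targets = as.list(set$targets),
    one_third_ear = as.list(set$one_third_ear),
    upper_limits = if (!is.null(set$upper_limits)) as.list(set$upper_limits),
    macro_band = purrr::pmap(
      set$macro_band,
      function(nutrient, low, high) {
        list(nutrient = nutrient, low = low, high = high)
      }
    )
  )
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML output", call. = FALSE)
    }
    writeLines(yaml::as.yaml(doc), path)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname save_guidelines
#' @export
load_guidelines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML input", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  band <- if (!is.null(doc$macro_band)) {
    purrr::map_dfr(doc$macro_band, function(b) {
      tibble::tibble(
        nutrient = b$nutrient,
        low = as.numeric(b$low), high = as.numeric(b$high)
      )
    })
  } else {
    default_macro_band()
  }
  guideline_set(
    category = doc$category,
    targets = as_nutrient_vector(unlist(doc$targets)),
    one_third_ear = unlist(doc$one_third_ear),
    upper_limits = if (!is.null(doc$upper_limits)) {
      as_nutrient_vector(unlist(doc$upper_limits))
    },
    macro_band = band
  )
}

#' Published worked-example compositions
#'
#' The nutrient composition of two published cost-optimized Karnataka
#' rations, shipped as packaged data for validation and as format
#' documentation: a hot cooked meal for children aged 3-6 y and a
#' take-home ration for children aged 1-3 y. Each table carries the
#' guideline value, the nutrient content of the optimized solution, and
#' the percent-of-guideline figure as printed in the source tables
#' (`percent_printed`; some printed percentages were computed by the
#' original tool from unrounded internal values and do not reproduce
#' exactly from the rounded printed inputs).
#'
#' @param which `"hcm_3_6y"` or `"thr_1_3y"`.
#' @return Tibble with columns `nutrient`, `guideline`, `content`,
#'   `percent_printed`.
#' @export
#' @examples
#' worked_example("thr_1_3y")
worked_example <- function(which = c("hcm_3_6y", "thr_1_3y")) {
  which <- match.arg(which)
  if (which == "hcm_3_6y") {
    tibble::tribble(
      ~nutrient, ~guideline, ~content, ~percent_printed,
      "energy", 400.0, 400.1, 100.0,
      "protein", 15.0, 17.0, 114.0,
      "fat", 15.0, 14.0, 94.0,
      "calcium", 150.0, 110.8, 74.0,
      "dietary_fiber", 6.8, 5.1, 76.0,
      "folate", 40.0, 75.2, 189.0,
      "iron", 3.0, 3.7, 125.0,
      "magnesium", 34.7, 79.4, 229.0,
      "vitamin_b3", 2.7, 2.3, 87.0,
      "vitamin_b6", 0.3, 0.2, 78.0,
      "vitamin_b2", 0.4, 0.2, 53.0,
      "vitamin_b1", 0.3, 0.2, 69.0,
      "vitamin_a", 80.0, 128.0, 161.0,
      "vitamin_b12", 0.7, 0.5, 77.0,
      "vitamin_c", 9.0, 11.0, 122.0,
      "zinc", 1.5, 2.1, 140.0
    )
  } else {
    tibble::tribble(
      ~nutrient, ~guideline, ~content, ~percent_printed,
      "energy", 400.0, 400.0, 100.0,
      "protein", 15.0, 13.7, 91.3,
      "fat", 15.0, 13.5, 90.0,
      "calcium", 135.0, 134.1, 99.3,
      "dietary_fiber", 5.6, 10.2, 183.8,
      "folate", 35.0, 50.9, 145.4,
      "iron", 2.0, 3.4, 170.0,
      "magnesium", 24.3, 118.5, 487.1,
      "vitamin_a", 60.0, 75.8, 126.3,
      "vitamin_b1", 0.2, 0.4, 200.0,
      "vitamin_b12", 0.3, 0.0, 0.0,
      "vitamin_b2", 0.3, 0.3, 111.1,
      "vitamin_b3", 2.0, 1.9, 95.0,
      "vitamin_b6", 0.3, 0.2, 74.1,
      "vitamin_c", 8.0, 0.4, 5.0,
      "zinc", 1.0, 2.6, 260.0
    )
  }
}
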