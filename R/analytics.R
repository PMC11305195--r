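#' Percent of guideline met per nutrient
#'
#' For each tracked nutrient with a positive guideline target, computes
#' `100 * content / target`, rounded to one decimal (half away from
#' zero, matching how program adequacy tables are printed). Nutrients
#' with a zero target are emitted with `percent = NA` and
#' `defined = FALSE` rather than dropped.
#'
#' @param content Nutrient totals: a `ration_solution`, a named nutrient
#'   vector, or a single-row data frame with nutrient columns.
#' @param guidelines A [guideline_set()].
#' @return Tibble with columns `nutrient`, `unit`, `guideline`,
#'   `content`, `percent`, `defined`.
#' @export
#' @examples
#' percent_of_guideline(
#'   c(energy = 400, protein = 13.7),
#'   default_guidelines("child_1_3y")
#' )
percent_of_guideline <- function(content, guidelines) {
  v <- as_nutrient_vector(content)
  t <- guidelines$targets
  info <- nutrient_info()
  tibble::tibble(
    nutrient = info$nutrient,
    unit = info$unit,
    guideline = unname(t[info$nutrient]),
    content = unname(v[info$nutrient]),
    defined = unname(t[info$nutrient]) > 0,
    percent = ifelse(
      .data$defined,
      round_half_away(100 * .data$content / .data$guideline, 1),
      NA_real_
    )
  )[, c("nutrient", "unit", "guideline", "content", "percent", "defined")]
}

#' Colour-code nutrient adequacy
#'
#' Maps percent-of-guideline values to the traffic-light scheme used in
#' program reports. Hot-cooked-meal mode: green above 60%, orange from
#' 30% to 60%, red below 30%. Take-home-ration mode: green above 80%,
#' orange from 50% to 80%, red below 50%. Boundary values fall in the
#' orange band (the rules use strict "greater than" for green and
#' strict "less than" for red).
#'
#' @param percent Numeric vector of percent-of-guideline values (>= 0).
#' @param mode `"hcm"` or `"thr"`.
#' @return Character vector: `"green"`, `"orange"` or `"red"` (`NA` in,
#'   `NA` out).
#' @export
#' @examples
#' adequacy_color(c(53, 60, 60.0001), mode = "hcm")
adequacy_color <- function(percent, mode = c("hcm", "thr")) {
  mode <- match.arg(mode)
  hi <- if (mode == "hcm") 60 else 80
  lo <- if (mode == "hcm") 30 else 50
  dplyr::case_when(
    is.na(percent) ~ NA_character_,
    percent > hi ~ "green",
    percent < lo ~ "red",
    TRUE ~ "orange"
  )
}

#' Adequacy table with colours
#'
#' Convenience wrapper: [percent_of_guideline()] plus a `color` column
#' from [adequacy_color()].
#'
#' @inheritParams percent_of_guideline
#' @param mode Passed to [adequacy_color()].
#' @return Tibble: the percent table plus `color`.
#' @export
adequacy_table <- function(content, guidelines, mode = c("hcm", "thr")) {
  mode <- match.arg(mode)
  tab <- percent_of_guideline(content, guidelines)
  tab$color <- adequacy_color(tab$percent, mode)
  tab
}

#' Food-group allocation of an optimized ration
#'
#' The share of each food group in the total raw weight of the solution
#' (the doughnut-chart data). Shares sum to 100.
#'
#' @param solution A `ration_solution` with positive total weight.
#' @param db Unused; accepted for call-site symmetry (the solution
#'   carries its groups).
#' @return Tibble with columns `group`, `weight_g`, `share_pct`, in
#'   decreasing share order.
#' @export
food_group_allocation <- function(solution, db = NULL) {
  qt <- dplyr::filter(solution$quantities, .data$selected)
  total <- sum(qt$weight)
  if (!length(total) || total <= 0) {
    stop("solution has zero total weight", call. = FALSE)
  }
  qt |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(weight_g = sum(.data$weight), .groups = "drop") |>
    dplyr::mutate(share_pct = 100 * .data$weight_g / total) |>
    dplyr::arrange(dplyr::desc(.data$share_pct))
}

#' Nutrient-to-guideline ratios (radar-chart data)
#'
#' The unrounded ratio of each nutrient's content to its guideline
#' target; a ratio of 1 means the target is exactly met. Zero-target
#' nutrients are flagged rather than divided.
#'
#' @inheritParams percent_of_guideline
#' @return Tibble with columns `nutrient`, `ratio`, `defined`.
#' @export
nutrient_ratio_radar <- function(content, guidelines) {
  v <- as_nutrient_vector(content)
  t <- guidelines$targets
  tibble::tibble(
    nutrient = nutrient_names(),
    defined = unname(t[nutrient_names()]) > 0,
    ratio = ifelse(
      .data$defined,
      unname(v[nutrient_names()] / t[nutrient_names()]),
      NA_real_
    )
  )[, c("nutrient", "ratio", "defined")]
}

#' Per-group nutrient and cost contributions
#'
#' Decomposes a solution into food-group contributions: for every
#' nutrient, how much each group supplies (stacked-bar data, summing to
#' the solution total), and each group's share of total cost. A
#' zero-cost solution is reported with zero shares and a flag.
#'
#' @param solution A `ration_solution`.
#' @param db Unused; accepted for call-site symmetry.
#' @return List with `nutrients` (tibble nutrient/group/contribution/
#'   share_pct), `cost` (tibble group/cost/share_pct) and `zero_cost`
#'   (logical).
#' @export
contribution_breakdown <- function(solution, db = NULL) {
  qt <- dplyr::filter(solution$quantities, .data$selected)
  long <- qt |>
    dplyr::select("id", "group", dplyr::all_of(nutrient_names())) |>
    tidyr::pivot_longer(
      dplyr::all_of(nutrient_names()),
      names_to = "nutrient", values_to = "contribution"
    ) |>
    dplyr::group_by(.data$nutrient, .data$group) |>
    dplyr::summarise(contribution = sum(.data$contribution), .groups = "drop_last") |>
    dplyr::mutate(
      total = sum(.data$contribution),
      share_pct = ifelse(
        .data$total > 0, 100 * .data$contribution / .data$total, 0
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::select("nutrient", "group", "contribution", "share_pct")
  total_cost <- sum(qt$cost)
  cost <- qt |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(cost = sum(.data$cost), .groups = "drop") |>
    dplyr::mutate(share_pct = if (total_cost > 0) {
      100 * .data$cost / total_cost
    } else {
      0
    })
  list(nutrients = long, cost = cost, zero_cost = total_cost <= 0)
}

#' Chart-data bundle for a solution
#'
#' Emits the structured data series behind the standard report charts
#' (doughnut allocation, radar ratios, adequacy colours) as a plain
#' list, ready to serialize as JSON; rendering is a consumer concern.
#'
#' @inheritParams adequacy_table
#' @return List with elements `allocation`, `radar`, `adequacy`,
#'   `contributions`.
#' @export
chart_data <- function(solution, guidelines, mode = c("hcm", "thr")) {
  mode <- match.arg(mode)
  list(
    allocation = food_group_allocation(solution),
    radar = nutrient_ratio_radar(solution, guidelines),
    adequacy = adequacy_table(solution, guidelines, mode),
    contributions = contribution_breakdown(solution)
  )
}
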