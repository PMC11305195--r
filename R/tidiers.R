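#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a ration solution
#'
#' One row per item with its selection flag, amount, weight and cost —
#' the quantities table of the solution.
#'
#' @param x A `ration_solution`.
#' @param selected_only Drop unselected items?
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ration_solution
#' @export
tidy.ration_solution <- function(x, selected_only = FALSE, ...) {
  out <- x$quantities[, c(
    "id", "group", "kind", "selected", "amount", "weight", "cost"
  )]
  if (selected_only) out <- dplyr::filter(out, .data$selected)
  out
}

#' Glance at a ration solution
#'
#' @param x A `ration_solution`.
#' @param ... Unused.
#' @return A one-row tibble: status, total cost, budget, macro totals,
#'   number of selected items.
#' @method glance ration_solution
#' @export
glance.ration_solution <- function(x, ...) {
  tibble::tibble(
    status = x$status,
    total_cost = x$total_cost,
    budget = x$budget %||% NA_real_,
    energy = x$nutrient_totals[["energy"]],
    protein = x$nutrient_totals[["protein"]],
    fat = x$nutrient_totals[["fat"]],
    n_selected = sum(x$quantities$selected)
  )
}

#' @method tidy weekly_menu
#' @export
tidy.weekly_menu <- function(x, ...) x$days

#' @method glance weekly_menu
#' @export
glance.weekly_menu <- function(x, ...) {
  tibble::tibble(
    n_days = nrow(x$days),
    mean_cost = x$mean_cost,
    sd_cost = x$sd_cost,
    mean_energy = mean(x$days$energy)
  )
}

#' Plot a ration solution
#'
#' Standard report charts: `"allocation"` (doughnut of food-group weight
#' shares), `"radar"` (nutrient-to-guideline ratios on polar axes;
#' requires `guidelines`), `"adequacy"` (colour-coded percent of
#' guideline; requires `guidelines`).
#'
#' @param object A `ration_solution`.
#' @param type Chart type.
#' @param guidelines A [guideline_set()] (for radar/adequacy).
#' @param mode Adequacy colour mode, `"hcm"` or `"thr"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ration_solution
#' @export
autoplot.ration_solution <- function(object,
                                     type = c("allocation", "radar", "adequacy"),
                                     guidelines = NULL, mode = "hcm", ...) {
  type <- match.arg(type)
  if (type == "allocation") {
    alloc <- food_group_allocation(object)
    return(
      ggplot2::ggplot(alloc, ggplot2::aes(
        x = 2, y = .data$share_pct, fill = .data$group
      )) +
        ggplot2::geom_col(width = 1, colour = "white") +
        ggplot2::coord_polar(theta = "y") +
        ggplot2::xlim(0.5, 2.5) +
        ggplot2::theme_void() +
        ggplot2::labs(
          title = "Food-group allocation (% of total weight)",
          fill = "Food group"
        )
    )
  }
  if (is.null(guidelines)) {
    stop("radar/adequacy plots need a guideline_set", call. = FALSE)
  }
  if (type == "radar") {
    rad <- dplyr::filter(nutrient_ratio_radar(object, guidelines), .data$defined)
    return(
      ggplot2::ggplot(rad, ggplot2::aes(
        x = .data$nutrient, y = .data$ratio, group = 1
      )) +
        ggplot2::geom_polygon(fill = "steelblue", alpha = 0.3) +
        ggplot2::geom_line(colour = "steelblue") +
        ggplot2::geom_hline(yintercept = 1, linetype = 2) +
        ggplot2::coord_polar() +
        ggplot2::labs(
          title = "Nutrient-to-guideline ratios", x = NULL, y = "ratio"
        )
    )
  }
  tab <- dplyr::filter(
    adequacy_table(object, guidelines, mode = mode), .data$defined
  )
  ggplot2::ggplot(tab, ggplot2::aes(
    x = stats::reorder(.data$nutrient, .data$percent),
    y = .data$percent, fill = .data$color
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 100, linetype = 2) +
    ggplot2::scale_fill_identity() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      title = "Percent of guideline met", x = NULL, y = "% of guideline"
    )
}

#' Plot a weekly menu's macro series
#'
#' Daily energy plus the protein:energy and fat:energy percentages
#' across the week.
#'
#' @param object A `weekly_menu`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot weekly_menu
#' @export
autoplot.weekly_menu <- function(object, ...) {
  d <- object$days |>
    dplyr::mutate(day = seq_len(dplyr::n())) |>
    tidyr::pivot_longer(
      c("protein_energy_pct", "fat_energy_pct"),
      names_to = "series", values_to = "pct"
    )
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$day, y = .data$pct, colour = .data$series
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      title = "Weekly macronutrient series (% of energy)",
      x = "day", y = "% of energy", colour = NULL
    )
}
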