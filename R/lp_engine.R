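#' Build a decision-variable specification
#'
#' One decision per optimizable item: a raw food (quantity in grams per
#' day) or a recipe (quantity in serving multipliers). Each decision
#' carries a semi-continuous window: the amount is either 0 (item not
#' selected) or within `[min, max]`. Selection is modelled with a binary
#' variable linked to the quantity, which is what lets the model count
#' selected items per food group and force compulsory items in.
#'
#' @param id Unique item identifier.
#' @param kind `"continuous_grams"` (raw foods) or
#'   `"semi_continuous_servings"` (recipes).
#' @param min,max Selection window in the item's unit (g or servings);
#'   `min <= max`, `min >= 0`.
#' @param unit_cost Cost per unit (currency per g or per serving).
#' @param unit_nutrients Named nutrient vector per unit.
#' @param unit_weight Grams of food per unit (1 for raw foods, the
#'   serving weight for recipes).
#' @param group Grouping label: a food group for raw foods, a recipe
#'   category for recipes.
#' @param required Must this item be selected (compulsory)?
#' @param premix Does this item enter premix-mode group windows?
#' @return A one-row tibble; rows from several calls bind into a
#'   decision table.
#' @export
decision_spec <- function(id, kind = c("continuous_grams", "semi_continuous_servings"),
                          min, max, unit_cost, unit_nutrients,
                          unit_weight = 1, group = "ungrouped",
                          required = FALSE, premix = FALSE) {
  kind <- match.arg(kind)
  nut <- as_nutrient_vector(unit_nutrients)
  tibble::tibble(
    id = id, kind = kind, min = min, max = max,
    required = required, premix = premix,
    unit_cost = unit_cost, unit_weight = unit_weight, group = group,
    !!!as.list(nut)
  )
}

validate_decisions <- function(decisions) {
  decisions <- tibble::as_tibble(decisions)
  req <- c(
    "id", "kind", "min", "max", "required", "premix",
    "unit_cost", "unit_weight", "group", nutrient_names()
  )
  miss <- setdiff(req, names(decisions))
  if (length(miss)) {
    stop("decision table lacks column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(decisions) < 1) stop("need at least one decision", call. = FALSE)
  if (anyDuplicated(decisions$id)) {
    stop("duplicate decision id(s)", call. = FALSE)
  }
  if (any(decisions$min > decisions$max) || any(decisions$min < 0)) {
    stop("decision bounds must satisfy 0 <= min <= max", call. = FALSE)
  }
  if (any(decisions$unit_cost < 0)) {
    stop("unit_cost must be >= 0", call. = FALSE)
  }
  decisions
}

#' Assemble a constraint set
#'
#' The program rules an optimized ration must satisfy, expressed over a
#' decision table. All parts are optional; omitted parts are
#' unconstrained.
#'
#' @param nutrient_lower,nutrient_upper Named numeric vectors of lower /
#'   upper bounds on total nutrient content (upper bounds are the
#'   tolerable upper limits).
#' @param group_min_count,group_max_count Named numeric vectors: minimum
#'   / maximum number of *selected* items per group (diet-diversity
#'   rules, recipe category counts).
#' @param group_windows Data frame with columns `group`, `premix`
#'   (logical; `NA` = both modes), `min_g`, `max_g`: bounds on the total
#'   food weight drawn from a group.
#' @param ratio Optional list `list(num_group=, den_group=, ratio=,
#'   tol=)` constraining total weight of `num_group` to
#'   `ratio x` weight of `den_group` within relative tolerance `tol`
#'   (e.g. the 2:1 cereal-to-pulse rule).
#' @param force_ids Item ids that must be selected.
#' @param budget Daily budget. By default a *reporting* threshold: a
#'   costlier optimum is returned with status `over_budget`. With
#'   `hard_budget = TRUE` it becomes a hard cap.
#' @param hard_budget Enforce the budget as a constraint?
#' @return A `constraint_set` object.
#' @export
constraint_set <- function(nutrient_lower = NULL, nutrient_upper = NULL,
                           group_min_count = NULL, group_max_count = NULL,
                           group_windows = NULL, ratio = NULL,
                           force_ids = character(), budget = NULL,
                           hard_budget = FALSE) {
  if (!is.null(ratio)) {
    stopifnot(
      is.list(ratio),
      all(c("num_group", "den_group", "ratio") %in% names(ratio))
    )
    ratio$tol <- ratio$tol %||% 0
    if (ratio$ratio <= 0 || ratio$tol < 0) {
      stop("ratio must be > 0 and tol >= 0", call. = FALSE)
    }
  }
  if (!is.null(group_windows)) {
    group_windows <- tibble::as_tibble(group_windows)
    stopifnot(all(c("group", "min_g", "max_g") %in% names(group_windows)))
    if (!"premix" %in% names(group_windows)) group_windows$premix <- NA
    if (any(group_windows$min_g > group_windows$max_g)) {
      stop("group window min_g > max_g", call. = FALSE)
    }
  }
  structure(
    list(
      nutrient_lower = nutrient_lower, nutrient_upper = nutrient_upper,
      group_min_count = group_min_count, group_max_count = group_max_count,
      group_windows = group_windows, ratio = ratio,
      force_ids = force_ids, budget = budget, hard_budget = hard_budget
    ),
    class = "constraint_set"
  )
}

#' Solver configuration
#'
#' @param mip_gap Relative optimality gap for branch-and-bound pruning.
#' @param feas_tol Feasibility tolerance.
#' @param node_limit Maximum branch-and-bound nodes before giving up.
#' @param hint Compute a relaxation hint when the model is infeasible?
#' @return A list of solver settings.
#' @export
lp_config <- function(mip_gap = 1e-6, feas_tol = 1e-7,
                      node_limit = 50000L, hint = TRUE) {
  list(
    mip_gap = mip_gap, feas_tol = feas_tol,
    node_limit = as.integer(node_limit), hint = hint
  )
}

# ---- model assembly ---------------------------------------------------

# Variables are x = (q_1..q_n, y_1..y_n): quantities and binary
# selection indicators, linked by min_i*y_i <= q_i <= max_i*y_i.
# Rows are built as (name, family, dir, a, rhs) over the 2n variables.
build_lp_rows <- function(decisions, constraints, extra_cuts = list()) {
  n <- nrow(decisions)
  nm <- decisions$id
  nut_mat <- as.matrix(decisions[, nutrient_names()]) # n x 16, per unit
  w <- decisions$unit_weight
  cost <- decisions$unit_cost

  rows <- list()
  add <- function(name, family, dir, qcoef, ycoef, rhs) {
    rows[[length(rows) + 1]] <<- list(
      name = name, family = family, dir = dir,
      a = c(qcoef, ycoef), rhs = rhs
    )
  }
  zq <- numeric(n)
  zy <- numeric(n)

  for (i in seq_len(n)) {
    qc <- zq
    yc <- zy
    qc[i] <- 1
    yc[i] <- -decisions$max[i]
    add(
      paste0("item_window_max_", nm[i]), "item_windows", "le", qc, yc, 0
    )
    if (decisions$min[i] > 0) {
      qc <- zq
      yc <- zy
      qc[i] <- 1
      yc[i] <- -decisions$min[i]
      add(
        paste0("item_window_min_", nm[i]), "item_windows", "ge", qc, yc, 0
      )
    }
    yc <- zy
    yc[i] <- 1
    add(paste0("select_ub_", nm[i]), "binary", "le", zq, yc, 1)
  }

  for (nut in names(constraints$nutrient_lower)) {
    b <- constraints$nutrient_lower[[nut]]
    if (is.finite(b) && b > 0) {
      add(paste0(nut, "_lower"), "nutrient_lower", "ge", nut_mat[, nut], zy, b)
    }
  }
  for (nut in names(constraints$nutrient_upper)) {
    b <- constraints$nutrient_upper[[nut]]
    if (is.finite(b)) {
      add(paste0(nut, "_upper"), "nutrient_upper", "le", nut_mat[, nut], zy, b)
    }
  }
  for (g in names(constraints$group_min_count)) {
    k <- constraints$group_min_count[[g]]
    if (k > 0) {
      # with fewer candidates than k the row is structurally infeasible,
      # which is the correct outcome
      yc <- as.numeric(decisions$group == g)
      add(paste0("group_count_", g), "group_counts", "ge", zq, yc, k)
    }
  }
  for (g in names(constraints$group_max_count)) {
    k <- constraints$group_max_count[[g]]
    yc <- as.numeric(decisions$group == g)
    add(paste0("group_count_max_", g), "group_counts", "le", zq, yc, k)
  }
  gw <- constraints$group_windows
  if (!is.null(gw)) {
    for (j in seq_len(nrow(gw))) {
      in_g <- decisions$group == gw$group[j]
      if (!is.na(gw$premix[j])) in_g <- in_g & (decisions$premix == gw$premix[j])
      qc <- ifelse(in_g, w, 0)
      tag <- if (is.na(gw$premix[j])) {
        gw$group[j]
      } else if (gw$premix[j]) {
        paste0(gw$group[j], "_premix")
      } else {
        paste0(gw$group[j], "_whole")
      }
      if (gw$min_g[j] > 0) {
        add(
          paste0("group_window_min_", tag), "group_windows", "ge",
          qc, zy, gw$min_g[j]
        )
      }
      if (is.finite(gw$max_g[j])) {
        add(
          paste0("group_window_max_", tag), "group_windows", "le",
          qc, zy, gw$max_g[j]
        )
      }
    }
  }
  rr <- constraints$ratio
  if (!is.null(rr)) {
    num <- ifelse(decisions$group == rr$num_group, w, 0)
    den <- ifelse(decisions$group == rr$den_group, w, 0)
    if (rr$tol > 0) {
      add(
        "ratio_high", "ratio", "le",
        num - rr$ratio * (1 + rr$tol) * den, zy, 0
      )
      add(
        "ratio_low", "ratio", "ge",
        num - rr$ratio * (1 - rr$tol) * den, zy, 0
      )
    } else {
      add("ratio_eq", "ratio", "eq", num - rr$ratio * den, zy, 0)
    }
  }
  forced <- constraints$force_ids
  for (fid in forced) {
    if (is.na(match(fid, nm))) {
      stop("force_ids references unknown id: ", fid, call. = FALSE)
    }
  }
  forced <- union(forced, nm[decisions$required])
  for (fid in forced) {
    i <- match(fid, nm)
    yc <- zy
    yc[i] <- 1
    add(paste0("force_", fid), "forcing", "ge", zq, yc, 1)
  }
  if (!is.null(constraints$budget) && constraints$hard_budget) {
    add("budget", "budget", "le", cost, zy, constraints$budget)
  }
  for (j in seq_along(extra_cuts)) {
    cut <- extra_cuts[[j]]
    add(paste0("cut_", j), "cuts", cut$dir, zq, cut$ycoef, cut$rhs)
  }

  A <- do.call(rbind, lapply(rows, `[[`, "a"))
  list(
    A = A,
    dir = vapply(rows, `[[`, character(1), "dir"),
    rhs = vapply(rows, `[[`, numeric(1), "rhs"),
    name = vapply(rows, `[[`, character(1), "name"),
    family = vapply(rows, `[[`, character(1), "family"),
    obj = c(cost, zy)
  )
}

# ---- dense two-phase simplex -------------------------------------------
#
# A self-contained primal simplex over the full tableau, written for the
# small dense models this package builds (tens of rows and columns).
# Phase 1 minimizes the sum of artificial variables; Bland's rule is
# switched on after a burn-in of Dantzig steps, so heavily degenerate
# bases (every linking row has a zero right-hand side) cannot cycle.

simplex_core <- function(Tm, b, cost, basis, eps = 1e-9, max_iter = 20000L) {
  m <- nrow(Tm)
  bland_after <- 50L + 10L * (m + ncol(Tm))
  for (it in seq_len(max_iter)) {
    red <- cost - as.numeric(crossprod(cost[basis], Tm))
    red[basis] <- 0
    cand <- which(red < -eps)
    if (!length(cand)) {
      return(list(status = "optimal", Tm = Tm, b = b, basis = basis))
    }
    j <- if (it > bland_after) cand[1] else cand[which.min(red[cand])]
    d <- Tm[, j]
    pos <- which(d > eps)
    if (!length(pos)) {
      return(list(status = "unbounded"))
    }
    ratios <- b[pos] / d[pos]
    rmin <- min(ratios)
    ties <- pos[ratios <= rmin + eps]
    r <- ties[which.min(basis[ties])] # Bland-style tie break
    piv <- Tm[r, j]
    Tm[r, ] <- Tm[r, ] / piv
    b[r] <- b[r] / piv
    others <- setdiff(seq_len(m), r)
    fac <- Tm[others, j]
    Tm[others, ] <- Tm[others, , drop = FALSE] - outer(fac, Tm[r, ])
    b[others] <- b[others] - fac * b[r]
    b[b < 0 & b > -1e-11] <- 0
    basis[r] <- j
  }
  list(status = "maxiter")
}

# Solve min obj'x s.t. A x (dir) rhs, x >= 0. dir in {"le","ge","eq"}.
lp_solve_raw <- function(obj, A, dir, rhs, eps = 1e-9) {
  neg <- rhs < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    rhs[neg] <- -rhs[neg]
    dir[neg] <- c(le = "ge", ge = "le", eq = "eq")[dir[neg]]
  }
  m <- nrow(A)
  n <- ncol(A)
  ineq <- which(dir != "eq")
  S <- matrix(0, m, length(ineq))
  if (length(ineq)) {
    S[cbind(ineq, seq_along(ineq))] <- ifelse(dir[ineq] == "le", 1, -1)
  }
  # rows whose slack (+1, rhs >= 0) can start in the basis need no
  # artificial; ge/eq rows get one artificial each
  art_rows <- which(dir != "le")
  Art <- matrix(0, m, length(art_rows))
  if (length(art_rows)) Art[cbind(art_rows, seq_along(art_rows))] <- 1
  Tm <- cbind(A, S, Art)
  ntot <- ncol(Tm)
  n_real <- n + length(ineq)
  basis <- integer(m)
  slack_col <- integer(m)
  slack_col[ineq] <- n + seq_along(ineq)
  basis[dir == "le"] <- slack_col[dir == "le"]
  basis[art_rows] <- n_real + seq_along(art_rows)

  b <- rhs
  if (length(art_rows)) {
    c1 <- c(rep(0, n_real), rep(1, length(art_rows)))
    ph1 <- simplex_core(Tm, b, c1, basis, eps = eps)
    if (ph1$status != "optimal") {
      return(list(status = if (ph1$status == "maxiter") "maxiter" else "infeasible"))
    }
    val1 <- sum(ph1$b[ph1$basis > n_real])
    if (val1 > 1e-7) {
      return(list(status = "infeasible"))
    }
    Tm <- ph1$Tm
    b <- ph1$b
    basis <- ph1$basis
    # pivot any artificial still basic (at zero) out on a real column
    for (r in which(basis > n_real)) {
      row <- Tm[r, seq_len(n_real)]
      j <- which(abs(row) > 1e-8)
      if (length(j)) {
        j <- j[1]
        piv <- Tm[r, j]
        Tm[r, ] <- Tm[r, ] / piv
        b[r] <- b[r] / piv
        others <- setdiff(seq_len(m), r)
        fac <- Tm[others, j]
        Tm[others, ] <- Tm[others, , drop = FALSE] - outer(fac, Tm[r, ])
        b[others] <- b[others] - fac * b[r]
        basis[r] <- j
      }
    }
    keep <- basis <= n_real
    if (!all(keep)) { # redundant rows
      Tm <- Tm[keep, , drop = FALSE]
      b <- b[keep]
      basis <- basis[keep]
    }
    Tm <- Tm[, seq_len(n_real), drop = FALSE]
  }
  c2 <- c(obj, rep(0, length(ineq)))
  ph2 <- simplex_core(Tm, b, c2, basis, eps = eps)
  if (ph2$status != "optimal") {
    return(list(status = ph2$status))
  }
  x <- numeric(n_real)
  x[ph2$basis] <- ph2$b
  list(
    status = "optimal",
    x = x[seq_len(n)],
    value = sum(obj * x[seq_len(n)])
  )
}

# ---- branch and bound -------------------------------------------------

#' Solve a least-cost ration model to proven optimality
#'
#' Minimizes total cost `sum(q_i * c_i)` over the decision quantities
#' subject to the constraint set, with binary selection variables
#' handling semi-continuous windows, group inclusion counts and
#' compulsory items. The mixed-integer program is solved exactly by
#' branch-and-bound on the selection variables over simplex LP
#' relaxations; the algorithm is deterministic for fixed input ordering.
#'
#' @param decisions Decision table (rows from [decision_spec()]).
#' @param constraints A [constraint_set()].
#' @param config Solver settings from [lp_config()].
#' @return A `ration_solution`: quantities, selection flags, total cost,
#'   nutrient totals, status (`optimal`, `over_budget` when a soft
#'   budget is exceeded, or `infeasible` with a relaxation hint), and
#'   the names of constraints binding at the optimum.
#' @export
#' @examples
#' d <- decision_spec("grain", "continuous_grams",
#'   min = 0, max = 200,
#'   unit_cost = 0.01, unit_nutrients = c(energy = 4), group = "cereals_and_millets"
#' )
#' s <- solve_min_cost(d, constraint_set(nutrient_lower = c(energy = 400)))
#' s$total_cost
solve_min_cost <- function(decisions, constraints, config = lp_config()) {
  decisions <- validate_decisions(decisions)
  res <- solve_milp(decisions, constraints, config)
  if (res$status == "infeasible") {
    hint <- if (isTRUE(config$hint)) {
      infeasibility_hint(decisions, constraints, config)
    }
    return(new_ration_solution(
      decisions, numeric(nrow(decisions)), constraints,
      status = "infeasible", infeasible_hint = hint
    ))
  }
  new_ration_solution(decisions, res$q, constraints, status = "optimal")
}

# Core MILP solve shared by solve_min_cost / enumerate_k_best / hints.
solve_milp <- function(decisions, constraints, config, extra_cuts = list()) {
  model <- build_lp_rows(decisions, constraints, extra_cuts)
  n <- nrow(decisions)
  int_tol <- 1e-6

  append_fix_rows <- function(fix) {
    idx0 <- which(fix == 0L)
    idx1 <- which(fix == 1L)
    extraA <- NULL
    extradir <- character(0)
    extrarhs <- numeric(0)
    if (length(idx0)) {
      B <- matrix(0, length(idx0), 2 * n)
      B[cbind(seq_along(idx0), n + idx0)] <- 1
      extraA <- rbind(extraA, B)
      extradir <- c(extradir, rep("le", length(idx0)))
      extrarhs <- c(extrarhs, rep(0, length(idx0)))
    }
    if (length(idx1)) {
      B <- matrix(0, length(idx1), 2 * n)
      B[cbind(seq_along(idx1), n + idx1)] <- 1
      extraA <- rbind(extraA, B)
      extradir <- c(extradir, rep("ge", length(idx1)))
      extrarhs <- c(extrarhs, rep(1, length(idx1)))
    }
    list(
      A = rbind(model$A, extraA),
      dir = c(model$dir, extradir),
      rhs = c(model$rhs, extrarhs)
    )
  }

  incumbent <- NULL
  inc_val <- Inf
  nodes <- 0L
  stack <- list(rep(NA_integer_, n))

  while (length(stack)) {
    fix <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    if (nodes > config$node_limit) {
      stop("branch-and-bound node limit reached (", config$node_limit,
        " nodes); the instance is too hard for the configured limit",
        call. = FALSE
      )
    }
    sys <- append_fix_rows(fix)
    lp <- lp_solve_raw(model$obj, sys$A, sys$dir, sys$rhs)
    if (lp$status == "maxiter") {
      stop("LP relaxation hit its iteration limit", call. = FALSE)
    }
    if (lp$status == "unbounded") {
      stop("LP relaxation is unbounded; check decision bounds", call. = FALSE)
    }
    if (lp$status == "infeasible") next
    if (is.finite(inc_val) &&
      lp$value >= inc_val - max(1e-9, config$mip_gap * abs(inc_val))) {
      next
    }
    y <- lp$x[(n + 1):(2 * n)]
    frac <- pmin(y - floor(y + int_tol), ceiling(y - int_tol) - y)
    frac[!is.na(fix)] <- 0
    if (max(frac) <= int_tol) {
      q <- lp$x[seq_len(n)]
      q[q < config$feas_tol] <- 0
      if (lp$value < inc_val) {
        inc_val <- lp$value
        incumbent <- q
      }
    } else {
      b <- which.max(frac)
      up <- fix
      up[b] <- 1L
      dn <- fix
      dn[b] <- 0L
      # explore the branch the relaxation leans toward first
      if (y[b] >= 0.5) {
        stack <- c(stack, list(dn), list(up))
      } else {
        stack <- c(stack, list(up), list(dn))
      }
    }
  }
  if (is.null(incumbent)) {
    list(status = "infeasible")
  } else {
    list(status = "optimal", q = incumbent, value = inc_val, nodes = nodes)
  }
}

# Which constraint families, relaxed one at a time, restore feasibility?
infeasibility_hint <- function(decisions, constraints, config) {
  relaxations <- list(
    nutrient_lower = function(cs) {
      cs$nutrient_lower <- NULL
      cs
    },
    nutrient_upper = function(cs) {
      cs$nutrient_upper <- NULL
      cs
    },
    group_counts = function(cs) {
      cs$group_min_count <- NULL
      cs$group_max_count <- NULL
      cs
    },
    group_windows = function(cs) {
      cs$group_windows <- NULL
      cs
    },
    ratio = function(cs) {
      cs$ratio <- NULL
      cs
    },
    forcing = function(cs) {
      cs$force_ids <- character()
      cs
    },
    budget = function(cs) {
      cs$hard_budget <- FALSE
      cs
    }
  )
  active <- c(
    nutrient_lower = !is.null(constraints$nutrient_lower),
    nutrient_upper = !is.null(constraints$nutrient_upper),
    group_counts = !is.null(constraints$group_min_count) ||
      !is.null(constraints$group_max_count),
    group_windows = !is.null(constraints$group_windows),
    ratio = !is.null(constraints$ratio),
    forcing = length(constraints$force_ids) > 0,
    budget = !is.null(constraints$budget) && constraints$hard_budget
  )
  cfg <- config
  cfg$hint <- FALSE
  cfg$node_limit <- min(config$node_limit, 5000L)
  hits <- character(0)
  for (fam in names(relaxations)[active]) {
    relaxed <- relaxations[[fam]](constraints)
    ok <- tryCatch(
      solve_milp(decisions, relaxed, cfg)$status == "optimal",
      error = function(e) FALSE
    )
    if (ok) hits <- c(hits, fam)
  }
  hits
}

#' Enumerate the k least expensive distinct rations
#'
#' Returns up to `k` solutions in nondecreasing cost order, each using a
#' different *support* (set of selected items) from all previous ones:
#' after each solve, a no-good cut on the selection variables excludes
#' the support just found, so alternatives differ in which items are
#' used, not merely in quantities. This is how "next least expensive"
#' options are produced when the cheapest basket exceeds the budget.
#'
#' @inheritParams solve_min_cost
#' @param k Maximum number of solutions (>= 1).
#' @return List of `ration_solution`s (possibly shorter than `k` when
#'   supports are exhausted); empty with attribute `status =
#'   "infeasible"` when the base model is infeasible.
#' @export
enumerate_k_best <- function(decisions, constraints, k, config = lp_config()) {
  stopifnot(k >= 1)
  decisions <- validate_decisions(decisions)
  n <- nrow(decisions)
  cuts <- list()
  out <- list()
  for (j in seq_len(k)) {
    cfg <- config
    cfg$hint <- FALSE
    res <- solve_milp(decisions, constraints, cfg, extra_cuts = cuts)
    if (res$status != "optimal") break
    sol <- new_ration_solution(decisions, res$q, constraints, status = "optimal")
    out[[length(out) + 1]] <- sol
    sel <- sol$quantities$selected
    if (!any(sel)) {
      cuts[[length(cuts) + 1]] <- list(
        dir = "ge", ycoef = rep(1, n), rhs = 1
      )
    } else {
      cuts[[length(cuts) + 1]] <- list(
        dir = "le", ycoef = ifelse(sel, 1, -1), rhs = sum(sel) - 1
      )
    }
  }
  if (!length(out)) attr(out, "status") <- "infeasible"
  out
}

# ---- solution object --------------------------------------------------

new_ration_solution <- function(decisions, q, constraints, status,
                                infeasible_hint = NULL) {
  n <- nrow(decisions)
  selected <- q > 1e-9
  nut_mat <- as.matrix(decisions[, nutrient_names()])
  contrib <- nut_mat * q
  totals <- colSums(contrib)
  quantities <- tibble::tibble(
    id = decisions$id, group = decisions$group, kind = decisions$kind,
    premix = decisions$premix, selected = selected, amount = q,
    unit_weight = decisions$unit_weight,
    weight = q * decisions$unit_weight,
    unit_cost = decisions$unit_cost, cost = q * decisions$unit_cost
  )
  quantities <- dplyr::bind_cols(quantities, tibble::as_tibble(contrib))
  total_cost <- sum(quantities$cost)
  budget <- constraints$budget
  if (status == "optimal" && !is.null(budget) && !constraints$hard_budget &&
    total_cost > budget + 1e-9) {
    status <- "over_budget"
  }
  binding <- character(0)
  if (status != "infeasible") {
    model <- build_lp_rows(decisions, constraints)
    x <- c(q, as.numeric(selected))
    lhs <- as.numeric(model$A %*% x)
    keep <- !model$family %in% c("binary", "cuts")
    tight <- abs(lhs - model$rhs) <= 1e-6 * pmax(1, abs(model$rhs))
    binding <- model$name[keep & tight]
  }
  structure(
    list(
      quantities = quantities,
      total_cost = total_cost,
      nutrient_totals = stats::setNames(totals, nutrient_names()),
      status = status,
      binding_constraints = binding,
      infeasible_hint = infeasible_hint,
      budget = budget
    ),
    class = "ration_solution"
  )
}

#' @export
print.ration_solution <- function(x, ...) {
  cat("<ration_solution> status:", x$status, "\n")
  if (x$status == "infeasible") {
    if (length(x$infeasible_hint)) {
      cat(
        " relaxing any one of these constraint families restores",
        "feasibility:", paste(x$infeasible_hint, collapse = ", "), "\n"
      )
    }
    return(invisible(x))
  }
  cat(" total cost:", format(x$total_cost, digits = 6), "\n")
  sel <- dplyr::filter(x$quantities, .data$selected)
  print(sel[, c("id", "group", "amount", "weight", "cost")])
  invisible(x)
}

#' Brute-force grid oracle
#'
#' Exhaustively enumerates every combination of quantities on a regular
#' grid (each item at 0 or at `min, min + step, ..., max`) and returns
#' the cheapest grid-feasible combination. Exponential in the number of
#' items, so it refuses instances beyond `1e7` combinations; it exists
#' as an independent verification oracle for the branch-and-bound
#' solver, not as a production path.
#'
#' @inheritParams solve_min_cost
#' @param grid_step Grid resolution in the item's unit.
#' @return A `ration_solution` (status `optimal` or `infeasible`).
#' @export
brute_force_oracle <- function(decisions, constraints, grid_step = 1) {
  decisions <- validate_decisions(decisions)
  n <- nrow(decisions)
  if (n > 6) stop("oracle limited to <= 6 decisions", call. = FALSE)
  grids <- lapply(seq_len(n), function(i) {
    v <- seq(decisions$min[i], decisions$max[i], by = grid_step)
    if (decisions$max[i] - v[length(v)] > 1e-9) v <- c(v, decisions$max[i])
    if (!decisions$required[i]) v <- c(0, v)
    unique(v)
  })
  sizes <- lengths(grids)
  total <- prod(sizes)
  if (total > 1e7) {
    stop(
      "oracle instance too large: ", format(total, big.mark = ","),
      " grid combinations exceed the 1e7 cap",
      call. = FALSE
    )
  }
  costs <- decisions$unit_cost
  best_cost <- Inf
  best_q <- NULL
  chunk <- 200000L
  base <- c(1, cumprod(sizes))[seq_len(n)]
  done <- 0
  while (done < total) {
    m <- min(chunk, total - done)
    idx <- done + seq_len(m) - 1
    Q <- matrix(0, m, n)
    for (j in seq_len(n)) {
      Q[, j] <- grids[[j]][(idx %/% base[j]) %% sizes[j] + 1]
    }
    feas <- feasible_matrix(Q, decisions, constraints)
    if (any(feas)) {
      cc <- as.numeric(Q[feas, , drop = FALSE] %*% costs)
      i <- which.min(cc)
      if (cc[i] < best_cost - 1e-12) {
        best_cost <- cc[i]
        best_q <- Q[feas, , drop = FALSE][i, ]
      }
    }
    done <- done + m
  }
  if (is.null(best_q)) {
    new_ration_solution(decisions, numeric(n), constraints,
      status = "infeasible",
      infeasible_hint = character(0)
    )
  } else {
    new_ration_solution(decisions, best_q, constraints, status = "optimal")
  }
}

# Vectorized semantic feasibility of quantity rows (used by the oracle;
# the single-row case backs the post-hoc checker).
feasible_matrix <- function(Q, decisions, constraints, tol = 1e-9) {
  n <- nrow(decisions)
  m <- nrow(Q)
  ok <- rep(TRUE, m)
  sel <- Q > 1e-9

  for (i in seq_len(n)) {
    ok <- ok & (!sel[, i] |
      (Q[, i] >= decisions$min[i] - tol & Q[, i] <= decisions$max[i] + tol))
    if (decisions$required[i]) ok <- ok & sel[, i]
  }
  nl <- constraints$nutrient_lower
  nu <- constraints$nutrient_upper
  if (length(nl) || length(nu)) {
    nut <- intersect(unique(c(names(nl), names(nu))), nutrient_names())
    totals <- Q %*% as.matrix(decisions[, nut, drop = FALSE])
    for (j in seq_along(nut)) {
      lo <- nl[[nut[j]]]
      hi <- nu[[nut[j]]]
      if (!is.null(lo) && is.finite(lo) && lo > 0) {
        ok <- ok & totals[, j] >= lo - tol * max(1, lo)
      }
      if (!is.null(hi) && is.finite(hi)) {
        ok <- ok & totals[, j] <= hi + tol * max(1, hi)
      }
    }
  }
  for (g in names(constraints$group_min_count)) {
    k <- constraints$group_min_count[[g]]
    if (k > 0) {
      cnt <- rowSums(sel[, decisions$group == g, drop = FALSE])
      ok <- ok & cnt >= k
    }
  }
  for (g in names(constraints$group_max_count)) {
    cnt <- rowSums(sel[, decisions$group == g, drop = FALSE])
    ok <- ok & cnt <= constraints$group_max_count[[g]]
  }
  gw <- constraints$group_windows
  if (!is.null(gw)) {
    Wt <- sweep(Q, 2, decisions$unit_weight, `*`)
    for (j in seq_len(nrow(gw))) {
      in_g <- decisions$group == gw$group[j]
      if (!is.na(gw$premix[j])) in_g <- in_g & (decisions$premix == gw$premix[j])
      tot <- rowSums(Wt[, in_g, drop = FALSE])
      ok <- ok & tot >= gw$min_g[j] - tol * max(1, gw$min_g[j])
      if (is.finite(gw$max_g[j])) {
        ok <- ok & tot <= gw$max_g[j] + tol * max(1, gw$max_g[j])
      }
    }
  }
  rr <- constraints$ratio
  if (!is.null(rr)) {
    Wt <- sweep(Q, 2, decisions$unit_weight, `*`)
    num <- rowSums(Wt[, decisions$group == rr$num_group, drop = FALSE])
    den <- rowSums(Wt[, decisions$group == rr$den_group, drop = FALSE])
    slack <- rr$tol * rr$ratio * den + tol * pmax(1, rr$ratio * den)
    ok <- ok & abs(num - rr$ratio * den) <= slack
  }
  for (fid in constraints$force_ids) {
    i <- match(fid, decisions$id)
    ok <- ok & sel[, i]
  }
  if (!is.null(constraints$budget) && constraints$hard_budget) {
    cc <- as.numeric(Q %*% decisions$unit_cost)
    ok <- ok & cc <= constraints$budget + tol * max(1, constraints$budget)
  }
  ok
}

#' Post-hoc constraint checker
#'
#' Re-evaluates every rule of a constraint set against a solution's raw
#' quantities, independently of the solver's own algebra, and reports
#' each violation beyond the relative tolerance. An empty result means
#' the solution verifiably satisfies the stated model.
#'
#' @param solution A `ration_solution`.
#' @param decisions The decision table the solution was computed from.
#' @param constraints The [constraint_set()] to verify against.
#' @param tol Relative slack allowed before a row counts as violated.
#' @return Tibble with columns `constraint`, `value`, `bound`,
#'   `violation`; zero rows when fully satisfied.
#' @export
check_solution <- function(solution, decisions, constraints, tol = 1e-6) {
  decisions <- validate_decisions(decisions)
  q <- solution$quantities$amount[match(decisions$id, solution$quantities$id)]
  viol <- list()
  note <- function(constraint, value, bound, violation) {
    viol[[length(viol) + 1]] <<- tibble::tibble(
      constraint = constraint, value = value, bound = bound,
      violation = violation
    )
  }
  sel <- q > 1e-9
  for (i in seq_len(nrow(decisions))) {
    if (sel[i]) {
      if (q[i] < decisions$min[i] - tol * max(1, decisions$min[i])) {
        note(
          paste0("item_window_min_", decisions$id[i]), q[i],
          decisions$min[i], decisions$min[i] - q[i]
        )
      }
      if (q[i] > decisions$max[i] + tol * max(1, decisions$max[i])) {
        note(
          paste0("item_window_max_", decisions$id[i]), q[i],
          decisions$max[i], q[i] - decisions$max[i]
        )
      }
    } else if (decisions$required[i]) {
      note(paste0("force_", decisions$id[i]), 0, 1, 1)
    }
  }
  totals <- as.numeric(q %*% as.matrix(decisions[, nutrient_names()]))
  names(totals) <- nutrient_names()
  for (nut in names(constraints$nutrient_lower)) {
    lo <- constraints$nutrient_lower[[nut]]
    if (is.finite(lo) && lo > 0 && totals[nut] < lo - tol * max(1, lo)) {
      note(paste0(nut, "_lower"), totals[nut], lo, lo - totals[nut])
    }
  }
  for (nut in names(constraints$nutrient_upper)) {
    hi <- constraints$nutrient_upper[[nut]]
    if (is.finite(hi) && totals[nut] > hi + tol * max(1, hi)) {
      note(paste0(nut, "_upper"), totals[nut], hi, totals[nut] - hi)
    }
  }
  for (g in names(constraints$group_min_count)) {
    k <- constraints$group_min_count[[g]]
    cnt <- sum(sel[decisions$group == g])
    if (cnt < k) note(paste0("group_count_", g), cnt, k, k - cnt)
  }
  for (g in names(constraints$group_max_count)) {
    k <- constraints$group_max_count[[g]]
    cnt <- sum(sel[decisions$group == g])
    if (cnt > k) note(paste0("group_count_max_", g), cnt, k, cnt - k)
  }
  gw <- constraints$group_windows
  wts <- q * decisions$unit_weight
  if (!is.null(gw)) {
    for (j in seq_len(nrow(gw))) {
      in_g <- decisions$group == gw$group[j]
      if (!is.na(gw$premix[j])) in_g <- in_g & (decisions$premix == gw$premix[j])
      tot <- sum(wts[in_g])
      if (tot < gw$min_g[j] - tol * max(1, gw$min_g[j])) {
        note(
          paste0("group_window_min_", gw$group[j]), tot, gw$min_g[j],
          gw$min_g[j] - tot
        )
      }
      if (is.finite(gw$max_g[j]) && tot > gw$max_g[j] + tol * max(1, gw$max_g[j])) {
        note(
          paste0("group_window_max_", gw$group[j]), tot, gw$max_g[j],
          tot - gw$max_g[j]
        )
      }
    }
  }
  rr <- constraints$ratio
  if (!is.null(rr)) {
    num <- sum(wts[decisions$group == rr$num_group])
    den <- sum(wts[decisions$group == rr$den_group])
    dev <- abs(num - rr$ratio * den)
    slack <- rr$tol * rr$ratio * den + tol * max(1, rr$ratio * den)
    if (dev > slack) note("ratio", num, rr$ratio * den, dev - slack)
  }
  for (fid in constraints$force_ids) {
    i <- match(fid, decisions$id)
    if (!sel[i]) note(paste0("force_", fid), 0, 1, 1)
  }
  if (!is.null(constraints$budget) && constraints$hard_budget) {
    cc <- sum(q * decisions$unit_cost)
    if (cc > constraints$budget + tol * max(1, constraints$budget)) {
      note("budget", cc, constraints$budget, cc - constraints$budget)
    }
  }
  if (length(viol)) dplyr::bind_rows(viol) else {
    tibble::tibble(
      constraint = character(), value = numeric(), bound = numeric(),
      violation = numeric()
    )
  }
}

#' Serialize a solution to JSON
#'
#' Writes a solution with stable key ordering and numbers formatted to
#' six significant digits, so identical runs produce byte-identical
#' files.
#'
#' @param solution A `ration_solution`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_solution_json <- function(solution, path) {
  sig <- function(x) signif(x, 6)
  qt <- solution$quantities[order(solution$quantities$id), ]
  doc <- list(
    status = solution$status,
    total_cost = sig(solution$total_cost),
    budget = if (!is.null(solution$budget)) sig(solution$budget),
    quantities = purrr::pmap(
      qt[, c("id", "group", "selected", "amount", "weight", "cost")],
      function(id, group, selected, amount, weight, cost) {
        list(
          id = id, group = group, selected = selected,
          amount = sig(amount), weight = sig(weight), cost = sig(cost)
        )
      }
    ),
    nutrient_totals = as.list(sig(solution$nutrient_totals)),
    binding_constraints = as.list(sort(solution$binding_constraints)),
    infeasible_hint = as.list(solution$infeasible_hint)
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Export a model in LP text format
#'
#' Writes the objective and all constraint rows of the assembled model
#' in the conventional LP file format, for inspection with external
#' solvers or by eye.
#'
#' @inheritParams solve_min_cost
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_lp_format <- function(decisions, constraints, path) {
  decisions <- validate_decisions(decisions)
  model <- build_lp_rows(decisions, constraints)
  n <- nrow(decisions)
  vn <- c(paste0("q_", decisions$id), paste0("y_", decisions$id))
  term <- function(a) {
    nz <- which(abs(a) > 1e-12)
    paste(sprintf("%+g %s", a[nz], vn[nz]), collapse = " ")
  }
  lines <- c(
    "Minimize", paste(" obj:", term(model$obj)), "Subject To"
  )
  op <- c(le = "<=", ge = ">=", eq = "=")
  for (i in seq_along(model$rhs)) {
    lines <- c(lines, sprintf(
      " %s: %s %s %g", model$name[i],
      term(model$A[i, ]), op[[model$dir[i]]], model$rhs[i]
    ))
  }
  lines <- c(
    lines, "Binary",
    paste(" ", paste0("y_", decisions$id), collapse = ""), "End"
  )
  writeLines(lines, path)
  invisible(path)
}
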