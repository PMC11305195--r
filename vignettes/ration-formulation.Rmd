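---
title: "Least-cost ration formulation: model, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Least-cost ration formulation: model, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rationplan)
```

## The problem

Supplementary nutrition programs distribute two kinds of provision: dry
take-home rations (THR) — raw foods, measured in grams per beneficiary
per day — and hot cooked meals (HCM) — recipe servings composed into a
daily menu. Program rules define, per beneficiary category (children
6–12 months, 1–3 and 3–6 years, severely acutely malnourished [SAM]
children, pregnant and lactating women), how much energy, protein and
fat a daily provision must supply, which micronutrient guideline values
it is scored against, and a set of diet-diversity and procurement rules.
The planner's task is to pick foods and quantities meeting all rules at
minimal cost, ideally within the program budget (₹8 per child per day by
default here). `rationplan` formulates this as a mixed-integer linear
program (MILP) and solves it exactly.

## Decision variables and constraints

Every optimizable item becomes one *decision* (`decision_spec()`): a raw
food with quantity in grams, or a recipe with quantity in serving
multipliers. Each decision carries a **semi-continuous window**: its
quantity is either 0 (not selected) or inside `[min, max]`. A binary
selection variable $y_i$ is linked to the quantity $Q_i$ by
$min_i\,y_i \le Q_i \le max_i\,y_i$; this is what makes "at least one
food from each mandatory group", "compulsorily include this cereal" and
"a different food combination" expressible as linear constraints.

The constraint families (`constraint_set()`):

* **Nutrient bounds.** Lower bounds from the guideline targets, upper
  bounds from macro bands and tolerable upper limits. Sixteen nutrients
  are tracked (energy, protein, fat, dietary fiber, calcium, zinc, iron,
  magnesium, vitamins A, B1, B2, B3, B6, B12, C, folate), stored per
  100 g edible portion, the convention of the food composition tables
  the schema mirrors.
* **Group inclusion counts.** For THR, at least one selected food from
  each of cereals-and-millets, pulses-and-legumes, sugars, and
  edible-oils-and-fats. For HCM, per-category recipe counts (below).
* **Quantity windows** per group (separately for whole foods and
  blended premixes) and per item.
* **Ratio rules.** Total cereal grams equal twice total pulse grams,
  within a relative tolerance (default 2%; a tolerance of 0 gives the
  exact equality). Premix contributions count toward the ratio: the rule
  is interpreted over total raw grams of each group.
* **Forcing** of compulsory items, and an optional **budget**, which by
  default is a reporting threshold — an optimum costlier than the budget
  is returned with status `over_budget`, not suppressed — with an
  opt-in hard-cap mode. The soft default reflects how such tools are
  used: planners need to *see* the cheapest compliant basket to argue
  for subsidies or budget revisions.

## Macro bands and micronutrients

Energy is constrained to 100–102% of its target; protein and fat to
90–135%. These defaults encode two practical facts: energy is the
budgeted quantity and is pinned essentially exactly, while protein and
fat interact with food composition so tightly (any energy source carries
some of both) that exact equality is regularly infeasible with real
foods — cheap protein sources overshoot protein while fat sits slightly
under target. The bands are per-guideline-set configuration
(`guideline_set(macro_band = ...)`), not hard-coded.

Micronutrient guideline values are **reported against, not enforced**,
by default: real THR solutions can sit at a few percent of a vitamin C
guideline and still be accepted, because the program mandates macros and
displays micronutrient provision for planning supplementation. Any
subset can be promoted to hard lower bounds via
`thr_config(enforce_micros = ...)`. Several guideline values are
single-meal shares — one-third of the estimated average requirement —
and are flagged as such (`one_third_ear`). A target of 0 means
"unconstrained below", never "force zero intake". Tolerable upper limits
ship empty and become upper-bound constraints when the user supplies
them.

## Take-home rations

`optimize_thr()` builds one decision per raw food (per-gram cost from
the retail or subsidised price; per-gram nutrients, including the
additive fortification overlay of fortified foods when enabled). Item
windows default to 5–250 g/day, with tighter caps on restricted classes:
oils 5–15 g, sugars 5–30 g, nuts 5–30 g, milk products 5–60 g, egg
5–60 g. The published program rules name these restricted classes
without printing their caps, so the values here are program-plausible
defaults, chosen once, documented, and overridable per class or per food
(`thr_config(class_windows =, item_windows =)`). The 5 g floor defines
what "selected" means: an included food must appear in a meaningful
amount, which also keeps the group-inclusion rule honest.

Cost extrapolations use 7 days/week, 30 days/month and 365 days/year —
display conventions, not model inputs.

## Hot cooked meals

A daily meal selects recipes by category: one main dish, one curry, at
most one side dish, up to two "additional" accompaniments (chutneys,
salads — they may or may not enter the optimum), and no snacks in the
base meal. These counts (`default_category_counts()`) follow the
structure of typical center menus ("steamed rice and lentil gravy") and
are configurable. Each selected recipe's quantity is a multiple of its
predetermined serving size, between `serving_fraction_low` and 1.5. The
lower fraction defaults to 0.5 — half a serving is the smallest portion
worth plating for a child — and is an explicit configuration point
because no authoritative value exists. Compulsory recipes (only egg,
milk and milk-powder dishes are eligible) are forced into the solution.

Per-serving recipe cost and nutrients are always recomputed from the raw
ingredients (`recipe_profile()`), never cached, so price edits,
subsidies and fortification toggles propagate.

**SAM augmentation** (`augment_for_sam()`): SAM categories have elevated
macro targets. Rather than re-optimizing from scratch, the package
mirrors program practice: add one or two snack servings, scale the
meal's multipliers uniformly (default cap 1.25×, never beyond the 1.5
serving ceiling), or both. Candidates are enumerated (snack subsets of
size 0–2 × the minimal scale factor closing the gaps) and the cheapest
one meeting the SAM bands wins; snacks are tried before scaling in the
sense that scaling is kept minimal for each snack set. When nothing
suffices the best-effort augmentation is returned with an explicit
per-nutrient shortfall table — never silently.

**Weekly menus** (`build_weekly_menu()`) optimize each day independently
and assemble: users combine or repeat suggested meals, so a joint
week-level optimization would add coupling the workflow doesn't have.
The menu reports mean and sample (n−1) standard deviation of daily cost
and per-day macro series, with protein:energy and fat:energy expressed
as percent of energy via the Atwater factors 4 kcal/g and 9 kcal/g.

## The solver

No LP or MILP solver library is a dependency; the package carries its
own, sized for these desk-scale models (tens of items, under a hundred
rows):

* **LP relaxations** are solved by a dense two-phase tableau simplex.
  Phase 1 minimizes artificial variables (only `>=`/`=` rows get them;
  `<=` rows start on their slacks). These models are heavily degenerate —
  every linking row has a zero right-hand side — so the pivot rule
  switches from Dantzig to Bland's rule after a burn-in, guaranteeing
  termination; leftover zero-value artificials are pivoted out or their
  redundant rows dropped.
* **Branch-and-bound** on the selection variables: depth-first, most
  fractional variable, the branch the relaxation leans toward explored
  first, pruning at a relative optimality gap of 1e-6. Feasibility
  tolerance 1e-7. Everything is deterministic for a fixed input
  ordering; there is no randomized component in the solve itself.
* **k-best enumeration** adds, after each solution with support $S$, the
  no-good cut $\sum_{i\in S} y_i - \sum_{i\notin S} y_i \le |S|-1$ and
  re-solves. Alternatives therefore differ in *which* items are used;
  pure quantity re-shuffles of the same basket are not reported as
  alternatives. Costs are nondecreasing by construction.
* **Infeasibility hints.** When a model is infeasible, each constraint
  family (nutrient lower bounds, upper limits, group counts, windows,
  ratio, forcing, hard budget) is relaxed in turn and re-solved; the
  families whose removal restores feasibility are reported.

Two independent checks guard the implementation. The **grid oracle**
(`brute_force_oracle()`) enumerates every quantity combination on a
regular grid (refusing instances beyond $10^7$ combinations) and bounds
the true optimum: the MILP cost can never exceed the oracle's, and the
oracle's can exceed the MILP's by at most one grid step per item. The
**post-hoc checker** (`check_solution()`) re-evaluates every rule from
the raw quantities, independently of the solver's algebra, at 1e-6
relative slack.

## Analytics and report conventions

Percent-of-guideline values are rounded to **one decimal, half away from
zero** (the convention of printed program adequacy tables); radar ratios
are unrounded. The colour code is a step function of the percent alone:
for meals, green above 60%, orange 30–60%, red below 30%; for rations,
green above 80%, orange 50–80%, red below 50%. The published captions
use strict "greater than" for green and strict "less than" for red, so
boundary values (exactly 60, 30, 80, 50) fall in the orange band.
Zero-target nutrients are flagged, not divided. Chart outputs are
structured data (tibbles, JSON via the CLI); rendering is a consumer
concern, with `autoplot()` methods provided for quick looks.

## Synthetic data

`generate_food_db()` draws synthetic food databases from per-group
nutrient and price ranges plausible for food composition tables (cereals
around 330–365 kcal/100 g with 8–12 g protein, pulses 20–25 g protein,
oils ~100 g fat, a milk-powder-like product supplying protein and fat
jointly, and so on). `guaranteed_feasible` databases are verified by
actually solving the child-1-3y THR model (re-drawing from a derived
seed when needed); `guaranteed_infeasible` databases are built so every
food's protein density is too low for the protein floor to be reachable
even with every item at its cap — an arithmetic certificate checked at
generation time, not a solver claim.

What the generator emulates: realistic group-level nutrient magnitudes,
price dispersion, and the structural features the optimizer exercises
(group membership, subsidies, windows). What it does not: real regional
food lists and prices, seasonality, cooking losses (vitamin losses of
10–60% during cooking are out of scope altogether), correlations between
nutrients within a food beyond the group ranges, and data-entry noise.
Passing tests on synthetic databases therefore validates the *model and
solver*, not the nutritional realism of any particular national
database — users supply their own food tables.

Hand-printed toy instances (`toy_instances()`) keep the oracle
comparisons exact and the documentation concrete: `thr_toy_5` has one
food per mandatory THR group plus a subsidizable milk powder;
`hcm_toy` has two mains, two curries, one side and one
compulsory-eligible egg dish.

## Validation suite sizes

The shipped tests compare the solver against the grid oracle on 20
seeded random instances of up to 5 items at a 1 g grid, check the full
rule set on 50 guaranteed-feasible synthetic databases and 50
price-jittered meal instances, and probe cost monotonicity (subsidies,
food-set growth, k-best ordering) on 8 further databases. These sizes
give each property multiple independent draws while keeping every
instance within the oracle's enumeration cap.

## Known limitations

* Guideline micronutrient defaults are packaged only for the 1–3 y and
  3–6 y child categories; other categories carry macro targets until the
  user supplies micronutrient values.
* The solver is exact but not industrial: models with many hundreds of
  items will branch slowly. The intended scale is a state or district
  food list.
* SAM augmentation is a structured heuristic over an already-optimized
  meal (by design, mirroring practice); it does not claim the globally
  cheapest SAM-compliant meal.
* Cooking nutrient losses, palatability/repetition penalties, premix
  blending processes, and multi-objective trade-offs beyond k-best
  enumeration are out of scope.
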