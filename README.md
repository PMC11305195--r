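# rationplan

Least-cost ration and menu formulation for supplementary nutrition
programs.

Large supplementary feeding programs — India's Integrated Child
Development Services Supplementary Nutrition Program (ICDS-SNP) is the
motivating example — hand out dry **take-home rations** (THR, raw foods
in grams per beneficiary per day) and serve **hot cooked meals** (HCM,
recipe servings at village centres). Program rules fix what a ration
must deliver (energy, protein and fat targets per beneficiary category,
micronutrient guideline values, tolerable upper limits, diet-diversity
rules such as one food from each mandatory group and a 2:1
cereal-to-pulse ratio) and what it may cost (a budget of about ₹8 per
child per day). Composing baskets and menus that satisfy all of this at
minimal cost from local foods is an integer-constrained optimization
problem; `rationplan` solves it exactly and reports the nutrient
adequacy of the result.

## The model

For decision quantities `Q_i` (grams of raw food *i*, or serving
multiplier of recipe *i*) with unit costs `C_i`, the package solves

```
minimize   sum_i Q_i * C_i
subject to nutrient bounds     L_n <= sum_i Q_i * a_{i,n} <= U_n
           selection windows   Q_i = 0  or  min_i <= Q_i <= max_i
           group inclusion     #{selected i in group g} >= k_g
           ratio rules         sum_cereal Q_i = 2 * sum_pulse Q_i  (± tol)
           compulsory items    selected
           budget              sum_i Q_i * C_i <= B   (optional hard cap)
```

The semi-continuous windows, group counting, compulsory items and
alternative-solution enumeration require binary selection variables
`y_i` linked by `min_i * y_i <= Q_i <= max_i * y_i`. The resulting
mixed-integer linear program is solved to proven optimality by a
branch-and-bound over LP relaxations (a self-contained two-phase
simplex with Bland's anti-cycling rule). "Next least expensive"
alternatives are enumerated with no-good cuts on the selection support,
so each alternative uses a different set of foods, not merely different
quantities. A brute-force grid oracle (`brute_force_oracle()`)
independently verifies optima on small instances.

Nutrient targets per beneficiary category (children by age band, SAM
children, pregnant and lactating women) ship as packaged defaults
(`default_guidelines()`) and are fully user-editable
(`load_guidelines()` / `save_guidelines()`).

## Worked example

Optimize a take-home ration for a 1–3-year-old child over the packaged
five-food toy database:

```r
library(rationplan)

db  <- toy_instances()$thr_toy_5
g   <- default_guidelines("child_1_3y")   # 400 kcal, 15 g protein, 15 g fat
sol <- optimize_thr(db, g)[[1]]
sol
#> <ration_solution> status: optimal
#>  total cost: 0.842695
#>   id              group                  amount weight  cost
#> 1 toy_cereal      cereals_and_millets     44.6   44.6  0.134
#> 2 toy_pulse       pulses_and_legumes      22.8   22.8  0.182
#> 3 toy_oil         edible_oils_and_fats     8.55   8.55 0.103
#> 4 toy_sugar       sugars                   5      5    0.02
#> 5 toy_milk_powder milk_and_milk_products  15.6   15.6  0.404
```

The optimum costs ₹0.84/day. All four mandatory groups are present, the
cereal mass (44.6 g) is twice the pulse mass (22.8 g) within the 2%
tolerance, and the macro totals sit inside the guideline bands
(energy 408 kcal ≤ 102% of 400; protein and fat at 13.5 g = 90% of 15 g,
the band floor). `thr_product_summary(sol, g)` extrapolates the cost to
the week (₹5.90), month (₹25.28) and year (₹307.58) and attaches the
percent-of-guideline adequacy table.

A hot cooked meal for a 3–6-year-old, with a compulsory egg dish:

```r
hdb  <- toy_instances()$hcm_toy
meal <- optimize_meal(hdb, default_guidelines("child_3_6y"),
                      selection = hdb$recipes$id,
                      config = meal_config(compulsory_recipe_ids = "boiled_egg"))[[1]]
glance(meal)
#>   status      total_cost budget energy protein   fat n_selected
#> 1 over_budget       9.46      8    400    14.6  13.5          3
```

The cheapest compliant meal (steamed rice at 0.65 servings, lentil
gravy at 1.27, half a boiled egg serving) costs ₹9.46 — flagged
`over_budget` against the ₹8 default. Subsidising the egg from ₹100 to
₹50/kg and re-optimizing with `use_subsidy = TRUE` brings it down to
₹8.16. `meal_config(k_alternatives = 5)` returns the next least
expensive recipe combinations; `build_weekly_menu()` assembles day
solutions into a weekly plan with mean (SD) daily cost and
protein:energy / fat:energy series; `augment_for_sam()` adapts a meal to
the elevated targets of severely malnourished children by adding snacks
and scaling servings.

Analytics mirror standard program reports: `percent_of_guideline()`,
colour-coded `adequacy_table()` (green/orange/red), doughnut
`food_group_allocation()`, radar `nutrient_ratio_radar()`, and
`contribution_breakdown()`, each with an `autoplot()` view.

A command-line wrapper ships at
`system.file("cli", "rationtool.R", package = "rationplan")` with
subcommands `thr`, `hcm`, `report` and `fixtures`.

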