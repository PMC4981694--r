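---
title: "Individualized diet modeling by constraint optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized diet modeling by constraint optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietmodelr)
```

## The problem

Dietary intervention trials prescribe diets as daily servings per food
group. The prescription must satisfy two kinds of requirement at once:
trial-level composition targets — a fixed share of energy from
carbohydrate, protein and fat, 50/20/30 by default — and food-based
constraints that keep the diet implementable and consistent with
dietary guidelines (at least 5 servings of vegetables, fruit between 2
and 4 servings, a cap on added sugar, and so on). Each participant
brings their own energy requirement, so the same trial configuration
must yield a different serving vector for every participant.
`dietmodelr` formalizes this as a small constrained nonlinear program
and solves it reproducibly.

## Energy requirement

Resting energy expenditure comes from the Mifflin-type anthropometric
equations (kcal/day):

$$\mathrm{REE} = 9.99\,w + 6.25\,h - 4.92\,a + \begin{cases}-161 &
\text{female}\\ +5 & \text{male}\end{cases}$$

with weight $w$ in kg, height $h$ in cm and age $a$ in years. The
estimated energy requirement is $\mathrm{EER} = \mathrm{REE} \times
\mathrm{PA}$; the package ships the standard activity-factor menu
(sedentary 1.2 through very active 1.9) with 1.6 ("light activity") as
the default. Two structural identities follow directly from the
equations and are asserted as tests: REE is strictly monotone in each
anthropometric input, and at matched anthropometry the male and female
values differ by exactly 166 kcal (the intercept gap).

The equations yield kcal/day while diet models are framed in kJ. The
package computes and stores both, bridging with the exact factor
1 kcal = 4.184 kJ; the solver consumes the full-precision kJ value
rather than a value rounded to a 500-kJ increment, so prescriptions
are tailored to the individual.

## Diet totals, percentages and the objective

For serving vector $X$ and per-serving gram contents
$\mathrm{CHO}_i, \mathrm{PTN}_i, \mathrm{FAT}_i$:

$$\mathrm{TotalEnergy} = 17\sum_i X_i \mathrm{CHO}_i +
17\sum_i X_i \mathrm{PTN}_i + 36\sum_i X_i \mathrm{FAT}_i
\quad\text{(kJ)}$$

using the conventional 17/17/36 kJ/g energy factors (no alcohol or
fibre terms). Each macronutrient's percentage of energy uses its own
total (e.g. $\%\mathrm{FAT} = 36\,\mathrm{TotalFAT} /
\mathrm{TotalEnergy} \times 100$), which guarantees the three
percentages close to exactly 100 for any non-empty diet — a property
asserted to $10^{-9}$ across the randomized test suite. A zero-energy
diet has undefined percentages; this is flagged rather than raised as
an arithmetic error.

The objective is the Euclidean distance in percentage points between
achieved and target splits,
$d = \lVert(\%\mathrm{CHO}, \%\mathrm{PTN}, \%\mathrm{FAT}) -
(T_\mathrm{CHO}, T_\mathrm{PTN}, T_\mathrm{FAT})\rVert_2$,
minimized subject to $X_i \ge T_i$ (plus optional maxima) and
$\mathrm{TotalEnergy} \le \mathrm{EER}$.

## Degeneracy and the energy tie-break

The percentages depend on $X$ only through ratios, so they are
invariant under $X \mapsto cX$. Whenever a distance-minimal diet exists
in the interior of the constraint set, a whole ray of equally good
diets exists with it — the stated problem does not determine the
*amount* of food, only its composition. This is the one place the
problem statement is genuinely under-determined, and the package
resolves it with a lexicographic secondary objective: among
(near-)distance-minimal diets, maximize total energy. A prescription
should meet, not undershoot, the participant's requirement; the CLI
report notes this convention. Consequences asserted in tests: on the
pure-macronutrient fixture with targets (50, 20, 30) and a 3400 kJ cap
the solver returns exactly (10, 4, 5.667) servings at 3400 kJ, the
unique energy-maximal zero-distance point.

## Solver

The squared distance $d^2$ (smooth at the optimum, unlike $d$) is
minimized with `stats::constrOptim` — a log-barrier interior method
over the linear inequality constraints — using an analytic gradient,
from several starts: three deterministic minima-anchored,
energy-scaled starts plus `n_starts` seeded random ones (default 10;
convergence tolerance $10^{-6}$ on the distance). Serving bounds with
`max = min` (excluded groups such as whole milk) are eliminated from
the decision vector and folded into constant gram/energy offsets,
since an interior method cannot traverse a zero-width box.

The tie-break then proceeds in two stages. First, exact ray scaling:
the optimum is scaled out along its ray to the first binding
constraint, which preserves the distance exactly and usually lands on
the energy cap. Second, when a serving *maximum* truncates the ray
short of the cap (fruits at their upper bound, typically), the
remaining groups can often still grow at equal distance; the package
bisects on the energy level, at each trial level re-minimizing the
distance with the diet's energy softly pinned by a quadratic penalty
(weight $10^4$ on the squared relative deviation, 12 bisection steps),
accepting a level only if the pinned minimum stays within the distance
tolerance of the unconstrained optimum. If no improvement survives
that check the ray-scaled solution is kept, so the refinement can only
help.

Infeasibility is decided exactly: since every group's energy is
non-negative, the minima alone exceeding the cap
($\sum e_i T_i > \mathrm{EER}$) is necessary and sufficient, and the
violating margin is reported. All solver randomness sits behind a
single integer seed, and the caller's RNG state is restored on exit;
identical inputs and seed give identical output.

### The brute-force oracle

`brute_force_solve()` enumerates a regular serving grid (anchored at
the minima; per-group upper limit the configured maximum or the first
grid point whose solo energy exceeds the cap) and applies the same
distance-then-energy ordering. It is deliberately independent of the
continuous solver — different code path, no shared optimization logic
— and the test suite requires the continuous solution to dominate the
grid optimum and to sit within one grid step of it, where "one grid
step" is measured per instance as the largest distance change from
perturbing the grid optimum by one increment in any single coordinate.
The oracle refuses grids beyond $10^7$ points with sizing advice.

## Rounding to practical servings

Continuous optima are snapped to each constraint's serving increment
(default 0.5, the grid used in exchange-list practice; an opt-in
`integral` flag per constraint gives whole servings). A repair pass
then restores minima, re-imposes maxima, and — if snapping pushed the
diet over the energy cap — retracts the round-ups with the largest
energy excess first. If no feasible rounding exists the continuous
values are returned with an explicit flag rather than silently
violated constraints. Groups carrying a `weekly_unit_g` (cheese, eggs,
oily fish) are exempt from snapping: their fractional daily servings
encode weekly portion frequencies (0.43 servings/day of 30 g fish
units is one 90 g portion per week) and rounding them to halves would
destroy that meaning. `weekly_frequency()` performs the conversion
`servings/day × 7 × unit_g / portion_g`.

## Study configuration semantics

Three details of the shipped default constraint set deserve note.

* The published constraint table marks some groups with a symbol whose
  own footnote reads "no upper constraint limit"; the package follows
  the footnote (absence of a maximum) and offers the integer reading
  as the separate `integral` flag, since the symbol conventionally
  denotes integers.
* "Fruits ≥ 2, < 4" is a strict upper bound; it is stored as
  `max_servings = 4` with `strict_max = TRUE` and handled by the solver
  as `max = 4 − increment`.
* The high-energy adjustment (lean-meat minimum raised to 5, sugar cap
  dropped) applies from 8500 kJ *inclusive*, matching the lower edge
  of the stated 8500–10,000 kJ range.

Per-participant overrides (`apply_override()`) are pure functions: a
vegetarian swap of meat for meat alternatives never mutates the study
default, so the next participant starts from the trial configuration
by construction.

## Group statistics and screening

Within each food group, per-nutrient item statistics use the sample
standard deviation (n − 1 denominator — the items are a sample of a
larger food supply) and CV = SD/mean × 100. The acceptability screen
is *strictly* below 15%, following the stated rule; groups with a zero
mean have an undefined CV and are routed to manual review against
published exchange lists rather than auto-flagged. Primary-source
ranking orders groups by descending share of a nutrient's total and
returns the shortest prefix whose cumulative share stays strictly
below 75%.

## The synthetic generator

The food-composition and pooled-trial databases behind the original
tool are not published, so the package generates stand-ins. The
realistic preset carries a 13-group roster (vegetables through PUFA
products) with per-serving archetype means chosen from ordinary
food-composition values; group profiles get 5% multiplicative
log-normal noise, and item-level per-100 g values are drawn around
each profile and then affinely standardized so the sample CV of every
nonzero macronutrient equals the requested `cv_target` *exactly* —
the calibration is deterministic, not statistical. The participant
generator places EER targets evenly across 4800–10,200 kJ and solves
the REE equation for weight given randomly drawn sex, age and height
(clipping to 30–150 kg and pushing stature/age toward the target when
the clip binds), so every 500-kJ band between 5000 and 10,000 kJ is
covered under the default 1.6 activity factor.

What the generator does *not* emulate: real nutrient correlations
between macronutrients within a food, seasonal or brand variation,
item-level serving-size heterogeneity, and the consumption-frequency
weighting of actual trial intake data. Passing tests on these fixtures
therefore demonstrate the *machinery* — parsing, statistics,
optimization, reporting — not agreement with any real food supply.
Absolute serving outputs (e.g. how many grain servings a 7000-kJ model
prescribes) depend on the unpublished composition data and are not
reproducible here; the test suite instead pins the arithmetic
(percent-difference cells, energy equations), the solver's provable
properties (feasibility, oracle agreement, exact recovery on a
constructed instance), and the generator's calibration.

## Comparison reports

`percent_difference()` implements the validation metric
$|x - \mathrm{ref}|/\mathrm{ref} \times 100$, rounded to the nearest
integer with halves away from zero, denominator always the reference
method. The published comparison cells are reproduced from
full-precision servings: 0.286 vs 0.58 gives 51 where the
display-rounded 0.29 vs 0.58 would give 50, so reports carry
full-precision servings internally and round only at display. A zero
reference leaves the cell undefined (`NA`) rather than infinite. One
published footnote equates 0.286 eggs/day with 1 egg/week, which is
inconsistent with a 60 g egg counted in 30 g units; the package
exposes the generic conversion and encodes eggs with
`weekly_unit_g = 60` rather than silently matching the footnote.

## Numerical choices and problem sizes

* Convergence: $10^{-6}$ on distance; barrier `outer.eps` $10^{-10}$;
  BFGS `reltol` $10^{-14}$.
* Tie tolerance in the oracle: distances within $10^{-9}$ are tied,
  resolved by energy.
* Feasibility slack: energy cap checked to a $10^{-8}$ relative
  tolerance in tests (interior-point iterates are feasible by
  construction).
* Randomized suites: 500 instances (2–6 groups) for feasibility, 100
  bounded instances (2–3 groups, 0.25-serving oracle grid) for
  solver–oracle agreement, sizes chosen to exercise the solver
  broadly while keeping the default test run fast.
* Degenerate inputs: header-only tables load as empty; zero-serving
  diets flag undefined percentages; all-zero nutrient contributions
  refuse ranking; single-item groups report SD = CV = 0.

## Limitations

Micronutrients, vitamins and minerals are out of scope — the model
controls macronutrient composition and energy only, which limits use
to trials framed around those quantities. The objective is nonconvex
in general; multi-start search with the oracle cross-check has been
robust on the tested instance family, but global optimality is not
certified. Meal-level scheduling, food allergies and professional
judgment about individual foods remain with the dietitian; the tool
standardizes the serving arithmetic, not the clinical decision.
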