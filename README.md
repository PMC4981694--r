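# dietmodelr

Individualized food-group serving prescriptions for dietary intervention
trials, by constraint optimization.

Dietary trials prescribe diets as *servings per food group* (vegetables,
whole grains, lean meat, ...) that must deliver a target macronutrient
energy split — typically 50% of energy from carbohydrate, 20% from
protein and 30% from fat — without exceeding the participant's estimated
energy requirement. Doing this by hand is slow and varies between
dietitians; `dietmodelr` automates it while keeping the trial's
food-group constraints intact. It is aimed at research dietitians and
nutrition-informatics developers who need reproducible, per-participant
diet models.

## The model

For a participant with weight *w* (kg), height *h* (cm) and age *a*
(years), resting energy expenditure in kcal/day is

```
REE = 9.99 w + 6.25 h − 4.92 a − 161   (female)
REE = 9.99 w + 6.25 h − 4.92 a + 5     (male)
```

and the estimated energy requirement is `EER = REE × PA`, with activity
factor PA = 1.6 ("light activity") by default. Energy is carried in kJ
(1 kcal = 4.184 kJ).

Given a food table with per-serving grams of carbohydrate, protein and
fat for each group *i*, and a serving vector X = (X₁, ..., Xₙ), the diet
totals are Σᵢ Xᵢ·CHOᵢ etc., total energy is `17·CHO + 17·PTN + 36·FAT`
kJ, and each macronutrient's share of energy is

```
%CHO = 17·TotalCHO / TotalEnergy × 100     (likewise %PTN, %FAT with 17 and 36)
```

The solver chooses X to minimize the Euclidean distance

```
d = sqrt((%CHO − TargetCHO)² + (%PTN − TargetPTN)² + (%FAT − TargetFAT)²)
```

subject to `Xᵢ ≥ Tᵢ` (trial serving minima, with optional maxima) and
`TotalEnergy ≤ EER`. Because the percentages are scale-invariant, many
diets attain the same distance at different energy levels; ties are
broken by maximizing total energy, so prescriptions meet rather than
undershoot the requirement.

Around the solver the package provides food-table I/O, within-group
homogeneity statistics (CV = SD/mean × 100, screened at < 15%),
primary-source ranking, method-vs-reference percent-difference reports,
a brute-force grid oracle used to verify the solver, and a seeded
synthetic fixture generator.

## Worked example

```r
library(dietmodelr)

# 45-year-old woman, 165 cm, 60 kg, light activity
er <- estimated_energy_requirement("female", age_y = 45,
                                   height_cm = 165, weight_kg = 60,
                                   pa_factor = 1.6)
round(er, 2)
#>   ree_kcal  ree_kj eer_kcal  eer_kj pa_factor
#>    1248.25 5222.68   1997.2 8356.28       1.6

# synthetic food table + the built-in trial constraint set
fx  <- generate_food_table(fixture_spec(seed = 1))
cfg <- high_energy_adjustment(study_config_table1(), er$eer_kj)
solve_servings(cfg, fx$table, er$eer_kj, seed = 1)
#> Serving prescription (status: optimal )
#>          vegetables        whole_grains              fruits               sugar
#>               5.461               8.697               3.500               2.476
#> milk_yoghurt_lowfat  milk_yoghurt_whole      soy_milk_whole           lean_meat
#>               2.817               0.000               0.000               3.298
#>              cheese                eggs           oily_fish                mufa
#>               0.157               0.215               0.648               3.895
#>                pufa
#>               4.049
#>   distance from targets: 0.0000 percentage points
#>   energy: 8356.3 kJ of 8356.3 kJ allowed
#>   rounded to serving grid:
#>          vegetables        whole_grains              fruits               sugar
#>               5.500               8.500               3.500               2.500
#>   ...
```

The prescription hits the 50/20/30 split exactly (distance 0.0
percentage points) at the participant's full energy allowance
(8356 kJ), honouring every serving constraint (vegetables ≥ 5, fruits
< 4, lean meat ≥ 3, ...). The rounded block snaps servings to the
half-serving grid used in practice; weekly-frequency groups (cheese,
eggs, oily fish) keep their fractional daily values, which convert to
practical portions via `weekly_frequency()` (0.648 servings/day of
30 g fish units ≈ 1.5 × 90 g portions per week).

A command-line wrapper over the same functions is installed at
`inst/cli/dietmodel.R` with subcommands `synth`, `eer`, `model`,
`compare` and `stats`.

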