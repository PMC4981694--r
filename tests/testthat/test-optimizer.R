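one_group_table <- function(cho = 15, ptn = 5, fat = 2) {
  food_table(data.frame(group_id = "g", name = "g", serving_size_g = 40,
                        cho_g = cho, ptn_g = ptn, fat_g = fat))
}

test_that("diet totals match hand arithmetic with 17/17/36 kJ/g", {
  tot <- diet_totals(c(g = 2), one_group_table())
  expect_equal(tot$total_cho_g, 30)
  expect_equal(tot$total_ptn_g, 10)
  expect_equal(tot$total_fat_g, 4)
  expect_equal(tot$total_energy_kj, 824)
  # 51000/824, 17000/824, 14400/824 percent
  expect_equal(unname(tot$pct),
               c(61.8932038835, 20.6310679612, 17.4757281553),
               tolerance = 1e-9)
})

test_that("zero-serving diets flag undefined percentages, no error", {
  tot <- diet_totals(c(g = 0), one_group_table())
  expect_equal(tot$total_energy_kj, 0)
  expect_false(tot$defined)
  expect_true(all(is.na(tot$pct)))
  expect_error(macro_distance(tot, c(cho = 50, ptn = 20, fat = 30)),
               "undefined")
})

test_that("percentages are scale invariant and close to 100", {
  tab <- one_group_table()
  t1 <- diet_totals(c(g = 2), tab)
  t2 <- diet_totals(c(g = 4), tab)
  expect_equal(t2$total_energy_kj, 2 * t1$total_energy_kj)
  expect_equal(t2$pct, t1$pct, tolerance = 1e-12)
  expect_equal(sum(t1$pct), 100, tolerance = 1e-9)
})

test_that("percentage closure holds across randomized diets", {
  for (s in 1:40) {
    inst <- rand_instance(s)
    set.seed(s + 1000)
    x <- stats::setNames(runif(nrow(inst$tab), 0.01, 10),
                         inst$tab$group_id)
    tot <- diet_totals(x, inst$tab)
    if (tot$defined) expect_equal(sum(tot$pct), 100, tolerance = 1e-9)
  }
})

test_that("macro distance reproduces the worked values", {
  mk <- function(pct) {
    structure(list(pct = stats::setNames(pct, c("cho", "ptn", "fat")),
                   defined = TRUE), class = "diet_totals")
  }
  targets <- c(cho = 50, ptn = 20, fat = 30)
  expect_equal(macro_distance(mk(c(50, 20, 30)), targets), 0)
  expect_equal(macro_distance(mk(c(53, 20, 27)), targets),
               sqrt(18), tolerance = 1e-12)
  # the one-group two-serving diet above, exactly
  tot <- diet_totals(c(g = 2), one_group_table())
  expect_equal(macro_distance(tot, targets), 17.2830532784,
               tolerance = 1e-9)
})

test_that("solver recovers the analytic optimum on the pure-macro table", {
  sol <- solve_servings(pure_macro_config(), pure_macro_table(),
                        eer_kj = 3400, seed = 1)
  expect_equal(sol$status, "optimal")
  expect_lt(sol$distance, 1e-6)
  expect_equal(unname(sol$prescription), c(10, 4, 17 / 3),
               tolerance = 1e-4)
  # energy-maximizing tie-break drives the diet to the cap
  expect_equal(sol$totals$total_energy_kj, 3400, tolerance = 1e-6)
})

test_that("minima beyond the energy cap are reported infeasible", {
  tab <- food_table(data.frame(group_id = "g", name = "g",
                               serving_size_g = 30, cho_g = 100 / 17,
                               ptn_g = 0, fat_g = 0))   # 100 kJ/serving
  cfg <- study_config("s", c(cho = 50, ptn = 20, fat = 30),
                      data.frame(group_id = "g", min_servings = 10))
  sol <- solve_servings(cfg, tab, eer_kj = 500, seed = 1)
  expect_equal(sol$status, "infeasible")
  expect_equal(sol$infeasible_margin_kj, 500, tolerance = 1e-9)

  bf <- brute_force_solve(cfg, tab, eer_kj = 500)
  expect_equal(bf$status, "infeasible")
})

test_that("when the cap binds at minima the optimum is the minima", {
  cfg <- study_config("s", c(cho = 50, ptn = 20, fat = 30),
                      data.frame(group_id = c("cho_pure", "ptn_pure",
                                              "fat_pure"),
                                 min_servings = c(10, 4, 17 / 3)))
  sol <- solve_servings(cfg, pure_macro_table(), eer_kj = 3400, seed = 1)
  expect_equal(sol$status, "optimal")
  expect_equal(unname(sol$prescription), c(10, 4, 17 / 3),
               tolerance = 1e-9)
  expect_lt(sol$distance, 1e-9)
})

test_that("identical inputs and seed give identical solutions", {
  inst <- rand_instance(3)
  s1 <- solve_servings(inst$cfg, inst$tab, inst$eer, seed = 7)
  s2 <- solve_servings(inst$cfg, inst$tab, inst$eer, seed = 7)
  expect_identical(s1$prescription, s2$prescription)
  expect_identical(s1$distance, s2$distance)
})

test_that("solver respects all bounds and the cap on random instances", {
  for (s in 1:25) {
    inst <- rand_instance(s + 200)
    sol <- solve_servings(inst$cfg, inst$tab, inst$eer, seed = s,
                          n_starts = 4, round = FALSE)
    expect_true(sol$status %in% c("optimal", "not_converged",
                                  "infeasible"))
    if (sol$status == "optimal") {
      expect_true(all(sol$prescription >= inst$lower - 1e-8))
      expect_lte(sol$totals$total_energy_kj, inst$eer * (1 + 1e-8))
    }
  }
})

test_that("continuous solve dominates the grid oracle on small instances", {
  for (s in 1:15) {
    inst <- rand_small_instance(s + 400)
    sol <- solve_servings(inst$cfg, inst$tab, inst$eer, seed = s,
                          n_starts = 6, round = FALSE)
    bf <- brute_force_solve(inst$cfg, inst$tab, inst$eer, grid = 0.25)
    expect_lte(sol$distance, bf$distance + 1e-6)
  }
})

test_that("optimal percentages are invariant to serving-size rescaling", {
  # tripling every serving's nutrient content while shrinking the serving
  # bounds threefold describes the same diet in different units
  inst <- rand_small_instance(42)
  tab2 <- inst$tab
  for (cl in c("cho_g", "ptn_g", "fat_g")) tab2[[cl]] <- tab2[[cl]] * 3
  tab2 <- food_table(as.data.frame(tab2))
  cfg2 <- study_config("scaled", inst$cfg$targets,
                       data.frame(group_id = inst$tab$group_id,
                                  min_servings = inst$lower / 3,
                                  max_servings = inst$upper / 3))
  s1 <- solve_servings(inst$cfg, inst$tab, inst$eer, seed = 5,
                       round = FALSE)
  s2 <- solve_servings(cfg2, tab2, inst$eer, seed = 5, round = FALSE)
  expect_equal(s1$distance, s2$distance, tolerance = 1e-4)
  expect_equal(s2$totals$pct, s1$totals$pct, tolerance = 1e-3)
})

test_that("brute force refuses oversized grids with sizing advice", {
  inst <- rand_small_instance(1)
  expect_error(brute_force_solve(inst$cfg, inst$tab, inst$eer,
                                 grid = 0.001),
               "coarsen the grid")
})

test_that("rounding snaps to the half-serving grid and reports energy", {
  tab <- pure_macro_table()
  cfg <- pure_macro_config()
  x <- c(cho_pure = 10, ptn_pure = 4, fat_pure = 17 / 3)
  rp <- round_prescription(x, cfg, tab, eer_kj = 3400)
  expect_true(rp$feasible)
  expect_equal(unname(rp$servings), c(10, 4, 5.5))
  # fat group delivers 180 kJ/serving; 1/6 serving lost to rounding
  expect_equal(rp$energy_change_kj, -30, tolerance = 1e-9)

  # idempotence on grid points
  rp2 <- round_prescription(rp$servings, cfg, tab, eer_kj = 3400)
  expect_equal(rp2$servings, rp$servings)
  expect_equal(rp2$energy_change_kj, 0)
})

test_that("irreconcilable rounding returns continuous values with a flag", {
  tab <- food_table(data.frame(group_id = "g", name = "g",
                               serving_size_g = 30, cho_g = 100 / 17,
                               ptn_g = 0, fat_g = 0))   # 100 kJ/serving
  cfg <- study_config("s", c(cho = 50, ptn = 20, fat = 30),
                      data.frame(group_id = "g", min_servings = 0.8))
  # x = 0.8 feasible at cap 85; up-round 1.0 breaks the cap, down-round
  # 0.5 breaks the minimum
  rp <- round_prescription(c(g = 0.8), cfg, tab, eer_kj = 85)
  expect_false(rp$feasible)
  expect_equal(unname(rp$servings), 0.8)
  expect_match(rp$note, "continuous values retained")
})

test_that("weekly-unit groups are exempt from grid snapping", {
  tab <- food_table(data.frame(
    group_id = c("grains", "fish"), name = c("Grains", "Fish"),
    serving_size_g = c(40, 30), cho_g = c(15, 0), ptn_g = c(3, 7),
    fat_g = c(1, 3), weekly_unit_g = c(NA, 30)))
  cfg <- study_config("s", c(cho = 50, ptn = 20, fat = 30),
                      data.frame(group_id = c("grains", "fish"),
                                 min_servings = 0))
  rp <- round_prescription(c(grains = 4.3, fish = 0.43), cfg, tab,
                           eer_kj = 5000)
  expect_equal(unname(rp$servings["grains"]), 4.5)
  expect_equal(unname(rp$servings["fish"]), 0.43)  # untouched
})
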