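# Randomized problem instances used by the property and acceptance
# suites. All randomness is seeded by the caller.

# general instance: 2-6 groups, minima only
rand_instance <- function(seed) {
  set.seed(seed)
  n <- sample(2:6, 1)
  tab <- food_table(data.frame(
    group_id = paste0("g", seq_len(n)), name = paste0("g", seq_len(n)),
    serving_size_g = runif(n, 20, 200),
    cho_g = runif(n, 0, 15), ptn_g = runif(n, 0, 10),
    fat_g = runif(n, 0, 8), stringsAsFactors = FALSE))
  lo <- round(runif(n, 0, 2), 1)
  cfg <- study_config("rand", c(cho = 50, ptn = 20, fat = 30),
                      data.frame(group_id = tab$group_id,
                                 min_servings = lo,
                                 stringsAsFactors = FALSE))
  e <- serving_energy_kj(tab)
  eer <- sum(e * lo) * runif(1, 1.1, 2) + runif(1, 500, 2000)
  list(tab = tab, cfg = cfg, eer = eer, lower = lo)
}

# small instance with serving maxima, enumerable by the grid oracle
rand_small_instance <- function(seed) {
  set.seed(seed)
  n <- sample(2:3, 1)
  tab <- food_table(data.frame(
    group_id = paste0("g", seq_len(n)), name = paste0("g", seq_len(n)),
    serving_size_g = runif(n, 20, 200),
    cho_g = runif(n, 1, 15), ptn_g = runif(n, 0.5, 10),
    fat_g = runif(n, 0.2, 8), stringsAsFactors = FALSE))
  lo <- round(runif(n, 0, 2), 1)
  cfg <- study_config("rand_small", c(cho = 50, ptn = 20, fat = 30),
                      data.frame(group_id = tab$group_id,
                                 min_servings = lo,
                                 max_servings = lo + 10,
                                 stringsAsFactors = FALSE))
  e <- serving_energy_kj(tab)
  eer <- sum(e * lo) * runif(1, 1.05, 1.6) + runif(1, 300, 1500)
  list(tab = tab, cfg = cfg, eer = eer, lower = lo, upper = lo + 10)
}

# largest change in distance from moving the grid optimum by one grid
# increment in a single coordinate: the resolution bound for
# solver-vs-oracle agreement
grid_step_bound <- function(inst, bf, grid) {
  x <- bf$prescription
  mx <- 0
  for (i in seq_along(x)) {
    for (s in c(-grid, grid)) {
      y <- x
      y[i] <- y[i] + s
      if (y[i] < 0) next
      tot <- diet_totals(y, inst$tab)
      if (!tot$defined) next
      mx <- max(mx, abs(macro_distance(tot, inst$cfg$targets) -
                          bf$distance))
    }
  }
  mx
}

# minimal two-group table used across I/O tests
tiny_table_csv <- function(path) {
  writeLines(c("group_id,name,serving_size_g,cho_g,ptn_g,fat_g",
               "veg,Vegetables,75,3,2,0.3",
               "grains,Grains,40,15,3,1"), path)
  path
}

make_items <- function(group_id, cho, ptn = cho, fat = cho) {
  food_items(data.frame(
    item_id = paste0(group_id, "_", seq_along(cho)),
    group_id = group_id,
    cho_g_100g = cho, ptn_g_100g = ptn, fat_g_100g = fat,
    stringsAsFactors = FALSE))
}
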