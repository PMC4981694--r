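#' Seeded synthetic fixtures
#'
#' The production tool drew on a national food composition database and
#' pooled baseline intake data from completed trials; neither is
#' published. These generators emulate their shape — food groups with
#' representative per-serving macronutrient profiles, item-level data with
#' controlled within-group variation, and participant rosters spanning the
#' trial energy range — so every stage of the pipeline is testable without
#' any download. Values are plausible for the food groups named, but they
#' are fixtures, not measurements.
#'
#' @name synthetic
NULL

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Specification for synthetic fixture generation
#'
#' @param preset `"realistic"` (a 13-group roster mirroring a trial
#'   constraint set) or `"exact"` (the 3-group pure-macronutrient table of
#'   [pure_macro_table()], on which the solver provably attains zero
#'   distance).
#' @param items_per_group item-level rows per group.
#' @param cv_target within-group coefficient of variation of each
#'   macronutrient across items, percent; realized exactly (sample CV) by
#'   affine standardization of multiplicative noise.
#' @param n_participants roster size.
#' @param age_range,height_range participant ranges (years, cm).
#' @param eer_range_kj range of EERs (kJ/day, after the 1.6 activity
#'   factor) that the roster must span.
#' @param sexes sexes to draw participants from.
#' @param seed integer seed; fixed seed gives byte-identical fixtures.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(preset = "realistic", items_per_group = 8,
                         cv_target = 10, n_participants = 12,
                         age_range = c(25, 80),
                         height_range = c(145, 195),
                         eer_range_kj = c(4800, 10200),
                         sexes = c("female", "male"), seed = 1L) {
  sexes <- match.arg(sexes, c("female", "male"), several.ok = TRUE)
  preset <- match.arg(preset, c("realistic", "exact"))
  if (!is.finite(cv_target) || cv_target < 0) {
    stop("cv_target must be >= 0", call. = FALSE)
  }
  if (items_per_group < 1) stop("items_per_group must be >= 1",
                                call. = FALSE)
  if (n_participants < 1) stop("n_participants must be >= 1",
                               call. = FALSE)
  if (diff(age_range) < 0 || diff(height_range) < 0 ||
      diff(eer_range_kj) < 0) {
    stop("ranges must be non-decreasing", call. = FALSE)
  }
  structure(list(preset = preset, items_per_group = items_per_group,
                 cv_target = cv_target, n_participants = n_participants,
                 age_range = age_range, height_range = height_range,
                 eer_range_kj = eer_range_kj, sexes = sexes,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# per-serving archetype means for the realistic roster
.realistic_roster <- function() {
  data.frame(
    group_id = c("vegetables", "whole_grains", "fruits", "sugar",
                 "milk_yoghurt_lowfat", "milk_yoghurt_whole",
                 "soy_milk_whole", "lean_meat", "cheese", "eggs",
                 "oily_fish", "mufa", "pufa"),
    name = c("Vegetables", "Whole grains", "Fruits", "Sugar",
             "Milk/yoghurt (low fat)", "Milk/yoghurt (whole)",
             "Soy milk (whole)", "Lean meat", "Cheese (reduced fat)",
             "Eggs", "Oily fish", "MUFA products", "PUFA products"),
    serving_size_g = c(75, 40, 150, 5, 250, 250, 250, 30, 30, 60, 30, 5,
                       5),
    cho_g = c(3, 15, 15, 5, 12, 12, 9, 0, 0.3, 0.3, 0, 0, 0),
    ptn_g = c(2, 3, 1, 0, 9, 8, 8, 7, 7.5, 6.3, 7, 0, 0),
    fat_g = c(0.3, 1, 0.3, 0, 3, 9, 8, 1.5, 7.5, 5.3, 3, 5, 5),
    weekly_unit_g = c(NA, NA, NA, NA, NA, NA, NA, NA, 30, 60, 30, NA,
                      NA),
    stringsAsFactors = FALSE
  )
}

#' Pure-macronutrient food table
#'
#' Three groups each delivering exactly one macronutrient (10 g
#' carbohydrate, 10 g protein or 5 g fat per serving). On this table any
#' macronutrient split is achievable exactly, so the solver's optimum is
#' known analytically: for targets (50, 20, 30) and an energy cap E the
#' energy-maximizing zero-distance prescription is
#' (0.50 E / 170, 0.20 E / 170, 0.30 E / 180) servings.
#'
#' @return a [food_table()].
#' @export
pure_macro_table <- function() {
  food_table(data.frame(
    group_id = c("cho_pure", "ptn_pure", "fat_pure"),
    name = c("Pure carbohydrate", "Pure protein", "Pure fat"),
    serving_size_g = c(50, 40, 6),
    cho_g = c(10, 0, 0),
    ptn_g = c(0, 10, 0),
    fat_g = c(0, 0, 5),
    stringsAsFactors = FALSE
  ))
}

#' @rdname pure_macro_table
#' @return `pure_macro_config()`: a [study_config()] with all minima at
#'   zero and the 50/20/30 targets.
#' @export
pure_macro_config <- function() {
  study_config("pure_macro", c(cho = 50, ptn = 20, fat = 30),
               data.frame(group_id = c("cho_pure", "ptn_pure",
                                       "fat_pure"),
                          min_servings = 0, stringsAsFactors = FALSE))
}

# rescale positive values so the sample CV (n-1 denominator) equals
# cv_pct exactly while keeping the sample mean
.force_cv <- function(v, mean_target, cv_pct) {
  n <- length(v)
  if (n == 1 || cv_pct == 0 || mean_target == 0) {
    return(rep(mean_target, n))
  }
  u <- v / mean(v) - 1
  s0 <- stats::sd(u)
  if (s0 == 0) u <- seq(-1, 1, length.out = n) * 0.5
  s0 <- stats::sd(u)
  a <- (cv_pct / 100) / s0
  out <- mean_target * (1 + a * (u - mean(u)))
  if (any(out < 0)) {
    # compress the spread symmetrically until positive (rare, high CV)
    out <- pmax(out, 0)
    out <- .force_cv(out + mean_target * 0.01, mean_target, cv_pct)
  }
  out
}

#' Generate a synthetic food table and item collection
#'
#' Group per-serving profiles are the archetype means perturbed by
#' multiplicative log-normal noise (sd 5 percent); item-level per-100 g
#' values are drawn around each group profile and then standardized so the
#' sample CV of every macronutrient with a nonzero mean equals
#' `cv_target` exactly. The `"exact"` preset returns the deterministic
#' [pure_macro_table()] with items at zero spread.
#'
#' @param spec a [fixture_spec()].
#' @return list: `table` (a [food_table()]) and `items` (a
#'   `food_items` data.frame).
#' @export
generate_food_table <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_seed(spec$seed, {
    if (spec$preset == "exact") {
      tab <- pure_macro_table()
      cv <- 0
    } else {
      roster <- .realistic_roster()
      noise <- matrix(stats::rlnorm(nrow(roster) * 3, 0, 0.05),
                      ncol = 3)
      tab <- roster
      tab$cho_g <- roster$cho_g * noise[, 1]
      tab$ptn_g <- roster$ptn_g * noise[, 2]
      tab$fat_g <- roster$fat_g * noise[, 3]
      tab <- food_table(tab)
      cv <- spec$cv_target
    }
    m <- spec$items_per_group
    items <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
      per100 <- c(cho = tab$cho_g[i], ptn = tab$ptn_g[i],
                  fat = tab$fat_g[i]) / tab$serving_size_g[i] * 100
      raw <- vapply(per100, function(mu) {
        if (mu == 0) return(rep(0, m))
        .force_cv(mu * stats::rlnorm(m, 0, cv / 100 + 1e-3), mu, cv)
      }, numeric(m))
      if (m == 1) raw <- matrix(raw, nrow = 1)
      data.frame(item_id = sprintf("%s_%02d", tab$group_id[i],
                                   seq_len(m)),
                 group_id = tab$group_id[i],
                 cho_g_100g = raw[, 1], ptn_g_100g = raw[, 2],
                 fat_g_100g = raw[, 3], stringsAsFactors = FALSE)
    }))
    list(table = tab, items = food_items(items, table = tab))
  })
}

#' Generate a participant roster spanning the trial energy range
#'
#' Participants are constructed so that, after the default 1.6 activity
#' factor, their EERs cover `eer_range_kj` evenly — every 500-kJ
#' comparison band between 5000 and 10,000 kJ is hit by the default
#' spec. Sex, age and height are drawn at random; weight is then solved
#' from the REE equation to land each participant on the intended energy
#' level (clipped to 35-140 kg, re-drawing height when the clip binds).
#'
#' @param spec a [fixture_spec()].
#' @param pa_factor activity factor used to map target EERs back to REE.
#' @return data.frame roster (`participant_id,sex,age_y,height_cm,
#'   weight_kg,activity_label`).
#' @export
generate_participants <- function(spec, pa_factor = 1.6) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_participants
  .with_seed(spec$seed + 1L, {
    eer_kj <- if (n == 1) {
      mean(spec$eer_range_kj)
    } else {
      seq(spec$eer_range_kj[1], spec$eer_range_kj[2], length.out = n)
    }
    ree_kcal <- eer_kj / pa_factor / KJ_PER_KCAL
    sex <- sample(spec$sexes, n, replace = TRUE)
    age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
    height <- stats::runif(n, spec$height_range[1], spec$height_range[2])
    solve_weight <- function(i) {
      intercept <- if (sex[i] == "female") -161 else 5
      (ree_kcal[i] - 6.25 * height[i] + 4.92 * age[i] - intercept) / 9.99
    }
    weight <- vapply(seq_len(n), solve_weight, 1)
    for (i in which(weight < 30 | weight > 150)) {
      # push anthropometry toward the target: small, older stature for
      # low energy levels; tall, younger for high ones
      low <- weight[i] < 30
      height[i] <- if (low) spec$height_range[1] else spec$height_range[2]
      age[i] <- if (low) spec$age_range[2] else spec$age_range[1]
      if (low && "female" %in% spec$sexes) sex[i] <- "female"
      if (!low && "male" %in% spec$sexes) sex[i] <- "male"
      weight[i] <- min(max(solve_weight(i), 30), 150)
    }
    data.frame(participant_id = sprintf("P%03d", seq_len(n)),
               sex = sex, age_y = round(age, 1),
               height_cm = round(height, 1),
               weight_kg = round(weight, 2),
               activity_label = "light", stringsAsFactors = FALSE)
  })
}

#' Write a full fixture set to disk
#'
#' Emits `foods.csv`, `items.csv`, `participants.csv` and `study.yaml`
#' (the built-in default configuration) into `dir`, the files every other
#' subcommand consumes.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return named character vector of the paths written, invisibly.
#' @export
write_fixtures <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fx <- generate_food_table(spec)
  roster <- generate_participants(spec)
  paths <- c(foods = file.path(dir, "foods.csv"),
             items = file.path(dir, "items.csv"),
             participants = file.path(dir, "participants.csv"),
             study = file.path(dir, "study.yaml"))
  write_food_table(fx$table, paths["foods"])
  utils::write.csv(as.data.frame(fx$items), paths["items"],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(roster, paths["participants"], row.names = FALSE,
                   quote = FALSE)
  cfg <- if (spec$preset == "exact") pure_macro_config() else
    study_config_table1()
  write_study_config(cfg, paths["study"])
  invisible(paths)
}
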