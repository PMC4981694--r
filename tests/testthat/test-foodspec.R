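test_that("food table CSV parses per-serving profiles and round-trips", {
  path <- tiny_table_csv(withr::local_tempfile(fileext = ".csv"))
  tab <- load_food_table(path)
  expect_s3_class(tab, "food_table")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$cho_g[tab$group_id == "veg"], 3)
  expect_equal(tab$serving_size_g[tab$group_id == "grains"], 40)

  out <- withr::local_tempfile(fileext = ".csv")
  write_food_table(tab, out)
  expect_equal(load_food_table(out), tab)
  # and the serialized bytes themselves are stable across a second pass
  out2 <- withr::local_tempfile(fileext = ".csv")
  write_food_table(load_food_table(out), out2)
  expect_identical(readLines(out), readLines(out2))
})

test_that("header-only table loads as empty without error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("group_id,name,serving_size_g,cho_g,ptn_g,fat_g", path)
  tab <- load_food_table(path)
  expect_equal(nrow(tab), 0)
})

test_that("schema and validation errors name the offending column/row", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("group_id,name,serving_size_g,cho_g,ptn_g",
               "veg,Vegetables,75,3,2"), path)
  expect_error(load_food_table(path), "fat_g")

  writeLines(c("group_id,name,serving_size_g,cho_g,ptn_g,fat_g",
               "veg,Vegetables,75,-1,2,0.3"), path)
  expect_error(load_food_table(path), "cho_g.*row 1")

  writeLines(c("group_id,name,serving_size_g,cho_g,ptn_g,fat_g",
               "veg,Vegetables,75,3,2,0.3",
               "veg,Vegetables 2,75,3,2,0.3"), path)
  expect_error(load_food_table(path), "duplicate group_id")
})

test_that("fatty-acid subclasses may not exceed total fat", {
  df <- data.frame(group_id = "g", name = "g", serving_size_g = 30,
                   cho_g = 0, ptn_g = 0, fat_g = 5,
                   sat_g = 3, mufa_g = 2, pufa_g = 1)
  expect_error(food_table(df), "subclasses exceed total fat")
  df$pufa_g <- 0
  expect_s3_class(food_table(df), "food_table")
})

test_that("group statistics match hand arithmetic (n-1 denominator)", {
  items <- make_items("g1", cho = c(10, 12, 14))
  st <- group_statistics(items, "cho")
  expect_equal(st$mean, 12)
  expect_equal(st$sd, 2)
  expect_equal(st$range, 4)
  expect_equal(st$cv, 2 / 12 * 100, tolerance = 1e-12)

  st0 <- group_statistics(make_items("g1", cho = c(8, 8, 8)), "cho")
  expect_equal(st0$sd, 0)
  expect_equal(st0$cv, 0)

  empty <- food_items(data.frame(item_id = character(),
                                 group_id = character(),
                                 cho_g_100g = numeric(),
                                 ptn_g_100g = numeric(),
                                 fat_g_100g = numeric()))
  expect_error(group_statistics(empty), "no items")
})

test_that("CV is invariant under positive scaling of item values", {
  base <- c(10, 12, 14)
  cv0 <- group_statistics(make_items("g", base), "cho")$cv
  expect_equal(cv0, 16.6667, tolerance = 1e-4)
  set.seed(42)
  for (s in runif(10, 0.01, 50)) {
    cv_s <- group_statistics(make_items("g", base * s), "cho")$cv
    expect_equal(cv_s, cv0, tolerance = 1e-9)
  }
})

test_that("range is zero exactly when all items are equal", {
  set.seed(7)
  for (i in 1:20) {
    v <- round(runif(5, 0, 20), sample(0:2, 1))
    st <- group_statistics(make_items("g", v), "cho")
    expect_equal(st$range == 0, length(unique(v)) == 1)
    expect_gte(st$range, 0)
    expect_gte(st$sd, 0)
  }
})

test_that("CV screen uses a strict 15 percent boundary", {
  st <- group_statistics(make_items("g1", c(10, 12, 14)), "cho")
  fl <- flag_high_variation(st)
  expect_false(fl$acceptable)          # cv 16.67
  expect_equal(fl$flag, "high_variation")

  st$cv <- 0
  expect_true(flag_high_variation(st)$acceptable)

  st$cv <- 15          # printed rule is strict '<'
  expect_false(flag_high_variation(st)$acceptable)
  st$cv <- 14.999
  expect_true(flag_high_variation(st)$acceptable)
})

test_that("zero-mean groups are routed to manual review, not flagged", {
  st <- group_statistics(make_items("g1", cho = c(0, 0, 0)), "cho")
  expect_false(st$cv_defined)
  fl <- flag_high_variation(st)
  expect_true(is.na(fl$acceptable))
  expect_equal(fl$flag, "needs_review")
})

test_that("primary-source ranking returns the strict <cutoff prefix", {
  items <- food_items(data.frame(
    item_id = paste0("i", 1:4),
    group_id = c("g1", "g2", "g3", "g4"),
    cho_g_100g = c(50, 20, 20, 10), ptn_g_100g = 0, fat_g_100g = 0))
  rk <- rank_primary_sources(items, "cho", cutoff = 0.75)
  expect_equal(rk$primary, c("g1", "g2"))
  expect_equal(rk$ranking$cumulative[2], 0.70, tolerance = 1e-12)

  items2 <- make_items("g1", cho = 5)
  expect_warning(rk2 <- rank_primary_sources(items2, "cho"),
                 "prefix is empty")
  expect_length(rk2$primary, 0)

  items3 <- food_items(data.frame(
    item_id = c("a", "b"), group_id = c("g1", "g2"),
    cho_g_100g = c(74, 26), ptn_g_100g = 0, fat_g_100g = 0))
  expect_equal(rank_primary_sources(items3, "cho")$primary, "g1")

  expect_error(rank_primary_sources(make_items("g1", cho = 0), "cho"),
               "zero")
})

test_that("per-100 g item values convert to per-serving by serving mass", {
  tab <- food_table(data.frame(group_id = "g", name = "g",
                               serving_size_g = 40, cho_g = 6,
                               ptn_g = 1.2, fat_g = 0.4))
  items <- make_items("g", cho = c(15, 16))
  conv <- items_per_serving(items, tab)
  expect_equal(conv$cho_g_serv, c(6, 6.4))
})
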