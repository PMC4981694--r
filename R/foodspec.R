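#' Food composition tables and group-level statistics
#'
#' A food table holds one row per food group: the mass of a standard serving
#' and the grams of carbohydrate, protein and fat it delivers. Optional
#' columns carry the fatty-acid subclasses (saturated, monounsaturated,
#' polyunsaturated) and a "practical portion" mass used for weekly-frequency
#' reporting of infrequent groups (e.g. a 90 g fish portion counted in
#' 0.43 servings/day).
#'
#' @name foodspec
NULL

FOOD_TABLE_REQUIRED <- c("group_id", "name", "serving_size_g",
                         "cho_g", "ptn_g", "fat_g")
FOOD_TABLE_OPTIONAL <- c("sat_g", "mufa_g", "pufa_g", "weekly_unit_g")

NUTRIENT_COLS <- c("cho_g", "ptn_g", "fat_g", "sat_g", "mufa_g", "pufa_g")

#' Construct and validate a food table
#'
#' @param df data.frame with columns `group_id`, `name`, `serving_size_g`,
#'   `cho_g`, `ptn_g`, `fat_g` (grams per serving) and optionally `sat_g`,
#'   `mufa_g`, `pufa_g`, `weekly_unit_g`.
#' @param fat_tol tolerance allowed for the sum of fatty-acid subclasses
#'   over total fat, grams.
#' @return the validated data.frame with class `food_table`.
#' @export
food_table <- function(df, fat_tol = 1e-6) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(FOOD_TABLE_REQUIRED, names(df))
  if (length(missing_cols) > 0) {
    stop("food table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$group_id <- as.character(df$group_id)
  df$name <- as.character(df$name)
  num_cols <- intersect(c("serving_size_g", NUTRIENT_COLS, "weekly_unit_g"),
                        names(df))
  for (cl in num_cols) df[[cl]] <- as.numeric(df[[cl]])

  if (nrow(df) > 0) {
    dup <- df$group_id[duplicated(df$group_id)]
    if (length(dup) > 0) {
      stop("duplicate group_id: ", paste(unique(dup), collapse = ", "),
           call. = FALSE)
    }
    if (any(!is.finite(df$serving_size_g)) || any(df$serving_size_g <= 0)) {
      bad <- which(!is.finite(df$serving_size_g) | df$serving_size_g <= 0)
      stop("serving_size_g must be > 0 (row ", bad[1], ")", call. = FALSE)
    }
    for (cl in intersect(NUTRIENT_COLS, names(df))) {
      bad <- which(!is.na(df[[cl]]) & df[[cl]] < 0)
      if (length(bad) > 0) {
        stop("negative value in column '", cl, "' at row ", bad[1],
             call. = FALSE)
      }
    }
    if (all(c("sat_g", "mufa_g", "pufa_g") %in% names(df))) {
      sub_sum <- rowSums(df[, c("sat_g", "mufa_g", "pufa_g")])
      bad <- which(!is.na(sub_sum) & sub_sum > df$fat_g + fat_tol)
      if (length(bad) > 0) {
        stop("fatty-acid subclasses exceed total fat at row ", bad[1],
             call. = FALSE)
      }
    }
  }
  class(df) <- c("food_table", "data.frame")
  df
}

#' Read a food table from CSV
#'
#' Expected header: `group_id,name,serving_size_g,cho_g,ptn_g,fat_g`
#' with optional `sat_g,mufa_g,pufa_g,weekly_unit_g`. Nutrients are grams
#' per serving.
#'
#' @param path path to a UTF-8 comma-separated file with a header row.
#' @return a [food_table()].
#' @export
load_food_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  food_table(df)
}

#' Write a food table to CSV
#'
#' Round-trips with [load_food_table()].
#'
#' @param table a [food_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_food_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read item-level composition data from CSV
#'
#' Individual foods belonging to the groups, with nutrients expressed per
#' 100 g (`item_id,group_id,cho_g_100g,ptn_g_100g,fat_g_100g`, optional
#' fatty-acid subclass columns with the same suffix). Used for the
#' within-group homogeneity screen.
#'
#' @param path CSV path.
#' @param table optional [food_table()]; when given, each item's `group_id`
#'   must resolve against it.
#' @return data.frame of items with class `food_items`.
#' @export
load_food_items <- function(path, table = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  food_items(df, table = table)
}

#' @rdname load_food_items
#' @param df data.frame of item rows.
#' @export
food_items <- function(df, table = NULL) {
  required <- c("item_id", "group_id", "cho_g_100g", "ptn_g_100g",
                "fat_g_100g")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("item table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$item_id <- as.character(df$item_id)
  df$group_id <- as.character(df$group_id)
  for (cl in grep("_g_100g$", names(df), value = TRUE)) {
    df[[cl]] <- as.numeric(df[[cl]])
    bad <- which(!is.na(df[[cl]]) & df[[cl]] < 0)
    if (length(bad) > 0) {
      stop("negative value in column '", cl, "' at row ", bad[1],
           call. = FALSE)
    }
  }
  if (!is.null(table)) {
    unknown <- setdiff(unique(df$group_id), table$group_id)
    if (length(unknown) > 0) {
      stop("item group_id not in food table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  class(df) <- c("food_items", "data.frame")
  df
}

#' Convert per-100 g item values to per-serving
#'
#' Applies the group's serving mass: per_serving = per_100g *
#' serving_size_g / 100.
#'
#' @param items a `food_items` data.frame.
#' @param table a [food_table()] supplying `serving_size_g` per group.
#' @return items with additional `*_g_serv` columns.
#' @export
items_per_serving <- function(items, table) {
  idx <- match(items$group_id, table$group_id)
  if (anyNA(idx)) {
    stop("item group_id not in food table: ",
         paste(unique(items$group_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  scale <- table$serving_size_g[idx] / 100
  for (cl in grep("_g_100g$", names(items), value = TRUE)) {
    items[[sub("_100g$", "_serv", cl)]] <- items[[cl]] * scale
  }
  items
}

.nutrient_column <- function(items, nutrient) {
  nutrient <- match.arg(nutrient, c("cho", "ptn", "fat", "sat", "mufa",
                                    "pufa"))
  col <- paste0(nutrient, "_g_100g")
  if (!col %in% names(items)) {
    stop("items carry no data for nutrient '", nutrient, "'", call. = FALSE)
  }
  col
}

#' Within-group nutrient statistics
#'
#' For each food group, the mean, sample standard deviation (n-1
#' denominator), range (max - min) and coefficient of variation
#' (CV = SD/mean x 100) of one nutrient across the group's items. The CV is
#' the homogeneity screen used to decide whether a single representative
#' per-serving profile can stand for the whole group.
#'
#' @param items a `food_items` data.frame (per-100 g values).
#' @param nutrient one of `"cho"`, `"ptn"`, `"fat"`, `"sat"`, `"mufa"`,
#'   `"pufa"`.
#' @return data.frame with one row per group: `group_id`, `nutrient`, `n`,
#'   `mean`, `sd`, `range`, `cv` (percent; `NA` with `cv_defined = FALSE`
#'   when the mean is zero).
#' @export
group_statistics <- function(items, nutrient = "cho") {
  col <- .nutrient_column(items, nutrient)
  if (nrow(items) == 0) stop("no items supplied", call. = FALSE)
  groups <- unique(items$group_id)
  out <- lapply(groups, function(g) {
    v <- items[[col]][items$group_id == g]
    m <- mean(v)
    s <- if (length(v) > 1) stats::sd(v) else 0
    rg <- max(v) - min(v)
    defined <- m > 0
    cv <- if (defined) s / m * 100 else NA_real_
    if (defined && s == 0) cv <- 0
    data.frame(group_id = g, nutrient = nutrient, n = length(v),
               mean = m, sd = s, range = rg, cv = cv,
               cv_defined = defined, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("group_statistics", "data.frame")
  res
}

#' Screen groups against the CV acceptability threshold
#'
#' A group is acceptable when its coefficient of variation is strictly below
#' the threshold (default 15 percent). Groups whose CV is undefined (zero
#' mean) are flagged `"needs_review"` for manual comparison against
#' published exchange lists.
#'
#' @param stats output of [group_statistics()].
#' @param threshold CV threshold in percent; the boundary is exclusive.
#' @return `stats` with columns `acceptable` (logical, `NA` when CV
#'   undefined) and `flag` (`"acceptable"`, `"high_variation"`,
#'   `"needs_review"`).
#' @export
flag_high_variation <- function(stats, threshold = 15) {
  stopifnot(is.data.frame(stats), "cv" %in% names(stats))
  defined <- if ("cv_defined" %in% names(stats)) stats$cv_defined else
    !is.na(stats$cv)
  acceptable <- ifelse(defined, stats$cv < threshold, NA)
  stats$acceptable <- acceptable
  stats$flag <- ifelse(!defined, "needs_review",
                       ifelse(acceptable, "acceptable", "high_variation"))
  stats
}

#' Rank food groups as primary sources of a nutrient
#'
#' Groups are ordered by descending share of the total amount of the
#' nutrient across all items; the "primary sources" are the shortest prefix
#' of that ordering whose cumulative share stays strictly below `cutoff`
#' (default 75 percent).
#'
#' @param items a `food_items` data.frame.
#' @param nutrient nutrient selector, as in [group_statistics()].
#' @param cutoff cumulative-share cutoff as a fraction.
#' @return list with `ranking` (data.frame: `group_id`, `total`, `share`,
#'   `cumulative`, `primary`) and `primary` (character vector of group ids
#'   in the prefix).
#' @export
rank_primary_sources <- function(items, nutrient = "cho", cutoff = 0.75) {
  col <- .nutrient_column(items, nutrient)
  totals <- tapply(items[[col]], items$group_id, sum)
  grand <- sum(totals)
  if (!is.finite(grand) || grand <= 0) {
    stop("total contribution of '", nutrient, "' is zero", call. = FALSE)
  }
  ord <- order(totals, decreasing = TRUE)
  ranking <- data.frame(group_id = names(totals)[ord],
                        total = as.numeric(totals[ord]),
                        stringsAsFactors = FALSE)
  ranking$share <- ranking$total / grand
  ranking$cumulative <- cumsum(ranking$share)
  ranking$primary <- ranking$cumulative < cutoff
  primary <- ranking$group_id[ranking$primary]
  if (length(primary) == 0) {
    warning("no group falls below the cumulative cutoff of ", cutoff,
            "; primary prefix is empty", call. = FALSE)
  }
  list(ranking = ranking, primary = primary)
}

#' Per-serving energy of each food group
#'
#' @param table a [food_table()].
#' @return numeric vector of kJ per serving, named by `group_id`.
#' @export
serving_energy_kj <- function(table) {
  e <- KJ_PER_G["cho"] * table$cho_g + KJ_PER_G["ptn"] * table$ptn_g +
    KJ_PER_G["fat"] * table$fat_g
  stats::setNames(as.numeric(e), table$group_id)
}
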