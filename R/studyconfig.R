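#' Study configuration: macronutrient targets and serving constraints
#'
#' A study configuration carries the trial-level macronutrient energy
#' targets (percent of total energy from carbohydrate/protein/fat, summing
#' to 100) and one serving constraint per food group: a daily minimum
#' `min_servings` (the target serving T_i, the lower bound the solver must
#' respect), an optional maximum, and the serving granularity used when
#' rounding prescriptions for practical use.
#'
#' @name studyconfig
NULL

CONSTRAINT_COLS <- c("group_id", "min_servings", "max_servings",
                     "strict_max", "increment", "integral")

.constraint_frame <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"group_id" %in% names(df)) {
    stop("constraints need a group_id column", call. = FALSE)
  }
  if (is.null(df$min_servings)) df$min_servings <- 0
  if (is.null(df$max_servings)) df$max_servings <- NA_real_
  if (is.null(df$strict_max)) df$strict_max <- FALSE
  if (is.null(df$increment)) df$increment <- 0.5
  if (is.null(df$integral)) df$integral <- FALSE
  unknown <- setdiff(names(df), CONSTRAINT_COLS)
  if (length(unknown) > 0) {
    stop("unknown constraint field: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  df$group_id <- as.character(df$group_id)
  df$min_servings <- as.numeric(df$min_servings)
  df$max_servings <- as.numeric(df$max_servings)
  df$strict_max <- as.logical(df$strict_max)
  df$strict_max[is.na(df$strict_max)] <- FALSE
  df$increment <- as.numeric(df$increment)
  df$increment[is.na(df$increment)] <- 0.5
  df$integral <- as.logical(df$integral)
  df$integral[is.na(df$integral)] <- FALSE
  df$min_servings[is.na(df$min_servings)] <- 0
  if (any(df$min_servings < 0)) stop("min_servings must be >= 0",
                                     call. = FALSE)
  if (any(df$increment <= 0)) stop("increment must be > 0", call. = FALSE)
  bad <- which(!is.na(df$max_servings) &
                 df$max_servings < df$min_servings)
  if (length(bad) > 0) {
    stop("max_servings < min_servings for group ", df$group_id[bad[1]],
         call. = FALSE)
  }
  if (anyDuplicated(df$group_id)) {
    stop("duplicate constraint for group ",
         df$group_id[duplicated(df$group_id)][1], call. = FALSE)
  }
  df[, CONSTRAINT_COLS]
}

#' Construct a study configuration
#'
#' @param study_id short study label.
#' @param targets numeric vector or list with elements `cho`, `ptn`, `fat`:
#'   percent of total energy, each in (0, 100), summing to 100 (within
#'   0.01).
#' @param constraints data.frame (or list of lists) with columns
#'   `group_id`, `min_servings`, and optionally `max_servings`,
#'   `strict_max` (the printed bound is exclusive; the solver uses
#'   `max - increment`), `increment` (rounding grid, default 0.5 servings)
#'   and `integral` (opt-in integer-servings reading).
#' @param energy_rule only `"at_most_eer"` is defined: total prescribed
#'   energy may not exceed the participant's EER.
#' @return object of class `study_config`.
#' @export
study_config <- function(study_id, targets, constraints,
                         energy_rule = "at_most_eer") {
  targets <- unlist(targets)
  if (!all(MACROS %in% names(targets))) {
    stop("targets must name cho, ptn and fat", call. = FALSE)
  }
  targets <- as.numeric(targets[MACROS])
  names(targets) <- MACROS
  if (any(targets <= 0) || any(targets >= 100)) {
    stop("each target percentage must lie in (0, 100)", call. = FALSE)
  }
  if (abs(sum(targets) - 100) > 0.01) {
    stop("target percentages must sum to 100 (got ", sum(targets), ")",
         call. = FALSE)
  }
  if (is.list(constraints) && !is.data.frame(constraints)) {
    constraints <- do.call(rbind, lapply(constraints, function(x) {
      x <- as.list(x)
      known <- intersect(names(x), CONSTRAINT_COLS)
      unknown <- setdiff(names(x), CONSTRAINT_COLS)
      if (length(unknown) > 0) {
        stop("unknown constraint field: ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
      for (f in setdiff(CONSTRAINT_COLS, known)) x[[f]] <- NA
      as.data.frame(x[CONSTRAINT_COLS], stringsAsFactors = FALSE)
    }))
  }
  energy_rule <- match.arg(energy_rule, "at_most_eer")
  cfg <- list(study_id = as.character(study_id),
              targets = targets,
              constraints = .constraint_frame(constraints),
              energy_rule = energy_rule)
  class(cfg) <- "study_config"
  cfg
}

#' @export
print.study_config <- function(x, ...) {
  cat("Study configuration:", x$study_id, "\n")
  cat(sprintf("  targets: %%CHO %.1f  %%PTN %.1f  %%FAT %.1f\n",
              x$targets["cho"], x$targets["ptn"], x$targets["fat"]))
  cat("  constraints:\n")
  print(x$constraints, row.names = FALSE)
  invisible(x)
}

#' Built-in default study configuration
#'
#' The constraint set used for the partially automated solver comparison:
#' vegetables >= 5, whole grains >= 4, fruits >= 2 and < 4, sugar <= 3,
#' low-fat milk/yoghurt >= 2.5, whole milk and whole soy milk excluded,
#' lean meat >= 3 (30 g servings), cheese/eggs/MUFA/PUFA unconstrained
#' below, oily fish >= 0.43 (one 90 g portion per week counted in
#' 30 g-equivalent daily servings). Targets default to the 50/20/30
#' carbohydrate/protein/fat energy split.
#'
#' @return a [study_config()].
#' @export
study_config_table1 <- function() {
  constraints <- data.frame(
    group_id = c("vegetables", "whole_grains", "fruits", "sugar",
                 "milk_yoghurt_lowfat", "milk_yoghurt_whole",
                 "soy_milk_whole", "lean_meat", "cheese", "eggs",
                 "oily_fish", "mufa", "pufa"),
    min_servings = c(5, 4, 2, 0, 2.5, 0, 0, 3, 0, 0, 0.43, 0, 0),
    max_servings = c(NA, NA, 4, 3, NA, 0, 0, NA, NA, NA, NA, NA, NA),
    strict_max = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                   FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  study_config("table1_default", c(cho = 50, ptn = 20, fat = 30),
               constraints)
}

#' Load a study configuration from a YAML document
#'
#' Top-level keys: `study_id`, `targets` (mapping with `cho`, `ptn`,
#' `fat`), `constraints` (sequence of constraint mappings) and optional
#' `energy_rule`. The name `"table1_default"` resolves to the built-in
#' default of [study_config_table1()].
#'
#' @param path YAML file path, or `"table1_default"`.
#' @return a [study_config()].
#' @export
load_study_config <- function(path) {
  if (identical(path, "table1_default")) return(study_config_table1())
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  allowed <- c("study_id", "targets", "constraints", "energy_rule")
  unknown <- setdiff(names(doc), allowed)
  if (length(unknown) > 0) {
    stop("unknown config field: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(doc$targets) || is.null(doc$constraints)) {
    stop("config must define targets and constraints", call. = FALSE)
  }
  study_config(doc$study_id %||% "unnamed", doc$targets, doc$constraints,
               doc$energy_rule %||% "at_most_eer")
}

#' Serialize a study configuration to YAML
#'
#' Inverse of [load_study_config()]: a config written with this function
#' re-loads to an equal object.
#'
#' @param cfg a [study_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_study_config <- function(cfg, path) {
  cons <- lapply(seq_len(nrow(cfg$constraints)), function(i) {
    row <- as.list(cfg$constraints[i, ])
    if (is.na(row$max_servings)) row$max_servings <- NULL
    row
  })
  doc <- list(study_id = cfg$study_id,
              targets = as.list(cfg$targets),
              constraints = cons,
              energy_rule = cfg$energy_rule)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Apply a per-participant override
#'
#' Removes groups (e.g. meat for a vegetarian participant) and adds or
#' replaces constraints. Pure: the input configuration is untouched, so the
#' study defaults are automatically restored for the next participant.
#'
#' @param cfg a [study_config()].
#' @param removed_groups character vector of group ids to drop.
#' @param constraints data.frame of constraints to add or replace
#'   (matched by `group_id`).
#' @return a new [study_config()].
#' @export
apply_override <- function(cfg, removed_groups = character(),
                           constraints = NULL) {
  stopifnot(inherits(cfg, "study_config"))
  removed_groups <- as.character(removed_groups)
  added <- if (is.null(constraints) || NROW(constraints) == 0) {
    NULL
  } else {
    .constraint_frame(constraints)
  }
  if (!is.null(added) && length(intersect(removed_groups,
                                          added$group_id)) > 0) {
    stop("a removed group may not also appear in added constraints: ",
         paste(intersect(removed_groups, added$group_id), collapse = ", "),
         call. = FALSE)
  }
  missing_rm <- setdiff(removed_groups, cfg$constraints$group_id)
  if (length(missing_rm) > 0) {
    stop("cannot remove unknown group(s): ",
         paste(missing_rm, collapse = ", "), call. = FALSE)
  }
  cons <- cfg$constraints[!cfg$constraints$group_id %in% removed_groups, ,
                          drop = FALSE]
  if (!is.null(added)) {
    cons <- cons[!cons$group_id %in% added$group_id, , drop = FALSE]
    cons <- rbind(cons, added)
  }
  rownames(cons) <- NULL
  study_config(cfg$study_id, cfg$targets, cons, cfg$energy_rule)
}

#' Relax constraints for high-energy models
#'
#' For participants whose EER is at least 8500 kJ/day the default
#' constraint set is adjusted: the lean-meat minimum rises to 5 servings
#' and the sugar cap is dropped. Below the threshold the configuration is
#' returned unchanged. The threshold is inclusive.
#'
#' @param cfg a [study_config()].
#' @param eer_kj participant EER in kJ/day, > 0.
#' @param threshold_kj adjustment threshold, kJ/day.
#' @return a [study_config()] (new object when adjusted).
#' @export
high_energy_adjustment <- function(cfg, eer_kj, threshold_kj = 8500) {
  stopifnot(inherits(cfg, "study_config"))
  if (!is.finite(eer_kj) || eer_kj <= 0) {
    stop("eer_kj must be > 0", call. = FALSE)
  }
  if (eer_kj < threshold_kj) return(cfg)
  cons <- cfg$constraints
  if ("lean_meat" %in% cons$group_id) {
    i <- cons$group_id == "lean_meat"
    cons$min_servings[i] <- pmax(cons$min_servings[i], 5)
  }
  if ("sugar" %in% cons$group_id) {
    i <- cons$group_id == "sugar"
    cons$max_servings[i] <- NA_real_
    cons$strict_max[i] <- FALSE
  }
  study_config(cfg$study_id, cfg$targets, cons, cfg$energy_rule)
}
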