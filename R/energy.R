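#' Resting energy expenditure (Mifflin-type equations)
#'
#' REE in kcal/day from weight (kg), height (cm), age (years) and sex:
#' females 9.99 w + 6.25 h - 4.92 a - 161, males 9.99 w + 6.25 h -
#' 4.92 a + 5. At matched anthropometry the two differ by exactly 166 kcal
#' (the intercept gap).
#'
#' @param sex `"female"` or `"male"` (vectorised).
#' @param age_y age in years, > 0.
#' @param height_cm height in centimetres, > 0.
#' @param weight_kg weight in kilograms, > 0.
#' @return REE in kcal/day.
#' @examples
#' resting_energy_expenditure("female", 30, 165, 60)  # 1322.05
#' @export
resting_energy_expenditure <- function(sex, age_y, height_cm, weight_kg) {
  sex <- match.arg(tolower(as.character(sex)), c("female", "male"),
                   several.ok = TRUE)
  if (any(!is.finite(age_y)) || any(age_y <= 0)) {
    stop("age_y must be > 0", call. = FALSE)
  }
  if (any(!is.finite(height_cm)) || any(height_cm <= 0)) {
    stop("height_cm must be > 0", call. = FALSE)
  }
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0)) {
    stop("weight_kg must be > 0", call. = FALSE)
  }
  base <- 9.99 * weight_kg + 6.25 * height_cm - 4.92 * age_y
  base + ifelse(sex == "female", -161, 5)
}

#' Standard physical-activity factor menu
#'
#' Dimensionless multipliers applied to REE; the trial default is 1.6
#' ("light activity").
#'
#' @return named numeric vector of PA factors.
#' @export
activity_factors <- function() {
  c(sedentary = 1.2, light = 1.6, moderate = 1.75, active = 1.85,
    very_active = 1.9)
}

#' Estimated energy requirement
#'
#' EER = REE x PA, reported in both kcal/day and kJ/day
#' (1 kcal = 4.184 kJ). The full-precision kJ value is what the serving
#' solver consumes as its energy cap.
#'
#' @inheritParams resting_energy_expenditure
#' @param pa_factor physical-activity multiplier, >= 1; or a label from
#'   [activity_factors()].
#' @return data.frame with `ree_kcal`, `ree_kj`, `eer_kcal`, `eer_kj`,
#'   `pa_factor`.
#' @examples
#' estimated_energy_requirement("female", 30, 165, 60, 1.6)
#' @export
estimated_energy_requirement <- function(sex, age_y, height_cm, weight_kg,
                                         pa_factor = 1.6) {
  if (is.character(pa_factor)) {
    menu <- activity_factors()
    if (!all(pa_factor %in% names(menu))) {
      stop("unknown activity label: ",
           paste(setdiff(pa_factor, names(menu)), collapse = ", "),
           call. = FALSE)
    }
    pa_factor <- unname(menu[pa_factor])
  }
  if (any(!is.finite(pa_factor)) || any(pa_factor < 1)) {
    stop("pa_factor must be >= 1", call. = FALSE)
  }
  ree <- resting_energy_expenditure(sex, age_y, height_cm, weight_kg)
  data.frame(ree_kcal = ree,
             ree_kj = ree * KJ_PER_KCAL,
             eer_kcal = ree * pa_factor,
             eer_kj = ree * pa_factor * KJ_PER_KCAL,
             pa_factor = pa_factor)
}

#' Read a participant roster from CSV
#'
#' Header `participant_id,sex,age_y,height_cm,weight_kg` with an optional
#' `activity_label` column (defaulting to `"light"`, PA 1.6).
#'
#' @param path CSV path.
#' @return data.frame of validated participants.
#' @export
load_participants <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "sex", "age_y", "height_cm", "weight_kg")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("participant roster is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$sex <- tolower(as.character(df$sex))
  bad <- which(!df$sex %in% c("female", "male"))
  if (length(bad) > 0) {
    stop("unrecognised sex at row ", bad[1], call. = FALSE)
  }
  if (nrow(df) > 0) {
    # reuse the REE validators for the anthropometry range checks
    invisible(resting_energy_expenditure(df$sex, df$age_y, df$height_cm,
                                         df$weight_kg))
  }
  if (!"activity_label" %in% names(df)) df$activity_label <- "light"
  df$activity_label[is.na(df$activity_label) | df$activity_label == ""] <-
    "light"
  df
}
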