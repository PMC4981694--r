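#' Percent difference against a reference prescription
#'
#' |x - ref| / ref * 100, rounded to the nearest integer with halves
#' rounded away from zero — the validation metric used to compare
#' modeling methods against the reference (manual, experienced-dietitian)
#' prescriptions. Asymmetric: the denominator is always the reference.
#'
#' @param x servings from the method under comparison.
#' @param ref servings from the reference method, > 0 (vectorised;
#'   elements with `ref == 0` yield `NA`).
#' @return integer percent difference (`NA` where undefined).
#' @examples
#' percent_difference(7.00, 5.00)  # 40
#' percent_difference(3, 1)        # 200
#' @export
percent_difference <- function(x, ref) {
  stopifnot(is.numeric(x), is.numeric(ref), length(x) == length(ref) ||
              length(x) == 1 || length(ref) == 1)
  raw <- abs(x - ref) / ref * 100
  out <- .round_half_away(raw)
  out[!is.finite(ref) | ref <= 0] <- NA_real_
  out
}

# round half away from zero (base round() rounds half to even)
.round_half_away <- function(v) {
  sign(v) * floor(abs(v) + 0.5)
}

#' Build a method-versus-reference comparison table
#'
#' One row per (model, energy target, food group): the method's servings,
#' the reference servings, and the integer percent difference. Percent
#' differences are computed on the full-precision servings supplied and
#' rounded only for display.
#'
#' @param methods data.frame with columns `model`, `kj_target`,
#'   `group_id`, `servings`: one prescription row per group per energy
#'   level per method.
#' @param reference data.frame with columns `kj_target`, `group_id`,
#'   `servings` for the reference method.
#' @return data.frame with columns `model`, `kj_target`, `group_id`,
#'   `servings`, `reference_servings`, `pct_diff`. Groups missing from
#'   the reference get `NA` with a warning.
#' @export
compare_models <- function(methods, reference) {
  need_m <- c("model", "kj_target", "group_id", "servings")
  need_r <- c("kj_target", "group_id", "servings")
  if (!all(need_m %in% names(methods))) {
    stop("methods needs columns: ", paste(need_m, collapse = ", "),
         call. = FALSE)
  }
  if (!all(need_r %in% names(reference))) {
    stop("reference needs columns: ", paste(need_r, collapse = ", "),
         call. = FALSE)
  }
  key_m <- paste(methods$kj_target, methods$group_id, sep = "\r")
  key_r <- paste(reference$kj_target, reference$group_id, sep = "\r")
  idx <- match(key_m, key_r)
  out <- data.frame(model = methods$model,
                    kj_target = methods$kj_target,
                    group_id = methods$group_id,
                    servings = methods$servings,
                    reference_servings = reference$servings[idx],
                    stringsAsFactors = FALSE)
  if (anyNA(idx)) {
    warning("group(s) absent from the reference: ",
            paste(unique(methods$group_id[is.na(idx)]), collapse = ", "),
            call. = FALSE)
  }
  out$pct_diff <- ifelse(is.na(out$reference_servings) |
                           out$reference_servings <= 0, NA_real_,
                         percent_difference(out$servings,
                                            out$reference_servings))
  out
}

#' Convert daily servings to weekly practical portions
#'
#' Infrequent food groups (oily fish, eggs, cheese) are prescribed in
#' fractional daily servings counted in small units (e.g. 30 g) but eaten
#' as larger practical portions a few times per week (e.g. a 90 g fish
#' portion): portions/week = servings/day x 7 x unit_g / portion_g.
#'
#' @param servings_per_day daily servings (in counted units).
#' @param unit_g grams per counted unit, > 0.
#' @param portion_g grams per practical portion, > 0.
#' @return portions per week.
#' @examples
#' weekly_frequency(0.43, 30, 90)  # ~1 fish portion/week
#' @export
weekly_frequency <- function(servings_per_day, unit_g, portion_g) {
  if (any(unit_g <= 0)) stop("unit_g must be > 0", call. = FALSE)
  if (any(portion_g <= 0)) stop("portion_g must be > 0", call. = FALSE)
  if (any(servings_per_day < 0)) {
    stop("servings_per_day must be >= 0", call. = FALSE)
  }
  servings_per_day * 7 * unit_g / portion_g
}
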