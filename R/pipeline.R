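#' Run the full modeling pipeline for a participant roster
#'
#' The end-to-end workflow: load/validate inputs, compute each
#' participant's EER, apply the high-energy constraint adjustment where it
#' triggers, solve for the serving prescription, round it to the serving
#' grid, and collect one report row per participant. Infeasible
#' participants are reported with their violating margin and the pipeline
#' continues.
#'
#' @param study a [study_config()] or a path accepted by
#'   [load_study_config()].
#' @param foods a [food_table()] or CSV path.
#' @param participants a roster data.frame or CSV path
#'   (see [load_participants()]).
#' @param seed integer seed forwarded to every solve.
#' @param out_dir optional directory; when given, `report.csv`,
#'   `servings.csv` and `manifest.json` are written there.
#' @param high_energy logical: apply [high_energy_adjustment()] per
#'   participant.
#' @param n_starts solver restarts per participant.
#' @return list of class `pipeline_run`: `report` (one row per
#'   participant: EER, status, distance, energies), `servings` (long
#'   data.frame of continuous and rounded servings), `solutions` (list of
#'   `serving_solution`), `manifest`.
#' @export
run_pipeline <- function(study, foods, participants, seed = 1L,
                         out_dir = NULL, high_energy = TRUE,
                         n_starts = 10L) {
  digests <- list()
  if (is.character(study)) {
    digests$study <- .input_digest(study)
    study <- load_study_config(study)
  }
  if (is.character(foods)) {
    digests$foods <- .input_digest(foods)
    foods <- load_food_table(foods)
  }
  if (is.character(participants)) {
    digests$participants <- .input_digest(participants)
    participants <- load_participants(participants)
  }
  stopifnot(inherits(study, "study_config"),
            inherits(foods, "food_table"),
            is.data.frame(participants))

  menu <- activity_factors()
  rows <- list()
  servings_rows <- list()
  solutions <- list()
  for (i in seq_len(nrow(participants))) {
    p <- participants[i, ]
    pa <- unname(menu[p$activity_label] %||% 1.6)
    if (is.na(pa)) pa <- 1.6
    er <- estimated_energy_requirement(p$sex, p$age_y, p$height_cm,
                                       p$weight_kg, pa)
    cfg_i <- if (high_energy) high_energy_adjustment(study, er$eer_kj)
             else study
    sol <- solve_servings(cfg_i, foods, er$eer_kj,
                          seed = seed + i, n_starts = n_starts)
    solutions[[p$participant_id]] <- sol
    rows[[i]] <- data.frame(
      participant_id = p$participant_id, sex = p$sex,
      eer_kcal = er$eer_kcal, eer_kj = er$eer_kj, pa_factor = pa,
      status = sol$status,
      distance = if (is.null(sol$distance)) NA_real_ else sol$distance,
      energy_kj = if (is.null(sol$totals)) NA_real_ else
        sol$totals$total_energy_kj,
      infeasible_margin_kj = sol$infeasible_margin_kj %||% 0,
      stringsAsFactors = FALSE)
    if (sol$status != "infeasible") {
      servings_rows[[i]] <- data.frame(
        participant_id = p$participant_id,
        group_id = names(sol$prescription),
        servings = as.numeric(sol$prescription),
        rounded = if (is.null(sol$rounded)) NA_real_ else
          as.numeric(sol$rounded$servings[names(sol$prescription)]),
        stringsAsFactors = FALSE)
    }
  }
  report <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(participant_id = character(), sex = character(),
               eer_kcal = numeric(), eer_kj = numeric(),
               pa_factor = numeric(), status = character(),
               distance = numeric(), energy_kj = numeric(),
               infeasible_margin_kj = numeric())
  servings <- if (length(servings_rows) > 0) {
    do.call(rbind, servings_rows)
  } else {
    data.frame(participant_id = character(), group_id = character(),
               servings = numeric(), rounded = numeric())
  }
  manifest <- list(
    tool = "dietmodelr",
    version = as.character(utils::packageVersion("dietmodelr")),
    seed = seed,
    timestamp = format(Sys.time(), tz = "UTC"),
    input_digests = digests,
    study_id = study$study_id,
    targets = as.list(study$targets),
    n_participants = nrow(participants))
  out <- structure(list(report = report, servings = servings,
                        solutions = solutions, manifest = manifest),
                   class = "pipeline_run")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(report, file.path(out_dir, "report.csv"),
                     row.names = FALSE)
    utils::write.csv(servings, file.path(out_dir, "servings.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

.input_digest <- function(path) {
  unname(tools::md5sum(path))
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run:", x$manifest$study_id, "-",
      x$manifest$n_participants, "participant(s)\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}
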