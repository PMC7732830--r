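# Pipeline orchestration: run configuration, participant-level exclusion
# filtering, CSV/YAML I/O, and the end-to-end simulate -> calibrate -> score
# -> exclude -> mediate -> report chain with a reproducibility manifest.

#' Pipeline run configuration
#'
#' @param seed Master seed; every stage derives its randomness from it.
#' @param n_subjects Subjects to simulate before exclusions (default 45,
#'   which with the default planted violators retains 41).
#' @param violators Planted protocol violators passed to [simulate_cohort()]
#'   (default one missing-data, two pain-intolerance, one chance-performance).
#' @param n_boot Bootstrap resamples for the mediation stage. At least 1000
#'   is required for release-quality inference; smaller values are accepted
#'   with a warning for smoke runs.
#' @param moderators Trait moderators to test.
#' @param missing_frac,intolerance_frac Exclusion thresholds: fraction of
#'   missing trials / terminated painful trials above which a subject is
#'   dropped (both 0.5).
#' @param chance_A Session-mean 2-back A at or below which a subject counts
#'   as performing at chance (0.5).
#' @param cohort Optional [cohort_config()] override; its `n_subjects` and
#'   `seed` are replaced by the run-level values.
#' @param out_dir Output directory for [run_pipeline()] (`NULL` = don't write).
#' @return List of class `pb_run_config`.
#' @export
run_config <- function(seed = 1L, n_subjects = 45,
                       violators = c(missing_data = 1L, pain_intolerance = 2L,
                                     chance_performance = 1L),
                       n_boot = 10000, moderators = c("pcs", "stai_t", "ffmq4"),
                       missing_frac = 0.5, intolerance_frac = 0.5,
                       chance_A = 0.5, cohort = NULL, out_dir = NULL) {
  for (f in c(missing_frac, intolerance_frac)) {
    if (!is.numeric(f) || f <= 0 || f > 1) {
      stopf("pb_config_error", "exclusion fractions must lie in (0, 1].")
    }
  }
  if (n_boot < 1000) warn("n_boot < 1000: intervals unstable; use >= 1000 for release runs.")
  base <- cohort %||% cohort_config()
  base$n_subjects <- as.integer(n_subjects)
  base$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 violators = violators, n_boot = n_boot, moderators = moderators,
                 missing_frac = missing_frac, intolerance_frac = intolerance_frac,
                 chance_A = chance_A, cohort = base, out_dir = out_dir),
            class = "pb_run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized top-level keys are the arguments of [run_config()]; unknown
#' keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A `pb_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- setdiff(names(formals(run_config)), "cohort")
  bad <- setdiff(names(y), known)
  if (length(bad)) {
    stopf("pb_config_error", "unknown config key(s): %s.", paste(bad, collapse = ", "))
  }
  if (!is.null(y$violators)) y$violators <- unlist(y$violators)
  do.call(run_config, y)
}

#' Apply the participant-level exclusion criteria
#'
#' Excludes subjects with more than `missing_frac` of trials missing, more
#' than `intolerance_frac` of painful trials terminated, or session-mean
#' 2-back performance at or below `chance_A`. When a subject violates
#' several rules the first matching reason (in that order) is logged.
#'
#' @param subjects Subject table.
#' @param trials Trial table with `missing`/`terminated` flags and `A`.
#' @param config A [run_config()] (or anything with the three thresholds).
#' @return List: `subjects` and `trials` (retained rows only) and
#'   `exclusions`, a tibble of `subject_id` + `reason`.
#' @export
apply_exclusion_criteria <- function(subjects, trials, config = run_config()) {
  check_columns(trials, c("subject_id", "task", "heat", "A"), "trials")
  if (!"missing" %in% names(trials)) trials$missing <- FALSE
  if (!"terminated" %in% names(trials)) trials$terminated <- FALSE
  per <- trials |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      frac_missing = mean(.data$missing),
      frac_intolerant = mean(.data$terminated[.data$heat == "pain"]),
      mean_A_2back = mean(.data$A[.data$task == "2back" & !.data$missing]),
      .groups = "drop") |>
    dplyr::mutate(reason = dplyr::case_when(
      .data$frac_missing > config$missing_frac ~ "missing_data",
      .data$frac_intolerant > config$intolerance_frac ~ "pain_intolerance",
      .data$mean_A_2back <= config$chance_A ~ "chance_performance",
      TRUE ~ NA_character_))
  exclusions <- per |>
    dplyr::filter(!is.na(.data$reason)) |>
    dplyr::select("subject_id", "reason")
  keep <- setdiff(subjects$subject_id, exclusions$subject_id)
  list(subjects = subjects[subjects$subject_id %in% keep, ],
       trials = trials[trials$subject_id %in% keep, ],
       exclusions = exclusions)
}

#' Recompute trial scores from the discrete response counts
#'
#' Adds hit rate `H`, false-alarm rate `F`, the recomputed statistic
#' `A_scored`, and a `below_chance` flag to a trial table.
#'
#' @param trials Trial table with `hits`, `misses`, `false_alarms`,
#'   `correct_rejections`.
#' @return The trial table with scoring columns appended.
#' @export
score_trials <- function(trials) {
  check_columns(trials, c("hits", "misses", "false_alarms", "correct_rejections"),
                "trials")
  trials |>
    dplyr::mutate(
      H = .data$hits / (.data$hits + .data$misses),
      F = .data$false_alarms / (.data$false_alarms + .data$correct_rejections),
      A_scored = compute_A(.data$H, .data$F),
      below_chance = .data$H < .data$F)
}

#' Run the full analysis pipeline
#'
#' Chains simulation, psychophysical calibration, trial scoring, exclusion
#' filtering, both moderated mediation models and the descriptive reports,
#' all deterministically from the configured seed. When `config$out_dir` is
#' set, every stage's table is written as CSV alongside a JSON manifest
#' (config hash, seed, per-stage row counts, exclusion log), so a rerun with
#' the same seed reproduces every file byte for byte.
#'
#' @param config A [run_config()].
#' @return (Invisibly) a list with `cohort`, `curves`, `trials`, `retained`,
#'   `exclusions`, `mediations` (one `pb_mediation` per model), `derived`,
#'   `group_stats`, `table1`, `quartile_slopes`, `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "pb_run_config"))
  cohort <- simulate_cohort(config$cohort, violators = config$violators)
  curves <- calibrate_cohort(cohort$calibration)
  trials <- score_trials(cohort$trials)
  excl <- apply_exclusion_criteria(cohort$subjects, trials, config)

  mediations <- lapply(c("pain_interference", "task_analgesia"), function(m) {
    run_model(excl$trials, m, subjects = excl$subjects,
              moderators = config$moderators, n_boot = config$n_boot,
              seed = derive_seed(config$seed, match(m, c("pain_interference",
                                                         "task_analgesia"))))
  })
  names(mediations) <- c("pain_interference", "task_analgesia")

  derived <- compute_mta_mpi(excl$trials)
  gs <- group_stats(excl$trials, excl$subjects, curves)
  tb1 <- descriptives_table(excl$subjects, curves)
  qs <- purrr::map(config$moderators, function(tr) {
    purrr::map(mediations, function(md) {
      quartile_slopes(md$paths, excl$subjects, tr) |>
        dplyr::mutate(model = md$model, .before = 1)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  mediation_results <- purrr::map(mediations, tidy) |> dplyr::bind_rows()
  manifest <- list(
    package_version = as.character(utils::packageVersion("painbalance")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    n_boot = config$n_boot,
    stage_rows = list(subjects = nrow(cohort$subjects),
                      calibration = nrow(cohort$calibration),
                      trials = nrow(trials),
                      retained_subjects = nrow(excl$subjects),
                      mediation_results = nrow(mediation_results)),
    exclusions = purrr::transpose(as.list(excl$exclusions)))

  result <- list(cohort = cohort, curves = curves, trials = trials,
                 retained = excl$subjects, exclusions = excl$exclusions,
                 mediations = mediations, derived = derived, group_stats = gs,
                 table1 = tb1, quartile_slopes = qs, manifest = manifest)
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  invisible(result)
}

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) readr::write_csv(df, file.path(dir, name))
  w(result$cohort$subjects, "subjects.csv")
  w(result$cohort$calibration, "calibration.csv")
  w(result$trials, "trials.csv")
  w(result$curves, "curves.csv")
  w(result$exclusions, "exclusions.csv")
  w(purrr::map(result$mediations, tidy) |> dplyr::bind_rows(), "mediation_results.csv")
  w(result$derived, "derived_measures.csv")
  w(result$group_stats$contrasts, "group_stats.csv")
  w(result$table1, "table1.csv")
  w(result$quartile_slopes, "quartile_slopes.csv")
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a simulated cohort back from CSV files
#'
#' Round-trip counterpart of the writer used by [run_pipeline()].
#'
#' @param dir Directory containing `subjects.csv`, `calibration.csv`,
#'   `trials.csv`.
#' @return A list of class `pb_cohort` (without the generating config).
#' @export
read_cohort <- function(dir) {
  rd <- function(name) {
    readr::read_csv(file.path(dir, name), show_col_types = FALSE,
                    progress = FALSE)
  }
  structure(list(subjects = rd("subjects.csv"),
                 calibration = rd("calibration.csv"),
                 trials = rd("trials.csv"), config = NULL),
            class = "pb_cohort")
}
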