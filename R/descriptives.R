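# Questionnaire scoring, condition summaries, task-analgesia / pain-
# interference derived measures, group contrasts, and quartile slope
# extraction for the moderator figures.

#' Scoring key for one of the trait questionnaires
#'
#' Reads the packaged key table (editable: reverse-keyed item indices are
#' instrument metadata shipped as documented defaults, not study data).
#' PCS: 13 items scored 0-4 (sum 0-52). STAI-T: 20 items scored 1-4 with the
#' anxiety-absent items reverse-keyed (sum 20-80). FFMQ4: the 32 items of the
#' four retained facets scored 1-5, 'observing' facet excluded (sum 32-160).
#'
#' @param name `"PCS"`, `"STAI-T"` or `"FFMQ4"`.
#' @param key_file Optional path to an alternative key CSV.
#' @return A list of class `pb_questionnaire_key`: `name`, `n_items`,
#'   `item_min`, `item_max`, `reverse_items`.
#' @export
questionnaire_key <- function(name = c("PCS", "STAI-T", "FFMQ4"),
                              key_file = NULL) {
  name <- match.arg(name)
  path <- key_file %||% system.file("extdata", "questionnaire_keys.csv",
                                    package = "painbalance", mustWork = TRUE)
  keys <- readr::read_csv(path, show_col_types = FALSE)
  row <- keys[keys$name == name, ]
  if (nrow(row) != 1) stopf("pb_validation_error", "no key named `%s`.", name)
  rev_idx <- if (is.na(row$reverse_items) || row$reverse_items == "") integer(0)
             else as.integer(strsplit(row$reverse_items, ";")[[1]])
  structure(list(name = name, n_items = row$n_items, item_min = row$item_min,
                 item_max = row$item_max, reverse_items = rev_idx),
            class = "pb_questionnaire_key")
}

#' Score a questionnaire from item responses
#'
#' Reverse-keyed items are inverted (`min + max - item`) before summing.
#'
#' @param items Integer vector of item responses.
#' @param key A [questionnaire_key()].
#' @return Integer sum score within the instrument's printed range.
#' @examples
#' score_questionnaire(rep(4, 13), questionnaire_key("PCS"))  # 52
#' @export
score_questionnaire <- function(items, key) {
  stopifnot(inherits(key, "pb_questionnaire_key"))
  if (length(items) != key$n_items) {
    stopf("pb_validation_error", "%s expects %d items, got %d.",
          key$name, key$n_items, length(items))
  }
  check_number(items, "items", key$item_min, key$item_max)
  items[key$reverse_items] <- key$item_min + key$item_max - items[key$reverse_items]
  as.integer(sum(items))
}

#' Per-subject condition means and the MTA / MPI derived measures
#'
#' Mean task-induced analgesia: `MTA = mean sensation(Pain x LR) - mean
#' sensation(Pain x 2-back)` -- how much the demanding task blunts pain.
#' Mean pain-induced interference: `MPI = mean A(Warm x 2-back) - mean
#' A(Pain x 2-back)` -- how much painful heat degrades performance.
#'
#' @param trials Trial table with `subject_id`, `task`, `heat`, `sensation`,
#'   `A`. All four task-by-heat cells must be present for every subject.
#' @return Tibble, one row per subject: the eight condition means
#'   (`sens_*`, `A_*`) plus `mta` and `mpi`.
#' @export
compute_mta_mpi <- function(trials) {
  check_columns(trials, c("subject_id", "task", "heat", "sensation", "A"), "trials")
  cells <- trials |>
    dplyr::group_by(.data$subject_id, .data$task, .data$heat) |>
    dplyr::summarise(sens = mean(.data$sensation), A = mean(.data$A),
                     .groups = "drop")
  counts <- cells |> dplyr::count(.data$subject_id)
  if (any(counts$n != 4)) {
    bad <- counts$subject_id[counts$n != 4]
    stopf("pb_missing_cell_error",
          "subject(s) %s lack one or more task x heat cells.",
          paste(bad, collapse = ", "))
  }
  wide <- cells |>
    tidyr::pivot_wider(names_from = c("heat", "task"),
                       values_from = c("sens", "A"), names_sep = "_")
  wide |>
    dplyr::mutate(mta = .data$sens_pain_LR - .data$sens_pain_2back,
                  mpi = .data$A_warm_2back - .data$A_pain_2back)
}

cohen_d_paired <- function(x, y) {
  d <- x - y
  if (sd(d) == 0) return(0)
  mean(d) / sd(d)
}

#' Group-level contrasts and correlation table
#'
#' Paired t-tests (with Cohen's d computed as mean difference / SD of
#' differences) for the heat contrast on 2-back and LR performance and for
#' the task contrast on pain- and warm-trial sensation; a Wilcoxon
#' signed-rank test (with effect size r = |z| / sqrt(n)) for LR vs 2-back
#' performance; and a Pearson correlation matrix over traits, derived
#' measures and (optionally) calibration parameters. Zero-variance columns
#' yield `NA` correlations.
#'
#' @param trials Cohort trial table.
#' @param subjects Optional subject table (adds trait correlations).
#' @param curves Optional calibration output of [calibrate_cohort()] (adds
#'   temperature-parameter correlations).
#' @return List of class `pb_group_stats` with tibbles `contrasts`,
#'   `nonparametric`, and `correlations` (long form: `var1`, `var2`, `r`,
#'   `p`, `n`).
#' @export
group_stats <- function(trials, subjects = NULL, curves = NULL) {
  derived <- compute_mta_mpi(trials)
  if (nrow(derived) < 3) stopf("pb_validation_error", "need >= 3 subjects.")
  paired <- function(label, x, y) {
    if (sd(x - y) == 0) {
      # identical paired conditions: null contrast by definition
      return(tibble(contrast = label, mean_1 = mean(x), mean_2 = mean(y),
                    t = 0, df = length(x) - 1, p = 1, cohens_d = 0))
    }
    tt <- t.test(x, y, paired = TRUE)
    tibble(contrast = label, mean_1 = mean(x), mean_2 = mean(y),
           t = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value, cohens_d = cohen_d_paired(x, y))
  }
  contrasts <- dplyr::bind_rows(
    paired("A 2-back: warm vs pain", derived$A_warm_2back, derived$A_pain_2back),
    paired("A LR: warm vs pain", derived$A_warm_LR, derived$A_pain_LR),
    paired("sensation pain: LR vs 2-back", derived$sens_pain_LR, derived$sens_pain_2back),
    paired("sensation warm: LR vs 2-back", derived$sens_warm_LR, derived$sens_warm_2back))

  lr <- (derived$A_warm_LR + derived$A_pain_LR) / 2
  nb <- (derived$A_warm_2back + derived$A_pain_2back) / 2
  wt <- suppressWarnings(wilcox.test(lr, nb, paired = TRUE, exact = FALSE))
  zval <- qnorm(wt$p.value / 2, lower.tail = FALSE) * sign(median(lr - nb))
  nonparametric <- tibble(
    contrast = "A: LR vs 2-back (signed-rank)",
    median_1 = median(lr), median_2 = median(nb),
    z = zval, p = wt$p.value, r = abs(zval) / sqrt(nrow(derived)))

  corr_df <- derived |> dplyr::select("subject_id", "mta", "mpi")
  if (!is.null(subjects)) {
    corr_df <- dplyr::left_join(
      corr_df, dplyr::select(subjects, "subject_id", dplyr::any_of(
        c("pcs", "stai_t", "ffmq4", "task_interval"))), by = "subject_id")
  }
  if (!is.null(curves)) {
    corr_df <- dplyr::left_join(
      corr_df, dplyr::select(curves, "subject_id", dplyr::any_of(
        c("pain_threshold", "warm_temp", "pain_temp"))), by = "subject_id")
  }
  correlations <- correlation_table(dplyr::select(corr_df, -"subject_id"))
  structure(list(contrasts = contrasts, nonparametric = nonparametric,
                 correlations = correlations),
            class = "pb_group_stats")
}

correlation_table <- function(df) {
  vars <- names(df)
  pairs <- utils::combn(vars, 2, simplify = FALSE)
  purrr::map(pairs, function(pr) {
    x <- df[[pr[1]]]; y <- df[[pr[2]]]
    ok <- complete.cases(x, y)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      return(tibble(var1 = pr[1], var2 = pr[2], r = NA_real_, p = NA_real_,
                    n = sum(ok)))
    }
    ct <- cor.test(x[ok], y[ok])
    tibble(var1 = pr[1], var2 = pr[2], r = unname(ct$estimate), p = ct$p.value,
           n = sum(ok))
  }) |> dplyr::bind_rows()
}

#' @export
print.pb_group_stats <- function(x, ...) {
  cat("Group-level contrasts:\n")
  print(x$contrasts)
  cat("\nNon-parametric contrast:\n")
  print(x$nonparametric)
  cat("\nCorrelations (long form):", nrow(x$correlations), "pairs\n")
  invisible(x)
}

#' Descriptive table of means, SDs and intercorrelations
#'
#' A cohort summary laid out like a standard descriptives-and-
#' intercorrelations table: one row per measure with its mean (SD) and the
#' upper-triangle Pearson correlations.
#'
#' @param subjects Subject table.
#' @param curves Optional [calibrate_cohort()] output.
#' @return Tibble with `measure`, `mean`, `sd`, and one correlation column
#'   per measure.
#' @export
descriptives_table <- function(subjects, curves = NULL) {
  d <- dplyr::select(subjects, dplyr::any_of(
    c("subject_id", "pain_threshold", "pcs", "stai_t", "ffmq4", "task_interval")))
  if (!is.null(curves)) {
    d <- dplyr::left_join(
      d, dplyr::select(curves, "subject_id", "warm_temp", "pain_temp"),
      by = "subject_id")
  }
  num <- dplyr::select(d, -"subject_id")
  cm <- cor(as.matrix(num))
  cm[lower.tri(cm, diag = TRUE)] <- NA
  tibble(measure = names(num),
         mean = vapply(num, mean, numeric(1)),
         sd = vapply(num, sd, numeric(1))) |>
    dplyr::bind_cols(as_tibble(cm))
}

#' Mean b-path slope and intercept for trait quartiles
#'
#' For visualizing moderation: averages the per-subject `b` coefficient
#' (and the intercept of the same Y ~ X + M regression) over the
#' `quartile_n` highest- and lowest-scoring subjects on a trait. Ties at a
#' quartile boundary are broken deterministically by subject id and flagged.
#'
#' @param paths Per-subject coefficients from a fitted [run_model()]
#'   (`object$paths`).
#' @param subjects Subject table containing the trait.
#' @param trait Trait column name.
#' @param quartile_n Group size (default `round(n/4)`, e.g. 10 of 41).
#' @return Tibble with rows `upper` and `lower`: `n`, `slope` (mean b),
#'   `intercept`, `trait_mean`, `ties_broken`.
#' @export
quartile_slopes <- function(paths, subjects, trait, quartile_n = NULL) {
  check_columns(subjects, c("subject_id", trait), "subjects")
  d <- dplyr::inner_join(paths, subjects, by = "subject_id",
                         suffix = c("", ".subj"))
  n <- nrow(d)
  quartile_n <- quartile_n %||% round(n / 4)
  if (quartile_n < 1 || 2 * quartile_n > n) {
    stopf("pb_validation_error", "`quartile_n` must be in [1, n/2].")
  }
  d <- d[order(d[[trait]], d$subject_id), ]
  lower <- d[seq_len(quartile_n), ]
  upper <- d[seq(n - quartile_n + 1, n), ]
  boundary_tie <- function(group, rest) any(group[[trait]] %in% rest[[trait]])
  ties <- boundary_tie(lower, d[-seq_len(quartile_n), ]) ||
    boundary_tie(upper, d[seq_len(n - quartile_n), ])
  summarise_group <- function(g, lbl) {
    tibble(quartile = lbl, n = nrow(g), slope = mean(g$b),
           intercept = mean(g$intercept), trait_mean = mean(g[[trait]]))
  }
  dplyr::bind_rows(summarise_group(upper, "upper"),
                   summarise_group(lower, "lower")) |>
    dplyr::mutate(trait = trait, ties_broken = ties)
}
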