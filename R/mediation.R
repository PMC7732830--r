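# Trial-level multilevel mediation: per-subject OLS path coefficients on
# within-subject z-scored variables, population inference by bias-corrected
# subject-level bootstrap, and second-level trait moderation of every path.

PATHS <- c("a", "b", "c", "c_prime", "ab")

#' Specification of one of the two mediation models
#'
#' `pain_interference` examines, on 2-back trials only, whether the effect of
#' heat level (X) on task performance (Y = A) is mediated by reported thermal
#' sensation (M). `task_analgesia` examines, on painful-heat trials only,
#' whether the effect of task difficulty (X, 2-back vs left-right) on
#' sensation (Y) is mediated by task performance (M = A). Binary predictors
#' are effect-coded (-0.5 / +0.5, with pain and 2-back positive) before
#' standardization.
#'
#' @param name `"pain_interference"` or `"task_analgesia"`.
#' @return A list of class `pb_model_spec` with the trial filter and the
#'   x/m/y column roles.
#' @export
model_spec <- function(name = c("pain_interference", "task_analgesia")) {
  name <- match.arg(name)
  spec <- switch(name,
    pain_interference = list(
      filter_col = "task", filter_value = "2back",
      x_var = "heat", x_positive = "pain", m_var = "sensation", y_var = "A"),
    task_analgesia = list(
      filter_col = "heat", filter_value = "pain",
      x_var = "task", x_positive = "2back", m_var = "A", y_var = "sensation"))
  structure(c(list(name = name), spec), class = "pb_model_spec")
}

#' z-transform values within subject
#'
#' Centers and scales (sample SD) each subject's values so that trial-level
#' coefficients are comparable across subjects regardless of idiosyncratic
#' rating or performance scales.
#'
#' @param data A data frame of trial-level values.
#' @param vars Character vector of columns to transform in place.
#' @param subject_col Grouping column (default `"subject_id"`).
#' @return `data` with the named columns replaced by within-subject z-scores.
#'   Subjects with a constant column are flagged in the
#'   `"degenerate_subjects"` attribute (their z-scores become `NaN`).
#' @export
zscore_within_subject <- function(data, vars, subject_col = "subject_id") {
  check_columns(data, c(subject_col, vars), "data")
  degenerate <- character(0)
  out <- data |>
    dplyr::group_by(.data[[subject_col]]) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(vars), function(v) {
      s <- sd(v)
      if (!is.finite(s) || s == 0) {
        degenerate <<- union(degenerate, dplyr::cur_group()[[1]])
        rep(NaN, length(v))
      } else (v - mean(v)) / s
    })) |>
    dplyr::ungroup()
  attr(out, "degenerate_subjects") <- degenerate
  out
}

# Fast OLS slope helpers on already-centered/scaled inputs.
ols_fit <- function(X, y) {
  qr.coef(qr(X), y)
}

#' Fit one subject's mediation path coefficients
#'
#' Given one subject's filtered trials, effect-codes and standardizes X and
#' z-scores M and Y, then estimates `a` (M ~ X), `b` and `c'` (Y ~ X + M) and
#' `c` (Y ~ X) by ordinary least squares; `ab = a * b`. Because all three
#' regressions use the same trial set, the OLS decomposition
#' `c = c' + a * b` holds to machine precision.
#'
#' @param trials Tibble of one subject's trials (already filtered to the
#'   model's trial subset) containing the spec's x/m/y columns.
#' @param spec A [model_spec()].
#' @return One-row tibble: `subject_id`, `n_trials`, `a`, `b`, `c`,
#'   `c_prime`, `ab`, and `intercept` (of the Y ~ X + M regression).
#' @export
fit_subject_paths <- function(trials, spec) {
  stopifnot(inherits(spec, "pb_model_spec"))
  check_columns(trials, c("subject_id", spec$x_var, spec$m_var, spec$y_var), "trials")
  n <- nrow(trials)
  if (n < 4) {
    stopf("pb_subject_excluded", "subject %s has fewer than 4 usable trials (%d).",
          trials$subject_id[1], n)
  }
  x_ec <- ifelse(trials[[spec$x_var]] == spec$x_positive, 0.5, -0.5)
  m_raw <- trials[[spec$m_var]]
  y_raw <- trials[[spec$y_var]]
  if (sd(x_ec) == 0 || sd(m_raw) == 0 || sd(y_raw) == 0) {
    stopf("pb_degenerate_subject", "subject %s has a constant X, M or Y.",
          trials$subject_id[1])
  }
  x <- as.numeric(scale(x_ec))
  m <- as.numeric(scale(m_raw))
  y <- as.numeric(scale(y_raw))
  if (abs(cor(x, m)) > 1 - 1e-10) {
    stopf("pb_collinear_error",
          "subject %s: mediator collinear with predictor; paths unidentifiable.",
          trials$subject_id[1])
  }
  one <- rep(1, n)
  a <- ols_fit(cbind(one, x), m)[2]
  cf2 <- ols_fit(cbind(one, x, m), y)
  c_tot <- ols_fit(cbind(one, x), y)[2]
  tibble(subject_id = trials$subject_id[1], n_trials = n,
         a = unname(a), b = unname(cf2[3]), c = unname(c_tot),
         c_prime = unname(cf2[2]), ab = unname(a * cf2[3]),
         intercept = unname(cf2[1]))
}

# Bias-corrected percentile machinery ---------------------------------------

# Empirical CDF value with midpoint treatment of ties, clamped away from 0/1.
ecdf_mid <- function(boot, value) {
  n <- length(boot)
  p <- (sum(boot < value) + 0.5 * sum(boot == value)) / n
  clamp(p, 1 / (n + 1), n / (n + 1))
}

bc_summary <- function(boot, observed, conf = 0.95) {
  boot <- boot[is.finite(boot)]
  if (!length(boot) || sd(boot) == 0) {
    # degenerate bootstrap distribution: no resampling variability
    p <- if (abs(observed) < 1e-12) 1 else 1 / (length(boot) + 1)
    return(tibble(estimate = observed, ci_lo = observed, ci_hi = observed, p = p))
  }
  z0 <- qnorm(ecdf_mid(boot, observed))
  alpha <- (1 - conf) / 2
  lv <- pnorm(2 * z0 + qnorm(c(alpha, 1 - alpha)))
  ci <- unname(quantile(boot, lv))
  # two-sided p from the bias-corrected bootstrap CDF at zero
  g0 <- pnorm(qnorm(ecdf_mid(boot, 0)) - 2 * z0)
  p <- clamp(2 * min(g0, 1 - g0), 2 / (length(boot) + 1), 1)
  tibble(estimate = observed, ci_lo = min(ci[1], observed),
         ci_hi = max(ci[2], observed), p = p)
}

#' Population-level test of the mediation paths
#'
#' The population estimate of each path (`a`, `b`, `c`, `c'`, `ab`) is the
#' unweighted mean of the per-subject coefficients. Subjects are resampled
#' with replacement (jointly across paths) `n_boot` times; each path gets a
#' bias-corrected percentile confidence interval and a two-sided p-value from
#' the bias-corrected bootstrap CDF. A zero-variance bootstrap distribution
#' falls back to an exact degenerate branch (p = 1 for a zero estimate).
#'
#' @param paths Tibble of per-subject coefficients from [fit_subject_paths()].
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed Optional integer seed for the resampling.
#' @param conf Confidence level (default 0.95).
#' @return Tibble with one row per path: `path`, `estimate`, `ci_lo`,
#'   `ci_hi`, `p`, `n_boot`, `n_subjects`.
#' @export
test_population_paths <- function(paths, n_boot = 10000, seed = NULL, conf = 0.95) {
  check_columns(paths, c("subject_id", PATHS), "paths")
  S <- nrow(paths)
  if (S < 10) warn(sprintf("only %d subjects; bootstrap inference is fragile.", S))
  if (n_boot < 1000) warn("n_boot < 1000; intervals will be unstable.")
  mat <- as.matrix(paths[, PATHS])
  obs <- colMeans(mat)
  boot_means <- with_seed_(seed, {
    idx <- matrix(sample.int(S, S * n_boot, replace = TRUE), S, n_boot)
    apply(mat, 2, function(col) colMeans(matrix(col[idx], S, n_boot)))
  })
  purrr::map(PATHS, function(p) {
    dplyr::bind_cols(tibble(path = p), bc_summary(boot_means[, p], obs[[p]], conf))
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(n_boot = n_boot, n_subjects = S)
}

residualize <- function(x, covariate_mat) {
  if (is.null(covariate_mat) || ncol(covariate_mat) == 0) return(x - mean(x))
  X <- cbind(1, covariate_mat)
  as.numeric(x - X %*% ols_fit(X, x))
}

#' Second-level trait moderation of the mediation paths
#'
#' Tests whether a subject-level trait moderates each first-level path. The
#' moderator is first residualized against the session covariates
#' (inter-session interval, pain threshold, calibrated task interval) and
#' standardized; each per-subject path coefficient is then standardized and
#' regressed on it, so each moderation coefficient (`a2`, `b2`, `c2`,
#' `c_prime2`, `ab2`) is a standardized slope: positive `b2` means the `b`
#' path becomes more positive per SD of the moderator. Inference uses the
#' same subject-resampling bias-corrected bootstrap as the first-level paths
#' (residualization and standardization are redone inside every resample).
#'
#' @param paths Per-subject coefficients from [fit_subject_paths()].
#' @param subjects Subject table containing the moderator and covariates.
#' @param moderator Column name of the trait moderator (one at a time).
#' @param covariates Covariate column names (default the three session
#'   covariates); use `character(0)` for none.
#' @param n_boot Bootstrap resamples; `0` skips inference (p = NA).
#' @param seed Optional seed.
#' @return Tibble with one row per path: `moderator`, `path` (`a2` ... `ab2`),
#'   `estimate`, `ci_lo`, `ci_hi`, `p`.
#' @export
moderated_mediation <- function(paths, subjects, moderator,
                                covariates = c("intersession_days",
                                               "pain_threshold", "task_interval"),
                                n_boot = 10000, seed = NULL) {
  check_columns(subjects, c("subject_id", moderator, covariates), "subjects")
  d <- dplyr::inner_join(paths, subjects, by = "subject_id",
                         suffix = c("", ".subj"))
  S <- nrow(d)
  cov_mat <- if (length(covariates)) as.matrix(d[, covariates]) else NULL
  mod_slopes <- function(rows) {
    z <- residualize(d[[moderator]][rows],
                     if (is.null(cov_mat)) NULL else cov_mat[rows, , drop = FALSE])
    sz <- sd(z)
    if (!is.finite(sz) || sz < 1e-12) return(NULL)
    z <- z / sz
    vapply(PATHS, function(p) {
      v <- d[[p]][rows]
      sv <- sd(v)
      if (!is.finite(sv) || sv == 0) return(NA_real_)
      mean(z * (v - mean(v)) / sv) * S_adj(length(rows))
    }, numeric(1))
  }
  # standardized slope with one predictor = sample correlation; computed via
  # cross-moment with an (n-1)/n correction so it matches lm() on scale()d data
  S_adj <- function(n) n / (n - 1)
  obs <- mod_slopes(seq_len(S))
  if (is.null(obs)) {
    stopf("pb_degenerate_moderator",
          "moderator `%s` is constant after residualization.", moderator)
  }
  names(obs) <- paste0(sub("c_prime", "c_prime", PATHS), "2")
  if (n_boot <= 0) {
    return(tibble(moderator = moderator, path = names(obs),
                  estimate = unname(obs), ci_lo = NA_real_, ci_hi = NA_real_,
                  p = NA_real_))
  }
  boot <- with_seed_(seed, {
    vapply(seq_len(n_boot), function(i) {
      sl <- mod_slopes(sample.int(S, S, replace = TRUE))
      if (is.null(sl)) rep(NA_real_, length(PATHS)) else sl
    }, numeric(length(PATHS)))
  })
  purrr::imap(obs, function(o, nm) {
    k <- match(sub("2$", "", nm), PATHS)
    dplyr::bind_cols(tibble(moderator = moderator, path = nm),
                     bc_summary(boot[k, ], o))
  }) |>
    dplyr::bind_rows()
}

#' Run one full moderated multilevel mediation model
#'
#' Applies the model's trial filter, drops flagged trials (missing or
#' terminated) and subjects with too few usable trials or degenerate data,
#' fits per-subject paths, tests the population paths by bias-corrected
#' bootstrap, and tests each trait moderator in turn.
#'
#' @param trials Cohort trial table (`subject_id`, `task`, `heat`,
#'   `sensation`, `A`, optional `missing`/`terminated` flags).
#' @param model `"pain_interference"` or `"task_analgesia"` (or a
#'   [model_spec()]).
#' @param subjects Subject table (traits + covariates); required for
#'   moderation, optional otherwise.
#' @param moderators Trait columns to test one at a time (default the three
#'   questionnaires); `character(0)` skips moderation.
#' @param n_boot,seed,conf Bootstrap settings (default 10000 resamples).
#' @return Object of class `pb_mediation`: list with `model`, `paths`
#'   (per-subject), `population`, `moderation`, `excluded`, `n_boot`, `seed`.
#' @export
run_model <- function(trials, model, subjects = NULL,
                      moderators = c("pcs", "stai_t", "ffmq4"),
                      n_boot = 10000, seed = NULL, conf = 0.95) {
  spec <- if (inherits(model, "pb_model_spec")) model else model_spec(model)
  check_columns(trials, c("subject_id", spec$filter_col, spec$x_var,
                          spec$m_var, spec$y_var), "trials")
  keep <- trials[[spec$filter_col]] == spec$filter_value
  if ("missing" %in% names(trials)) keep <- keep & !trials$missing
  if ("terminated" %in% names(trials)) keep <- keep & !trials$terminated
  filtered <- trials[keep, ]
  if (nrow(filtered) == 0) {
    stopf("pb_empty_model", "no trials remain after the %s filter.", spec$name)
  }
  pieces <- filtered |> dplyr::group_split(.data$subject_id)
  excluded <- list()
  paths <- purrr::map(pieces, function(d) {
    tryCatch(fit_subject_paths(d, spec),
             painbalance_error = function(e) {
               excluded[[length(excluded) + 1]] <<-
                 tibble(subject_id = d$subject_id[1], reason = conditionMessage(e))
               NULL
             })
  }) |> dplyr::bind_rows()
  excluded <- dplyr::bind_rows(excluded)
  if (nrow(excluded)) {
    warn(sprintf("%d subject(s) excluded from the %s model.",
                 nrow(excluded), spec$name))
  }
  if (nrow(paths) < 2) {
    stopf("pb_empty_model", "fewer than 2 subjects with usable paths.")
  }
  population <- test_population_paths(paths, n_boot = n_boot,
                                      seed = if (is.null(seed)) NULL else derive_seed(seed, 1),
                                      conf = conf)
  moderation <- NULL
  if (!is.null(subjects) && length(moderators)) {
    moderation <- purrr::imap(setNames(moderators, moderators), function(m, i) {
      moderated_mediation(paths, subjects, m, n_boot = n_boot,
                          seed = if (is.null(seed)) NULL else
                            derive_seed(seed, 10 + match(m, moderators)))
    }) |> dplyr::bind_rows()
  }
  structure(list(model = spec$name, paths = paths, population = population,
                 moderation = moderation, excluded = excluded,
                 n_boot = n_boot, seed = seed),
            class = "pb_mediation")
}

#' @export
print.pb_mediation <- function(x, ...) {
  cat("Multilevel mediation model:", x$model, "\n")
  cat(sprintf("  %d subjects, %d bootstrap resamples\n",
              nrow(x$paths), x$n_boot))
  pop <- x$population
  for (i in seq_len(nrow(pop))) {
    cat(sprintf("  %-8s % .3f  [% .3f, % .3f]  p = %.4g\n",
                pop$path[i], pop$estimate[i], pop$ci_lo[i], pop$ci_hi[i], pop$p[i]))
  }
  if (!is.null(x$moderation)) {
    cat("  moderators tested:", paste(unique(x$moderation$moderator), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a fitted mediation model
#'
#' @param x A `pb_mediation` object.
#' @param ... Unused.
#' @return Tibble of population paths (moderator `NA`) stacked with the
#'   moderation coefficients.
#' @export
tidy.pb_mediation <- function(x, ...) {
  pop <- x$population |>
    dplyr::mutate(moderator = NA_character_, .before = 1) |>
    dplyr::select("moderator", "path", "estimate", "ci_lo", "ci_hi", "p")
  if (is.null(x$moderation)) return(dplyr::mutate(pop, model = x$model, .before = 1))
  dplyr::bind_rows(pop, dplyr::select(x$moderation, "moderator", "path",
                                      "estimate", "ci_lo", "ci_hi", "p")) |>
    dplyr::mutate(model = x$model, .before = 1)
}

#' One-row summary of a fitted mediation model
#'
#' @param x A `pb_mediation` object.
#' @param ... Unused.
#' @export
glance.pb_mediation <- function(x, ...) {
  tibble(model = x$model, n_subjects = nrow(x$paths),
         n_trials = sum(x$paths$n_trials), n_excluded = nrow(x$excluded),
         n_boot = x$n_boot,
         ab_estimate = x$population$estimate[x$population$path == "ab"],
         ab_p = x$population$p[x$population$path == "ab"])
}
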