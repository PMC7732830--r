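# Thermal psychophysics: the combined warmth-pain scale, correction of
# calibration ratings for order/site adaptation, and stimulus-response curve
# fitting with derivation of individualized stimulation temperatures.

CALIBRATION_TEMPS <- c(40, 44, 45, 46, 47, 48, 49)
N_SITES <- 4L
MAX_TEMP_C <- 49
SENSATION_WARM <- 80    # combined-scale target for the Warm temperature
SENSATION_THRESHOLD <- 100  # warmth/pain boundary (pain intensity 0)
SENSATION_PAIN <- 140   # combined-scale target for the Pain temperature (40/100 pain)

#' Map a 0-100 rating onto the combined 0-200 warmth-pain scale
#'
#' Non-painful warmth and pain intensity are reported on separate 0-100
#' scales but analysed on a single continuum: warmth ratings map to 0-100 and
#' pain-intensity ratings to 100-200, so a pain intensity of 0 sits exactly at
#' the pain threshold (combined value 100). The mapping is strictly
#' order-preserving across the boundary.
#'
#' @param is_painful Logical; `TRUE` if the rating came from the pain scale.
#' @param rating_0_100 Rating(s) in [0, 100].
#' @return Combined-scale rating(s) in [0, 200].
#' @examples
#' combine_scale(FALSE, 40)  # warmth 40 -> 40
#' combine_scale(TRUE, 0)    # pain threshold -> 100
#' combine_scale(TRUE, 40)   # Pain-temperature target -> 140
#' @export
combine_scale <- function(is_painful, rating_0_100) {
  check_number(rating_0_100, "rating_0_100", 0, 100)
  if (!is.logical(is_painful) || anyNA(is_painful)) {
    stopf("pb_validation_error", "`is_painful` must be logical and non-missing.")
  }
  ifelse(rep_len(is_painful, length(rating_0_100)), 100 + rating_0_100, rating_0_100)
}

# Latent power-law temperature -> combined sensation curve and its inverse.
curve_sensation <- function(temp_C, offset, gain, exponent) {
  gain * pmax(0, temp_C - offset)^exponent
}

curve_temperature <- function(sensation, offset, gain, exponent) {
  offset + (sensation / gain)^(1 / exponent)
}

# Site-nonspecific sensitization (grows with overall presentation index) and
# site-specific habituation (decays with per-site repeat count).
adaptation_terms <- function(order_idx, site_repeat, sens_amp, sens_tau,
                             habit_amp, habit_decay) {
  sens_amp * (1 - exp(-order_idx / sens_tau)) +
    habit_amp * exp(-habit_decay * (site_repeat - 1))
}

site_repeat_count <- function(site, order_idx) {
  stats::ave(order_idx, site, FUN = function(o) rank(o, ties.method = "first"))
}

check_calibration_design <- function(obs) {
  check_columns(obs, c("order_idx", "site", "temp_C", "rating_raw"),
                "calibration observations")
  if (nrow(obs) != length(CALIBRATION_TEMPS) * N_SITES) {
    stopf("pb_validation_error",
          "expected %d calibration observations (7 temperatures x 4 sites), got %d.",
          length(CALIBRATION_TEMPS) * N_SITES, nrow(obs))
  }
  if (anyDuplicated(obs$order_idx)) {
    stopf("pb_validation_error", "calibration `order_idx` must be unique.")
  }
  tab <- table(obs$temp_C, obs$site)
  if (!identical(dim(tab), c(7L, 4L)) || any(tab != 1L) ||
      !all(sort(unique(obs$temp_C)) == CALIBRATION_TEMPS)) {
    stopf("pb_validation_error",
          "each of the 7 calibration temperatures must appear exactly once per site.")
  }
  invisible(obs)
}

# Bounded multi-start nonlinear least squares via minpack.lm, returning the
# converged fit with lowest residual sum of squares (NULL if all starts fail).
nls_multistart <- function(formula, data, starts, lower, upper) {
  best <- NULL
  best_rss <- Inf
  for (st in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        formula, data = data, start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                             ptol = 1e-12))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (rss < best_rss - 1e-12) {
        best <- fit
        best_rss <- rss
      }
    }
  }
  best
}

#' Correct calibration ratings for sensitization and habituation
#'
#' Jointly fits, by bounded nonlinear least squares, the latent power-law
#' stimulus-response curve plus two additive adaptation components: a
#' site-nonspecific sensitization term `sens_amp * (1 - exp(-order/sens_tau))`
#' shared across sites, and a site-specific habituation term
#' `habit_amp * exp(-habit_decay * (site_repeat - 1))`. Ratings are then
#' corrected by removing the fitted adaptation relative to the reference
#' state (first presentation, first site visit), so a series without
#' adaptation is returned unchanged. Corrected ratings are deliberately not
#' clipped to [0, 200]: clipping would bias the subsequent curve fit.
#'
#' @param obs A tibble of one subject's 28 calibration observations with
#'   columns `order_idx`, `site`, `temp_C`, `rating_raw` (7 temperatures x
#'   4 sites; any other design is rejected).
#' @return A list with `observations` (input plus `site_repeat` and
#'   `rating_corrected`) and `fit`, a one-row tibble with the adaptation
#'   parameters (`sens_amp`, `sens_tau`, `habit_amp`, `habit_decay`),
#'   `residual_sd`, and a `converged` flag. On optimizer failure the raw
#'   ratings are passed through with a warning and `converged = FALSE`.
#' @export
correct_ratings <- function(obs) {
  check_calibration_design(obs)
  obs <- dplyr::mutate(obs, site_repeat = site_repeat_count(.data$site, .data$order_idx))
  # seed the joint fit from a curve-only prefit on per-temperature means,
  # then try several adaptation starting points around it
  prefit <- tryCatch({
    means <- obs |>
      dplyr::group_by(.data$temp_C) |>
      dplyr::summarise(rating_corrected = mean(.data$rating_raw), .groups = "drop")
    f <- fit_stimulus_response(means)
    list(offset = f$offset, gain = f$gain, exponent = f$exponent)
  }, error = function(e) list(offset = 41, gain = 10, exponent = 1.3))
  starts <- lapply(
    list(c(0, 8, 0, 0.7), c(10, 8, 8, 0.7), c(10, 4, 8, 1.5),
         c(-8, 12, -8, 0.3)),
    function(ad) c(prefit, list(sens_amp = ad[1], sens_tau = ad[2],
                                habit_amp = ad[3], habit_decay = ad[4])))
  # adaptation terms are parameterized relative to the reference state
  # (first presentation, first site visit), so the curve keeps its scale and
  # the correction is exactly zero at the reference
  fit <- nls_multistart(
    rating_raw ~ gain * pmax(0, temp_C - offset)^exponent +
      sens_amp * (exp(-1 / sens_tau) - exp(-order_idx / sens_tau)) +
      habit_amp * (exp(-habit_decay * (site_repeat - 1)) - 1),
    data = obs, starts = starts,
    lower = c(offset = 20, gain = 1e-3, exponent = 0.2,
              sens_amp = -80, sens_tau = 0.5, habit_amp = -80, habit_decay = 0),
    upper = c(offset = 43.99, gain = 200, exponent = 5,
              sens_amp = 80, sens_tau = 100, habit_amp = 80, habit_decay = 5))
  if (is.null(fit)) {
    warn("adaptation fit did not converge; raw ratings passed through uncorrected.")
    fit_tbl <- tibble(sens_amp = 0, sens_tau = NA_real_, habit_amp = 0,
                      habit_decay = NA_real_, residual_sd = NA_real_,
                      converged = FALSE)
    obs$rating_corrected <- obs$rating_raw
    return(list(observations = obs, fit = fit_tbl))
  }
  p <- as.list(coef(fit))
  adapt_rel <- adaptation_terms(obs$order_idx, obs$site_repeat,
                                p$sens_amp, p$sens_tau, p$habit_amp, p$habit_decay) -
    adaptation_terms(1, 1, p$sens_amp, p$sens_tau, p$habit_amp, p$habit_decay)
  obs$rating_corrected <- obs$rating_raw - adapt_rel
  fit_tbl <- tibble(sens_amp = p$sens_amp, sens_tau = p$sens_tau,
                    habit_amp = p$habit_amp, habit_decay = p$habit_decay,
                    residual_sd = sd(residuals(fit)), converged = TRUE)
  list(observations = obs, fit = fit_tbl)
}

#' Fit the stimulus-response curve and derive stimulation temperatures
#'
#' Least-squares fit of the monotone power-law curve
#' `sensation = gain * max(0, temp - offset)^exponent` to corrected
#' combined-scale ratings (bounded Levenberg-Marquardt, three starts,
#' tie-break by lowest residual). Inverting the fitted curve yields the Warm
#' temperature (combined sensation 80), the pain threshold (100), and the
#' Pain temperature (140, i.e. pain intensity 40/100). A predicted Pain
#' temperature above 49 degrees C is capped at 49.0 with `capped = TRUE`,
#' mirroring the maximal safe stimulation temperature.
#'
#' @param obs Tibble with columns `temp_C` and `rating_corrected` (or
#'   `rating_raw` as fallback); at least 3 distinct temperatures.
#' @return One-row tibble: `offset`, `gain`, `exponent`, `warm_temp`,
#'   `pain_threshold`, `pain_temp`, `capped`, `converged`, `monotone`,
#'   `residual_sd`.
#' @export
fit_stimulus_response <- function(obs) {
  check_columns(obs, "temp_C", "observations")
  if (!"rating_corrected" %in% names(obs)) obs$rating_corrected <- obs$rating_raw
  if (length(unique(obs$temp_C)) < 3) {
    stopf("pb_validation_error", "need ratings at >= 3 distinct temperatures.")
  }
  if (sd(obs$rating_corrected) < 1e-12) {
    stopf("pb_degenerate_fit_error", "all ratings identical; curve fit is degenerate.")
  }
  r_max <- max(obs$rating_corrected)
  mk_start <- function(offset, exponent) {
    span <- max(max(obs$temp_C) - offset, 0.5)
    list(offset = offset, gain = max(r_max, 1) / span^exponent, exponent = exponent)
  }
  starts <- list(mk_start(42, 1.3), mk_start(39, 1), mk_start(35, 2))
  fit <- nls_multistart(
    rating_corrected ~ gain * pmax(0, temp_C - offset)^exponent,
    data = obs, starts = starts,
    lower = c(offset = 20, gain = 1e-3, exponent = 0.2),
    upper = c(offset = 43.99, gain = 200, exponent = 5))
  if (is.null(fit)) {
    stopf("pb_degenerate_fit_error", "stimulus-response curve fit failed to converge.")
  }
  p <- as.list(coef(fit))
  mono <- cor(obs$temp_C, obs$rating_corrected, method = "spearman") > 0
  pain_temp <- curve_temperature(SENSATION_PAIN, p$offset, p$gain, p$exponent)
  capped <- pain_temp > MAX_TEMP_C
  tibble(
    offset = p$offset, gain = p$gain, exponent = p$exponent,
    warm_temp = curve_temperature(SENSATION_WARM, p$offset, p$gain, p$exponent),
    pain_threshold = curve_temperature(SENSATION_THRESHOLD, p$offset, p$gain, p$exponent),
    pain_temp = if (capped) MAX_TEMP_C else pain_temp,
    capped = capped, converged = TRUE, monotone = mono,
    residual_sd = sd(residuals(fit)))
}

#' Calibrate every subject in a cohort
#'
#' Applies [correct_ratings()] then [fit_stimulus_response()] per subject.
#'
#' @param calibration Tibble of calibration observations for one or more
#'   subjects (`subject_id`, `order_idx`, `site`, `temp_C`, `rating_raw`).
#' @return A tibble of fitted curves, one row per subject, with the
#'   adaptation-fit parameters appended (`sens_amp`, `sens_tau`, `habit_amp`,
#'   `habit_decay`, `adaptation_converged`).
#' @export
calibrate_cohort <- function(calibration) {
  check_columns(calibration, c("subject_id", "order_idx", "site", "temp_C", "rating_raw"),
                "calibration table")
  calibration |>
    dplyr::group_split(.data$subject_id) |>
    purrr::map(function(d) {
      corr <- correct_ratings(d)
      curve <- fit_stimulus_response(corr$observations)
      dplyr::bind_cols(
        tibble(subject_id = d$subject_id[1]), curve,
        corr$fit |>
          dplyr::select("sens_amp", "sens_tau", "habit_amp", "habit_decay") |>
          dplyr::mutate(adaptation_converged = corr$fit$converged))
    }) |>
    dplyr::bind_rows()
}
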