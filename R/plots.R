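# ggplot2 visual summaries of the main result types.

#' Plot one subject's stimulus-response calibration
#'
#' Raw and adaptation-corrected ratings against temperature, the fitted
#' power-law curve, and the derived Warm (sensation 80), pain-threshold
#' (100) and Pain (140) temperatures.
#'
#' @param correction Output of [correct_ratings()].
#' @param curve Output of [fit_stimulus_response()] on the same subject.
#' @return A ggplot object.
#' @export
plot_stimulus_response <- function(correction, curve) {
  obs <- correction$observations
  grid <- tibble(temp_C = seq(min(obs$temp_C), max(obs$temp_C), length.out = 200))
  grid$fit <- curve_sensation(grid$temp_C, curve$offset, curve$gain, curve$exponent)
  long <- obs |>
    tidyr::pivot_longer(c("rating_raw", "rating_corrected"),
                        names_to = "kind", values_to = "rating")
  ggplot(long, aes(x = .data$temp_C, y = .data$rating)) +
    geom_point(aes(shape = .data$kind), alpha = 0.7) +
    geom_line(data = grid, aes(y = .data$fit), linewidth = 0.8) +
    geom_hline(yintercept = c(80, 100, 140), linetype = "dotted") +
    geom_vline(xintercept = c(curve$warm_temp, curve$pain_threshold,
                              curve$pain_temp), linetype = "dashed",
               colour = "grey50") +
    labs(x = "Temperature (°C)", y = "Combined sensation (0-200)",
         shape = NULL, title = "Stimulus-response calibration") +
    theme_minimal()
}

#' Condition means of sensation and performance
#'
#' Cohort means with standard-error bars for the four task-by-heat cells,
#' one panel for reported sensation (the dotted line marks the combined-scale
#' pain threshold of 100) and one for the performance statistic A.
#'
#' @param trials Cohort trial table.
#' @return A ggplot object.
#' @export
plot_condition_means <- function(trials) {
  derived <- compute_mta_mpi(trials)
  long <- derived |>
    tidyr::pivot_longer(dplyr::matches("^(sens|A)_"), names_to = "cell",
                        values_to = "value") |>
    tidyr::separate_wider_regex(
      "cell", c(measure = "^[^_]+", "_", heat = "[^_]+", "_", task = ".+$")) |>
    dplyr::mutate(measure = ifelse(.data$measure == "sens",
                                   "Sensation (0-200)", "Performance (A)"))
  summ <- long |>
    dplyr::group_by(.data$measure, .data$heat, .data$task) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = sd(.data$value) / sqrt(dplyr::n()), .groups = "drop")
  thr <- tibble(measure = "Sensation (0-200)", yintercept = 100)
  ggplot(summ, aes(x = .data$task, y = .data$mean, fill = .data$heat)) +
    geom_col(position = position_dodge(0.8), width = 0.7) +
    geom_errorbar(aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
                  position = position_dodge(0.8), width = 0.2) +
    geom_hline(data = thr, aes(yintercept = .data$yintercept), linetype = "dotted") +
    facet_wrap(~measure, scales = "free_y") +
    labs(x = NULL, y = NULL, fill = "Heat") +
    theme_minimal()
}

#' Quartile b-path lines for a trait moderator
#'
#' Draws the mean within-subject regression line (slope = mean b path) for
#' the upper and lower trait quartiles, visualizing how the trait modulates
#' the sensation-performance trade-off.
#'
#' @param qs Output of [quartile_slopes()] (optionally several traits/models
#'   row-bound).
#' @return A ggplot object.
#' @export
plot_quartile_slopes <- function(qs) {
  seg <- qs |>
    dplyr::mutate(x0 = -1.5, x1 = 1.5,
                  y0 = .data$intercept - 1.5 * .data$slope,
                  y1 = .data$intercept + 1.5 * .data$slope)
  p <- ggplot(seg) +
    geom_segment(aes(x = .data$x0, xend = .data$x1, y = .data$y0,
                     yend = .data$y1, colour = .data$quartile),
                 linewidth = 0.9) +
    labs(x = "Mediator (z)", y = "Outcome (z)", colour = "Trait quartile") +
    theme_minimal()
  if ("trait" %in% names(qs) && length(unique(qs$trait)) > 1) {
    p <- p + facet_wrap(~trait)
  }
  p
}

#' Forest plot of mediation path estimates
#'
#' @param object A `pb_mediation` from [run_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pb_mediation <- function(object, ...) {
  pop <- object$population |>
    dplyr::mutate(path = factor(.data$path, levels = rev(PATHS)))
  ggplot(pop, aes(x = .data$estimate, y = .data$path)) +
    geom_vline(xintercept = 0, linetype = "dotted") +
    geom_pointrange(aes(xmin = .data$ci_lo, xmax = .data$ci_hi)) +
    labs(x = "Standardized coefficient (95% BC bootstrap CI)", y = NULL,
         title = paste("Mediation paths:", object$model)) +
    theme_minimal()
}
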