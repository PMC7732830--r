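# Synthetic cohort generator: subjects with correlated trait questionnaires
# and latent psychophysical curves, thermal calibration sessions with
# order/site adaptation, and behavioral pain-task sessions with a tunable
# trial-level pain-performance coupling.

# Fixed pseudorandom 36-trial condition order (2 tasks x 2 heat levels x 9),
# shared across all simulated subjects, mirroring a session design in which
# every participant sees the same trial sequence.
TRIAL_ORDER <- tibble::tibble(
  trial_idx = 1:36,
  task = c("2back", "2back", "2back", "2back", "2back", "LR", "LR", "LR", "LR",
           "LR", "LR", "2back", "LR", "2back", "2back", "LR", "2back", "2back",
           "LR", "2back", "LR", "LR", "2back", "2back", "2back", "2back",
           "2back", "2back", "LR", "LR", "LR", "LR", "2back", "LR", "LR", "LR"),
  heat = c("pain", "pain", "warm", "warm", "pain", "warm", "pain", "pain",
           "pain", "pain", "pain", "warm", "warm", "pain", "warm", "warm",
           "pain", "pain", "pain", "pain", "warm", "warm", "warm", "warm",
           "warm", "pain", "warm", "warm", "pain", "pain", "warm", "pain",
           "pain", "warm", "warm", "warm"))

# Default trait targets: reference-cohort means, SDs, intercorrelations and
# the instruments' printed scale ranges.
TRAIT_DEFAULTS <- list(
  means = c(pcs = 14.02, stai_t = 39.34, ffmq4 = 103.22),
  sds = c(pcs = 10.69, stai_t = 10.13, ffmq4 = 17.20),
  ranges = list(pcs = c(0, 52), stai_t = c(20, 80), ffmq4 = c(32, 160)))

TRAIT_CORR_DEFAULT <- matrix(
  c(1, 0.43, -0.59,
    0.43, 1, -0.66,
    -0.59, -0.66, 1), 3, 3,
  dimnames = list(c("pcs", "stai_t", "ffmq4"), c("pcs", "stai_t", "ffmq4")))

#' Configuration for a synthetic cohort
#'
#' Bundles every tunable of the generator, with defaults that reproduce the
#' emulated study conditions: 7 calibration temperatures x 4 arm sites, 36
#' behavioral trials (9 per task x heat cell), trait questionnaires drawn
#' with reference-cohort means/SDs/intercorrelations, and four-condition
#' means for sensation and performance set to reference group means. The
#' trial-level coupling between sensation and performance is controlled by
#' `base_coupling` (the latent slope, non-positive under defaults) and by
#' `moderation_strength`, which steepens the coupling with higher pain
#' catastrophizing / trait anxiety and flattens it with higher mindfulness.
#'
#' @param n_subjects Number of subjects (>= 2); default 41, the analysed
#'   sample size.
#' @param seed Integer cohort seed; per-subject child seeds are derived
#'   deterministically from it.
#' @param trait_corr 3x3 trait correlation matrix (pcs, stai_t, ffmq4).
#' @param trait_means,trait_sds Named numeric vectors of generative trait
#'   means and SDs.
#' @param moderation_strength Named vector: effect (per latent-trait SD) of
#'   each trait on the coupling slope. Positive values steepen the coupling
#'   for pcs/stai_t and flatten it for ffmq4.
#' @param base_coupling Baseline latent coupling slope (<= 0 by default).
#' @param coupling_sd SD of subject-level coupling noise (default 0, so with
#'   all moderation zero every subject shares the same slope).
#' @param attention_share Fraction (0-1) of within-condition sensation SD
#'   carried by the shared attention variable that also drives performance.
#' @param cond_means_sensation,cond_means_A Named vectors (`pain_LR`,
#'   `pain_2back`, `warm_LR`, `warm_2back`) of condition means.
#' @param sensation_sd_within,sensation_sd_between Within-trial and
#'   between-subject SDs of sensation ratings.
#' @param a_sd_within_2back,a_sd_within_LR,a_sd_between Within-trial (per
#'   task) and between-subject SDs of the performance statistic A.
#' @param rating_noise_sd Calibration rating noise SD.
#' @param trials_per_condition,temperatures,n_sites Design constants.
#' @return A list of class `pb_cohort_config`.
#' @export
cohort_config <- function(n_subjects = 41,
                          seed = 1L,
                          trait_corr = TRAIT_CORR_DEFAULT,
                          trait_means = TRAIT_DEFAULTS$means,
                          trait_sds = TRAIT_DEFAULTS$sds,
                          moderation_strength = c(pcs = 0.05, stai_t = 0.05, ffmq4 = 0.05),
                          base_coupling = -0.11,
                          coupling_sd = 0,
                          attention_share = 0.6,
                          cond_means_sensation = c(pain_LR = 129.85, pain_2back = 116.17,
                                                   warm_LR = 49.09, warm_2back = 37.74),
                          cond_means_A = c(pain_LR = 0.99, pain_2back = 0.84,
                                           warm_LR = 0.99, warm_2back = 0.86),
                          sensation_sd_within = 15,
                          sensation_sd_between = 18,
                          a_sd_within_2back = 0.06,
                          a_sd_within_LR = 0.01,
                          a_sd_between = 0.05,
                          rating_noise_sd = 8,
                          trials_per_condition = 9,
                          temperatures = CALIBRATION_TEMPS,
                          n_sites = 4L) {
  if (n_subjects < 2) stopf("pb_config_error", "`n_subjects` must be >= 2.")
  if (!isTRUE(all.equal(dim(trait_corr), c(3L, 3L))) ||
      any(abs(trait_corr) > 1) || !isSymmetric(unname(trait_corr))) {
    stopf("pb_config_error",
          "`trait_corr` must be a symmetric 3x3 matrix with entries in [-1, 1].")
  }
  ev <- eigen(trait_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stopf("pb_config_error", "`trait_corr` must be positive-definite.")
  }
  mods <- c(pcs = 0, stai_t = 0, ffmq4 = 0)
  mods[names(moderation_strength)] <- moderation_strength
  structure(
    list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
         trait_corr = trait_corr, trait_means = trait_means, trait_sds = trait_sds,
         moderation_strength = mods, base_coupling = base_coupling,
         coupling_sd = coupling_sd, attention_share = attention_share,
         cond_means_sensation = cond_means_sensation, cond_means_A = cond_means_A,
         sensation_sd_within = sensation_sd_within,
         sensation_sd_between = sensation_sd_between,
         a_sd_within_2back = a_sd_within_2back, a_sd_within_LR = a_sd_within_LR,
         a_sd_between = a_sd_between, rating_noise_sd = rating_noise_sd,
         trials_per_condition = as.integer(trials_per_condition),
         temperatures = temperatures, n_sites = as.integer(n_sites)),
    class = "pb_cohort_config")
}

#' Draw a cohort of subjects with latent curves and correlated traits
#'
#' Trait sum scores are drawn from a multivariate normal with the configured
#' means, SDs and correlation matrix, then rounded and clipped to the printed
#' scale ranges (PCS 0-52, STAI-T 20-80, 4-FFMQ 32-160). The latent
#' (pre-clipping) standardized traits drive the subject's coupling slope:
#' `base_coupling - m_pcs*z_pcs - m_stai*z_stai + m_ffmq*z_ffmq`, truncated at
#' zero so the trade-off never becomes positive under the default setup.
#' Latent psychophysical curve parameters are drawn so the implied pain
#' threshold matches the sampled threshold temperature.
#'
#' @param config A [cohort_config()].
#' @return A tibble, one row per subject: identifiers and child seeds,
#'   questionnaire scores, session covariates (`pain_threshold`,
#'   `task_interval`, `intersession_days`), latent curve and adaptation
#'   parameters, `coupling_slope` and `base_ability`.
#' @export
generate_subjects <- function(config = cohort_config()) {
  stopifnot(inherits(config, "pb_cohort_config"))
  n <- config$n_subjects
  with_seed_(config$seed, {
    z <- matrix(rnorm(n * 3), n, 3) %*% chol(config$trait_corr)
    colnames(z) <- c("pcs", "stai_t", "ffmq4")
    raw <- sweep(sweep(z, 2, config$trait_sds, "*"), 2, config$trait_means, "+")
    clip_trait <- function(v, nm) {
      r <- TRAIT_DEFAULTS$ranges[[nm]]
      as.integer(clamp(round(v), r[1], r[2]))
    }
    m <- config$moderation_strength
    coupling <- pmin(0, config$base_coupling -
                       m[["pcs"]] * z[, "pcs"] -
                       m[["stai_t"]] * z[, "stai_t"] +
                       m[["ffmq4"]] * z[, "ffmq4"] +
                       rnorm(n, 0, config$coupling_sd))

    pain_threshold <- clamp(rnorm(n, 46.20, 1.24), 44, 48.9)
    offset <- clamp(rnorm(n, 41, 1), 35, 43.5)
    exponent <- exp(rnorm(n, log(1.3), 0.15))
    gain <- SENSATION_THRESHOLD / (pain_threshold - offset)^exponent
    # calibrated task speed: right-skewed around the sample mean of 579 ms
    sdlog <- sqrt(log(1 + (346 / 579)^2))
    task_interval <- round(clamp(
      exp(rnorm(n, log(579) - sdlog^2 / 2, sdlog)),
      INTERVAL_RANGE_MS[1], INTERVAL_RANGE_MS[2]))

    tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      child_seed = vapply(seq_len(n), function(i) derive_seed(config$seed, i),
                          integer(1)),
      pcs = clip_trait(raw[, "pcs"], "pcs"),
      stai_t = clip_trait(raw[, "stai_t"], "stai_t"),
      ffmq4 = clip_trait(raw[, "ffmq4"], "ffmq4"),
      pcs_latent = raw[, "pcs"], stai_t_latent = raw[, "stai_t"],
      ffmq4_latent = raw[, "ffmq4"],
      pain_threshold = pain_threshold,
      task_interval = task_interval,
      intersession_days = pmax(1, round(rnorm(n, 7, 3))),
      curve_offset = offset, curve_gain = gain, curve_exponent = exponent,
      sens_amp = pmax(0, rnorm(n, 10, 4)),
      sens_tau = clamp(rnorm(n, 8, 2), 2, 30),
      habit_amp = pmax(0, rnorm(n, 8, 3)),
      habit_decay = clamp(rnorm(n, 0.7, 0.2), 0.05, 3),
      rating_noise_sd = config$rating_noise_sd,
      coupling_slope = as.numeric(coupling),
      base_ability = rnorm(n, 0, config$a_sd_between),
      sens_shift = rnorm(n, 0, config$sensation_sd_between))
  })
}

#' Simulate one subject's thermal calibration session
#'
#' 28 stimulations: each of the 7 temperatures once per each of the 4 volar
#' forearm sites, in a pseudorandom Latin-square presentation order (sites
#' cycle in blocks; each site's temperature order is a rotation of a random
#' base permutation). The raw rating is the latent curve value plus the
#' site-nonspecific sensitization and site-specific habituation terms plus
#' Gaussian noise, clipped to the 0-200 combined scale.
#'
#' @param subject One row of [generate_subjects()] output.
#' @param config The [cohort_config()].
#' @param seed Optional seed; defaults to the subject's child seed.
#' @return Tibble with columns `subject_id`, `order_idx`, `site`, `site_repeat`,
#'   `temp_C`, `rating_true` (latent curve value), `rating_raw`, `is_painful`.
#' @export
generate_calibration_session <- function(subject, config = cohort_config(),
                                         seed = subject$child_seed) {
  stopifnot(nrow(subject) == 1)
  temps <- config$temperatures
  k <- length(temps)
  ns <- config$n_sites
  with_seed_(seed, {
    base_perm <- sample(k)
    site_order <- sample(ns)
    # slot t visits site site_order[(t-1) %% ns + 1]; the j-th visit of site s
    # presents the temperature base_perm rotated by s
    slots <- tibble(
      order_idx = seq_len(k * ns),
      site = rep(site_order, k))
    slots <- slots |>
      dplyr::group_by(.data$site) |>
      dplyr::mutate(site_repeat = dplyr::row_number()) |>
      dplyr::ungroup() |>
      dplyr::mutate(temp_C = temps[base_perm[((.data$site_repeat + .data$site - 2) %% k) + 1]])
    true_val <- curve_sensation(slots$temp_C, subject$curve_offset,
                                subject$curve_gain, subject$curve_exponent)
    adapt <- adaptation_terms(slots$order_idx, slots$site_repeat,
                              subject$sens_amp, subject$sens_tau,
                              subject$habit_amp, subject$habit_decay) -
      adaptation_terms(1, 1, subject$sens_amp, subject$sens_tau,
                       subject$habit_amp, subject$habit_decay)
    raw <- clamp(true_val + adapt + rnorm(nrow(slots), 0, subject$rating_noise_sd),
                 0, 200)
    dplyr::mutate(slots,
                  subject_id = subject$subject_id,
                  rating_true = true_val,
                  rating_raw = raw,
                  is_painful = raw >= SENSATION_THRESHOLD,
                  .before = 1)
  })
}

# Invert the A statistic along the symmetric diagonal F = 1 - H (used to turn
# a latent continuous A into discrete hit/false-alarm counts).
symmetric_rates_from_A <- function(A) {
  A <- clamp(A, 0.5, 1)
  H <- (2.5 - sqrt(4.25 - 4 * A)) / 2
  list(H = H, F = 1 - H)
}

# Vectorized trial generation for a whole cohort (one row per trial).
generate_trials_cohort <- function(subjects, config) {
  n_sub <- nrow(subjects)
  ord <- TRIAL_ORDER
  n_tr <- nrow(ord)
  idx <- rep(seq_len(n_sub), each = n_tr)
  d <- tibble(
    subject_id = subjects$subject_id[idx],
    trial_idx = rep(ord$trial_idx, n_sub),
    task = rep(ord$task, n_sub),
    heat = rep(ord$heat, n_sub))
  cond <- paste(d$heat, d$task, sep = "_")
  mu_s <- config$cond_means_sensation[cond]
  mu_a <- config$cond_means_A[cond]
  w <- config$attention_share
  sig_s <- config$sensation_sd_within
  sig_a <- ifelse(d$task == "2back", config$a_sd_within_2back, config$a_sd_within_LR)
  coupling <- subjects$coupling_slope[idx]

  u <- rnorm(nrow(d))
  e_s <- rnorm(nrow(d))
  e_a <- rnorm(nrow(d))
  sensation <- clamp(
    mu_s + subjects$sens_shift[idx] + sig_s * (w * u + sqrt(1 - w^2) * e_s),
    0, 200)
  A_cont <- clamp(
    mu_a + subjects$base_ability[idx] +
      sig_a * (coupling * u + sqrt(pmax(0, 1 - coupling^2)) * e_a),
    0, 1)

  # discrete realization of the trial: item counts from the subject's
  # calibrated speed, response counts matching A on the symmetric ROC diagonal
  interval <- subjects$task_interval[idx]
  n_items <- items_per_trial(interval)
  n_sig <- ifelse(d$task == "2back",
                  pmax(1L, round(0.25 * (n_items - 2))),
                  pmax(1L, round(0.25 * n_items)))
  n_noise <- ifelse(d$task == "2back", (n_items - 2L) - n_sig, n_items - n_sig)
  rates <- symmetric_rates_from_A(A_cont)
  hits <- pmin(n_sig, round(rates$H * n_sig))
  fas <- pmin(n_noise, round(rates$F * n_noise))

  # temperatures actually applied, from the subject's latent curve
  warm_t <- curve_temperature(SENSATION_WARM, subjects$curve_offset,
                              subjects$curve_gain, subjects$curve_exponent)
  pain_t <- pmin(MAX_TEMP_C, curve_temperature(SENSATION_PAIN, subjects$curve_offset,
                                               subjects$curve_gain,
                                               subjects$curve_exponent))
  d |>
    dplyr::mutate(
      temp_C = ifelse(.data$heat == "pain", pain_t[idx], warm_t[idx]),
      interval_ms = interval, n_items = n_items,
      n_targets = as.integer(n_sig), n_nontargets = as.integer(n_noise),
      hits = as.integer(hits), misses = as.integer(n_sig - hits),
      false_alarms = as.integer(fas),
      correct_rejections = as.integer(n_noise - fas),
      A = A_cont, sensation = sensation,
      missing = FALSE, terminated = FALSE)
}

#' Simulate one subject's 36-trial behavioral session
#'
#' Four conditions (2-back vs left-right task x Warm vs Pain heat), nine
#' trials each, in the fixed pseudorandom order shared by all subjects. A
#' latent per-trial attention variable is shared between the sensation rating
#' and the performance statistic, inducing a negative sensation-performance
#' coupling with the subject's `coupling_slope` (zero slope decouples them).
#' Pain trials average above the combined-scale pain threshold of 100, warm
#' trials below; left-right performance sits near ceiling.
#'
#' @param subject One row of [generate_subjects()] output.
#' @param config The [cohort_config()].
#' @param seed Optional seed; defaults to the subject's child seed offset.
#' @return Tibble, one row per trial: condition, applied temperature, item and
#'   response counts, continuous `A`, post-trial `sensation`, and the
#'   `missing`/`terminated` flags used by the exclusion stage.
#' @export
generate_behavioral_session <- function(subject, config = cohort_config(),
                                        seed = derive_seed(subject$child_seed, 2)) {
  stopifnot(nrow(subject) == 1)
  with_seed_(seed, generate_trials_cohort(subject, config))
}

#' Simulate a full cohort: subjects, calibration sessions, behavioral sessions
#'
#' Optionally plants protocol violators (used to exercise the exclusion
#' stage): subjects with > 50% missing trials, subjects terminating > 50% of
#' painful trials, and subjects at chance-level 2-back performance. Violators
#' occupy the last rows of the subject table.
#'
#' @param config A [cohort_config()].
#' @param violators Named integer vector with entries `missing_data`,
#'   `pain_intolerance`, `chance_performance` (default all 0).
#' @param calibration Generate calibration sessions? (Skipping them speeds up
#'   simulation studies that need only behavioral trials.)
#' @return A list of class `pb_cohort`: `subjects`, `calibration` (or NULL),
#'   `trials`, `config`.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            violators = c(missing_data = 0L, pain_intolerance = 0L,
                                          chance_performance = 0L),
                            calibration = TRUE) {
  stopifnot(inherits(config, "pb_cohort_config"))
  v <- c(missing_data = 0L, pain_intolerance = 0L, chance_performance = 0L)
  v[names(violators)] <- as.integer(violators)
  if (sum(v) >= config$n_subjects) {
    stopf("pb_config_error", "more planted violators than subjects.")
  }
  subjects <- generate_subjects(config)
  calib <- NULL
  if (calibration) {
    calib <- purrr::map(seq_len(nrow(subjects)), function(i) {
      generate_calibration_session(subjects[i, ], config)
    }) |> dplyr::bind_rows()
  }
  trials <- with_seed_(derive_seed(config$seed, 999983),
                       generate_trials_cohort(subjects, config))
  if (sum(v) > 0) {
    trials <- with_seed_(derive_seed(config$seed, 999979),
                         plant_violators(trials, subjects, v))
  }
  structure(list(subjects = subjects, calibration = calib, trials = trials,
                 config = config),
            class = "pb_cohort")
}

plant_violators <- function(trials, subjects, v) {
  ids <- rev(subjects$subject_id)
  take <- function(k) {
    out <- head(ids, k)
    ids <<- setdiff(ids, out)
    out
  }
  miss_ids <- take(v[["missing_data"]])
  intol_ids <- take(v[["pain_intolerance"]])
  chance_ids <- take(v[["chance_performance"]])
  # planted violations use fixed 60% counts so they always clear the >50%
  # exclusion thresholds regardless of sampling noise
  mark <- function(eligible, frac = 0.6) {
    k <- ceiling(frac * sum(eligible))
    out <- logical(length(eligible))
    out[sample(which(eligible), k)] <- TRUE
    out
  }
  for (id in miss_ids) {
    rows <- trials$subject_id == id
    trials$missing[rows] <- mark(rep(TRUE, sum(rows)))
  }
  for (id in intol_ids) {
    rows <- which(trials$subject_id == id)
    trials$terminated[rows] <- mark(trials$heat[rows] == "pain")
  }
  for (id in chance_ids) {
    rows <- trials$subject_id == id & trials$task == "2back"
    trials$A[rows] <- clamp(rnorm(sum(rows), 0.46, 0.03), 0, 1)
  }
  trials
}

#' @export
print.pb_cohort <- function(x, ...) {
  cat("Synthetic cohort: ", nrow(x$subjects), " subjects, ",
      nrow(x$trials), " behavioral trials",
      if (!is.null(x$calibration)) sprintf(", %d calibration ratings", nrow(x$calibration)),
      " (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}
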