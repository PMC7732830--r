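# Independent oracles and small fixture builders used across the suite.

# Geometric proper-ROC-area oracle for the A statistic, independent of the
# package's closed form. The minimum-area proper ROC through (F, H) is the
# chord polyline (0,0)-(F,H)-(1,1); the maximum-area curve is the best
# clipped supporting line through (F,H) (slope searched numerically within
# the concavity-feasible range), with exact handling of the vertical-segment
# degeneracies at F = 0 and H = 1. A is the average of the two areas.
oracle_area_line <- function(s, H, F) {
  x1 <- F + (1 - H) / s            # where the line reaches 1
  lo <- 0
  hi <- min(1, x1)
  y_lo <- H + s * (lo - F)
  y_hi <- H + s * (hi - F)
  (hi - lo) * (y_lo + y_hi) / 2 + (1 - hi)
}

oracle_A <- function(H, F) {
  if (H < F) return(1 - oracle_A(F, H))
  if (H == F) return(0.5)
  area_min <- (1 + H - F) / 2
  if (F == 0 || H == 1) {
    area_max <- 1
  } else {
    s_lo <- (1 - H) / (1 - F)
    s_hi <- H / F
    opt <- optimize(oracle_area_line, c(s_lo, s_hi), H = H, F = F,
                    maximum = TRUE, tol = 1e-10)
    area_max <- max(opt$objective,
                    oracle_area_line(s_lo, H, F), oracle_area_line(s_hi, H, F))
  }
  (area_min + area_max) / 2
}

# Analytic standardized path values implied by the generator's trial model,
# for the pain-interference case (2-back trials; X = heat, M = sensation,
# Y = A). Derived directly from the generative equations: within-condition
# shared-attention covariance sigma_s*w * sigma_a*coupling, condition-mean
# separations ds/dA, within-condition SDs sigma_s/sigma_a.
analytic_paths_pain_interference <- function(config, coupling = config$base_coupling) {
  ds <- config$cond_means_sensation[["pain_2back"]] -
    config$cond_means_sensation[["warm_2back"]]
  dA <- config$cond_means_A[["pain_2back"]] - config$cond_means_A[["warm_2back"]]
  ss <- config$sensation_sd_within
  sa <- config$a_sd_within_2back
  w <- config$attention_share
  VM <- (ds / 2)^2 + ss^2
  VY <- (dA / 2)^2 + sa^2
  a <- (ds / 2) / sqrt(VM)
  b <- (ss * sa * w * coupling / sqrt(VM * VY)) / (ss^2 / VM)
  c_tot <- (dA / 2) / sqrt(VY)
  list(a = a, b = b, c = c_tot, c_prime = c_tot - a * b, ab = a * b)
}

# One noiseless calibration design (7 temps x 4 sites, deterministic order)
# lying exactly on a given latent curve, optionally with adaptation terms.
make_calibration_series <- function(offset = 43, gain = 10, exponent = 1.4,
                                    sens_amp = 0, sens_tau = 8,
                                    habit_amp = 0, habit_decay = 0.7,
                                    noise_sd = 0) {
  temps <- c(40, 44, 45, 46, 47, 48, 49)
  # sites cycle 1..4; within a site the temperature order is a rotation of the
  # block index, so each temperature appears exactly once per site
  d <- tibble::tibble(order_idx = 1:28, site = rep(1:4, 7))
  d$temp_C <- temps[((d$order_idx - 1) %/% 4 + (d$order_idx - 1) %% 4) %% 7 + 1]
  stopifnot(all(table(d$temp_C, d$site) == 1))
  rep_count <- stats::ave(d$order_idx, d$site,
                          FUN = function(o) rank(o, ties.method = "first"))
  latent <- gain * pmax(0, d$temp_C - offset)^exponent
  adapt <- sens_amp * (1 - exp(-d$order_idx / sens_tau)) +
    habit_amp * exp(-habit_decay * (rep_count - 1))
  ref <- sens_amp * (1 - exp(-1 / sens_tau)) + habit_amp
  d$rating_raw <- latent + (adapt - ref) + rnorm(28, 0, noise_sd)
  d
}

# Per-subject mediation paths for a simulated cohort (thin wrapper used by
# the Monte-Carlo tests).
cohort_paths <- function(config, model = "pain_interference") {
  co <- simulate_cohort(config, calibration = FALSE)
  sp <- model_spec(model)
  tr <- co$trials[co$trials[[sp$filter_col]] == sp$filter_value, ]
  paths <- lapply(split(tr, tr$subject_id), fit_subject_paths, spec = sp)
  list(paths = dplyr::bind_rows(paths), subjects = co$subjects,
       trials = co$trials)
}
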