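test_that("trait generation reproduces the configured correlation structure", {
  cfg <- cohort_config(n_subjects = 500, seed = 21)
  subj <- generate_subjects(cfg)
  cm <- cor(cbind(subj$pcs, subj$stai_t, subj$ffmq4))
  expect_lt(abs(cm[1, 2] - 0.43), 0.1)
  expect_lt(abs(cm[1, 3] - (-0.59)), 0.1)
  expect_lt(abs(cm[2, 3] - (-0.66)), 0.1)
})

test_that("trait means match the configured targets at large n", {
  cfg <- cohort_config(n_subjects = 2000, seed = 22)
  subj <- generate_subjects(cfg)
  expect_lt(abs(mean(subj$pcs) / 14.02 - 1), 0.05)
  expect_lt(abs(mean(subj$stai_t) / 39.34 - 1), 0.05)
  expect_lt(abs(mean(subj$ffmq4) / 103.22 - 1), 0.05)
})

test_that("trait scores respect their printed scale ranges for any config", {
  for (s in 1:20) {
    set.seed(s)
    cfg <- cohort_config(n_subjects = 60, seed = s,
                         trait_means = c(pcs = runif(1, 0, 52),
                                         stai_t = runif(1, 20, 80),
                                         ffmq4 = runif(1, 32, 160)),
                         trait_sds = c(pcs = runif(1, 2, 25),
                                       stai_t = runif(1, 2, 25),
                                       ffmq4 = runif(1, 2, 40)))
    subj <- generate_subjects(cfg)
    expect_true(all(subj$pcs >= 0 & subj$pcs <= 52))
    expect_true(all(subj$stai_t >= 20 & subj$stai_t <= 80))
    expect_true(all(subj$ffmq4 >= 32 & subj$ffmq4 <= 160))
  }
})

test_that("zero moderation gives every subject the same coupling slope", {
  cfg <- cohort_config(n_subjects = 50, seed = 5,
                       moderation_strength = c(pcs = 0, stai_t = 0, ffmq4 = 0))
  subj <- generate_subjects(cfg)
  expect_equal(length(unique(subj$coupling_slope)), 1L)
  expect_equal(unique(subj$coupling_slope), cfg$base_coupling)
})

test_that("non-positive-definite trait correlations are rejected", {
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(cohort_config(trait_corr = bad), class = "pb_config_error")
  expect_error(cohort_config(n_subjects = 1), class = "pb_config_error")
})

test_that("calibration sessions implement the 7 x 4 Latin-square design", {
  cfg <- cohort_config(n_subjects = 3, seed = 31)
  subj <- generate_subjects(cfg)
  for (i in 1:3) {
    cal <- generate_calibration_session(subj[i, ], cfg)
    expect_identical(nrow(cal), 28L)
    expect_true(all(table(cal$temp_C) == 4))
    expect_true(all(table(cal$temp_C, cal$site) == 1))
    expect_identical(sort(cal$order_idx), 1:28)
    expect_true(all(cal$rating_raw >= 0 & cal$rating_raw <= 200))
  }
})

test_that("noise- and adaptation-free calibration ratings lie on the latent curve", {
  cfg <- cohort_config(n_subjects = 2, seed = 32, rating_noise_sd = 0)
  subj <- generate_subjects(cfg)
  subj$sens_amp <- 0
  subj$habit_amp <- 0
  cal <- generate_calibration_session(subj[1, ], cfg)
  latent <- painbalance:::curve_sensation(cal$temp_C, subj$curve_offset[1],
                                          subj$curve_gain[1], subj$curve_exponent[1])
  expect_equal(cal$rating_raw, pmin(200, latent))
})

test_that("sensitization raises late-session ratings at matched temperatures", {
  cfg <- cohort_config(n_subjects = 2, seed = 33)
  diffs <- vapply(1:100, function(s) {
    subj <- generate_subjects(cohort_config(n_subjects = 2, seed = s))[1, ]
    subj$sens_amp <- 12
    subj$habit_amp <- 0
    cal <- generate_calibration_session(subj, cfg, seed = s)
    # same temperatures appear in each half by design balance; compare means
    # of matched-temperature ratings between the last and first 14 trials
    first <- cal[cal$order_idx <= 14, ]
    last <- cal[cal$order_idx > 14, ]
    shared <- intersect(first$temp_C, last$temp_C)
    mean(last$rating_raw[last$temp_C %in% shared]) -
      mean(first$rating_raw[first$temp_C %in% shared])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("noise-free generation round-trips through the calibration fit", {
  cfg <- cohort_config(n_subjects = 2, seed = 35, rating_noise_sd = 0)
  subj <- generate_subjects(cfg)
  cal <- generate_calibration_session(subj[1, ], cfg)
  corr <- correct_ratings(cal)
  fit <- fit_stimulus_response(corr$observations)
  expect_equal(fit$offset, subj$curve_offset[1], tolerance = 0.05)
  expect_equal(fit$exponent, subj$curve_exponent[1], tolerance = 0.05)
  expect_equal(min(fit$pain_temp, 49),
               min(painbalance:::curve_temperature(140, subj$curve_offset[1],
                                                   subj$curve_gain[1],
                                                   subj$curve_exponent[1]), 49),
               tolerance = 0.05)
})

test_that("behavioral sessions have the exact condition structure", {
  cfg <- cohort_config(n_subjects = 2, seed = 41)
  subj <- generate_subjects(cfg)
  tr <- generate_behavioral_session(subj[1, ], cfg)
  expect_identical(nrow(tr), 36L)
  expect_true(all(table(tr$task, tr$heat) == 9))
  expect_true(all(tr$A >= 0 & tr$A <= 1))
  expect_true(all(tr$sensation >= 0 & tr$sensation <= 200))
  # shared fixed pseudorandom order across subjects
  tr2 <- generate_behavioral_session(subj[2, ], cfg)
  expect_identical(tr$task, tr2$task)
  expect_identical(tr$heat, tr2$heat)
  # pain trials above the combined-scale threshold on average, warm below
  expect_gt(mean(tr$sensation[tr$heat == "pain"]), 100)
  expect_lt(mean(tr$sensation[tr$heat == "warm"]), 100)
  # response counts internally consistent
  expect_identical(tr$hits + tr$misses, tr$n_targets)
  expect_identical(tr$false_alarms + tr$correct_rejections, tr$n_nontargets)
})

test_that("zero coupling decouples sensation from performance", {
  # correlation within one task x heat cell, where condition-mean differences
  # cannot masquerade as trial-level coupling
  r <- vapply(1:200, function(s) {
    cfg <- cohort_config(n_subjects = 30, seed = 5000 + s, base_coupling = 0,
                         moderation_strength = c(pcs = 0, stai_t = 0, ffmq4 = 0))
    co <- simulate_cohort(cfg, calibration = FALSE)
    tr <- co$trials[co$trials$task == "2back" & co$trials$heat == "pain", ]
    rs <- tapply(seq_len(nrow(tr)), tr$subject_id, function(ix) {
      cor(tr$sensation[ix], tr$A[ix])
    })
    mean(rs)
  }, numeric(1))
  expect_lt(abs(mean(r)), 0.02)
})

test_that("negative coupling yields negative pooled within-subject correlations", {
  neg <- vapply(1:200, function(s) {
    cfg <- cohort_config(n_subjects = 41, seed = 6000 + s, base_coupling = -0.5,
                         moderation_strength = c(pcs = 0, stai_t = 0, ffmq4 = 0))
    co <- simulate_cohort(cfg, calibration = FALSE)
    tr <- co$trials[co$trials$task == "2back", ]
    rs <- tapply(seq_len(nrow(tr)), tr$subject_id, function(ix) {
      cor(tr$sensation[ix], tr$A[ix])
    })
    mean(rs)
  }, numeric(1))
  expect_gt(mean(neg < 0), 0.95)
})
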