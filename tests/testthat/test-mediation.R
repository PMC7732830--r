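test_that("within-subject z-scores have the defining properties", {
  d <- tibble::tibble(subject_id = rep(c("a", "b"), each = 3),
                      v = c(1, 2, 3, 10, 30, 50))
  z <- zscore_within_subject(d, "v")
  expect_equal(z$v[1:3], c(-1, 0, 1))  # sample-SD convention
  # location-scale invariance: both subjects have identical rank patterns
  expect_equal(z$v[1:3], z$v[4:6])
  by_subj <- tapply(z$v, z$subject_id, function(x) c(mean(x), sd(x)))
  for (s in by_subj) expect_equal(s, c(0, 1), tolerance = 1e-12)
  # constant subjects are flagged as degenerate
  dc <- tibble::tibble(subject_id = rep("a", 3), v = c(2, 2, 2))
  zc <- zscore_within_subject(dc, "v")
  expect_identical(attr(zc, "degenerate_subjects"), "a")
})

test_that("per-subject OLS decomposition c = c' + a*b is exact", {
  sp <- model_spec("pain_interference")
  set.seed(14)
  for (i in 1:50) {
    n <- sample(8:36, 1)
    d <- tibble::tibble(
      subject_id = "s",
      heat = sample(c("warm", "pain"), n, replace = TRUE, prob = c(0.5, 0.5)),
      sensation = rnorm(n, ifelse(heat == "pain", 120, 40), 15),
      A = rnorm(n, 0.85, 0.06))
    if (length(unique(d$heat)) < 2) next
    p <- fit_subject_paths(d, sp)
    expect_lt(abs(p$c - (p$c_prime + p$a * p$b)), 1e-10)
  }
})

test_that("null data produce null paths", {
  sp <- model_spec("pain_interference")
  set.seed(2)
  d <- tibble::tibble(
    subject_id = "s",
    heat = rep(c("warm", "pain"), 5000),
    sensation = rnorm(10000),
    A = rnorm(10000))
  p <- fit_subject_paths(d, sp)
  expect_lt(max(abs(c(p$a, p$b, p$c, p$c_prime))), 0.03)
})

test_that("degenerate subjects are rejected with classed errors", {
  sp <- model_spec("pain_interference")
  base <- tibble::tibble(subject_id = "s",
                         heat = rep(c("warm", "pain"), 3),
                         sensation = c(40, 120, 41, 121, 39, 119),
                         A = c(0.9, 0.8, 0.88, 0.82, 0.91, 0.79))
  expect_error(fit_subject_paths(base[1:3, ], sp), class = "pb_subject_excluded")
  const <- base
  const$A <- 0.8
  expect_error(fit_subject_paths(const, sp), class = "pb_degenerate_subject")
  # M a deterministic function of X: collinear, paths unidentifiable
  coll <- base
  coll$sensation <- ifelse(coll$heat == "pain", 1, 0)
  expect_error(fit_subject_paths(coll, sp), class = "pb_collinear_error")
})

test_that("bias-corrected bootstrap handles the degenerate zero-variance null", {
  paths <- tibble::tibble(subject_id = sprintf("s%02d", 1:12),
                          n_trials = 18, a = 0, b = 0, c = 0, c_prime = 0,
                          ab = 0, intercept = 0)
  res <- suppressWarnings(test_population_paths(paths, n_boot = 1000, seed = 1))
  expect_true(all(res$p == 1))
  expect_true(all(res$ci_lo == 0 & res$ci_hi == 0))
  # default resample count follows the reported analysis protocol
  expect_equal(formals(test_population_paths)$n_boot, 10000)
})

test_that("bootstrap intervals are ordered and deterministic under a seed", {
  set.seed(3)
  paths <- tibble::tibble(subject_id = sprintf("s%02d", 1:20),
                          n_trials = 18, a = rnorm(20, 0.8, 0.1),
                          b = rnorm(20, -0.2, 0.2), c = rnorm(20, -0.1, 0.1),
                          c_prime = rnorm(20, 0.05, 0.1), intercept = 0)
  paths$ab <- paths$a * paths$b
  r1 <- test_population_paths(paths, n_boot = 2000, seed = 42)
  r2 <- test_population_paths(paths, n_boot = 2000, seed = 42)
  expect_identical(r1, r2)
  expect_true(all(r1$ci_lo <= r1$estimate & r1$estimate <= r1$ci_hi))
  expect_true(all(r1$p > 0 & r1$p <= 1))
  # subject order must not matter for the point estimates
  shuf <- suppressWarnings(
    test_population_paths(paths[sample(20), ], n_boot = 500, seed = 42))
  expect_equal(shuf$estimate, r1$estimate)
})

test_that("bootstrap type-I error for the ab path is near nominal", {
  # null generator: zero coupling, zero moderation => generative ab = 0
  rejections <- vapply(1:300, function(s) {
    cfg <- cohort_config(n_subjects = 41, seed = 20000 + s, base_coupling = 0,
                         moderation_strength = c(pcs = 0, stai_t = 0, ffmq4 = 0))
    cp <- cohort_paths(cfg)
    res <- test_population_paths(cp$paths, n_boot = 1000, seed = s)
    res$p[res$path == "ab"] < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.01)
  expect_lt(mean(rejections), 0.09)
})

test_that("population a and b paths are recovered at scale", {
  cfg <- cohort_config(n_subjects = 200, seed = 77,
                       moderation_strength = c(pcs = 0, stai_t = 0, ffmq4 = 0))
  cp <- cohort_paths(cfg)
  expected <- analytic_paths_pain_interference(cfg)
  est <- colMeans(cp$paths[, c("a", "b")])
  expect_lt(abs(est[["a"]] - expected$a), 0.05)
  expect_lt(abs(est[["b"]] - expected$b), 0.05)
})

test_that("bootstrap CI coverage for the mean a path is near nominal", {
  # reference value: population mean of the per-subject statistic, from one
  # large independent cohort
  big <- cohort_paths(cohort_config(n_subjects = 4000, seed = 909,
                                    moderation_strength = c(pcs = 0, stai_t = 0,
                                                            ffmq4 = 0)))
  truth <- mean(big$paths$a)
  covered <- vapply(1:400, function(s) {
    cfg <- cohort_config(n_subjects = 41, seed = 30000 + s,
                         moderation_strength = c(pcs = 0, stai_t = 0, ffmq4 = 0))
    cp <- cohort_paths(cfg)
    res <- test_population_paths(cp$paths, n_boot = 2000, seed = s)
    a <- res[res$path == "a", ]
    a$ci_lo <= truth && truth <= a$ci_hi
  }, logical(1))
  expect_gt(mean(covered), 0.92)
  expect_lt(mean(covered), 0.98)
})

test_that("moderation is null when the trait is independent of coupling", {
  b2 <- vapply(1:200, function(s) {
    cfg <- cohort_config(n_subjects = 41, seed = 40000 + s,
                         moderation_strength = c(pcs = 0, stai_t = 0, ffmq4 = 0))
    cp <- cohort_paths(cfg)
    m <- moderated_mediation(cp$paths, cp$subjects, "pcs", n_boot = 0)
    m$estimate[m$path == "b2"]
  }, numeric(1))
  expect_lt(abs(median(b2)), 0.05)
})

test_that("strong catastrophizing moderation is recovered with the documented sign", {
  # higher pcs steepens the (negative) coupling, so the b path grows more
  # negative with pcs: b2 < 0 under this package's sign convention
  b2 <- vapply(1:200, function(s) {
    cfg <- cohort_config(n_subjects = 41, seed = 50000 + s, base_coupling = -0.3,
                         moderation_strength = c(pcs = 0.15, stai_t = 0, ffmq4 = 0))
    cp <- cohort_paths(cfg)
    m <- moderated_mediation(cp$paths, cp$subjects, "pcs", n_boot = 0)
    m$estimate[m$path == "b2"]
  }, numeric(1))
  expect_gt(mean(b2 < 0), 0.9)
})

test_that("residualization against orthogonal covariates is a no-op", {
  set.seed(9)
  cfg <- cohort_config(n_subjects = 60, seed = 61)
  cp <- cohort_paths(cfg)
  subj <- cp$subjects
  # covariates exactly orthogonal to the moderator
  subj$cov_orth1 <- rnorm(60)
  subj$cov_orth1 <- residuals(lm(subj$cov_orth1 ~ subj$pcs))
  subj$cov_orth2 <- residuals(lm(rnorm(60) ~ subj$pcs))
  with_cov <- moderated_mediation(cp$paths, subj, "pcs",
                                  covariates = c("cov_orth1", "cov_orth2"),
                                  n_boot = 0)
  without <- moderated_mediation(cp$paths, subj, "pcs",
                                 covariates = character(0), n_boot = 0)
  expect_equal(with_cov$estimate, without$estimate, tolerance = 1e-6)
  # constant moderator after residualization is rejected
  subj$flat <- 5
  expect_error(moderated_mediation(cp$paths, subj, "flat", n_boot = 0),
               class = "pb_degenerate_moderator")
})

test_that("run_model applies the documented trial filters", {
  cfg <- cohort_config(n_subjects = 12, seed = 71)
  co <- simulate_cohort(cfg, calibration = FALSE)
  m1 <- run_model(co$trials, "pain_interference", subjects = co$subjects,
                  moderators = character(0), n_boot = 1000, seed = 1)
  expect_equal(sum(m1$paths$n_trials), sum(co$trials$task == "2back"))
  m2 <- run_model(co$trials, "task_analgesia", subjects = co$subjects,
                  moderators = character(0), n_boot = 1000, seed = 1)
  expect_equal(sum(m2$paths$n_trials), sum(co$trials$heat == "pain"))
  # empty filtered set is an explicit error
  warm_only <- co$trials[co$trials$heat == "warm", ]
  expect_error(run_model(warm_only, "task_analgesia"), class = "pb_empty_model")
  # tidy/glance interfaces
  td <- tidy(m1)
  expect_true(all(c("model", "moderator", "path", "estimate", "p") %in% names(td)))
  expect_equal(nrow(td), 5)
  gl <- glance(m1)
  expect_equal(gl$n_subjects, 12)
})

test_that("the task-analgesia model shows the suppression pattern", {
  # negative coupling: the indirect effect ab opposes the total effect c
  res <- vapply(1:200, function(s) {
    cfg <- cohort_config(n_subjects = 41, seed = 60000 + s)
    cp <- cohort_paths(cfg, model = "task_analgesia")
    est <- colMeans(cp$paths[, c("ab", "c")])
    sign(est[["ab"]]) != sign(est[["c"]])
  }, logical(1))
  expect_gt(mean(res), 0.5)
})
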