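test_that("stabilized baseline weight matches the two-stratum closed form", {
  # P(A=1)=0.5 marginally, P(A=1|eligible)=0.8, P(A=1|ineligible)=0.2:
  # treated eligible rows get 0.5/0.8 = 0.625
  co <- manual_cohort(
    baseline_cd4 = rep(c(150, 250), each = 100),
    art_init_time = c(rep(0L, 80), rep(NA_integer_, 20),
                      rep(0L, 20), rep(NA_integer_, 80)),
    event_time = rep(NA_integer_, 200),
    followup_end = rep(5L, 200))
  ws <- fit_baseline_weights(co, weight_model_spec(denominator = "eligible"))
  w <- ws$weights$w_treat
  treated_elig <- !is.na(co$art_init_time) & co$baseline_cd4 < 200
  expect_equal(unique(round(w[treated_elig], 10)), 0.625)
  untreated_inel <- is.na(co$art_init_time) & co$baseline_cd4 >= 200
  expect_equal(unique(round(w[untreated_inel], 10)), 0.625)
  expect_lt(abs(mean(w) - 1), 1e-9)
})

test_that("weights are near one when covariates do not predict treatment", {
  sim <- generate_cohort(sim_config(n_subjects = 3000, p_init_below = 0.5,
                                    p_init_above = 0.5, n_periods = 6,
                                    seed = 33L))
  ws <- fit_baseline_weights(sim$cohort)
  expect_lt(abs(mean(ws$weights$w_treat) - 1), 0.02)
  expect_lt(sd(ws$weights$w_treat), 0.1)
})

test_that("time-varying ratios collapse to one when models coincide", {
  sim <- small_cohort()
  pp <- expand_person_periods(sim$cohort)
  same <- weight_model_spec(denominator = c("baseline_cd4", "eligible"),
                            numerator = c("baseline_cd4", "eligible"))
  ws <- fit_timevarying_weights(pp, same)
  expect_lt(max(abs(ws$weights$w_treat - 1)), 1e-10)
})

test_that("cumulative time-varying weights match a per-subject loop oracle", {
  cfg <- sim_config(n_subjects = 50, p_init_below = 0.4, p_init_above = 0.2,
                    late_init_hazard = 0.05, n_periods = 18, seed = 35L)
  pp <- expand_person_periods(generate_cohort(cfg)$cohort)
  ws <- fit_timevarying_weights(pp)

  # refit the pooled models exactly as specified and accumulate per subject
  first_on <- pp$art_now == 1 & !duplicated(paste(pp$subject_id, pp$art_now))
  at_risk <- pp$art_now == 0 | first_on
  init_k <- as.numeric(first_on)
  Ld <- cbind(rddmsm:::weight_covariate_frame(
    pp, c("baseline_cd4", "eligible", "current_cd4"), 200),
    rddmsm:::period_frame(pp$period))
  Ln <- cbind(rddmsm:::weight_covariate_frame(
    pp, c("baseline_cd4", "eligible"), 200),
    rddmsm:::period_frame(pp$period))
  p_d <- fitted(glm(init_k ~ ., data = cbind(init_k = init_k, Ld)[at_risk, ],
                    family = binomial()))
  p_n <- fitted(glm(init_k ~ ., data = cbind(init_k = init_k, Ln)[at_risk, ],
                    family = binomial()))
  contrib <- rep(1, nrow(pp))
  contrib[at_risk] <- ifelse(init_k[at_risk] == 1, p_n / p_d,
                             (1 - p_n) / (1 - p_d))
  oracle <- numeric(nrow(pp))
  for (s in unique(pp$subject_id)) {
    rows <- which(pp$subject_id == s)
    rows <- rows[order(pp$period[rows])]
    acc <- 1
    for (r in rows) {
      acc <- acc * contrib[r]
      oracle[r] <- acc
    }
  }
  expect_lt(max(abs(ws$weights$w_treat - oracle)), 1e-12)
})

test_that("censoring weights are unity without censoring", {
  co <- manual_cohort(baseline_cd4 = c(150, 250),
                      art_init_time = c(0L, NA),
                      event_time = c(NA, NA),
                      followup_end = c(11L, 11L),
                      labs = list(c(0L, 6L), c(0L, 6L)))
  pp <- expand_person_periods(co)
  cw <- fit_censoring_weights(pp)
  expect_true(all(cw$weights$w_cens == 1))
})

test_that("non-informative censoring gives weights near one at scale", {
  cfg <- sim_config(n_subjects = 2500, p_lab_miss = 0.35, n_periods = 30,
                    seed = 37L)
  pp <- apply_lab_gap_censoring(expand_person_periods(
    generate_cohort(cfg)$cohort))
  cw <- fit_censoring_weights(pp)
  expect_lt(abs(mean(cw$weights$w_cens) - 1), 0.05)
})

test_that("censoring weights move the estimate toward the truth under informative dropout", {
  # disengagement rises as the measured CD4 falls and is rarer on ART;
  # with deferred initiation in play this censors the sick untreated
  # differentially, attenuating the unweighted estimate
  runs <- t(vapply(1:20, function(s) {
    cfg <- sim_config(n_subjects = 3000, n_periods = 36, seed = 800 + s,
                      cd4_sd = 30, dropout_rate = 0.03,
                      dropout_cd4_slope = -0.025,
                      dropout_art_multiplier = 0.2)
    ppc <- apply_lab_gap_censoring(expand_person_periods(
      generate_cohort(cfg)$cohort))
    tw <- fit_timevarying_weights(ppc)
    cw <- fit_censoring_weights(ppc, tw)
    c(unc = log(fit_msm(ppc, tw, "time-varying")$hr),
      cor = log(fit_msm(ppc, cw, "time-varying-censor")$hr))
  }, c(unc = 0, cor = 0)))
  # informative censoring attenuates the unweighted estimate; the paired
  # within-cohort comparison isolates the correction from shared
  # cohort-level noise
  shift <- runs[, "unc"] - runs[, "cor"]
  expect_gt(mean(shift) / (sd(shift) / sqrt(nrow(runs))), 2)
  expect_lt(abs(mean(runs[, "cor"]) - log(0.5)), 0.1)
})

test_that("all-ones weights reproduce the unweighted fit exactly", {
  sim <- small_cohort()
  pp <- expand_person_periods(sim$cohort)
  ones <- rddmsm:::new_weight_set(pp$subject_id, pp$period,
                                  rep(1, nrow(pp)))
  f0 <- fit_msm(pp, NULL, "time-invariant")
  f1 <- fit_msm(pp, ones, "time-invariant")
  expect_equal(f0$coefficients, f1$coefficients, tolerance = 1e-12)
  expect_false(f0$weighted)
  expect_true(f1$weighted)
})

test_that("weight and row misalignment and zero events are rejected", {
  sim <- small_cohort()
  pp <- expand_person_periods(sim$cohort)
  short <- rddmsm:::new_weight_set(pp$subject_id[1:10], pp$period[1:10],
                                   rep(1, 10))
  expect_error(fit_msm(pp, short, "time-varying"), "align")
  pp0 <- pp[pp$event == 0, ][1:500, ]
  expect_error(fit_msm(pp0, NULL, "time-invariant"), "events")
})

test_that("interaction model recovers a time-sloped treatment effect", {
  res <- vapply(1:15, function(s) {
    cfg <- sim_config(n_subjects = 4000, n_periods = 36, seed = 940 + s,
                      p_init_below = 0.9, p_init_above = 0.1,
                      late_init_hazard = 0, effect_time_slope = log(0.9))
    pp <- expand_person_periods(generate_cohort(cfg)$cohort)
    log(fit_msm_interaction(pp, NULL)$per_year_hr)
  }, 0)
  expect_lt(abs(mean(res) - log(0.9)), 0.09)
})

test_that("weight diagnostics summarize and warn as specified", {
  d0 <- weight_diagnostics(rep(1, 100))
  expect_equal(d0$mean, 1)
  expect_equal(d0$sd, 0)
  expect_length(d0$warnings, 0)
  expect_warning(d1 <- weight_diagnostics(c(rep(1, 999), 50)), "maximum")
  expect_true(any(grepl("exceeds 10", d1$warnings)))
  d2 <- suppressWarnings(weight_diagnostics(c(rep(1, 99), 50)))
  expect_length(d2$warnings, 2L)  # both mean drift and extreme maximum
  expect_error(weight_diagnostics(numeric(0)), "empty")
})

test_that("weight truncation clamps the extremes symmetrically", {
  set.seed(51)
  w <- exp(rnorm(500))
  tr <- rddmsm:::truncate_weights(w, c(0.05, 0.95))
  expect_equal(min(tr), unname(quantile(w, 0.05)))
  expect_equal(max(tr), unname(quantile(w, 0.95)))
  expect_identical(rddmsm:::truncate_weights(w, NULL), w)
})
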