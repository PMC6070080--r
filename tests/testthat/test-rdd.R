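test_that("first stage is exact under a sharp design and null under no jump", {
  sharp <- generate_cohort(sim_config(n_subjects = 1500, p_init_below = 1,
                                      p_init_above = 0, late_init_hazard = 0,
                                      n_periods = 12, seed = 2L))
  fs <- fit_first_stage(sharp$cohort)
  expect_equal(fs$jump, 1, tolerance = 1e-9)

  flat <- generate_cohort(sim_config(n_subjects = 4000, p_init_below = 0.5,
                                     p_init_above = 0.5, late_init_hazard = 0,
                                     n_periods = 12, seed = 4L))
  fs0 <- fit_first_stage(flat$cohort)
  expect_lt(abs(fs0$jump), 3 * fs0$se)
})

test_that("first-stage jump is recovered inside a narrow window", {
  sim <- generate_cohort(sim_config(n_subjects = 10000, p_init_below = 0.8,
                                    p_init_above = 0.2, late_init_hazard = 0,
                                    n_periods = 12, seed = 6L))
  fs <- fit_first_stage(sim$cohort, bandwidth_window(150, 250))
  expect_lt(abs(fs$jump - 0.6), 3 * fs$se)
  expect_error(fit_first_stage(sim$cohort, bandwidth_window(300, 350)),
               "below")
})

test_that("binned summaries conserve cohort totals and bin conventions", {
  sim <- small_cohort()
  bs <- binned_summary(sim$cohort)
  expect_equal(sum(bs$deaths), sum(!is.na(sim$cohort$event_time)))
  expect_lt(abs(sum(bs$person_years) -
                  sum(sim$cohort$followup_end + 1) / 12), 1e-9)
  expect_equal(sum(bs$n), nrow(sim$cohort))
  # a count of exactly 200 falls in the bin starting at 200
  co <- manual_cohort(200, NA_integer_, NA_integer_, 11L)
  b1 <- binned_summary(co)
  expect_equal(b1$n[b1$bin_lower == 200], 1L)
  # single bin collapses to the overall incidence rate
  whole <- binned_summary(sim$cohort, bin_width = 350)
  ir <- incidence_rate(sum(!is.na(sim$cohort$event_time)),
                       sum(sim$cohort$followup_end + 1) / 12)
  expect_equal(100 * whole$hazard[1], ir$rate_per_100py, tolerance = 1e-9)
})

test_that("density continuity diagnostic is calibrated and flags degeneracy", {
  sim <- generate_cohort(sim_config(n_subjects = 10000, n_periods = 6,
                                    seed = 8L))
  dc <- density_continuity_check(sim$cohort)
  expect_equal(dc$status, "consistent")
  expect_true(dc$ci95[1] < 1 && dc$ci95[2] > 1)

  low <- manual_cohort(rep(c(120, 150), 20), rep(NA_integer_, 40),
                       rep(NA_integer_, 40), rep(5L, 40))
  expect_equal(density_continuity_check(low)$status, "inconclusive")
})

test_that("ITT eligibility coefficient is null when nothing jumps", {
  cfg <- sim_config(n_subjects = 4000, p_init_below = 0, p_init_above = 0,
                    late_init_hazard = 0, true_log_hr = 0,
                    n_periods = 24, seed = 10L)
  pp <- expand_person_periods(generate_cohort(cfg)$cohort)
  fit <- fit_rdd_itt(pp, rdd_spec())
  b <- fit$coefficients["eligible"]
  expect_lt(abs(b), 3 * fit$se["eligible"])
})

test_that("ITT functional forms and covariates fit without degeneracy", {
  sim <- small_cohort()
  pp <- expand_person_periods(sim$cohort)
  for (form in c("linear-gap", "squared-below", "spline")) {
    fit <- fit_rdd_itt(pp, rdd_spec(form = form))
    expect_true(fit$hr > 0)
    expect_true(fit$ci95[1] <= fit$hr && fit$hr <= fit$ci95[2])
  }
  fit_cv <- fit_rdd_itt(pp, rdd_spec(covariates = c("age", "sex")))
  expect_true(is.finite(fit_cv$hr))
})

test_that("ITT errors name the event-free side", {
  co <- manual_cohort(baseline_cd4 = c(150, 250, 160, 260),
                      art_init_time = rep(NA_integer_, 4),
                      event_time = c(5L, NA, NA, NA),
                      followup_end = c(5L, 11L, 11L, 11L))
  pp <- expand_person_periods(co)
  expect_error(fit_rdd_itt(pp, rdd_spec()), "above")
})

test_that("discrete-hazard coefficients match a direct likelihood oracle", {
  # 30-row fixture with two periods; oracle maximizes the Bernoulli
  # cloglog likelihood by Nelder-Mead from a remote start
  co <- manual_cohort(
    baseline_cd4 = c(120, 140, 160, 180, 190, 205, 215, 230, 260, 290,
                     110, 150, 170, 185, 195, 210, 225, 245, 270, 300),
    art_init_time = rep(NA_integer_, 20),
    event_time = c(1L, NA, 0L, NA, 1L, NA, 1L, NA, NA, 0L,
                   NA, 1L, NA, 0L, NA, 1L, NA, NA, 1L, NA),
    followup_end = c(1L, 1L, 0L, 1L, 1L, 1L, 1L, 1L, 1L, 0L,
                     1L, 1L, 1L, 0L, 1L, 1L, 1L, 1L, 1L, 1L))
  pp <- expand_person_periods(co)
  expect_equal(nrow(pp), 37L)
  pp <- pp[1:30, ]
  fit <- fit_rdd_itt(pp, rdd_spec())

  elig <- as.numeric(pp$baseline_cd4 < 200)
  gap <- pp$baseline_cd4 - 200
  X <- cbind(1, elig, gap * elig, gap * (1 - elig),
             as.numeric(pp$period == 1))
  nll <- function(b) {
    eta <- drop(X %*% b)
    p <- 1 - exp(-exp(eta))
    -sum(ifelse(pp$event == 1, log(p), log(1 - p)))
  }
  o <- optim(rep(0, 5), nll, method = "Nelder-Mead",
             control = list(maxit = 50000, reltol = 1e-14))
  o <- optim(o$par, nll, method = "Nelder-Mead",
             control = list(maxit = 50000, reltol = 1e-14))
  expect_lt(max(abs(unname(fit$coefficients) - o$par)), 1e-3)
})

test_that("CACE equals ITT under a sharp design", {
  sim <- generate_cohort(sim_config(n_subjects = 3000, p_init_below = 1,
                                    p_init_above = 0, late_init_hazard = 0,
                                    n_periods = 24, seed = 12L))
  pp <- expand_person_periods(sim$cohort)
  itt <- fit_rdd_itt(pp, rdd_spec(link = "probit"))
  cace <- fit_rdd_cace(pp, rdd_spec())
  expect_match(cace$method, "sharp")
  expect_lt(abs(unname(itt$coefficients["eligible"]) - cace$coef), 1e-6)
})

test_that("Wald complier effect: arithmetic and dilution logic", {
  expect_equal(wald_cace(-0.03, 0.6), -0.05)
  expect_equal(wald_cace(-0.2, 1), -0.2)  # perfect compliance = ITT
  expect_error(wald_cace(-0.1, 0), "zero")
})

test_that("Wald ratio recovers the complier risk difference in one-period cohorts", {
  # compliance classes fixed by construction: 10% always, 60% complier,
  # 30% never; risk 0.12 untreated, 0.06 treated
  set.seed(15)
  est <- replicate(200, {
    n <- 2000
    z <- rbinom(n, 1, 0.5)
    u <- runif(n)
    a <- as.numeric(u < 0.1 | (u < 0.7 & z == 1))
    y <- rbinom(n, 1, 0.12 - 0.06 * a)
    itt <- mean(y[z == 1]) - mean(y[z == 0])
    jump <- mean(a[z == 1]) - mean(a[z == 0])
    wald_cace(itt, jump)
  })
  expect_lt(abs(mean(est) - (-0.06)), 0.006)
})

test_that("fuzzy CACE warns when the first stage is weak", {
  sim <- generate_cohort(sim_config(n_subjects = 1500, p_init_below = 0.4,
                                    p_init_above = 0.4,
                                    late_init_hazard = 0.02,
                                    n_periods = 24, seed = 14L))
  pp <- expand_person_periods(sim$cohort)
  expect_warning(fit_rdd_cace(pp, rdd_spec()), "weak first stage")
})
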