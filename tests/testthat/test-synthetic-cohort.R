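test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- sim_config(n_subjects = 300, n_periods = 18, seed = 9L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth, b$truth)
})

test_that("empty cohort request returns empty tables without error", {
  sim <- generate_cohort(sim_config(n_subjects = 0))
  expect_equal(nrow(sim$cohort), 0L)
  expect_equal(nrow(sim$truth), 0L)
})

test_that("config validation rejects invalid probabilities and ranges", {
  expect_error(sim_config(p_init_below = 1.2), "probabilities")
  expect_error(sim_config(cd4_range = c(300, 100)), "increasing")
  expect_error(sim_config(threshold = 400), "threshold")
  expect_error(sim_config(hazard_slope = 0.01), "hazard_slope")
  expect_error(sim_config(n_assets = 1), "n_assets")
})

test_that("eligible fraction matches the configured CD4 mass below threshold", {
  sim <- generate_cohort(sim_config(seed = 11L, n_periods = 6))
  frac <- mean(sim$cohort$baseline_cd4 < 200)
  expect_lt(abs(frac - 2751 / 4435), 0.015)
})

test_that("sharp assignment limits are deterministic", {
  cfg <- sim_config(n_subjects = 500, p_init_below = 1, p_init_above = 0,
                    late_init_hazard = 0, n_periods = 12, seed = 3L)
  sim <- generate_cohort(cfg)
  below <- sim$cohort$baseline_cd4 < 200
  expect_true(all(sim$cohort$art_init_time[below] == 0L))
  expect_true(all(is.na(sim$cohort$art_init_time[!below])))
})

test_that("compliance classes are exhaustive and contain no defiers", {
  sim <- generate_cohort(sim_config(n_subjects = 2000, n_periods = 6,
                                    seed = 21L))
  cls <- sim$truth$compliance_class
  expect_false(anyNA(cls))
  expect_true(all(cls %in% c("always", "complier", "never")))
  # immediate initiation is monotone in eligibility: every always-taker
  # initiates at 0 regardless of side, never-takers never do
  imm <- !is.na(sim$truth$assigned_init_time) &
    sim$truth$assigned_init_time == 0L
  expect_true(all(imm[cls == "always"]))
  expect_false(any(imm[cls == "never"]))
})

test_that("first-interval initiation jump matches configured probabilities", {
  cfg <- sim_config(n_subjects = 10000, p_init_below = 0.8,
                    p_init_above = 0.2, late_init_hazard = 0,
                    n_periods = 6, seed = 5L)
  sim <- generate_cohort(cfg)
  below <- sim$cohort$baseline_cd4 < 200
  init0 <- !is.na(sim$cohort$art_init_time) & sim$cohort$art_init_time == 0L
  jump <- mean(init0[below]) - mean(init0[!below])
  se <- sqrt(0.8 * 0.2 / sum(below) + 0.2 * 0.8 / sum(!below))
  expect_lt(abs(jump - 0.6), 3 * se)
})

test_that("constant-hazard cohorts die at the closed-form geometric rate", {
  cfg <- sim_config(n_subjects = 3000, p_init_below = 0, p_init_above = 0,
                    late_init_hazard = 0, dropout_rate = 0,
                    hazard_slope = 0, hazard_intercept = -4.0,
                    n_periods = 24, seed = 7L)
  sim <- generate_cohort(cfg)
  p <- 1 - exp(-exp(-4.0))
  expected <- 1 - (1 - p)^24
  observed <- mean(!is.na(sim$cohort$event_time))
  se <- sqrt(expected * (1 - expected) / 3000)
  expect_lt(abs(observed - expected), 4 * se)
})

test_that("mortality hazard decreases in CD4", {
  cfg <- sim_config(n_subjects = 6000, n_periods = 12, dropout_rate = 0,
                    seed = 13L)
  cd4 <- rep(c(50, 300), each = 3000)
  out <- simulate_outcomes(cd4, rep(NA_integer_, 6000), cfg)
  died <- !is.na(out$event_time)
  expect_gt(mean(died[cd4 == 50]), mean(died[cd4 == 300]))
})

test_that("null treatment effect leaves treated and untreated hazards equal", {
  cfg <- sim_config(n_subjects = 8000, true_log_hr = 0, n_periods = 12,
                    dropout_rate = 0, hazard_slope = 0, seed = 17L)
  cd4 <- rep(150, 8000)
  art <- rep(c(0L, NA_integer_), each = 4000)
  out <- simulate_outcomes(cd4, art, cfg)
  died <- !is.na(out$event_time)
  p1 <- mean(died[1:4000]); p0 <- mean(died[4001:8000])
  expect_lt(abs(p1 - p0), 4 * sqrt(2 * p1 * (1 - p1) / 4000))
})

test_that("absurd hazard parameters raise an error naming the CD4 value", {
  cfg <- sim_config(n_subjects = 5, hazard_intercept = 5, hazard_slope = 0,
                    n_periods = 2, seed = 1L)
  expect_error(simulate_outcomes(c(10, 20, 30, 40, 50),
                                 rep(NA_integer_, 5), cfg),
               "CD4")
})

test_that("disengagement stops labs and late initiation but not mortality follow-up", {
  cfg <- sim_config(n_subjects = 3000, dropout_rate = 0.05,
                    p_init_below = 0.5, p_init_above = 0.1,
                    late_init_hazard = 0.05, n_periods = 24, seed = 19L)
  sim <- generate_cohort(cfg)
  dis <- sim$truth$disengage_time
  has_dis <- !is.na(dis)
  expect_gt(sum(has_dis), 100)
  # follow-up extends beyond disengagement for survivors
  surv <- has_dis & is.na(sim$cohort$event_time)
  expect_true(all(sim$cohort$followup_end[surv] == cfg$n_periods - 1L))
  # no lab after disengagement
  labs <- parse_lab_times(sim$cohort$lab_times)
  last_lab <- vapply(labs, function(v) if (length(v)) max(v) else -1L, 0L)
  expect_true(all(last_lab[has_dis] <= dis[has_dis]))
  # no ART initiation after disengagement
  init <- sim$cohort$art_init_time
  both <- has_dis & !is.na(init)
  expect_true(all(init[both] <= dis[both]))
})

test_that("wealth quintiles partition subjects evenly for continuous scores", {
  set.seed(31)
  assets <- matrix(rbinom(1000 * 12, 1, 0.5), 1000, 12)
  q <- rddmsm:::wealth_quintiles(assets)$wealth_quintile
  expect_true(all(abs(table(q) - 200) <= 1))
})

test_that("a single informative asset column determines the quintiles", {
  assets <- cbind(split = rep(c(0, 1), each = 50),
                  matrix(1, 100, 4))
  out <- rddmsm:::wealth_quintiles(assets)
  q <- out$wealth_quintile
  expect_equal(length(unique(q[assets[, 1] == 0])), 1L)
  expect_equal(length(unique(q[assets[, 1] == 1])), 1L)
  expect_true(q[1] < q[100])  # owning the asset ranks higher
})

test_that("a zero-variance asset matrix is rejected", {
  expect_error(rddmsm:::wealth_quintiles(matrix(1, 50, 6)), "degenerate")
})

test_that("asset missingness propagates to the wealth quintile", {
  set.seed(41)
  out <- generate_assets_and_wealth(600, 10, p_missing = 0.2)
  miss <- is.na(out$wealth_quintile)
  expect_gt(mean(miss), 0.12)
  expect_lt(mean(miss), 0.28)
  expect_true(all(is.na(out$assets[miss, ])))
  expect_false(anyNA(out$assets[!miss, ]))
})
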