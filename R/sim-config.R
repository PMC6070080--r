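#' Simulation configuration for synthetic HIV-care cohorts
#'
#' Collects every knob of the synthetic-cohort generator into a validated
#' list.  The defaults emulate the data structure of a public-sector HIV
#' treatment programme in which patients entering care with a CD4 count at
#' or below 350 cells/uL become eligible for antiretroviral therapy (ART)
#' once the count drops below 200 cells/uL: a fuzzy jump in the probability
#' of prompt ART initiation at the threshold, a mortality hazard that falls
#' with CD4 count (confounding by indication), a protective conditional
#' treatment effect, 6-monthly laboratory monitoring with missed visits and
#' absorbing dropout, and a 32-item household asset inventory from which a
#' wealth index is derived by principal components analysis.
#'
#' @param n_subjects Number of subjects to generate.
#' @param threshold Eligibility threshold on the assignment variable
#'   (baseline CD4 count, cells/uL).  Counts strictly below the threshold
#'   are eligible.
#' @param cd4_range Length-2 numeric, support of the baseline CD4
#'   distribution in cells/uL.
#' @param p_eligible Target probability that a subject's baseline CD4 falls
#'   below \code{threshold}; the CD4 density is a continuous, linearly
#'   decreasing density on \code{cd4_range} calibrated to this mass.
#' @param p_init_below,p_init_above Probability of ART initiation within the
#'   first monitoring interval for subjects below / above the threshold.
#'   Their difference is the first-stage discontinuity of the fuzzy design.
#' @param late_init_hazard Per-period probability that an initial
#'   non-initiator starts ART in a later period (deferred patients return at
#'   subsequent monitoring visits).
#' @param true_log_hr Conditional log hazard ratio of current ART exposure,
#'   the ground truth that estimators are asked to recover.  Default
#'   \code{log(0.5)}.
#' @param effect_time_slope Additional log hazard ratio of ART per year
#'   since entry (effect heterogeneity over time); default 0, i.e. a
#'   constant effect.
#' @param hazard_intercept,hazard_slope Parameters of the baseline
#'   discrete-time hazard: the per-period (monthly) event probability for an
#'   untreated subject with current CD4 count \eqn{x} is
#'   \eqn{1 - \exp(-\exp(a + b x))} with intercept \eqn{a} and slope
#'   \eqn{b < 0}, so the hazard is strictly decreasing in CD4.
#' @param n_periods Maximum number of follow-up periods.
#' @param period_length Months per discrete period.
#' @param lab_interval Months between scheduled laboratory visits.
#' @param p_lab_miss Per-visit probability that a scheduled laboratory
#'   measurement is skipped (the entry measurement at period 0 is always
#'   recorded).
#' @param dropout_rate Per-period probability of disengaging from clinical
#'   care at the reference CD4 count of 200 cells/uL.  Disengagement is
#'   absorbing and ends laboratory monitoring (and any later ART
#'   initiation); mortality remains observed, mirroring ascertainment
#'   through population surveillance.
#' @param dropout_cd4_slope Log-odds change in the per-period dropout
#'   probability per cell/uL of current CD4; a negative value makes sicker
#'   patients drop out more (informative censoring).  Default 0.
#' @param dropout_art_multiplier Multiplier on the odds of dropout while on
#'   ART; values below 1 emulate better retention in care among treated
#'   patients, which together with a negative \code{dropout_cd4_slope}
#'   makes censoring informative for the treatment contrast.  Default 1.
#' @param cd4_drift Deterministic drift of the latent CD4 count in
#'   cells/uL per month (applied to everyone; default 0 so the treatment
#'   log hazard ratio is exactly \code{true_log_hr}).
#' @param cd4_sd Standard deviation of the per-period random-walk
#'   innovation of the latent CD4 count (cells/uL); default 0.
#' @param n_assets Number of binary household asset indicators.
#' @param p_assets_missing Fraction of subjects whose asset inventory (and
#'   hence wealth quintile) is missing.
#' @param p_residence_missing,p_education_missing Missingness fractions for
#'   the place-of-residence and educational-attainment covariates.
#' @param seed Integer RNG seed; the same configuration and seed reproduce
#'   the cohort exactly.
#'
#' @return An object of class \code{sim_config} (a named list).
#' @seealso [generate_cohort()]
#' @export
sim_config <- function(n_subjects = 4435,
                       threshold = 200,
                       cd4_range = c(0, 350),
                       p_eligible = 2751 / 4435,
                       p_init_below = 0.75,
                       p_init_above = 0.15,
                       late_init_hazard = 0.03,
                       true_log_hr = log(0.5),
                       effect_time_slope = 0,
                       hazard_intercept = -4.0,
                       hazard_slope = -0.007,
                       n_periods = 60,
                       period_length = 1,
                       lab_interval = 6,
                       p_lab_miss = 0.2,
                       dropout_rate = 0.01,
                       dropout_cd4_slope = 0,
                       dropout_art_multiplier = 1,
                       cd4_drift = 0,
                       cd4_sd = 0,
                       n_assets = 32,
                       p_assets_missing = 0.10,
                       p_residence_missing = 0.10,
                       p_education_missing = 0.02,
                       seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), threshold = threshold,
    cd4_range = as.numeric(cd4_range), p_eligible = p_eligible,
    p_init_below = p_init_below, p_init_above = p_init_above,
    late_init_hazard = late_init_hazard, true_log_hr = true_log_hr,
    effect_time_slope = effect_time_slope,
    hazard_intercept = hazard_intercept, hazard_slope = hazard_slope,
    n_periods = as.integer(n_periods), period_length = period_length,
    lab_interval = lab_interval, p_lab_miss = p_lab_miss,
    dropout_rate = dropout_rate, dropout_cd4_slope = dropout_cd4_slope,
    dropout_art_multiplier = dropout_art_multiplier,
    cd4_drift = cd4_drift, cd4_sd = cd4_sd,
    n_assets = as.integer(n_assets), p_assets_missing = p_assets_missing,
    p_residence_missing = p_residence_missing,
    p_education_missing = p_education_missing,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_subjects < 0L) stop("n_subjects must be nonnegative")
  probs <- c(cfg$p_eligible, cfg$p_init_below, cfg$p_init_above,
             cfg$late_init_hazard, cfg$p_lab_miss, cfg$dropout_rate,
             cfg$p_assets_missing, cfg$p_residence_missing,
             cfg$p_education_missing)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities in a sim_config must lie in [0, 1]")
  }
  if (length(cfg$cd4_range) != 2L || cfg$cd4_range[1] >= cfg$cd4_range[2]) {
    stop("cd4_range must be an increasing interval")
  }
  if (cfg$threshold < cfg$cd4_range[1] || cfg$threshold > cfg$cd4_range[2]) {
    stop("threshold must lie inside cd4_range")
  }
  if (cfg$dropout_art_multiplier <= 0) {
    stop("dropout_art_multiplier must be positive")
  }
  if (cfg$n_periods < 1L) stop("n_periods must be at least 1")
  if (cfg$period_length <= 0) stop("period_length must be positive")
  if (cfg$lab_interval <= 0) stop("lab_interval must be positive")
  if (cfg$hazard_slope > 0) {
    stop("hazard_slope must be <= 0: the hazard must not increase with CD4")
  }
  if (cfg$n_assets < 2L) stop("n_assets must be at least 2")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  n_subjects: %d, threshold: %g cells/uL, CD4 range: [%g, %g]\n",
              x$n_subjects, x$threshold, x$cd4_range[1], x$cd4_range[2]))
  cat(sprintf("  P(init | below): %.2f, P(init | above): %.2f, late-init hazard: %.3f\n",
              x$p_init_below, x$p_init_above, x$late_init_hazard))
  cat(sprintf("  true log HR: %.4f (HR %.3f), time slope: %.3f/yr\n",
              x$true_log_hr, exp(x$true_log_hr), x$effect_time_slope))
  cat(sprintf("  follow-up: %d periods of %g month(s), labs every %g months\n",
              x$n_periods, x$period_length, x$lab_interval))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Inverse-CDF sampler for the baseline CD4 distribution: a linearly
# decreasing density f(x) = a - b x on [lo, hi], continuous everywhere
# (in particular at the threshold), with P(X < threshold) = p_eligible.
# Solving the two moment conditions gives a and b in closed form.
cd4_density_coefs <- function(cfg) {
  lo <- cfg$cd4_range[1]; hi <- cfg$cd4_range[2]; thr <- cfg$threshold
  p <- cfg$p_eligible
  # integral lo..thr (a - b x) dx = p ; integral lo..hi = 1
  # a (thr-lo) - b (thr^2-lo^2)/2 = p ; a (hi-lo) - b (hi^2-lo^2)/2 = 1
  m <- rbind(c(thr - lo, -(thr^2 - lo^2) / 2),
             c(hi - lo,  -(hi^2 - lo^2) / 2))
  ab <- solve(m, c(p, 1))
  a <- ab[1]; b <- ab[2]
  if (a - b * lo <= 0 || a - b * hi <= 0) {
    stop("p_eligible is incompatible with a decreasing linear CD4 density ",
         "on this range")
  }
  c(a = a, b = b)
}

sample_cd4 <- function(n, cfg) {
  if (n == 0L) return(numeric(0))
  ab <- cd4_density_coefs(cfg)
  a <- ab["a"]; b <- ab["b"]
  lo <- cfg$cd4_range[1]
  u <- stats::runif(n)
  if (abs(b) < 1e-12) return(lo + u / a)
  # CDF F(x) = a (x - lo) - b (x^2 - lo^2) / 2 ; solve quadratic for x
  disc <- (a - b * lo)^2 - 2 * b * u
  x <- ((a - b * lo) - sqrt(pmax(disc, 0))) / b + lo
  pmin(pmax(x, cfg$cd4_range[1]), cfg$cd4_range[2])
}
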