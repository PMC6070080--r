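#' Household asset inventory and PCA wealth quintiles
#'
#' Draws a matrix of binary household asset indicators from a one-factor
#' latent wealth model and summarises it as quintiles of the first
#' principal-component score, the standard construction of an asset-based
#' wealth index in household surveys.
#'
#' @param n_subjects Number of subjects.
#' @param n_assets Number of binary asset indicators (>= 2).
#' @param p_missing Fraction of subjects whose whole asset inventory (and
#'   hence quintile) is set to missing.
#'
#' @return A list with components \code{assets} (an
#'   \code{n_subjects x n_assets} 0/1 matrix with \code{NA} rows for missing
#'   inventories), \code{score} (the first principal-component score,
#'   oriented so that larger means wealthier), and \code{wealth_quintile}
#'   (integer 1..5, \code{NA} where missing).
#' @export
generate_assets_and_wealth <- function(n_subjects, n_assets = 32,
                                       p_missing = 0) {
  if (n_assets < 2) stop("n_assets must be at least 2")
  if (n_subjects == 0L) {
    return(list(assets = matrix(numeric(0), 0, n_assets),
                score = numeric(0), wealth_quintile = integer(0)))
  }
  latent <- stats::rnorm(n_subjects)
  loadings <- seq(0.6, 1.4, length.out = n_assets)
  intercepts <- stats::qlogis(seq(0.25, 0.75, length.out = n_assets))
  p <- stats::plogis(outer(latent, loadings) +
                       matrix(intercepts, n_subjects, n_assets, byrow = TRUE))
  assets <- matrix(as.numeric(stats::runif(n_subjects * n_assets) < p),
                   n_subjects, n_assets)
  colnames(assets) <- sprintf("asset_%02d", seq_len(n_assets))
  miss <- stats::runif(n_subjects) < p_missing
  out <- wealth_quintiles(assets, miss)
  out$assets[miss, ] <- NA_real_
  out
}

# Quintiles of the first principal component of an asset matrix.  Rows
# flagged in `miss` are excluded from the PCA and get NA.  Ranks (average
# ties) rather than quantile breaks define the bins so that degenerate
# score distributions (few unique values) still bin deterministically.
wealth_quintiles <- function(assets, miss = rep(FALSE, nrow(assets))) {
  score <- rep(NA_real_, nrow(assets))
  quint <- rep(NA_integer_, nrow(assets))
  obs <- which(!miss)
  if (length(obs) > 0L) {
    a <- assets[obs, , drop = FALSE]
    if (all(apply(a, 2, stats::var) == 0)) {
      stop("degenerate asset matrix: every asset column has zero variance")
    }
    pc <- stats::prcomp(a, center = TRUE, scale. = FALSE)
    s <- pc$x[, 1]
    # orient so that owning more assets means a higher score
    if (stats::cor(s, rowMeans(a)) < 0) s <- -s
    r <- rank(s, ties.method = "average")
    quint[obs] <- as.integer(ceiling(5 * r / length(obs)))
    score[obs] <- s
  }
  list(assets = assets, score = score, wealth_quintile = quint)
}

#' Threshold-based treatment assignment with imperfect compliance
#'
#' Assigns an ART initiation period to each subject under the fuzzy
#' threshold rule: initiation within the first monitoring interval (period
#' 0) occurs with probability \code{p_init_below} if the baseline CD4 count
#' is strictly below the threshold and \code{p_init_above} otherwise.
#' Initial non-initiators may start later with a constant per-period hazard
#' \code{late_init_hazard}, mimicking deferral until a subsequent monitoring
#' visit.  A single uniform draw per subject determines the immediate
#' initiation status on both sides of the threshold, so compliance classes
#' are well defined and monotone by construction (no defiers).
#'
#' @param baseline_cd4 Numeric vector of baseline CD4 counts (cells/uL).
#' @param cfg A [sim_config()].
#'
#' @return A data frame with columns \code{art_init_time} (period index of
#'   initiation, \code{NA} if never), \code{immediate} (initiated in period
#'   0), and \code{compliance_class} (factor:
#'   \code{always}/\code{complier}/\code{never}, defined by the potential
#'   immediate-initiation status under each side of the threshold).
#' @export
assign_treatment <- function(baseline_cd4, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- length(baseline_cd4)
  if (any(baseline_cd4 < 0)) stop("baseline_cd4 must be nonnegative")
  below <- baseline_cd4 < cfg$threshold
  u <- stats::runif(n)
  p_side <- ifelse(below, cfg$p_init_below, cfg$p_init_above)
  immediate <- u < p_side
  p_lo <- min(cfg$p_init_below, cfg$p_init_above)
  p_hi <- max(cfg$p_init_below, cfg$p_init_above)
  cls <- ifelse(u < p_lo, "always", ifelse(u < p_hi, "complier", "never"))
  init <- ifelse(immediate, 0L, NA_integer_)
  late <- which(!immediate)
  if (length(late) > 0L && cfg$late_init_hazard > 0) {
    gaps <- stats::rgeom(length(late), cfg$late_init_hazard) + 1L
    ok <- gaps <= cfg$n_periods - 1L
    init[late[ok]] <- gaps[ok]
  }
  data.frame(
    art_init_time = as.integer(init),
    immediate = immediate,
    compliance_class = factor(cls, levels = c("always", "complier", "never"))
  )
}

#' Simulate survival outcomes, dropout and laboratory visits
#'
#' Walks each subject through discrete periods.  The per-period event
#' probability is \eqn{1 - \exp(-h \cdot \ell)} where \eqn{\ell} is the
#' period length in months and the monthly hazard is
#' \eqn{h = \exp(a + b \cdot \mathrm{CD4}_t + \beta(t) \cdot A_t)}, with
#' \eqn{\beta(t)} the treatment log hazard ratio (possibly drifting with
#' time since entry) and \eqn{A_t} the current ART indicator — a
#' complementary log-log discrete hazard, so the configured
#' \code{true_log_hr} is a genuine log hazard ratio.  Survivors may
#' disengage from care (absorbing, optionally dependent on current CD4 and
#' ART status): disengagement stops laboratory visits and any later ART
#' initiation, but deaths remain observed to the administrative end of
#' follow-up, emulating mortality ascertainment through population
#' surveillance rather than clinic contact.  Laboratory measurements follow
#' the scheduled cadence with per-visit misses; the entry measurement at
#' period 0 is always recorded.
#'
#' @param baseline_cd4 Numeric vector of baseline CD4 counts.
#' @param art_init_time Integer vector of assigned initiation periods
#'   (\code{NA} for never).
#' @param cfg A [sim_config()].
#'
#' @return A list with \code{event_time} (period index of death, \code{NA}
#'   if none), \code{followup_end} (last observed period index),
#'   \code{lab_times} (list of integer vectors of period indices with a
#'   recorded measurement), \code{lab_cd4} (the CD4 values recorded at
#'   those visits), \code{art_init_time} (the realized initiation periods:
#'   assigned late initiations are cancelled by earlier disengagement),
#'   \code{disengage_time}, and \code{cd4_at} (an \code{n x n_periods}
#'   matrix of the latent CD4 path, for diagnostics).
#' @export
simulate_outcomes <- function(baseline_cd4, art_init_time, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- length(baseline_cd4)
  stopifnot(length(art_init_time) == n)
  Tn <- cfg$n_periods
  plen <- cfg$period_length
  if (n == 0L) {
    return(list(event_time = integer(0), followup_end = integer(0),
                lab_times = list(), lab_cd4 = list(),
                art_init_time = integer(0), disengage_time = integer(0),
                cd4_at = matrix(numeric(0), 0, Tn)))
  }
  # all randomness drawn up front in a fixed order => reproducible
  U_event <- matrix(stats::runif(n * Tn), n, Tn)
  U_drop  <- matrix(stats::runif(n * Tn), n, Tn)
  U_miss  <- matrix(stats::runif(n * Tn), n, Tn)
  Z_cd4 <- if (cfg$cd4_sd > 0 || cfg$cd4_drift != 0) {
    matrix(stats::rnorm(n * Tn, mean = cfg$cd4_drift * plen,
                        sd = cfg$cd4_sd * sqrt(plen)), n, Tn)
  } else NULL

  cd4 <- baseline_cd4
  cd4_at <- matrix(NA_real_, n, Tn)
  event_time <- rep(NA_integer_, n)
  labs <- matrix(FALSE, n, Tn)
  alive <- rep(TRUE, n)
  # engaged = still attending the clinic: disengagement (dropout) is
  # absorbing and stops laboratory visits and any later ART initiation,
  # but mortality remains observed through the population surveillance the
  # synthetic world emulates
  engaged <- rep(TRUE, n)
  disengage_time <- rep(NA_integer_, n)
  art_init <- art_init_time
  art_assigned <- !is.na(art_init)

  lab_every <- cfg$lab_interval / plen
  cd4_rec <- baseline_cd4   # last recorded laboratory value per subject
  for (t in seq_len(Tn) - 1L) {
    if (!any(alive)) break
    idx <- which(alive)
    cd4_at[idx, t + 1L] <- cd4[idx]
    # scheduled lab at the start of the period; entry lab always recorded
    care <- which(alive & engaged)
    if (t == 0L) {
      labs[care, 1L] <- TRUE
      cd4_rec[care] <- cd4[care]
    } else if ((t %% lab_every) == 0 && length(care) > 0L) {
      rec <- U_miss[care, t + 1L] >= cfg$p_lab_miss
      labs[care[rec], t + 1L] <- TRUE
      cd4_rec[care[rec]] <- cd4[care[rec]]
    }
    art_now <- art_assigned[idx] & art_init[idx] <= t
    years <- t * plen / 12
    eta <- cfg$hazard_intercept + cfg$hazard_slope * cd4[idx] +
      (cfg$true_log_hr + cfg$effect_time_slope * years) * art_now
    p_event <- 1 - exp(-exp(eta) * plen)
    if (any(p_event >= 1 - 1e-12 | p_event <= 0)) {
      bad <- idx[which(p_event >= 1 - 1e-12 | p_event <= 0)[1]]
      stop(sprintf(
        "per-period event probability left (0,1) for CD4 = %.1f", cd4[bad]))
    }
    died <- U_event[idx, t + 1L] < p_event
    event_time[idx[died]] <- t
    alive[idx[died]] <- FALSE

    surv <- idx[!died]
    in_care <- surv[engaged[surv]]
    if (cfg$dropout_rate > 0 && length(in_care) > 0L) {
      on_art <- art_assigned[in_care] & art_init[in_care] <= t
      # disengagement responds to the last *measured* count (what the
      # clinic sees), not the latent one
      p_drop <- stats::plogis(stats::qlogis(cfg$dropout_rate) +
                                cfg$dropout_cd4_slope * (cd4_rec[in_care] - cfg$threshold) +
                                log(cfg$dropout_art_multiplier) * on_art)
      dropped <- in_care[U_drop[in_care, t + 1L] < p_drop]
      engaged[dropped] <- FALSE
      disengage_time[dropped] <- t
      # a disengaged patient cannot start ART later
      cancel <- dropped[art_assigned[dropped] & art_init[dropped] > t]
      art_init[cancel] <- NA_integer_
      art_assigned[cancel] <- FALSE
    }
    if (!is.null(Z_cd4) && length(surv) > 0L) {
      cd4[surv] <- pmax(cd4[surv] + Z_cd4[surv, t + 1L], 0)
    }
  }
  followup_end <- ifelse(is.na(event_time), Tn - 1L, event_time)
  lab_times <- lapply(seq_len(n), function(i) which(labs[i, ]) - 1L)
  lab_cd4 <- lapply(seq_len(n), function(i) {
    round(cd4_at[i, lab_times[[i]] + 1L])
  })
  list(event_time = event_time, followup_end = as.integer(followup_end),
       lab_times = lab_times, lab_cd4 = lab_cd4,
       art_init_time = art_init, disengage_time = disengage_time,
       cd4_at = cd4_at)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Composes the CD4 sampler, covariate and asset generators, the fuzzy
#' threshold treatment assignment and the outcome simulator into a full
#' cohort.  Returns both the observable subject table (what the estimators
#' see) and a hidden truth table (what validation code sees).
#'
#' @param cfg A [sim_config()].
#'
#' @return A list of class \code{sim_cohort} with elements \code{cohort}
#'   (one row per subject: identifiers, baseline covariates including
#'   \code{asset_*} columns, \code{art_init_time}, \code{lab_times} as a
#'   semicolon-separated string of period indices, \code{event_time},
#'   \code{followup_end}), \code{truth} (per-subject compliance class and
#'   counterfactual hazard parameters), and \code{config}.
#' @export
generate_cohort <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_subjects
  if (n == 0L) {
    cohort <- data.frame(subject_id = integer(0), baseline_cd4 = numeric(0),
                         age = numeric(0), sex = character(0),
                         education = character(0),
                         wealth_quintile = integer(0),
                         distance_km = numeric(0), residence = character(0),
                         entry_time = integer(0), art_init_time = integer(0),
                         lab_times = character(0), lab_cd4 = character(0),
                         event_time = integer(0),
                         followup_end = integer(0))
    truth <- data.frame(subject_id = integer(0), compliance_class = character(0),
                        baseline_log_hazard = numeric(0),
                        true_log_hr = numeric(0))
    return(structure(list(cohort = cohort, truth = truth, config = cfg),
                     class = "sim_cohort"))
  }
  baseline_cd4 <- round(sample_cd4(n, cfg))
  age <- round(pmin(pmax(stats::rlnorm(n, log(32), 0.28), 16), 90), 1)
  sex <- factor(ifelse(stats::runif(n) < 0.69, "female", "male"),
                levels = c("female", "male"))
  edu <- sample(c("<=7", "8-12", ">12"), n, replace = TRUE,
                prob = c(0.344, 0.569, 0.087))
  edu[stats::runif(n) < cfg$p_education_missing] <- NA
  distance_km <- round(stats::rgamma(n, shape = 2, scale = 1.4), 2)
  res <- sample(c("rural", "periurban", "urban"), n, replace = TRUE,
                prob = c(0.51, 0.37, 0.12))
  res[stats::runif(n) < cfg$p_residence_missing] <- NA
  wealth <- generate_assets_and_wealth(n, cfg$n_assets, cfg$p_assets_missing)
  trt <- assign_treatment(baseline_cd4, cfg)
  out <- simulate_outcomes(baseline_cd4, trt$art_init_time, cfg)

  art_obs <- out$art_init_time
  art_obs[!is.na(art_obs) & art_obs > out$followup_end] <- NA_integer_

  cohort <- data.frame(
    subject_id = seq_len(n),
    baseline_cd4 = baseline_cd4,
    age = age,
    sex = sex,
    education = factor(edu, levels = c("<=7", "8-12", ">12")),
    wealth_quintile = wealth$wealth_quintile,
    distance_km = distance_km,
    residence = factor(res, levels = c("rural", "periurban", "urban")),
    entry_time = 0L,
    art_init_time = art_obs,
    lab_times = vapply(out$lab_times, paste, "", collapse = ";"),
    lab_cd4 = vapply(out$lab_cd4, paste, "", collapse = ";"),
    event_time = out$event_time,
    followup_end = out$followup_end,
    stringsAsFactors = FALSE
  )
  cohort <- cbind(cohort, as.data.frame(wealth$assets))
  truth <- data.frame(
    subject_id = seq_len(n),
    compliance_class = trt$compliance_class,
    assigned_init_time = trt$art_init_time,
    disengage_time = out$disengage_time,
    baseline_log_hazard = cfg$hazard_intercept +
      cfg$hazard_slope * baseline_cd4,
    true_log_hr = cfg$true_log_hr
  )
  structure(list(cohort = cohort, truth = truth, config = cfg),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d deaths, %.1f%% eligible (CD4 < %g)\n",
              nrow(x$cohort), sum(!is.na(x$cohort$event_time)),
              100 * mean(x$cohort$baseline_cd4 < x$config$threshold),
              x$config$threshold))
  invisible(x)
}

#' Parse the semicolon-encoded lab visit column
#'
#' @param lab_times Character vector as stored in the cohort table.
#' @return A list of integer vectors of period indices.
#' @keywords internal
#' @export
parse_lab_times <- function(lab_times) {
  lapply(strsplit(as.character(lab_times), ";", fixed = TRUE),
         function(v) as.integer(v[nzchar(v)]))
}
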