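#' Specification of the inverse-probability weight models
#'
#' @param denominator Baseline covariates of the treatment (denominator)
#'   model.  The default is the standard set measured at entry: age, sex,
#'   baseline CD4 count (entered linearly plus the eligibility indicator,
#'   since treatment is assigned by the threshold rule on that count),
#'   educational attainment, household wealth quintile, distance to clinic,
#'   and place of residence.  Missing values of categorical covariates are
#'   modelled as an explicit \code{missing} category.
#' @param numerator Covariates of the numerator (stabilization) model;
#'   empty for time-invariant stabilization (marginal numerator), the
#'   baseline covariates for time-varying stabilization.  Must be a subset
#'   of \code{denominator}.
#' @param truncation Optional length-2 percentile pair (e.g.
#'   \code{c(0.01, 0.99)}) at which combined weights are symmetrically
#'   truncated; \code{NULL} (default) leaves weights untouched.
#' @return A \code{weight_model_spec} object.
#' @export
weight_model_spec <- function(denominator = c("age", "sex", "baseline_cd4",
                                              "eligible", "education",
                                              "wealth_quintile",
                                              "distance_km", "residence"),
                              numerator = character(0),
                              truncation = NULL) {
  if (!all(numerator %in% denominator)) {
    stop("numerator covariates must be a subset of denominator covariates")
  }
  if (!is.null(truncation)) {
    stopifnot(length(truncation) == 2, truncation[1] < truncation[2],
              truncation[1] >= 0, truncation[2] <= 1)
  }
  structure(list(denominator = denominator, numerator = numerator,
                 truncation = truncation),
            class = "weight_model_spec")
}

# Covariate frame for the weight models: categorical covariates get an
# explicit "missing" level, the eligibility indicator is derived from
# baseline CD4 when requested.
weight_covariate_frame <- function(df, vars, threshold = 200) {
  out <- list()
  for (v in vars) {
    col <- if (v == "eligible") {
      if (!is.null(df$eligible)) df$eligible
      else as.numeric(classify_eligibility(df$baseline_cd4, threshold))
    } else df[[v]]
    if (is.null(col)) stop(sprintf("covariate '%s' not found", v))
    if (v %in% c("education", "residence", "wealth_quintile") ||
        is.factor(col) || is.character(col)) {
      f <- factor(col)
      if (anyNA(f)) {
        levels(f) <- c(levels(f), "missing")
        f[is.na(f)] <- "missing"
      }
      col <- f
    }
    out[[v]] <- col
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

# positivity concerns the probability of the treatment / censoring status
# actually observed: a fitted probability of ~0 for a status nobody has is
# a structural zero, not a violation.
check_positivity <- function(p_observed, what) {
  bad <- p_observed < 1e-6
  if (any(bad)) {
    stop(sprintf(
      "positivity violation in the %s model: %d rows with fitted probability of the observed status below 1e-6",
      what, sum(bad)))
  }
  invisible(p_observed)
}

quiet_glm <- function(formula, data) {
  withCallingHandlers(
    stats::glm(formula, data = data, family = stats::binomial()),
    warning = function(w) {
      if (grepl("non-integer|fitted probabilities", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

new_weight_set <- function(subject_id, period, w_treat,
                           w_cens = rep(1, length(w_treat)),
                           type = "baseline") {
  ws <- data.frame(subject_id = subject_id, period = period,
                   w_treat = w_treat, w_cens = w_cens,
                   w_comb = w_treat * w_cens)
  if (any(!is.finite(ws$w_comb)) || any(ws$w_comb <= 0)) {
    stop("weights must be positive and finite")
  }
  structure(list(weights = ws, type = type), class = "weight_set")
}

#' Stabilized baseline inverse-probability-of-treatment weights
#'
#' Fits a logistic model for immediate ART initiation (the grace-period
#' exposure) on the baseline covariates, and a marginal numerator model,
#' and returns the stabilized weight — the marginal probability of the
#' subject's observed exposure over its covariate-conditional probability —
#' constant over each subject's follow-up.
#'
#' @param cohort Subject table.
#' @param spec A [weight_model_spec()].
#' @param grace_months,period_length,threshold Exposure and eligibility
#'   definitions, as in [expand_person_periods()].
#' @return A \code{weight_set}; one weight row per subject
#'   (\code{period = NA}).
#' @export
fit_baseline_weights <- function(cohort, spec = weight_model_spec(),
                                 grace_months = 3, period_length = 1,
                                 threshold = 200) {
  a <- as.numeric(classify_immediate_art(cohort$entry_time,
                                         cohort$art_init_time,
                                         grace_months, period_length))
  L <- weight_covariate_frame(cohort, spec$denominator, threshold)
  den <- quiet_glm(a ~ ., data = cbind(a = a, L))
  p_den <- stats::fitted(den)
  check_positivity(ifelse(a == 1, p_den, 1 - p_den),
                   "treatment denominator")
  p_num <- if (length(spec$numerator) == 0) {
    rep(mean(a), length(a))
  } else {
    Ln <- weight_covariate_frame(cohort, spec$numerator, threshold)
    stats::fitted(quiet_glm(a ~ ., data = cbind(a = a, Ln)))
  }
  w <- ifelse(a == 1, p_num / p_den, (1 - p_num) / (1 - p_den))
  w <- truncate_weights(w, spec$truncation)
  new_weight_set(cohort$subject_id, rep(NA_integer_, length(w)), w,
                 type = "baseline")
}

truncate_weights <- function(w, truncation) {
  if (is.null(truncation)) return(w)
  q <- stats::quantile(w, truncation)
  pmin(pmax(w, q[1]), q[2])
}

#' Time-varying stabilized treatment weights
#'
#' Pooled logistic models for the per-period probability of starting ART
#' among subjects not yet treated: the denominator conditions on the
#' baseline covariates and the most recent recorded CD4 count (carried
#' forward between laboratory visits), the numerator on the baseline
#' covariates only.  Since treatment is absorbing, periods after initiation
#' contribute a factor of 1.  The per-row weight is the cumulative product
#' of the per-period ratios of the probability of the observed treatment
#' status.
#'
#' @param pp Person-period table.
#' @param spec A [weight_model_spec()]; its \code{numerator} should be the
#'   baseline covariate set for time-varying stabilization (default used
#'   here: baseline CD4 and eligibility).
#' @return A \code{weight_set} with one row per person-period.
#' @export
fit_timevarying_weights <- function(pp,
                                    spec = weight_model_spec(
                                      denominator = c("baseline_cd4",
                                                      "eligible",
                                                      "current_cd4"),
                                      numerator = c("baseline_cd4",
                                                    "eligible"))) {
  ord <- order(pp$subject_id, pp$period)
  if (any(ord != seq_len(nrow(pp)))) pp <- pp[ord, ]
  first_on <- pp$art_now == 1 &
    !duplicated(paste(pp$subject_id, pp$art_now))  # initiation row
  at_risk <- pp$art_now == 0 | first_on
  init_k <- as.numeric(first_on)

  thr <- attr(pp, "threshold")
  if (is.null(thr)) thr <- 200
  Ld <- cbind(weight_covariate_frame(pp, spec$denominator, thr),
              period_frame(pp$period))
  Ln <- cbind(weight_covariate_frame(pp, spec$numerator, thr),
              period_frame(pp$period))
  dat_d <- cbind(init_k = init_k, Ld)[at_risk, ]
  dat_n <- cbind(init_k = init_k, Ln)[at_risk, ]
  p_den <- stats::fitted(quiet_glm(init_k ~ ., data = dat_d))
  obs_at_risk <- init_k[at_risk]
  check_positivity(ifelse(obs_at_risk == 1, p_den, 1 - p_den),
                   "time-varying treatment denominator")
  p_num <- stats::fitted(quiet_glm(init_k ~ ., data = dat_n))

  contrib <- rep(1, nrow(pp))
  contrib[at_risk] <- ifelse(obs_at_risk == 1, p_num / p_den,
                             (1 - p_num) / (1 - p_den))
  w <- stats::ave(contrib, pp$subject_id, FUN = cumprod)
  w <- truncate_weights(w, spec$truncation)
  new_weight_set(pp$subject_id, pp$period, w, type = "time-varying")
}

#' Inverse-probability-of-censoring weights for lab-gap censoring
#'
#' Pooled logistic models for the per-period probability of remaining
#' uncensored (not reaching a 12-month laboratory gap at the end of the
#' period): both models condition on treatment history (current ART
#' status) and the baseline covariates; the denominator additionally
#' conditions on the current (last recorded, carried forward) CD4 count,
#' the time-varying risk factor through which censoring is informative.
#' The per-row censoring weight is the cumulative product of the
#' per-period ratios of the probabilities of remaining uncensored; it
#' multiplies the treatment weight into the combined weight.
#'
#' @param pp Person-period table after [apply_lab_gap_censoring()], so the
#'   \code{censored_this_period} flags are present.
#' @param treatment_weights Optional \code{weight_set} of time-varying
#'   treatment weights to combine with.
#' @param spec A [weight_model_spec()].
#' @return A \code{weight_set} with \code{w_cens} filled (and
#'   \code{w_treat} from \code{treatment_weights} when supplied).
#' @export
fit_censoring_weights <- function(pp, treatment_weights = NULL,
                                  spec = weight_model_spec(
                                    denominator = c("baseline_cd4",
                                                    "eligible",
                                                    "current_cd4"),
                                    numerator = c("baseline_cd4",
                                                  "eligible"))) {
  ord <- order(pp$subject_id, pp$period)
  if (any(ord != seq_len(nrow(pp)))) pp <- pp[ord, ]
  cens <- pp$censored_this_period
  thr <- attr(pp, "threshold")
  if (is.null(thr)) thr <- 200
  if (all(cens == 0)) {
    w_c <- rep(1, nrow(pp))
  } else {
    art <- data.frame(art_now = pp$art_now)
    Ld <- cbind(art, weight_covariate_frame(pp, spec$denominator, thr),
                period_frame(pp$period))
    Ln <- cbind(art, weight_covariate_frame(pp, spec$numerator, thr),
                period_frame(pp$period))
    p_den <- stats::fitted(quiet_glm(cens ~ ., data = cbind(cens = cens, Ld)))
    check_positivity(1 - p_den, "censoring denominator")
    p_num <- stats::fitted(quiet_glm(cens ~ ., data = cbind(cens = cens, Ln)))
    contrib <- (1 - p_num) / (1 - p_den)
    w_c <- stats::ave(contrib, pp$subject_id, FUN = cumprod)
  }
  w_t <- if (is.null(treatment_weights)) rep(1, nrow(pp)) else {
    align_weights(pp, treatment_weights)
  }
  w_c <- truncate_weights(w_c, spec$truncation)
  new_weight_set(pp$subject_id, pp$period, w_t, w_c,
                 type = "time-varying + censoring")
}

# match a weight_set onto the rows of a person-period table
align_weights <- function(pp, ws) {
  stopifnot(inherits(ws, "weight_set"))
  w <- ws$weights
  if (all(is.na(w$period))) {
    m <- match(pp$subject_id, w$subject_id)
  } else {
    m <- match(paste(pp$subject_id, pp$period),
               paste(w$subject_id, w$period))
  }
  if (anyNA(m)) stop("weights do not align with the person-period rows")
  w$w_comb[m]
}

# smooth period (time-on-study) effects shared by the pooled models
period_frame <- function(period) {
  nd <- length(unique(period))
  if (nd >= 5) {
    B <- splines::ns(period, df = 3)
    colnames(B) <- paste0("period_ns", 1:3)
    as.data.frame(unclass(B))
  } else if (nd >= 2) {
    data.frame(period_f = factor(period))
  } else {
    data.frame(row.names = seq_along(period))[, FALSE, drop = FALSE]
  }
}

#' Weighted marginal structural discrete-time hazard model
#'
#' Fits the weighted regression of the per-period event indicator on the
#' treatment exposure plus smooth period effects in the pseudopopulation
#' defined by the weights.  The time-invariant model uses the baseline
#' immediate-ART exposure and no covariate adjustment; the time-varying
#' models use current ART status and additionally condition on the baseline
#' covariates that stabilize the weight numerator (baseline CD4 and
#' eligibility).  The interaction model adds treatment x years-since-entry
#' and reports the per-year multiplicative change in the hazard ratio.
#' Variances are cluster-robust by subject (weights induce within-subject
#' dependence).
#'
#' @param pp Person-period table.
#' @param weights A \code{weight_set}, or \code{NULL} for an unweighted fit.
#' @param model_tag One of \code{"time-invariant"}, \code{"time-varying"},
#'   \code{"time-varying-censor"}, \code{"interaction"}.
#' @param link \code{"cloglog"} (default; coefficients are log hazard
#'   ratios) or \code{"logit"}.
#' @return An \code{msm_fit} with the exposure hazard ratio, robust 95\%
#'   interval, and (for the interaction model) the per-year HR.
#' @export
fit_msm <- function(pp, weights = NULL,
                    model_tag = c("time-invariant", "time-varying",
                                  "time-varying-censor", "interaction"),
                    link = c("cloglog", "logit")) {
  model_tag <- match.arg(model_tag)
  link <- match.arg(link)
  if (sum(pp$event) == 0) stop("no events in the person-period table")
  w <- if (is.null(weights)) rep(1, nrow(pp)) else align_weights(pp, weights)

  plen <- attr(pp, "period_length")
  if (is.null(plen)) plen <- 1
  dat <- data.frame(
    event = pp$event,
    art = if (model_tag == "time-invariant") pp$art_immediate else pp$art_now,
    years = pp$period * plen / 12,
    baseline_cd4 = pp$baseline_cd4,
    eligible = pp$eligible,
    .w = w
  )
  dat <- cbind(dat, period_frame(pp$period))
  pterms <- setdiff(names(dat), c("event", "art", "years", "baseline_cd4",
                                  "eligible", ".w"))
  rhs <- c("art", pterms)
  if (model_tag %in% c("time-varying", "time-varying-censor")) {
    rhs <- c(rhs, "baseline_cd4", "eligible")
  }
  if (model_tag == "interaction") {
    rhs <- c(rhs, "baseline_cd4", "eligible", "art:years")
  }
  fml <- stats::reformulate(rhs, response = "event")
  fit <- withCallingHandlers(
    stats::glm(fml, data = dat, family = stats::quasibinomial(link),
               weights = .w),
    warning = function(wn) {
      if (grepl("non-integer", conditionMessage(wn))) {
        invokeRestart("muffleWarning")
      }
    })
  vc <- sandwich::vcovCL(fit, cluster = pp$subject_id)
  co <- stats::coef(fit)
  se <- sqrt(diag(vc))
  b <- co["art"]; s <- se["art"]
  z <- stats::qnorm(0.975)
  out <- list(
    hr = unname(exp(b)),
    ci95 = unname(exp(b + c(-1, 1) * z * s)),
    coefficients = co, se = se, vcov = vc,
    model_tag = model_tag, link = link,
    scale = if (link == "cloglog") "hazard ratio" else "odds ratio",
    n_subjects = length(unique(pp$subject_id)),
    n_events = sum(pp$event),
    weighted = !is.null(weights)
  )
  if (model_tag == "interaction") {
    bi <- co["art:years"]; si <- se["art:years"]
    out$per_year_hr <- unname(exp(bi))
    out$per_year_ci95 <- unname(exp(bi + c(-1, 1) * z * si))
  }
  structure(out, class = "msm_fit")
}

#' Interaction marginal structural model (ART effect drifting over time)
#'
#' Convenience wrapper for [fit_msm()] with \code{model_tag =
#' "interaction"}; intended for the censored, censor-weighted table.
#'
#' @inheritParams fit_msm
#' @return An \code{msm_fit} including \code{per_year_hr}.
#' @export
fit_msm_interaction <- function(pp, weights = NULL, link = "cloglog") {
  fit_msm(pp, weights, model_tag = "interaction", link = link)
}

#' @export
print.msm_fit <- function(x, ...) {
  cat(sprintf("MSM (%s%s): %s %.3f (95%% CI %.3f, %.3f)\n",
              x$model_tag, if (x$weighted) ", weighted" else ", unweighted",
              x$scale, x$hr, x$ci95[1], x$ci95[2]))
  if (!is.null(x$per_year_hr)) {
    cat(sprintf("  per-year change in HR: %.3f (95%% CI %.3f, %.3f)\n",
                x$per_year_hr, x$per_year_ci95[1], x$per_year_ci95[2]))
  }
  cat(sprintf("  %d subjects, %d events\n", x$n_subjects, x$n_events))
  invisible(x)
}

#' Summaries and sanity warnings for a set of weights
#'
#' @param ws A \code{weight_set} or a numeric vector of weights.
#' @return A list of summaries (mean, sd, min, max, 1st/99th percentiles,
#'   n) plus a character vector \code{warnings}; a warning condition is
#'   also raised when the mean deviates from 1 by more than 0.1 or the
#'   maximum exceeds 10.
#' @export
weight_diagnostics <- function(ws) {
  w <- if (inherits(ws, "weight_set")) ws$weights$w_comb else as.numeric(ws)
  if (length(w) == 0) stop("empty weight set")
  q <- stats::quantile(w, c(0.01, 0.99))
  out <- list(mean = mean(w), sd = stats::sd(w), min = min(w), max = max(w),
              p01 = unname(q[1]), p99 = unname(q[2]), n = length(w),
              warnings = character(0))
  if (abs(out$mean - 1) > 0.1) {
    out$warnings <- c(out$warnings, sprintf(
      "mean weight %.3f deviates from 1 by more than 0.1", out$mean))
  }
  if (out$max > 10) {
    out$warnings <- c(out$warnings,
                      sprintf("maximum weight %.2f exceeds 10", out$max))
  }
  for (msg in out$warnings) warning(msg, call. = FALSE)
  class(out) <- "weight_diagnostics"
  out
}

#' @export
print.weight_diagnostics <- function(x, ...) {
  cat(sprintf(
    "Weights (n=%d): mean %.3f, sd %.3f, range [%.3f, %.3f], P1/P99 %.3f/%.3f\n",
    x$n, x$mean, x$sd, x$min, x$max, x$p01, x$p99))
  for (msg in x$warnings) cat("  warning:", msg, "\n")
  invisible(x)
}
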