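#' Specification of a regression-discontinuity fit
#'
#' @param window A [bandwidth_window()]; subjects with baseline CD4 inside
#'   the window (inclusive) enter the fit.
#' @param form Functional form for the assignment variable: \code{"linear-gap"}
#'   (separate linear slopes in CD4 - threshold above and below),
#'   \code{"squared-below"} (adds a quadratic term below the threshold), or
#'   \code{"spline"} (natural cubic spline in CD4 with an interior knot,
#'   default 125 cells/uL, plus the eligibility jump).
#' @param covariates Optional baseline covariates added to the model
#'   (subset of \code{c("age", "sex")}).
#' @param link Link for the discrete-time hazard model: \code{"cloglog"}
#'   (coefficients are log hazard ratios) or \code{"logit"} or
#'   \code{"probit"}.
#' @param spline_knot Interior knot for \code{form = "spline"}.
#' @param threshold Eligibility threshold.
#' @return An \code{rdd_spec} object.
#' @export
rdd_spec <- function(window = bandwidth_window(0, 350),
                     form = c("linear-gap", "squared-below", "spline"),
                     covariates = character(0),
                     link = c("cloglog", "logit", "probit"),
                     spline_knot = 125,
                     threshold = 200) {
  form <- match.arg(form)
  link <- match.arg(link)
  stopifnot(inherits(window, "bandwidth_window"))
  if (!all(covariates %in% c("age", "sex"))) {
    stop("covariates must be a subset of c('age', 'sex')")
  }
  if (form == "spline" &&
      (spline_knot <= window$lower || spline_knot >= window$upper)) {
    stop("spline_knot must lie strictly inside the bandwidth window")
  }
  structure(list(window = window, form = form, covariates = covariates,
                 link = link, spline_knot = spline_knot,
                 threshold = threshold),
            class = "rdd_spec")
}

# Assignment-variable and period terms shared by the ITT and CACE models.
# Returns the exogenous design matrix (without intercept) and the
# eligibility indicator.
rdd_design <- function(pp, spec) {
  cd4 <- pp$baseline_cd4
  thr <- spec$threshold
  elig <- as.numeric(classify_eligibility(cd4, thr))
  gap <- cd4 - thr
  if (spec$form == "spline") {
    sb <- splines::ns(cd4, knots = spec$spline_knot,
                      Boundary.knots = c(spec$window$lower,
                                         spec$window$upper))
    X <- sb
    colnames(X) <- paste0("cd4_ns", seq_len(ncol(sb)))
  } else {
    X <- cbind(gap_below = gap * elig, gap_above = gap * (1 - elig))
    if (spec$form == "squared-below") {
      X <- cbind(X, gap_below_sq = (gap * elig)^2)
    }
  }
  per <- pp$period
  nd <- length(unique(per))
  if (nd >= 5) {
    P <- splines::ns(per, df = 3)
    colnames(P) <- paste0("period_ns", 1:3)
    X <- cbind(X, P)
  } else if (nd >= 2) {
    P <- stats::model.matrix(~ factor(per))[, -1, drop = FALSE]
    colnames(P) <- paste0("period_f", seq_len(ncol(P)))
    X <- cbind(X, P)
  }
  for (cv in spec$covariates) {
    v <- pp[[cv]]
    if (is.factor(v) || is.character(v)) {
      M <- stats::model.matrix(~ factor(v))[, -1, drop = FALSE]
      colnames(M) <- paste0(cv, seq_len(ncol(M)))
      X <- cbind(X, M)
    } else {
      X <- cbind(X, stats::setNames(data.frame(v), cv))
    }
  }
  list(X = as.matrix(X), eligible = elig)
}

#' Intention-to-treat effect of threshold eligibility (fuzzy RDD)
#'
#' Fits a discrete-time hazard model to person-period data restricted to
#' the bandwidth window: the per-period event indicator is regressed on the
#' eligibility indicator, separate terms for the CD4 gap above and below
#' the threshold (or a spline, per \code{spec$form}), smooth period
#' effects, and optional baseline covariates.  With the default
#' complementary log-log link the exponentiated eligibility coefficient is
#' the hazard ratio of eligibility — the intention-to-treat effect of the
#' threshold rule.
#'
#' @param pp Person-period table from [expand_person_periods()].
#' @param spec An [rdd_spec()].
#' @return An \code{rdd_fit} with the eligibility hazard ratio, its 95\%
#'   Wald interval, all coefficients, and counts.
#' @export
fit_rdd_itt <- function(pp, spec = rdd_spec()) {
  pp <- restrict_bandwidth(pp, spec$window)
  if (nrow(pp) == 0L) stop("no subjects inside the bandwidth window")
  d <- rdd_design(pp, spec)
  ev_below <- sum(pp$event[d$eligible == 1])
  ev_above <- sum(pp$event[d$eligible == 0])
  if (ev_below == 0L || ev_above == 0L) {
    side <- if (ev_below == 0L) "below" else "above"
    stop(sprintf("no events %s the threshold inside the window", side))
  }
  X <- cbind(`(Intercept)` = 1, eligible = d$eligible, d$X)
  fit <- suppressWarnings(
    stats::glm.fit(X, pp$event, family = stats::binomial(spec$link),
                   control = list(maxit = 100)))
  if (!fit$converged || any(abs(fit$coefficients) > 15, na.rm = TRUE)) {
    stop("model did not converge (possible separation); ",
         "consider a wider bandwidth")
  }
  co <- fit$coefficients
  w <- fit$weights
  vc <- solve(crossprod(X * sqrt(w)))
  se <- sqrt(diag(vc))
  names(se) <- names(co)
  b <- co["eligible"]; s <- se["eligible"]
  structure(list(
    hr = unname(exp(b)),
    ci95 = unname(exp(b + c(-1, 1) * stats::qnorm(0.975) * s)),
    coefficients = co, se = se, vcov = vc,
    n_subjects = length(unique(pp$subject_id)),
    n_events = sum(pp$event),
    link = spec$link, form = spec$form, window = spec$window,
    scale = if (spec$link == "cloglog") "hazard ratio" else
      if (spec$link == "logit") "odds ratio" else "probit coefficient"
  ), class = "rdd_fit")
}

#' @export
print.rdd_fit <- function(x, ...) {
  cat(sprintf(
    "RDD ITT (%s, %s link), window [%g, %g]: HR %.3f (95%% CI %.3f, %.3f)\n",
    x$form, x$link, x$window$lower, x$window$upper, x$hr,
    x$ci95[1], x$ci95[2]))
  cat(sprintf("  %d subjects, %d events; eligibility coefficient %.4f (SE %.4f)\n",
              x$n_subjects, x$n_events, x$coefficients["eligible"],
              x$se["eligible"]))
  invisible(x)
}

#' First-stage discontinuity in treatment uptake
#'
#' Estimates the jump at the threshold in the probability of ART initiation
#' within \code{init_window_months} of entry, from side-specific linear
#' probability fits in the bandwidth window — the strength of the fuzzy
#' design's instrument.
#'
#' @param cohort Subject table.
#' @param window A [bandwidth_window()].
#' @param init_window_months Initiation window in months, default 6.
#' @param threshold Eligibility threshold.
#' @param period_length Months per period, default 1.
#' @return A \code{first_stage_fit} with the jump, side probabilities at
#'   the threshold, and a 95\% Wald interval.
#' @export
fit_first_stage <- function(cohort, window = bandwidth_window(0, 350),
                            init_window_months = 6, threshold = 200,
                            period_length = 1) {
  cohort <- restrict_bandwidth(cohort, window)
  elig <- classify_eligibility(cohort$baseline_cd4, threshold)
  if (!any(elig) || !any(!elig)) {
    side <- if (!any(elig)) "below" else "above"
    stop(sprintf("no subjects %s the threshold inside the window", side))
  }
  init6 <- as.numeric(!is.na(cohort$art_init_time) &
                        cohort$art_init_time * period_length <
                          init_window_months)
  gap <- cohort$baseline_cd4 - threshold
  el <- as.numeric(elig)
  fit <- stats::lm(init6 ~ el + I(gap * el) + I(gap * (1 - el)))
  co <- stats::coef(fit)
  # a sharp design fits exactly; the zero-residual warning is expected
  se <- withCallingHandlers(
    sqrt(diag(stats::vcov(fit))),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  jump <- unname(co["el"])
  structure(list(
    jump = jump,
    se = unname(se["el"]),
    ci95 = jump + c(-1, 1) * stats::qnorm(0.975) * unname(se["el"]),
    p_below = unname(co[1] + co["el"]),
    p_above = unname(co[1]),
    n = nrow(cohort)
  ), class = "first_stage_fit")
}

#' @export
print.first_stage_fit <- function(x, ...) {
  cat(sprintf(
    "First stage: jump %.3f (95%% CI %.3f, %.3f); P(init)=%.3f below vs %.3f above (n=%d)\n",
    x$jump, x$ci95[1], x$ci95[2], x$p_below, x$p_above, x$n))
  invisible(x)
}

#' Complier average causal effect via instrumented probit
#'
#' Estimates the effect of current ART exposure on the per-period event
#' probability among compliers with the threshold rule, instrumenting the
#' (endogenous) treatment indicator with the eligibility indicator.  The
#' system — a probit outcome equation containing treatment, and a probit
#' treatment equation containing the instrument, with correlated errors —
#' is estimated by full maximum likelihood of the bivariate probit, with a
#' two-stage residual-inclusion fallback when the ML surface fails to
#' converge.  Both equations adjust for the same CD4 gap terms and period
#' effects as the ITT model.  When treatment coincides with eligibility in
#' every row (a sharp design) the system degenerates and a single-equation
#' probit is fitted, which reproduces the ITT exactly.
#'
#' The probit treatment coefficient is mapped to the hazard-ratio scale via
#' the implied per-period event probabilities with and without treatment at
#' the covariate means, \eqn{\log(1-p_1)/\log(1-p_0)}; this conversion is
#' an approximation and is tagged in the output.
#'
#' @param pp Person-period table.
#' @param spec An [rdd_spec()].
#' @return A \code{cace_fit} with the probit coefficient, the converted
#'   hazard ratio and 95\% interval, the first-stage strength, the error
#'   correlation, and the estimation-method tag.
#' @export
fit_rdd_cace <- function(pp, spec = rdd_spec()) {
  pp <- restrict_bandwidth(pp, spec$window)
  if (nrow(pp) == 0L) stop("no subjects inside the bandwidth window")
  d <- rdd_design(pp, spec)
  y <- pp$event
  a <- pp$art_now
  z <- d$eligible
  X0 <- cbind(`(Intercept)` = 1, d$X)

  if (all(a == z)) {
    # sharp design: treatment is the instrument; single-equation probit
    X <- cbind(X0[, 1, drop = FALSE], art_now = a, X0[, -1, drop = FALSE])
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial("probit"),
                     control = list(maxit = 100)))
    co <- fit$coefficients
    vc <- solve(crossprod(X * sqrt(fit$weights)))
    b <- co["art_now"]; s <- sqrt(vc["art_now", "art_now"])
    method <- "sharp (single-equation probit)"
    rho <- NA_real_
    fs <- NULL
    gamma <- co[setdiff(names(co), "art_now")]
    lin <- drop(X[, setdiff(colnames(X), "art_now"), drop = FALSE] %*% gamma)
  } else {
    if (stats::var(z) == 0) stop("instrument has no variation in the window")
    X2 <- cbind(X0[, 1, drop = FALSE], eligible = z, X0[, -1, drop = FALSE])
    X1 <- cbind(X0[, 1, drop = FALSE], art_now = a, X0[, -1, drop = FALSE])
    # person-period rows repeat the same (CD4, period, treatment, outcome)
    # patterns many times over; collapse to unique rows with frequency
    # weights before the ML pass (lexicographic sort + run boundaries)
    M <- cbind(y, a, X1, X2)
    ord <- do.call(order, lapply(seq_len(ncol(M)), function(j) M[, j]))
    Ms <- M[ord, , drop = FALSE]
    new_run <- c(TRUE, rowSums(abs(Ms[-1, , drop = FALSE] -
                                     Ms[-nrow(Ms), , drop = FALSE])) > 0)
    run_id <- cumsum(new_run)
    ui <- ord[new_run]
    wt <- tabulate(run_id)
    ml <- fit_biprobit(y[ui], a[ui], X1[ui, , drop = FALSE],
                       X2[ui, , drop = FALSE], wt = wt)
    if (ml$converged) {
      k1 <- ncol(X1)
      co <- ml$par[seq_len(k1)]
      names(co) <- colnames(X1)
      vc <- ml$vcov[seq_len(k1), seq_len(k1)]
      dimnames(vc) <- list(colnames(X1), colnames(X1))
      b <- co["art_now"]; s <- sqrt(vc["art_now", "art_now"])
      rho <- ml$rho
      fs_b <- ml$par[k1 + 2]           # eligibility coef, treatment eq
      fs_s <- sqrt(ml$vcov[k1 + 2, k1 + 2])
      method <- "bivariate probit ML"
    } else {
      ts <- fit_2sri(y, a, X1, X2)
      co <- ts$coefficients[colnames(X1)]
      b <- co["art_now"]
      s <- if (!is.null(ts$vcov)) sqrt(ts$vcov["art_now", "art_now"]) else NA
      rho <- NA_real_
      sw <- function(e) withCallingHandlers(
        e, warning = function(w) invokeRestart("muffleWarning"))
      fsg <- sw(stats::glm.fit(X2, a, family = stats::binomial("probit")))
      fs_b <- fsg$coefficients["eligible"]
      fs_s <- NA_real_
      method <- "two-stage residual inclusion (ML fallback)"
    }
    fs <- list(coef = unname(fs_b), se = unname(fs_s))
    # instrument strength judged at subject level (person-period rows of
    # one subject are not independent draws of the uptake process)
    f <- factor(pp$subject_id, levels = unique(pp$subject_id))
    init6 <- as.numeric(tapply(pp$art_now == 1 & pp$period < 6, f, any))
    zs <- z[!duplicated(pp$subject_id)]
    n1 <- sum(zs == 1); n0 <- sum(zs == 0)
    p1 <- sum(init6[zs == 1]) / n1
    p0 <- sum(init6[zs == 0]) / n0
    se_sub <- sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0)
    fs$jump_subject <- p1 - p0
    fs$se_subject <- se_sub
    if (se_sub > 0 && abs((p1 - p0) / se_sub) < 1.96) {
      warning("weak first stage: the eligibility jump in treatment uptake ",
              "is not distinguishable from zero in this window")
    }
    gamma <- co[setdiff(names(co), "art_now")]
    lin <- drop(X1[, setdiff(colnames(X1), "art_now"), drop = FALSE] %*%
                  gamma)
  }

  # standardized conversion: average the implied per-period event
  # probabilities with and without treatment over the sample's covariate
  # distribution, then take the discrete-hazard ratio of the averages
  to_hr <- function(beta) {
    p1 <- mean(stats::pnorm(lin + beta))
    p0 <- mean(stats::pnorm(lin))
    log1p(-p1) / log1p(-p0)
  }
  ci_b <- b + c(-1, 1) * stats::qnorm(0.975) * s
  structure(list(
    coef = unname(b), se = unname(s),
    coef_ci95 = unname(ci_b),
    hr = to_hr(unname(b)),
    ci95 = sort(vapply(unname(ci_b), to_hr, numeric(1))),
    hr_scale = "approximate: implied per-period event probabilities at covariate means",
    rho = unname(rho), first_stage = fs, method = method,
    n_subjects = length(unique(pp$subject_id)), n_events = sum(y),
    window = spec$window, form = spec$form
  ), class = "cace_fit")
}

#' @export
print.cace_fit <- function(x, ...) {
  cat(sprintf(
    "RDD CACE (%s), window [%g, %g]: HR %.3f (95%% CI %.3f, %.3f)\n",
    x$method, x$window$lower, x$window$upper, x$hr, x$ci95[1], x$ci95[2]))
  cat(sprintf("  probit coefficient %.4f (SE %.4f), rho %.3f; %d subjects, %d events\n",
              x$coef, x$se, x$rho, x$n_subjects, x$n_events))
  invisible(x)
}

#' Wald-type complier effect from ITT and first-stage estimates
#'
#' The classical instrumental-variable ratio: the intention-to-treat risk
#' difference scaled by the first-stage jump in treatment uptake.  With
#' perfect compliance (jump = 1) it equals the ITT.
#'
#' @param itt_risk_diff ITT effect on the risk (or hazard) difference scale.
#' @param first_stage_jump Jump in treatment probability at the threshold.
#' @return The ratio estimate.
#' @export
wald_cace <- function(itt_risk_diff, first_stage_jump) {
  if (first_stage_jump == 0) stop("first-stage jump is zero")
  itt_risk_diff / first_stage_jump
}

#' Binned mortality and treatment-uptake summary along the CD4 axis
#'
#' Partitions the assignment-variable range into fixed-width bins
#' (left-closed, right-open, so a count of 200 falls in the bin starting at
#' 200) and reports per-bin deaths, person-years, the raw mortality hazard
#' (deaths per person-year), and the fraction initiating ART within 6
#' months — the numbers behind the classic discontinuity figures.
#'
#' @param cohort Subject table.
#' @param bin_width Bin width in cells/uL, default 10.
#' @param range CD4 range to partition, default \code{c(0, 350)}.
#' @param init_window_months Initiation window for the uptake fraction.
#' @param period_length Months per period.
#' @return A data frame, one row per bin; bins with no subjects carry
#'   zero denominators and \code{empty = TRUE}.
#' @export
binned_summary <- function(cohort, bin_width = 10, range = c(0, 350),
                           init_window_months = 6, period_length = 1) {
  if (bin_width <= 0) stop("bin_width must be positive")
  lo <- seq(range[1], range[2] - bin_width, by = bin_width)
  bin <- findInterval(cohort$baseline_cd4, c(lo, range[2]),
                      rightmost.closed = TRUE)
  bin[bin < 1 | bin > length(lo)] <- NA
  init6 <- !is.na(cohort$art_init_time) &
    cohort$art_init_time * period_length < init_window_months
  py_i <- (cohort$followup_end + 1) * period_length / 12
  dead <- !is.na(cohort$event_time)
  out <- data.frame(bin_lower = lo, bin_upper = lo + bin_width)
  out$n <- as.vector(tabulate(bin, nbins = length(lo)))
  agg <- function(v) {
    s <- rep(0, length(lo))
    t <- tapply(v, bin, sum)
    s[as.integer(names(t))] <- t
    s
  }
  out$deaths <- agg(as.numeric(dead))
  out$person_years <- agg(py_i)
  out$hazard <- ifelse(out$person_years > 0,
                       out$deaths / out$person_years, NA_real_)
  out$init_fraction <- ifelse(out$n > 0, agg(as.numeric(init6)) / out$n,
                              NA_real_)
  out$empty <- out$n == 0
  out
}

#' Continuity diagnostic for the assignment-variable density
#'
#' Compares the subject counts in the two bins immediately adjacent to the
#' threshold.  Under a continuous density the count ratio is near 1; a
#' binomial interval that excludes 1 flags possible manipulation or sorting
#' of the assignment variable at the threshold.
#'
#' @param cohort Subject table.
#' @param threshold Eligibility threshold.
#' @param bin_width Width of the two comparison bins.
#' @return A list with the two counts, the below/above ratio, its 95\%
#'   interval, and a status flag (\code{"consistent"},
#'   \code{"discontinuity suspected"}, or \code{"inconclusive"}).
#' @export
density_continuity_check <- function(cohort, threshold = 200,
                                     bin_width = 10) {
  cd4 <- cohort$baseline_cd4
  n_below <- sum(cd4 >= threshold - bin_width & cd4 < threshold)
  n_above <- sum(cd4 >= threshold & cd4 < threshold + bin_width)
  if (n_below == 0L || n_above == 0L) {
    return(structure(list(n_below = n_below, n_above = n_above,
                          ratio = NA_real_, ci95 = c(NA_real_, NA_real_),
                          status = "inconclusive"),
                     class = "density_check"))
  }
  bt <- stats::binom.test(n_below, n_below + n_above)
  ci_p <- bt$conf.int
  ratio_ci <- ci_p / (1 - ci_p)
  status <- if (ratio_ci[1] > 1 || ratio_ci[2] < 1) {
    "discontinuity suspected"
  } else "consistent"
  structure(list(n_below = n_below, n_above = n_above,
                 ratio = n_below / n_above, ci95 = ratio_ci,
                 status = status),
            class = "density_check")
}

#' @export
print.density_check <- function(x, ...) {
  cat(sprintf(
    "Density continuity at threshold: %d below vs %d above, ratio %.2f (95%% CI %.2f, %.2f) - %s\n",
    x$n_below, x$n_above, x$ratio, x$ci95[1], x$ci95[2], x$status))
  invisible(x)
}
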