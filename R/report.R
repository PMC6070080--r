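#' Baseline characteristics stratified by threshold eligibility
#'
#' Summarises the cohort the way treatment-programme balance tables are
#' presented: counts and within-stratum percentages for categorical
#' covariates (with missing data as its own row) and median plus
#' interquartile range for continuous covariates, stratified by
#' eligibility at baseline.
#'
#' @param cohort Subject table.
#' @param threshold Eligibility threshold.
#' @return A data frame with one row per covariate level (categorical) or
#'   per covariate (continuous): columns \code{variable}, \code{level},
#'   \code{stat}, \code{n_below}, \code{pct_below}, \code{summary_below},
#'   and the same for above.
#' @export
make_balance_table <- function(cohort, threshold = 200) {
  if (nrow(cohort) == 0L) stop("cohort is empty")
  elig <- classify_eligibility(cohort$baseline_cd4, threshold)
  strata <- list(below = cohort[elig, , drop = FALSE],
                 above = cohort[!elig, , drop = FALSE])
  rows <- list()
  add <- function(df) rows[[length(rows) + 1L]] <<- df

  cont <- intersect(c("age", "baseline_cd4", "distance_km"), names(cohort))
  for (v in cont) {
    s <- lapply(strata, function(d) {
      if (nrow(d) == 0) return(c(NA, NA, NA))
      stats::quantile(d[[v]], c(0.5, 0.25, 0.75), na.rm = TRUE)
    })
    add(data.frame(
      variable = v, level = "", stat = "median (IQR)",
      n_below = NA_integer_, pct_below = NA_real_,
      summary_below = sprintf("%.1f (%.1f-%.1f)", s$below[1], s$below[2],
                              s$below[3]),
      n_above = NA_integer_, pct_above = NA_real_,
      summary_above = sprintf("%.1f (%.1f-%.1f)", s$above[1], s$above[2],
                              s$above[3]),
      stringsAsFactors = FALSE))
  }

  cats <- intersect(c("sex", "education", "wealth_quintile", "residence"),
                    names(cohort))
  for (v in cats) {
    f <- factor(cohort[[v]])
    levs <- c(levels(f), if (anyNA(f)) "missing")
    for (lv in levs) {
      cnt <- vapply(strata, function(d) {
        x <- factor(d[[v]], levels = levels(f))
        if (lv == "missing") sum(is.na(x)) else sum(x == lv, na.rm = TRUE)
      }, 0L)
      tot <- vapply(strata, nrow, 0L)
      pct <- ifelse(tot > 0, 100 * cnt / tot, NA_real_)
      add(data.frame(
        variable = v, level = lv, stat = "n (%)",
        n_below = cnt[["below"]], pct_below = pct[["below"]],
        summary_below = sprintf("%d (%.1f%%)", cnt[["below"]],
                                pct[["below"]]),
        n_above = cnt[["above"]], pct_above = pct[["above"]],
        summary_above = sprintf("%d (%.1f%%)", cnt[["above"]],
                                pct[["above"]]),
        stringsAsFactors = FALSE))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_below") <- nrow(strata$below)
  attr(out, "n_above") <- nrow(strata$above)
  out
}

#' Collect model fits into a forest-plot-ready estimate table
#'
#' @param fits A named list of \code{rdd_fit}, \code{cace_fit}, and
#'   \code{msm_fit} objects; names become row labels.
#' @return A data frame \code{(model, label, estimate, ci_lower, ci_upper,
#'   scale)}, ordered RDD ITT, RDD CACE, weighted MSMs, unadjusted,
#'   adjusted.
#' @export
make_estimate_table <- function(fits) {
  if (length(fits) == 0) stop("at least one fit is required")
  if (is.null(names(fits))) names(fits) <- paste0("fit", seq_along(fits))
  one <- function(f, label) {
    if (inherits(f, "rdd_fit")) {
      data.frame(model = "RDD ITT", label = label, estimate = f$hr,
                 ci_lower = f$ci95[1], ci_upper = f$ci95[2],
                 scale = f$scale, rank = 1, stringsAsFactors = FALSE)
    } else if (inherits(f, "cace_fit")) {
      data.frame(model = "RDD CACE", label = label, estimate = f$hr,
                 ci_lower = f$ci95[1], ci_upper = f$ci95[2],
                 scale = "hazard ratio (approx.)", rank = 2,
                 stringsAsFactors = FALSE)
    } else if (inherits(f, "msm_fit")) {
      rank <- if (f$weighted) 3 else if (f$model_tag == "adjusted") 5 else 4
      model <- if (f$weighted) paste("IPW MSM,", f$model_tag) else
        if (f$model_tag == "adjusted") "Adjusted" else "Unadjusted"
      data.frame(model = model, label = label, estimate = f$hr,
                 ci_lower = f$ci95[1], ci_upper = f$ci95[2],
                 scale = f$scale, rank = rank, stringsAsFactors = FALSE)
    } else stop("unsupported fit object of class ", class(f)[1])
  }
  tab <- do.call(rbind, Map(one, fits, names(fits)))
  tab <- tab[order(tab$rank, seq_len(nrow(tab))), ]
  tab$rank <- NULL
  rownames(tab) <- NULL
  tab
}

#' Unweighted reference fits: unadjusted and covariate-adjusted
#'
#' The comparators that bracket the causal estimates: an unweighted
#' discrete-time hazard model of the event on the baseline immediate-ART
#' exposure, without and with baseline covariate adjustment.  Under
#' confounding by indication the unadjusted estimate is biased toward harm.
#'
#' @param pp Person-period table (uncensored).
#' @param covariates Baseline covariates for the adjusted model.
#' @param link \code{"cloglog"} or \code{"logit"}.
#' @return A list with elements \code{unadjusted} and \code{adjusted},
#'   both \code{msm_fit} objects.
#' @export
fit_unadjusted_and_adjusted <- function(pp,
                                        covariates = c("age", "sex",
                                                       "baseline_cd4",
                                                       "eligible",
                                                       "education",
                                                       "wealth_quintile",
                                                       "distance_km",
                                                       "residence"),
                                        link = "cloglog") {
  unadj <- fit_msm(pp, NULL, model_tag = "time-invariant", link = link)
  unadj$model_tag <- "unadjusted"

  thr <- attr(pp, "threshold")
  if (is.null(thr)) thr <- 200
  covariates <- intersect(covariates,
                          c("eligible", names(pp)))
  L <- weight_covariate_frame(pp, covariates, thr)
  dat <- cbind(data.frame(event = pp$event, art = pp$art_immediate), L,
               period_frame(pp$period))
  fit <- stats::glm(event ~ ., data = dat,
                    family = stats::binomial(link))
  vc <- sandwich::vcovCL(fit, cluster = pp$subject_id)
  co <- stats::coef(fit)
  se <- sqrt(diag(vc))
  b <- co["art"]; s <- se["art"]
  z <- stats::qnorm(0.975)
  adj <- structure(list(
    hr = unname(exp(b)),
    ci95 = unname(exp(b + c(-1, 1) * z * s)),
    coefficients = co, se = se, vcov = vc,
    model_tag = "adjusted", link = link,
    scale = if (link == "cloglog") "hazard ratio" else "odds ratio",
    n_subjects = length(unique(pp$subject_id)),
    n_events = sum(pp$event),
    weighted = FALSE
  ), class = "msm_fit")
  list(unadjusted = unadj, adjusted = adj)
}
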