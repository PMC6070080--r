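#' Treatment eligibility under the threshold rule
#'
#' A subject is eligible for immediate ART initiation iff the baseline CD4
#' count is strictly below the threshold (a count exactly at the threshold
#' is ineligible: eligibility requires the count to have dropped below it).
#'
#' @param baseline_cd4 Numeric vector of CD4 counts (cells/uL), nonnegative.
#' @param threshold Eligibility threshold, default 200 cells/uL.
#' @return Logical vector.
#' @export
classify_eligibility <- function(baseline_cd4, threshold = 200) {
  if (any(baseline_cd4 < 0, na.rm = TRUE)) {
    stop("baseline_cd4 must be nonnegative")
  }
  baseline_cd4 < threshold
}

#' Immediate-initiation status under a grace period
#'
#' Immediate initiators are subjects who started ART within
#' \code{grace_months} of entry into care; this baseline (time-invariant)
#' exposure definition allows for minor administrative delays in starting
#' treatment.
#'
#' @param entry_time Entry period index (typically 0).
#' @param art_init_time Initiation period index, \code{NA} if never.
#' @param grace_months Grace period in months, default 3.
#' @param period_length Months per period, default 1.
#' @return Logical vector: initiated within the grace period.
#' @export
classify_immediate_art <- function(entry_time, art_init_time,
                                   grace_months = 3, period_length = 1) {
  if (any(!is.na(art_init_time) & art_init_time < entry_time)) {
    stop("art_init_time cannot precede entry_time")
  }
  !is.na(art_init_time) &
    (art_init_time - entry_time) * period_length < grace_months
}

#' Expand a subject-level cohort into a person-period table
#'
#' One row per subject per discrete period from entry to the end of
#' follow-up, the representation required by discrete-time hazard models.
#' Person-time is conserved exactly: the summed row durations equal the
#' summed subject follow-up durations.  The time-varying ART indicator
#' switches on at the initiation period and stays on (treatment is
#' absorbing); the event is flagged on the subject's final row.  The
#' current CD4 count is the most recent recorded laboratory value carried
#' forward between visits.
#'
#' @param cohort Subject table as produced by [generate_cohort()] (the
#'   \code{$cohort} element) or read from file.
#' @param period_length Months per period, default 1.
#' @param grace_months Grace period defining the baseline immediate-ART
#'   exposure, default 3 months.
#' @param threshold Eligibility threshold, default 200.
#' @return A \code{data.frame} person-period table with columns
#'   \code{subject_id}, \code{period}, \code{period_start},
#'   \code{period_stop} (months from entry), \code{at_risk}, \code{event},
#'   \code{eligible}, \code{art_now}, \code{art_immediate},
#'   \code{current_cd4}, \code{months_since_lab},
#'   \code{censored_this_period}, and the baseline covariates repeated on
#'   every row.
#' @export
expand_person_periods <- function(cohort, period_length = 1,
                                  grace_months = 3, threshold = 200) {
  if (nrow(cohort) == 0L) stop("cohort is empty")
  if (period_length <= 0) stop("period_length must be positive")
  if (any(cohort$followup_end < 0)) stop("negative follow-up duration")
  ev <- cohort$event_time
  if (any(!is.na(ev) & ev > cohort$followup_end)) {
    stop("event_time after followup_end")
  }
  n_per <- cohort$followup_end + 1L
  idx <- rep(seq_len(nrow(cohort)), n_per)
  period <- sequence(n_per) - 1L

  lab_t <- parse_lab_times(cohort$lab_times)
  lab_v <- if ("lab_cd4" %in% names(cohort)) {
    lapply(strsplit(as.character(cohort$lab_cd4), ";", fixed = TRUE),
           function(v) as.numeric(v[nzchar(v)]))
  } else {
    mapply(function(tt, b) rep(b, length(tt)), lab_t, cohort$baseline_cd4,
           SIMPLIFY = FALSE)
  }
  # last recorded lab at or before each period, per subject; done in one
  # global findInterval pass by giving each subject a disjoint time offset
  empty <- lengths(lab_t) == 0L
  if (any(empty)) {  # no recorded lab: treat the entry measurement as one
    lab_t[empty] <- list(0L)
    lab_v[empty] <- as.list(cohort$baseline_cd4[empty])
  }
  big <- max(cohort$followup_end) + 2
  offset <- (seq_len(nrow(cohort)) - 1L) * big
  lt_all <- unlist(lab_t) + rep(offset, lengths(lab_t))
  lv_all <- unlist(lab_v)
  first_lab <- cumsum(c(1L, lengths(lab_t)))[-(nrow(cohort) + 1L)]
  j <- findInterval(period + offset[idx], lt_all)
  j <- pmax(j, first_lab[idx])  # before first lab: carry entry value back
  cur_cd4 <- lv_all[j]
  since_lab <- (period - (lt_all[j] - offset[idx])) * period_length

  art0 <- cohort$art_init_time
  art_now <- !is.na(art0[idx]) & period >= art0[idx]
  imm <- classify_immediate_art(cohort$entry_time, cohort$art_init_time,
                                grace_months, period_length)
  pp <- data.frame(
    subject_id = cohort$subject_id[idx],
    period = period,
    period_start = period * period_length,
    period_stop = (period + 1L) * period_length,
    at_risk = 1L,
    event = as.integer(!is.na(ev[idx]) & period == cohort$followup_end[idx]),
    eligible = as.integer(classify_eligibility(cohort$baseline_cd4[idx],
                                               threshold)),
    art_now = as.integer(art_now),
    art_immediate = as.integer(imm[idx]),
    current_cd4 = cur_cd4,
    months_since_lab = since_lab,
    censored_this_period = 0L,
    stringsAsFactors = FALSE
  )
  base_cols <- intersect(c("baseline_cd4", "age", "sex", "education",
                           "wealth_quintile", "distance_km", "residence"),
                         names(cohort))
  pp <- cbind(pp, cohort[idx, base_cols, drop = FALSE])
  rownames(pp) <- NULL
  attr(pp, "period_length") <- period_length
  attr(pp, "threshold") <- threshold
  pp
}

#' Censor follow-up at a gap in laboratory monitoring
#'
#' Administratively censors a subject's person-time at the first period
#' whose start lies \code{gap_months} or more after the last recorded
#' laboratory measurement; that period and all later ones are removed, any
#' event occurring in them is discarded, and the last retained row is
#' flagged \code{censored_this_period}.  Intended for time-varying
#' analyses; time-invariant analyses are fitted on the uncensored table.
#'
#' @param pp A person-period table from [expand_person_periods()].
#' @param gap_months Censoring gap, default 12 months.
#' @return The censored person-period table (same columns).
#' @export
apply_lab_gap_censoring <- function(pp, gap_months = 12) {
  drop <- pp$months_since_lab >= gap_months
  if (!any(drop)) return(pp)
  # first offending row per subject (rows are grouped by subject with
  # consecutive periods); remove it and everything after
  bad <- which(drop)
  first_bad <- bad[!duplicated(pp$subject_id[bad])]
  cut_sub <- pp$subject_id[first_bad]
  cut_per <- pp$period[first_bad]
  m <- match(pp$subject_id, cut_sub)
  remove <- !is.na(m) & pp$period >= cut_per[m]
  out <- pp
  flag <- first_bad[cut_per > 0] - 1L
  out$censored_this_period[flag] <- 1L
  out$event[remove] <- 0L
  out <- out[!remove, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("period_length", "threshold")) {
    attr(out, a) <- attr(pp, a)
  }
  out
}

#' Bandwidth window around the threshold
#'
#' @param lower,upper Inclusive CD4 bounds in cells/uL.
#' @return A \code{bandwidth_window} object.
#' @export
bandwidth_window <- function(lower, upper) {
  if (lower > upper) stop("lower must not exceed upper")
  structure(list(lower = lower, upper = upper), class = "bandwidth_window")
}

#' Restrict a cohort or person-period table to a CD4 bandwidth
#'
#' Keeps subjects whose baseline CD4 lies in \code{[lower, upper]}, both
#' endpoints inclusive.
#'
#' @param x Subject table or person-period table with a \code{baseline_cd4}
#'   column.
#' @param window A [bandwidth_window()].
#' @return The filtered table.
#' @export
restrict_bandwidth <- function(x, window) {
  stopifnot(inherits(window, "bandwidth_window"))
  out <- x[x$baseline_cd4 >= window$lower & x$baseline_cd4 <= window$upper, ,
           drop = FALSE]
  rownames(out) <- NULL
  for (a in c("period_length", "threshold")) {
    if (!is.null(attr(x, a))) attr(out, a) <- attr(x, a)
  }
  out
}

#' Crude incidence rate per 100 person-years
#'
#' @param deaths Number of events.
#' @param person_years Total person-time at risk in years.
#' @return A list with \code{deaths}, \code{person_years}, and
#'   \code{rate_per_100py} = 100 * deaths / person_years.
#' @export
incidence_rate <- function(deaths, person_years) {
  if (person_years <= 0) stop("person_years must be positive")
  structure(list(deaths = deaths, person_years = person_years,
                 rate_per_100py = 100 * deaths / person_years),
            class = "incidence_summary")
}

#' @export
print.incidence_summary <- function(x, ...) {
  cat(sprintf("%d deaths over %.0f person-years: %.1f per 100 person-years\n",
              x$deaths, x$person_years, x$rate_per_100py))
  invisible(x)
}

#' Person-years of follow-up in a person-period table
#'
#' @param pp Person-period table.
#' @return Total at-risk person-time in years.
#' @export
person_years <- function(pp) {
  sum(pp$period_stop - pp$period_start) / 12
}
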