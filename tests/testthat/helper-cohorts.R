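# Shared fixtures: small cohorts built in code, cached per test run.

small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(sim_config(n_subjects = 800, n_periods = 24,
                                           seed = 42L))
    }
    cache
  }
})

recovery_config <- function(seed, n = 5000, n_periods = 36) {
  sim_config(n_subjects = n, p_init_below = 0.9, p_init_above = 0.1,
             late_init_hazard = 0, n_periods = n_periods, seed = seed)
}

# Hand-rolled subject table for bookkeeping tests: `labs` / `lab_vals`
# given as lists of period indices / values.
manual_cohort <- function(baseline_cd4, art_init_time, event_time,
                          followup_end, labs = NULL, lab_vals = NULL) {
  n <- length(baseline_cd4)
  if (is.null(labs)) labs <- lapply(seq_len(n), function(i) 0L)
  if (is.null(lab_vals)) {
    lab_vals <- lapply(seq_len(n), function(i) {
      rep(baseline_cd4[i], length(labs[[i]]))
    })
  }
  data.frame(
    subject_id = seq_len(n),
    baseline_cd4 = baseline_cd4,
    age = 30, sex = factor(rep("female", n), levels = c("female", "male")),
    education = factor(rep("8-12", n)),
    wealth_quintile = 3L,
    distance_km = 2,
    residence = factor(rep("rural", n)),
    entry_time = 0L,
    art_init_time = art_init_time,
    lab_times = vapply(labs, paste, "", collapse = ";"),
    lab_cd4 = vapply(lab_vals, paste, "", collapse = ";"),
    event_time = event_time,
    followup_end = followup_end,
    stringsAsFactors = FALSE
  )
}
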