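# Delimited-text I/O.  Every file starts with a one-line schema header
# ("# rddmsm <kind> v1") so readers can check they were handed the right
# artifact; missing values are empty fields; all times are months from
# entry (period indices for integer columns).

schema_line <- function(kind) sprintf("# rddmsm %s v1", kind)

write_table_with_schema <- function(df, path, kind) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(schema_line(kind), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, na = "",
                     qmethod = "double")
  invisible(path)
}

read_table_with_schema <- function(path, kind) {
  if (!file.exists(path)) stop("input file not found: ", path)
  first <- readLines(path, n = 1)
  if (!identical(first, schema_line(kind))) {
    stop(sprintf("'%s' is not a %s file (schema header mismatch)",
                 path, kind))
  }
  utils::read.csv(path, skip = 1, na.strings = "",
                  stringsAsFactors = FALSE)
}

#' Write / read a synthetic cohort and its truth table
#'
#' @param sim A \code{sim_cohort} from [generate_cohort()].
#' @param cohort_path,truth_path Output CSV paths.
#' @return The cohort path, invisibly.
#' @export
write_cohort <- function(sim, cohort_path, truth_path = NULL) {
  stopifnot(inherits(sim, "sim_cohort"))
  write_table_with_schema(sim$cohort, cohort_path, "cohort")
  if (!is.null(truth_path)) {
    write_table_with_schema(sim$truth, truth_path, "truth")
  }
  invisible(cohort_path)
}

#' @rdname write_cohort
#' @param path CSV path to read.
#' @export
read_cohort <- function(path) {
  df <- read_table_with_schema(path, "cohort")
  for (v in c("sex", "education", "residence")) {
    if (v %in% names(df)) df[[v]] <- factor(df[[v]])
  }
  if (!"lab_times" %in% names(df)) {
    stop("cohort file lacks a lab_times column")
  }
  df$lab_times <- as.character(df$lab_times)
  df$lab_times[is.na(df$lab_times)] <- ""
  if ("lab_cd4" %in% names(df)) {
    df$lab_cd4 <- as.character(df$lab_cd4)
    df$lab_cd4[is.na(df$lab_cd4)] <- ""
  }
  df
}

#' Write / read a person-period table
#'
#' @param pp Person-period table.
#' @param path CSV path.
#' @export
write_person_periods <- function(pp, path) {
  out <- pp
  attr(out, "period_length") <- NULL
  attr(out, "threshold") <- NULL
  write_table_with_schema(out, path, "person-periods")
  invisible(path)
}

#' @rdname write_person_periods
#' @param period_length,threshold Metadata re-attached on read.
#' @export
read_person_periods <- function(path, period_length = 1, threshold = 200) {
  df <- read_table_with_schema(path, "person-periods")
  for (v in c("sex", "education", "residence")) {
    if (v %in% names(df)) df[[v]] <- factor(df[[v]])
  }
  attr(df, "period_length") <- period_length
  attr(df, "threshold") <- threshold
  df
}

#' Write a per-row weights file
#'
#' @param ws A \code{weight_set}.
#' @param path CSV path.
#' @export
write_weights <- function(ws, path) {
  stopifnot(inherits(ws, "weight_set"))
  write_table_with_schema(ws$weights, path, "weights")
  invisible(path)
}

#' Read / write a simulation configuration as YAML
#'
#' @param cfg A [sim_config()].
#' @param path YAML path.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(sim_config, vals)
}

#' Write a fit as a machine-readable key-value report
#'
#' Flat \code{key=value} lines covering the estimate, interval, counts and
#' metadata of an \code{rdd_fit}, \code{cace_fit}, or \code{msm_fit}.
#'
#' @param fit A fit object.
#' @param path Output path.
#' @export
write_fit_report <- function(fit, path) {
  kv <- c()
  put <- function(k, v) kv <<- c(kv, sprintf("%s=%s", k, format(v, digits = 10)))
  if (inherits(fit, "rdd_fit")) {
    put("model", "rdd_itt"); put("form", fit$form); put("link", fit$link)
    put("window_lower", fit$window$lower); put("window_upper", fit$window$upper)
    put("hr", fit$hr); put("ci_lower", fit$ci95[1]); put("ci_upper", fit$ci95[2])
    put("eligible_coef", unname(fit$coefficients["eligible"]))
    put("eligible_se", unname(fit$se["eligible"]))
  } else if (inherits(fit, "cace_fit")) {
    put("model", "rdd_cace"); put("method", fit$method)
    put("window_lower", fit$window$lower); put("window_upper", fit$window$upper)
    put("hr", fit$hr); put("ci_lower", fit$ci95[1]); put("ci_upper", fit$ci95[2])
    put("probit_coef", fit$coef); put("probit_se", fit$se)
    if (!is.null(fit$first_stage)) {
      put("first_stage_coef", fit$first_stage$coef)
    }
  } else if (inherits(fit, "msm_fit")) {
    put("model", "msm"); put("tag", fit$model_tag); put("link", fit$link)
    put("hr", fit$hr); put("ci_lower", fit$ci95[1]); put("ci_upper", fit$ci95[2])
    if (!is.null(fit$per_year_hr)) {
      put("per_year_hr", fit$per_year_hr)
      put("per_year_ci_lower", fit$per_year_ci95[1])
      put("per_year_ci_upper", fit$per_year_ci95[2])
    }
  } else stop("unsupported fit object")
  put("n_subjects", fit$n_subjects); put("n_events", fit$n_events)
  writeLines(c(schema_line("fit-report"), kv), path)
  invisible(path)
}

#' Read a key-value fit report back as a named list
#'
#' @param path Report path.
#' @return Named list of character values (numbers unparsed).
#' @export
read_fit_report <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1], schema_line("fit-report"))) {
    stop(sprintf("'%s' is not a fit report", path))
  }
  kv <- strsplit(lines[-1], "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(x) paste(x[-1], collapse = "=")),
                  vapply(kv, `[[`, "", 1))
}
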