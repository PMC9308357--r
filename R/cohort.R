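#' Study configuration for cohort selection
#'
#' Bundles the calendar window from which utilisation episodes are drawn, the
#' minimum episode duration, and the administrative censor date at which
#' ongoing episodes (and open hospital stays) are truncated. The defaults are
#' the evaluation window of the Independent Supported Housing service this
#' package was built around: episodes starting between 2016-07-02 and
#' 2019-02-28, a 30-day minimum, and censoring at the window end.
#'
#' @param window_start first admissible episode start date.
#' @param window_end last admissible episode start date.
#' @param min_duration_days shortest episode retained, in days; episodes with
#'   duration strictly below this are excluded as too short to reflect
#'   meaningful service exposure.
#' @param censor_date calendar date at which ongoing episodes and open
#'   hospital stays are administratively censored. Must not precede
#'   `window_end`; equality is the study default.
#' @return an object of class `cohort_config`.
#' @examples
#' cohort_config()
#' cohort_config("2020-01-01", "2021-12-31", min_duration_days = 14)
#' @export
cohort_config <- function(window_start = "2016-07-02",
                          window_end = "2019-02-28",
                          min_duration_days = 30L,
                          censor_date = window_end) {
  ws <- as_date_scalar(window_start, "window_start")
  we <- as_date_scalar(window_end, "window_end")
  cd <- as_date_scalar(censor_date, "censor_date")
  if (!(ws < we)) stop("window_start must precede window_end", call. = FALSE)
  if (cd < we) stop("censor_date must not precede window_end", call. = FALSE)
  md <- as.integer(min_duration_days)
  if (is.na(md) || md < 1L) stop("min_duration_days must be a positive integer", call. = FALSE)
  structure(
    list(window_start = ws, window_end = we,
         min_duration_days = md, censor_date = cd),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Cohort configuration\n")
  cat(sprintf("  start-date window : %s .. %s\n", x$window_start, x$window_end))
  cat(sprintf("  minimum duration  : %d days\n", x$min_duration_days))
  cat(sprintf("  censor date       : %s\n", x$censor_date))
  invisible(x)
}

UTILISATION_REQUIRED <- c("record_id", "user_id", "start_date", "end_date")
UTILISATION_OPTIONAL <- c("end_reason", "age_years", "sex", "diagnosis_chapter",
                          "nationality_swiss", "civil_status")
ADMISSION_REQUIRED <- c("record_id", "user_id", "admit_date", "discharge_date")

DIAGNOSIS_LEVELS <- c("F0", "F1", "F2", "F3", "F4", "F6", "F8", "F9", "unknown")

#' Read utilisation episodes from CSV
#'
#' One row per intervention episode; required columns `record_id`, `user_id`,
#' `start_date`, `end_date` (ISO-8601; an empty `end_date` marks an ongoing
#' episode, which is closed at the configured censor date with end reason
#' `administrative_censor`). Optional columns: `end_reason`, `age_years`,
#' `sex`, `diagnosis_chapter`, `nationality_swiss`, `civil_status`.
#'
#' @param source path to a CSV file, or a data frame with the same columns.
#' @param config a [cohort_config()].
#' @return a validated data frame of utilisation episodes with `Date` columns,
#'   an integer `duration_days` column (`end - start`, half-open convention)
#'   and class `ish_utilisations`.
#' @seealso [validate_utilisations()] for the validation rules,
#'   [select_cohort()] for the inclusion/exclusion flow.
#' @export
read_utilisations <- function(source, config) {
  df <- if (is.data.frame(source)) source else
    utils::read.csv(source, colClasses = "character", check.names = TRUE)
  validate_utilisations(df, config)
}

#' Validate a table of utilisation episodes
#'
#' Applies the record invariants: dates parse as ISO-8601; ongoing episodes
#' are closed at the censor date with end reason `administrative_censor`;
#' every start date strictly precedes its effective end date (so duration is
#' at least one day); an `administrative_censor` end reason implies the end
#' date equals the censor date.
#'
#' @inheritParams read_utilisations
#' @param utilisations data frame of raw episode rows.
#' @return the validated `ish_utilisations` data frame.
#' @export
validate_utilisations <- function(utilisations, config) {
  stopifnot(inherits(config, "cohort_config"))
  df <- as.data.frame(utilisations, stringsAsFactors = FALSE)
  require_columns(df, UTILISATION_REQUIRED, "utilisations")

  out <- data.frame(
    record_id = as.character(df$record_id),
    user_id = as.character(df$user_id),
    start_date = parse_iso_date(df$start_date, "start_date"),
    end_date = parse_iso_date(df$end_date, "end_date"),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$record_id) || any(!nzchar(out$record_id))) {
    stop("utilisations: empty record_id", call. = FALSE)
  }
  if (anyDuplicated(out$record_id)) {
    stop(sprintf("utilisations: duplicated record_id '%s'",
                 out$record_id[anyDuplicated(out$record_id)]), call. = FALSE)
  }
  if (anyNA(out$start_date)) {
    stop(sprintf("utilisations: missing start_date for record '%s'",
                 out$record_id[which(is.na(out$start_date))[1]]), call. = FALSE)
  }

  reason <- if ("end_reason" %in% names(df)) as.character(df$end_reason) else
    rep(NA_character_, nrow(df))
  ongoing <- is.na(out$end_date)
  out$end_date[ongoing] <- config$censor_date
  reason[ongoing] <- "administrative_censor"
  blank <- is.na(reason) | !nzchar(trimws(reason))
  reason[blank] <- ifelse(out$end_date[blank] >= config$censor_date,
                          "administrative_censor", "withdrawal")
  bad_reason <- !reason %in% c("withdrawal", "administrative_censor")
  if (any(bad_reason)) {
    stop(sprintf("utilisations: unknown end_reason '%s' for record '%s'",
                 reason[which(bad_reason)[1]],
                 out$record_id[which(bad_reason)[1]]), call. = FALSE)
  }
  out$end_reason <- reason

  bad <- !(out$start_date < out$end_date)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("utilisations: record '%s' has end_date (%s) not after start_date (%s)",
                 out$record_id[i], out$end_date[i], out$start_date[i]), call. = FALSE)
  }
  bad_censor <- out$end_reason == "administrative_censor" &
    out$end_date != config$censor_date
  if (any(bad_censor)) {
    i <- which(bad_censor)[1]
    stop(sprintf("utilisations: record '%s' marked administrative_censor but end_date %s != censor date %s",
                 out$record_id[i], out$end_date[i], config$censor_date), call. = FALSE)
  }
  out$duration_days <- as.integer(out$end_date - out$start_date)

  # optional demographics, carried through untouched apart from light coercion
  out$age_years <- if ("age_years" %in% names(df))
    suppressWarnings(as.numeric(df$age_years)) else rep(NA_real_, nrow(out))
  if (any(!is.na(out$age_years) & out$age_years < 0)) {
    stop("utilisations: negative age_years", call. = FALSE)
  }
  coerce_opt <- function(col) {
    if (col %in% names(df)) {
      v <- as.character(df[[col]])
      v[!nzchar(trimws(v))] <- NA_character_
      v
    } else rep(NA_character_, nrow(out))
  }
  out$sex <- coerce_opt("sex")
  out$diagnosis_chapter <- coerce_opt("diagnosis_chapter")
  out$civil_status <- coerce_opt("civil_status")
  out$nationality_swiss <- rep(NA, nrow(out))
  if ("nationality_swiss" %in% names(df)) {
    v <- toupper(trimws(as.character(df$nationality_swiss)))
    out$nationality_swiss[v %in% c("TRUE", "T", "1", "YES")] <- TRUE
    out$nationality_swiss[v %in% c("FALSE", "F", "0", "NO")] <- FALSE
  }

  class(out) <- c("ish_utilisations", "data.frame")
  out
}

#' Read inpatient admission records from CSV
#'
#' One row per inpatient psychiatric stay; required columns `record_id`,
#' `user_id`, `admit_date`, `discharge_date` (ISO-8601; empty
#' `discharge_date` marks a stay still open at data extraction). Open stays
#' are kept open here and clipped at the analysis censor date by the counting
#' functions.
#'
#' @param source path to a CSV file, or a data frame with the same columns.
#' @return a validated data frame of class `ish_admissions`.
#' @export
read_admissions <- function(source) {
  df <- if (is.data.frame(source)) source else
    utils::read.csv(source, colClasses = "character", check.names = TRUE)
  validate_admissions(df)
}

#' Validate a table of admission records
#'
#' @param admissions data frame of raw stay rows.
#' @return the validated `ish_admissions` data frame.
#' @export
validate_admissions <- function(admissions) {
  df <- as.data.frame(admissions, stringsAsFactors = FALSE)
  require_columns(df, ADMISSION_REQUIRED, "admissions")
  out <- data.frame(
    record_id = as.character(df$record_id),
    user_id = as.character(df$user_id),
    admit_date = parse_iso_date(df$admit_date, "admit_date"),
    discharge_date = parse_iso_date(df$discharge_date, "discharge_date"),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$admit_date)) {
    stop(sprintf("admissions: missing admit_date for record '%s'",
                 out$record_id[which(is.na(out$admit_date))[1]]), call. = FALSE)
  }
  bad <- !is.na(out$discharge_date) & !(out$admit_date < out$discharge_date)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("admissions: record '%s' has discharge_date (%s) not after admit_date (%s)",
                 out$record_id[i], out$discharge_date[i], out$admit_date[i]), call. = FALSE)
  }
  class(out) <- c("ish_admissions", "data.frame")
  out
}

#' Select the analysis cohort
#'
#' Applies the inclusion/exclusion flow to validated utilisation episodes:
#' (1) only episodes starting inside `[window_start, window_end]` are
#' extracted (episodes starting earlier remain visible as evidence of prior
#' service use); (2) per user, only the earliest in-window episode is kept
#' (ties on start date broken by lexicographically smallest `record_id`, with
#' a warning); (3) every episode of a user with any recorded start before the
#' window is dropped (prior use); (4) episodes shorter than
#' `min_duration_days` are dropped. Exclusions are tallied in that order:
#' repeat use, prior use, short duration.
#'
#' @param utilisations an `ish_utilisations` table (see [read_utilisations()]).
#' @param config a [cohort_config()].
#' @return a list with components `cohort` (the included episodes, one per
#'   user) and `report` (a `selection_report`: step counts plus a per-record
#'   map of exclusion reasons).
#' @examples
#' cfg <- cohort_config("2020-01-01", "2020-12-31", 30, "2020-12-31")
#' u <- read_utilisations(data.frame(
#'   record_id = c("a", "b"), user_id = c("p1", "p1"),
#'   start_date = c("2020-02-01", "2020-06-01"),
#'   end_date = c("2020-04-01", "2020-08-01")), cfg)
#' select_cohort(u, cfg)$report
#' @export
select_cohort <- function(utilisations, config) {
  stopifnot(inherits(config, "cohort_config"))
  u <- utilisations
  reasons <- data.frame(record_id = character(), user_id = character(),
                        reason = character(), stringsAsFactors = FALSE)
  add_reason <- function(rows, why) {
    if (!nrow(rows)) return()
    reasons <<- rbind(reasons, data.frame(record_id = rows$record_id,
                                          user_id = rows$user_id,
                                          reason = why,
                                          stringsAsFactors = FALSE))
  }

  in_window <- u$start_date >= config$window_start & u$start_date <= config$window_end
  prior_users <- unique(u$user_id[u$start_date < config$window_start])
  add_reason(u[!in_window, , drop = FALSE], "out_of_window")
  ext <- u[in_window, , drop = FALSE]
  n_extracted <- nrow(ext)

  # step 1: repeat use — keep the earliest in-window episode per user
  ord <- order(ext$user_id, ext$start_date, ext$record_id)
  ext <- ext[ord, , drop = FALSE]
  first <- !duplicated(ext$user_id)
  dup_start <- ext$user_id[duplicated(paste(ext$user_id, ext$start_date))]
  if (length(dup_start)) {
    warning(sprintf("tie on start date for user(s) %s; keeping smallest record_id",
                    paste(unique(dup_start), collapse = ", ")), call. = FALSE)
  }
  add_reason(ext[!first, , drop = FALSE], "repeat_use")
  keep <- ext[first, , drop = FALSE]
  n_repeat <- sum(!first)

  # step 2: prior use removes the user entirely
  prior <- keep$user_id %in% prior_users
  add_reason(keep[prior, , drop = FALSE], "prior_use")
  keep <- keep[!prior, , drop = FALSE]
  n_prior <- sum(prior)

  # step 3: too short
  short <- keep$duration_days < config$min_duration_days
  add_reason(keep[short, , drop = FALSE], "short_duration")
  keep <- keep[!short, , drop = FALSE]
  n_short <- sum(short)

  keep <- keep[order(keep$record_id), , drop = FALSE]
  rownames(keep) <- NULL
  class(keep) <- c("ish_utilisations", "data.frame")

  report <- structure(
    list(n_extracted = n_extracted,
         n_excluded_repeat_use = n_repeat,
         n_excluded_prior_use = n_prior,
         n_excluded_short = n_short,
         n_included = nrow(keep),
         exclusions = reasons),
    class = "selection_report"
  )
  stopifnot(report$n_included ==
    report$n_extracted - n_repeat - n_prior - n_short)
  list(cohort = keep, report = report)
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Cohort selection\n")
  cat(sprintf("  extracted (start date in window) : %d\n", x$n_extracted))
  cat(sprintf("  - repeat use (not first episode) : %d\n", x$n_excluded_repeat_use))
  cat(sprintf("  - prior use before window        : %d\n", x$n_excluded_prior_use))
  cat(sprintf("  - shorter than minimum duration  : %d\n", x$n_excluded_short))
  cat(sprintf("  included                         : %d\n", x$n_included))
  invisible(x)
}

#' Serialise a selection report to JSON
#'
#' @param report a `selection_report` from [select_cohort()].
#' @param path optional file path; when omitted the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
selection_report_json <- function(report, path = NULL) {
  payload <- list(
    n_extracted = report$n_extracted,
    n_excluded_repeat_use = report$n_excluded_repeat_use,
    n_excluded_prior_use = report$n_excluded_prior_use,
    n_excluded_short = report$n_excluded_short,
    n_included = report$n_included,
    exclusions = report$exclusions
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE, na = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Descriptive summary of a selected cohort
#'
#' Reports the demographic and clinical composition of the cohort at the
#' index date — age mean/SD, sex, ICD-10 diagnosis chapter (with F0, F8, F9
#' and unknown pooled into "other"), nationality and civil status — plus the
#' utilisation-duration distribution and total person-time. Missing optional
#' fields yield "not available" entries rather than errors.
#'
#' @param utilisations a selected cohort (`ish_utilisations`).
#' @return an object of class `cohort_summary`.
#' @export
summarize_cohort <- function(utilisations) {
  u <- utilisations
  n <- nrow(u)
  pct_table <- function(x, levels = NULL) {
    if (all(is.na(x))) return(NULL)
    tab <- table(factor(x, levels = levels %||% sort(unique(stats::na.omit(x)))))
    data.frame(level = names(tab), n = as.integer(tab),
               pct = round(100 * as.integer(tab) / sum(tab), 1),
               stringsAsFactors = FALSE)
  }
  diag <- u$diagnosis_chapter
  diag[diag %in% c("F0", "F8", "F9", "unknown")] <- "other"
  durations <- u$duration_days
  person_days <- sum(durations)
  structure(
    list(
      n_users = n,
      age = if (all(is.na(u$age_years))) NULL else
        list(mean = round(mean(u$age_years, na.rm = TRUE), 1),
             sd = round(stats::sd(u$age_years, na.rm = TRUE), 1),
             min = min(u$age_years, na.rm = TRUE),
             max = max(u$age_years, na.rm = TRUE)),
      sex = pct_table(u$sex, c("female", "male")),
      diagnosis = pct_table(diag, c("F1", "F2", "F3", "F4", "F6", "other")),
      nationality_swiss = pct_table(ifelse(is.na(u$nationality_swiss), NA,
                                           ifelse(u$nationality_swiss, "swiss", "non-swiss")),
                                    c("swiss", "non-swiss")),
      civil_status = pct_table(u$civil_status,
                               c("single", "married", "divorced_widowed")),
      duration = if (n) list(mean = round(mean(durations), 1),
                             sd = round(stats::sd(durations), 1),
                             median = stats::median(durations),
                             min = min(durations), max = max(durations)) else NULL,
      person_days = person_days,
      person_years = person_days_to_years(person_days),
      n_censored = sum(u$end_reason == "administrative_censor"),
      n_withdrawn = sum(u$end_reason == "withdrawal")
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d service users\n", x$n_users))
  if (!is.null(x$age)) {
    cat(sprintf("  age: mean %.1f (SD %.1f), range %g-%g\n",
                x$age$mean, x$age$sd, x$age$min, x$age$max))
  } else cat("  age: not available\n")
  show_tab <- function(label, tab) {
    if (is.null(tab)) { cat(sprintf("  %s: not available\n", label)); return() }
    cat(sprintf("  %s: %s\n", label,
                paste(sprintf("%s %d (%.1f%%)", tab$level, tab$n, tab$pct),
                      collapse = ", ")))
  }
  show_tab("sex", x$sex)
  show_tab("diagnosis", x$diagnosis)
  show_tab("nationality", x$nationality_swiss)
  show_tab("civil status", x$civil_status)
  if (!is.null(x$duration)) {
    cat(sprintf("  utilisation days: mean %.1f (SD %.1f), median %g, range %g-%g\n",
                x$duration$mean, x$duration$sd, x$duration$median,
                x$duration$min, x$duration$max))
  }
  cat(sprintf("  person-time: %d person-days (%.1f person-years)\n",
              x$person_days, x$person_years))
  cat(sprintf("  censored: %d; withdrawn: %d\n", x$n_censored, x$n_withdrawn))
  invisible(x)
}
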