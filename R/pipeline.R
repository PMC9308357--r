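#' Run the full mirror-image analysis pipeline
#'
#' Reads and validates the utilisation and admission tables, applies the
#' inclusion/exclusion flow, summarises the cohort, runs the primary
#' mirror-image analysis for every requested period and both outcomes, the
#' lookback sensitivity analysis, and the per-interval admission-proportion
#' profile. When `out_dir` is given, writes `selection_report.json`,
#' `cohort_summary.json`, `results_primary.csv`, `results_sensitivity.csv`
#' and `proportions.csv` there; undefined statistics are written as empty
#' CSV fields and JSON nulls. The whole path is deterministic: two runs on
#' identical inputs produce byte-identical outputs.
#'
#' @param utilisations path to the utilisations CSV, or an equivalent data
#'   frame.
#' @param admissions path to the admissions CSV, or an equivalent data
#'   frame.
#' @param config a [cohort_config()].
#' @param periods list/vector mixing `"utilisation"` and fixed day lengths.
#' @param lookback_days sensitivity lookback window, days.
#' @param out_dir optional output directory for the artifact files.
#' @param alpha two-sided significance level.
#' @param proportions_numerator `"admissions"` or `"users"`, see
#'   [quarterly_admission_proportions()].
#' @param verbose log pipeline stages with counts to stderr?
#' @return invisibly, a list with `cohort`, `report`, `summary`, `primary`,
#'   `sensitivity`, `proportions` and `results` (primary and sensitivity
#'   stacked).
#' @export
run_analysis <- function(utilisations, admissions, config = cohort_config(),
                         periods = list("utilisation", 90L, 180L, 270L, 365L),
                         lookback_days = 90L, out_dir = NULL, alpha = 0.05,
                         proportions_numerator = "admissions",
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  u <- read_utilisations(utilisations, config)
  a <- read_admissions(admissions)
  say("read %d utilisation and %d admission records", nrow(u), nrow(a))

  sel <- select_cohort(u, config)
  say("selected %d of %d extracted episodes (repeat %d, prior %d, short %d)",
      sel$report$n_included, sel$report$n_extracted,
      sel$report$n_excluded_repeat_use, sel$report$n_excluded_prior_use,
      sel$report$n_excluded_short)
  cohort <- sel$cohort
  summ <- summarize_cohort(cohort)

  primary <- analyze_periods(cohort, a, periods, config$censor_date, alpha)
  sensitivity <- run_sensitivity(cohort, a, periods, lookback_days,
                                 config$censor_date, alpha)
  say("sensitivity exclusion removed %d users", attr(sensitivity, "n_excluded"))
  proportions <- quarterly_admission_proportions(
    cohort, a, numerator = proportions_numerator)
  results <- rbind(primary, as.data.frame(sensitivity))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    selection_report_json(sel$report, file.path(out_dir, "selection_report.json"))
    writeLines(jsonlite::toJSON(unclass(summ), auto_unbox = TRUE, pretty = TRUE,
                                na = "null", digits = NA),
               file.path(out_dir, "cohort_summary.json"))
    write_results_csv(primary, file.path(out_dir, "results_primary.csv"))
    write_results_csv(as.data.frame(sensitivity),
                      file.path(out_dir, "results_sensitivity.csv"))
    utils::write.csv(proportions, file.path(out_dir, "proportions.csv"),
                     row.names = FALSE, na = "")
    say("artifacts written to %s", out_dir)
  }
  invisible(list(cohort = cohort, report = sel$report, summary = summ,
                 primary = primary, sensitivity = sensitivity,
                 proportions = proportions, results = results))
}

#' Write a mirror-image results table as CSV
#'
#' Undefined statistics (zero pre-count rows) are written as empty fields.
#' [read_results_csv()] restores the exact in-memory table.
#'
#' @param results a results data frame from [analyze_periods()] or
#'   [run_sensitivity()].
#' @param path output file path.
#' @export
write_results_csv <- function(results, path) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(
                          analysis = "character", outcome = "character",
                          period = "character", n_users = "integer",
                          pre_count = "numeric", post_count = "numeric",
                          person_time_days = "numeric", irr = "numeric",
                          ci_low = "numeric", ci_high = "numeric",
                          significant = "logical"))
  df
}

#' Render a results table as aligned text
#'
#' Undefined statistics are rendered as an em dash, the convention of
#' published mirror-image tables.
#'
#' @param results a results data frame.
#' @return a character vector of lines, invisibly; also printed.
#' @export
format_results_table <- function(results) {
  fmt <- function(v) ifelse(is.na(v), "—", formatC(v, format = "f", digits = 2))
  lines <- c(
    sprintf("%-11s %-12s %-18s %6s %5s %5s %6s %6s %6s",
            "analysis", "outcome", "period", "n", "pre", "post",
            "IRR", "lo", "hi"),
    sprintf("%-11s %-12s %-18s %6d %5.0f %5.0f %6s %6s %6s",
            results$analysis, results$outcome, results$period,
            results$n_users, results$pre_count, results$post_count,
            fmt(results$irr), fmt(results$ci_low), fmt(results$ci_high)))
  cat(lines, sep = "\n")
  invisible(lines)
}
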