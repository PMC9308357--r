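#' Exclude users with a recent pre-index admission
#'
#' Regression toward the mean threatens mirror-image designs because the
#' intervention often starts shortly after a hospitalisation, transiently
#' inflating the pre-index rate. This filter removes every user with at
#' least one admission *event* in the half-open lookback window
#' `[index - lookback_days, index)`; a stay admitted before the lookback
#' window but still open inside it does not trigger exclusion (the criterion
#' is event-based).
#'
#' @param cohort a selected cohort (`ish_utilisations`).
#' @param admissions an `ish_admissions` table.
#' @param lookback_days length of the lookback window in days (default 90).
#' @return a list with `cohort` (the filtered cohort), `n_excluded`, and
#'   `excluded_users` (their ids).
#' @export
exclude_recent_admitters <- function(cohort, admissions, lookback_days = 90L) {
  L <- as.integer(lookback_days)
  stopifnot(L >= 1L)
  idx <- day_number(cohort$start_date)
  ad <- day_number(admissions$admit_date)
  m <- match(admissions$user_id, cohort$user_id)
  hit <- !is.na(m) & ad >= (idx[m] - L) & ad < idx[m]
  excluded <- unique(admissions$user_id[hit])
  keep <- !(cohort$user_id %in% excluded)
  filtered <- cohort[keep, , drop = FALSE]
  rownames(filtered) <- NULL
  class(filtered) <- c("ish_utilisations", "data.frame")
  list(cohort = filtered, n_excluded = sum(!keep), excluded_users = excluded)
}

#' Sensitivity analysis: re-run all mirror-image analyses after lookback exclusion
#'
#' Applies [exclude_recent_admitters()] once and re-runs [analyze_periods()]
#' on the filtered cohort for every period and both outcomes. By
#' construction, when the lookback is no longer than the shortest analysed
#' mirror length, the filtered cohort has exactly zero pre-index admissions
#' in the first `lookback_days` before the index, so short-period admission
#' IRRs can become undefined (zero pre-count) — exactly the behaviour this
#' analysis is meant to surface.
#'
#' @inheritParams exclude_recent_admitters
#' @inheritParams analyze_periods
#' @return a data frame in the same layout as [analyze_periods()] with
#'   `analysis = "sensitivity"`, plus attributes `n_excluded` and
#'   `excluded_users`.
#' @export
run_sensitivity <- function(cohort, admissions,
                            periods = list("utilisation", 90L, 180L, 270L, 365L),
                            lookback_days = 90L, clip_open_at, alpha = 0.05) {
  filt <- exclude_recent_admitters(cohort, admissions, lookback_days)
  res <- analyze_periods(filt$cohort, admissions, periods, clip_open_at, alpha)
  res$analysis <- "sensitivity"
  attr(res, "n_excluded") <- filt$n_excluded
  attr(res, "excluded_users") <- filt$excluded_users
  res
}
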