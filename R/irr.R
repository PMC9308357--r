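#' Incidence rate ratio with confidence interval
#'
#' Pooled post/pre incidence rate ratio (IRR) for event counts observed over
#' known person-time on each side of the index:
#' `irr = (post_count / post_time) / (pre_count / pre_time)`. The default
#' confidence interval uses the normal approximation on the log rate ratio,
#' `exp(log(irr) +/- z * sqrt(1/post_count + 1/pre_count))`, the convention
#' of standard epidemiological rate-ratio routines; an exact conditional
#' (binomial) interval is available with `method = "exact"`.
#'
#' This is the deliberately simple pooled analysis used by self-controlled
#' mirror-image studies: it ignores that the two periods come from the same
#' individuals, which is conservative (it exaggerates standard errors) and
#' sidesteps zero event counts in individual users.
#'
#' Zero-count policy: with `pre_count = 0` the ratio and interval are
#' undefined (all `NA`); with `post_count = 0` and `pre_count > 0` the point
#' estimate is 0 with an undefined interval.
#'
#' @param post_count,pre_count non-negative event totals after/before index.
#' @param post_time,pre_time person-time at risk on each side, in days;
#'   must be positive. With equal person-time the IRR reduces to
#'   `post_count / pre_count`.
#' @param alpha two-sided significance level (default 0.05 for a 95% CI).
#' @param method `"normal"` (log-scale normal approximation, default) or
#'   `"exact"` (conditional binomial).
#' @return an object of class `irr_result`: a list with the counts, times,
#'   `irr`, `ci_low`, `ci_high`, `alpha`, `significant` (CI excludes 1; `NA`
#'   when the interval is undefined) and `method`.
#' @examples
#' rate_ratio(28, 68, 1000, 1000)   # IRR 0.41 (0.27-0.64)
#' rate_ratio(802, 2113, 1, 1)      # scale-free with equal person-time
#' @export
rate_ratio <- function(post_count, pre_count, post_time, pre_time,
                       alpha = 0.05, method = c("normal", "exact")) {
  method <- match.arg(method)
  if (!is.finite(post_time) || !is.finite(pre_time) ||
      post_time <= 0 || pre_time <= 0) {
    stop("person-time must be positive on both sides", call. = FALSE)
  }
  if (post_count < 0 || pre_count < 0) {
    stop("event counts must be non-negative", call. = FALSE)
  }
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }

  irr <- ci_low <- ci_high <- NA_real_
  significant <- NA
  if (pre_count > 0) {
    irr <- (post_count / post_time) / (pre_count / pre_time)
    if (post_count > 0) {
      if (method == "normal") {
        z <- stats::qnorm(1 - alpha / 2)
        se <- sqrt(1 / post_count + 1 / pre_count)
        ci_low <- exp(log(irr) - z * se)
        ci_high <- exp(log(irr) + z * se)
      } else {
        # conditional on the total, post_count ~ Binomial(n, p) with
        # p = irr * post_time / (irr * post_time + pre_time)
        bt <- stats::binom.test(post_count, post_count + pre_count,
                                conf.level = 1 - alpha)
        p <- bt$conf.int
        ci_low <- (p[1] / (1 - p[1])) * (pre_time / post_time)
        ci_high <- (p[2] / (1 - p[2])) * (pre_time / post_time)
      }
      significant <- ci_low > 1 || ci_high < 1
    }
  }
  structure(
    list(pre_count = pre_count, post_count = post_count,
         pre_person_time = pre_time, post_person_time = post_time,
         irr = irr, ci_low = ci_low, ci_high = ci_high,
         alpha = alpha, significant = significant, method = method),
    class = "irr_result"
  )
}

#' @export
print.irr_result <- function(x, digits = 2, ...) {
  fmt <- function(v) if (is.na(v)) "—" else formatC(v, format = "f", digits = digits)
  cat(sprintf("IRR %s (%d%% CI %s–%s)  post %d / pre %d events\n",
              fmt(x$irr), round(100 * (1 - x$alpha)), fmt(x$ci_low), fmt(x$ci_high),
              x$post_count, x$pre_count))
  invisible(x)
}

#' Convert person-days to person-years
#'
#' Uses the mean Julian year of 365.25 days and reports one decimal place,
#' the resolution at which person-years are conventionally tabulated.
#'
#' @param d person-days, non-negative.
#' @return person-years rounded to one decimal.
#' @examples
#' person_days_to_years(44690)  # 122.4
#' @export
person_days_to_years <- function(d) {
  stopifnot(all(d >= 0))
  round(d / 365.25, 1)
}

#' Mirror-image analysis of one period
#'
#' Builds the mirror windows for the requested period, pools admission events
#' and hospitalised person-days across all eligible users on each side of the
#' index, and computes one pooled rate ratio per outcome. Person-time per
#' side is the summed window length of the eligible users, identical pre and
#' post by construction, so each IRR reduces to the ratio of pooled counts.
#'
#' @param cohort a selected cohort (`ish_utilisations`).
#' @param admissions an `ish_admissions` table.
#' @param period `"utilisation"` or a fixed window length in days (see
#'   [mirror_windows()]).
#' @param clip_open_at date at which open stays are closed (study censor
#'   date).
#' @param alpha two-sided significance level for the CIs.
#' @return a data frame with one row per outcome (`admissions`,
#'   `person_days`): period label, `n_users`, pre/post counts, person-time
#'   per side in days, `irr`, `ci_low`, `ci_high`, `significant`.
#' @export
analyze_period <- function(cohort, admissions, period, clip_open_at,
                           alpha = 0.05) {
  w <- mirror_windows(cohort, period)
  label <- if (identical(period, "utilisation")) "utilisation period"
           else paste0(as.integer(period), " days")
  n <- nrow(w)
  row <- function(outcome, pre, post, time) {
    if (n == 0L || time <= 0) {
      return(data.frame(outcome = outcome, period = label, n_users = n,
                        pre_count = pre, post_count = post,
                        person_time_days = time,
                        irr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        significant = NA, stringsAsFactors = FALSE))
    }
    r <- rate_ratio(post, pre, time, time, alpha = alpha)
    data.frame(outcome = outcome, period = label, n_users = n,
               pre_count = pre, post_count = post, person_time_days = time,
               irr = r$irr, ci_low = r$ci_low, ci_high = r$ci_high,
               significant = r$significant, stringsAsFactors = FALSE)
  }
  counts <- pooled_window_counts(w, admissions, clip_open_at)
  time <- sum(w$length_days)
  rbind(
    row("admissions", counts$pre_admissions, counts$post_admissions, time),
    row("person_days", counts$pre_person_days, counts$post_person_days, time)
  )
}

#' Mirror-image analysis over several periods
#'
#' Runs [analyze_period()] for the variable-length utilisation period and/or
#' each fixed length, returning the stacked results table in the layout of a
#' mirror-image results table: one row per outcome and period.
#'
#' @inheritParams analyze_period
#' @param periods list/vector mixing `"utilisation"` and integer day lengths.
#' @return a data frame of pooled IRR results with an `analysis` column set
#'   to `"primary"`.
#' @export
analyze_periods <- function(cohort, admissions,
                            periods = list("utilisation", 90L, 180L, 270L, 365L),
                            clip_open_at, alpha = 0.05) {
  out <- do.call(rbind, lapply(periods, function(p) {
    analyze_period(cohort, admissions, p, clip_open_at, alpha)
  }))
  cbind(analysis = "primary", out, stringsAsFactors = FALSE)
}

#' Proportion of admissions per 90-day interval around the index
#'
#' Splits the pre- and post-index timelines into consecutive intervals of
#' `interval_days` (quarter-years by default) and, for each interval,
#' reports a proportion among the users whose mirror windows cover that
#' interval (users with `duration_days >= k * interval_days` for the k-th
#' interval). The numerator is either the number of admissions in the
#' interval (`numerator = "admissions"`) or the number of users with at
#' least one admission (`numerator = "users"`); the published profile is
#' compatible with either reading, so both are offered.
#'
#' @inheritParams analyze_period
#' @param interval_days interval width in days (default 90).
#' @param max_intervals number of intervals per side; `NULL` means as many
#'   as the longest episode covers.
#' @param numerator `"admissions"` or `"users"`.
#' @return a data frame with `side` (`pre`/`post`), `interval_index` (1 =
#'   closest to the index), `interval_label`, `n_users_observed`, `n_events`
#'   and `proportion`.
#' @export
quarterly_admission_proportions <- function(cohort, admissions,
                                            interval_days = 90L,
                                            max_intervals = NULL,
                                            numerator = c("admissions", "users")) {
  numerator <- match.arg(numerator)
  I <- as.integer(interval_days)
  stopifnot(I >= 1L)
  if (!nrow(cohort)) {
    return(data.frame(side = character(), interval_index = integer(),
                      interval_label = character(), n_users_observed = integer(),
                      n_events = integer(), proportion = numeric(),
                      stringsAsFactors = FALSE))
  }
  K <- max(cohort$duration_days %/% I)
  if (!is.null(max_intervals)) K <- min(K, as.integer(max_intervals))
  idx <- day_number(cohort$start_date)
  ad <- day_number(admissions$admit_date)
  au <- admissions$user_id
  rows <- list()
  for (side in c("pre", "post")) {
    for (k in seq_len(K)) {
      eligible <- cohort$duration_days >= k * I
      n_obs <- sum(eligible)
      uid <- cohort$user_id[eligible]
      lo <- if (side == "pre") idx[eligible] - k * I else idx[eligible] + (k - 1L) * I
      hi <- lo + I
      sel <- au %in% uid
      m <- match(au[sel], uid)
      inside <- ad[sel] >= lo[m] & ad[sel] < hi[m]
      n_events <- if (numerator == "admissions") sum(inside) else
        length(unique(au[sel][inside]))
      label <- if (side == "pre") {
        sprintf("%d–%d days pre-index", (k - 1L) * I + 1L, k * I)
      } else {
        sprintf("%d–%d days post-index", (k - 1L) * I + 1L, k * I)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        side = side, interval_index = k, interval_label = label,
        n_users_observed = n_obs, n_events = n_events,
        proportion = if (n_obs > 0) n_events / n_obs else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
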