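#' Construct mirror windows for a cohort
#'
#' For each utilisation episode, builds an equal-length pair of half-open
#' observation windows around the index (the episode start date): the pre
#' window `[index - L, index)` and the post window `[index, index + L)`. The
#' index day itself belongs to the post window, since the intervention is
#' active from its start date.
#'
#' With `period = "utilisation"` the window length is the episode's own
#' (possibly censored) duration, so the post window is exactly the episode.
#' With an integer `period` of `L` days, only users whose episode covers the
#' entire length (`duration_days >= L`) are eligible and returned; eligible
#' sets are therefore nested across increasing lengths.
#'
#' @param utilisations a selected cohort (`ish_utilisations`).
#' @param period `"utilisation"` for variable-length windows, or a single
#'   positive integer length in days.
#' @return a data frame with one row per eligible user: `user_id`,
#'   `index_date`, `length_days`, `pre_start`, `post_end` (the pre window is
#'   `[pre_start, index_date)`, the post window `[index_date, post_end)`).
#' @examples
#' cfg <- cohort_config("2016-07-02", "2019-02-28")
#' u <- read_utilisations(data.frame(
#'   record_id = "u1", user_id = "p1",
#'   start_date = "2017-03-01", end_date = "2017-06-29"), cfg)
#' mirror_windows(u, "utilisation")
#' mirror_windows(u, 90)
#' @export
mirror_windows <- function(utilisations, period = "utilisation") {
  u <- utilisations
  if (identical(period, "utilisation")) {
    len <- u$duration_days
    keep <- rep(TRUE, nrow(u))
  } else {
    L <- as.integer(period)
    if (length(L) != 1L || is.na(L) || L < 1L) {
      stop("period must be \"utilisation\" or a single positive integer of days",
           call. = FALSE)
    }
    keep <- u$duration_days >= L
    len <- rep(L, nrow(u))
  }
  w <- data.frame(
    user_id = u$user_id[keep],
    index_date = u$start_date[keep],
    length_days = len[keep],
    stringsAsFactors = FALSE
  )
  w$pre_start <- w$index_date - w$length_days
  w$post_end <- w$index_date + w$length_days
  rownames(w) <- NULL
  w
}

#' Mirror windows at several fixed lengths
#'
#' Convenience wrapper around [mirror_windows()] returning one block per
#' requested length with a `period` label column; a user appears in a block
#' only if their episode covers that entire length.
#'
#' @inheritParams mirror_windows
#' @param lengths integer vector of window lengths in days, ascending.
#' @return a data frame of stacked mirror-window pairs with a `period` column.
#' @export
fixed_mirror_windows <- function(utilisations, lengths = c(90L, 180L, 270L, 365L)) {
  lengths <- sort(as.integer(lengths))
  out <- lapply(lengths, function(L) {
    w <- mirror_windows(utilisations, L)
    if (nrow(w)) w$period <- paste0(L, " days")
    else w$period <- character(0)
    w
  })
  do.call(rbind, out)
}

# Close open stays at `clip_open_at` and return numeric day-number intervals.
# Stays still open at the clip date contribute up to (but not including) it.
stay_intervals <- function(admissions, clip_open_at) {
  s <- day_number(admissions$admit_date)
  e <- ifelse(is.na(admissions$discharge_date),
              day_number(as_date_scalar(clip_open_at, "clip_open_at")),
              day_number(admissions$discharge_date))
  keep <- e > s  # an open stay admitted on/after the clip date contributes nothing
  list(user_id = admissions$user_id[keep], start = s[keep], end = e[keep])
}

# Merge overlapping/abutting-by-overlap intervals within user so person-days
# are counted on the union. Intervals touching end-to-start (end == next
# start) stay distinct but merging them is harmless for day totals.
merge_user_intervals <- function(user_id, start, end) {
  n <- length(start)
  if (n <= 1L) return(list(user_id = user_id, start = start, end = end))
  o <- order(user_id, start, end)
  u <- user_id[o]; s <- start[o]; e <- end[o]
  keep <- logical(n)
  keep[1] <- TRUE
  last <- 1L
  for (i in 2:n) {
    if (u[i] == u[last] && s[i] < e[last]) {
      e[last] <- max(e[last], e[i])  # absorb overlap
    } else {
      keep[i] <- TRUE
      last <- i
    }
  }
  list(user_id = u[keep], start = s[keep], end = e[keep])
}

#' Count admissions inside a window
#'
#' An admission is attributed to a window by its admission date alone: a stay
#' admitted before the window that is still ongoing inside it contributes
#' person-days (see [count_person_days()]) but no admission event.
#'
#' @param admissions an `ish_admissions` table (any mix of users; filter
#'   beforehand for per-user counts).
#' @param window_start,window_end half-open window bounds `[start, end)`.
#' @return the number of stays with `admit_date` in the window.
#' @export
count_admissions <- function(admissions, window_start, window_end) {
  ws <- as_date_scalar(window_start, "window_start")
  we <- as_date_scalar(window_end, "window_end")
  sum(admissions$admit_date >= ws & admissions$admit_date < we)
}

#' Count hospitalised person-days inside a window
#'
#' Sums, over the union of a user's stay intervals, the number of days that
#' fall inside the half-open window `[window_start, window_end)`. Stays
#' straddling a window boundary are clipped, so a stay admitted before the
#' window ("censored stay") still contributes its in-window days; stays with
#' no recorded discharge are first closed at `clip_open_at`. Overlapping
#' stays of one user are merged before counting so no day is counted twice.
#'
#' @inheritParams count_admissions
#' @param clip_open_at date at which stays without a discharge are closed
#'   (normally the study censor date).
#' @return total person-days, a non-negative integer-valued number.
#' @export
count_person_days <- function(admissions, window_start, window_end, clip_open_at) {
  ws <- day_number(as_date_scalar(window_start, "window_start"))
  we <- day_number(as_date_scalar(window_end, "window_end"))
  if (we < ws) stop("window_end before window_start", call. = FALSE)
  iv <- stay_intervals(admissions, clip_open_at)
  iv <- merge_user_intervals(iv$user_id, iv$start, iv$end)
  sum(pmax(0, pmin(iv$end, we) - pmax(iv$start, ws)))
}

# Vectorised pooled counting over a table of mirror windows: returns pre/post
# admission-event and person-day totals summed across users. Used by
# analyze_period(); exactly equivalent to looping count_admissions()/
# count_person_days() per user and side.
pooled_window_counts <- function(windows, admissions, clip_open_at) {
  res <- list(pre_admissions = 0L, post_admissions = 0L,
              pre_person_days = 0, post_person_days = 0)
  if (!nrow(windows)) return(res)
  a <- admissions[admissions$user_id %in% windows$user_id, , drop = FALSE]
  if (nrow(a)) {
    m <- match(a$user_id, windows$user_id)
    idx <- day_number(windows$index_date)[m]
    pre0 <- day_number(windows$pre_start)[m]
    post1 <- day_number(windows$post_end)[m]
    ad <- day_number(a$admit_date)
    res$pre_admissions <- sum(ad >= pre0 & ad < idx)
    res$post_admissions <- sum(ad >= idx & ad < post1)

    iv <- stay_intervals(a, clip_open_at)
    iv <- merge_user_intervals(iv$user_id, iv$start, iv$end)
    m2 <- match(iv$user_id, windows$user_id)
    idx2 <- day_number(windows$index_date)[m2]
    pre02 <- day_number(windows$pre_start)[m2]
    post12 <- day_number(windows$post_end)[m2]
    res$pre_person_days <- sum(pmax(0, pmin(iv$end, idx2) - pmax(iv$start, pre02)))
    res$post_person_days <- sum(pmax(0, pmin(iv$end, post12) - pmax(iv$start, idx2)))
  }
  res
}
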