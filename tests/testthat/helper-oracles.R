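# Brute-force day-scan oracles and tiny record builders shared across tests.
# The oracles enumerate calendar days one by one and never touch the
# interval-arithmetic code paths they are used to check.

make_util <- function(record_id, user_id, start, end, ...) {
  data.frame(record_id = record_id, user_id = user_id,
             start_date = as.character(start), end_date = as.character(end),
             ..., stringsAsFactors = FALSE)
}

make_adm <- function(user_id, admit, discharge = NA, record_id = NULL) {
  n <- length(user_id)
  discharge <- rep(discharge, length.out = n)
  data.frame(record_id = record_id %||% sprintf("a%03d", seq_len(n)),
             user_id = user_id, admit_date = as.character(admit),
             discharge_date = ifelse(is.na(discharge), "", as.character(discharge)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# O(days) oracle: count admission events by membership of each admit date.
brute_count_admissions <- function(admissions, window_start, window_end) {
  days <- seq(as.Date(window_start), as.Date(window_end) - 1, by = "day")
  sum(as.Date(admissions$admit_date) %in% days)
}

# O(days) oracle: a day is hospitalised if any stay of that user is open on
# it (admit <= day < discharge); open stays close at clip_open_at.
brute_person_days <- function(admissions, window_start, window_end, clip_open_at) {
  if (!nrow(admissions)) return(0)
  days <- seq(as.Date(window_start), as.Date(window_end) - 1, by = "day")
  adm <- as.Date(admissions$admit_date)
  raw <- as.character(admissions$discharge_date)
  raw[is.na(raw) | !nzchar(raw)] <- as.character(clip_open_at)
  dis <- as.Date(raw)
  total <- 0
  for (u in unique(admissions$user_id)) {
    i <- admissions$user_id == u
    for (d in as.numeric(days)) {
      if (any(as.numeric(adm[i]) <= d & d < as.numeric(dis[i]))) total <- total + 1
    }
  }
  total
}

# Random small stay set for property tests: dates near a fixed anchor,
# overlapping and open stays allowed.
random_stays <- function(n_stays, n_users = 2, anchor = as.Date("2018-01-01")) {
  user <- sprintf("p%d", sample.int(n_users, n_stays, replace = TRUE))
  admit <- anchor + sample(-40:40, n_stays, replace = TRUE)
  len <- sample(1:15, n_stays, replace = TRUE)
  open <- stats::runif(n_stays) < 0.1
  make_adm(user, admit, ifelse(open, NA, as.character(admit + len)))
}

study_config <- function() cohort_config("2016-07-02", "2019-02-28", 30, "2019-02-28")
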