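# Deterministic demonstration cohorts. These are synthetic, hand-constructed
# tables (no real records): their only purpose is to realise, exactly, the
# pooled totals of the published utilisation-period analyses and the
# selection flow so the full pipeline can be exercised end to end.

#' Synthetic cohort realising the published utilisation-period totals
#'
#' Constructs 144 users, each with a 365-day utilisation episode, and places
#' hospital stays fully inside their pre/post mirror windows so that the
#' pooled totals are exact: 68 pre-index and 28 post-index admissions; 2113
#' pre-index and 802 post-index hospitalised person-days. Exactly 24 users
#' have an admission within 90 days before their index, and the remaining
#' 120 users aggregate to 26/21 admissions and 1089/622 person-days — so the
#' same cohort also realises the published sensitivity-analysis
#' utilisation-period row.
#'
#' @return a list with `utilisations` and `admissions` character data frames
#'   in the CSV schemas of [read_utilisations()] / [read_admissions()].
#' @export
fixture_reference_cohort <- function() {
  n <- 144L
  start <- as.Date("2017-06-01")
  iso <- function(x) format(x, "%Y-%m-%d")
  utilisations <- data.frame(
    record_id = sprintf("U%03d", seq_len(n)),
    user_id = sprintf("P%03d", seq_len(n)),
    start_date = iso(rep(start, n)),
    end_date = iso(rep(start + 365L, n)),
    end_reason = "withdrawal",
    stringsAsFactors = FALSE
  )

  stays <- list()
  add <- function(users, offset, lens) {
    stays[[length(stays) + 1L]] <<- data.frame(
      user = users, admit = offset, len = lens, stringsAsFactors = FALSE)
  }
  # retained users (no admission within 90 days pre-index)
  add(1:26, -200L, distribute_integer(1089L, 26L))   # pre stays, 26 admissions
  add(1:21, 150L, distribute_integer(622L, 21L))     # post stays, 21 admissions
  # the 24 users excluded by the 90-day lookback
  add(121:144, -50L, rep(25L, 24L))                  # lookback admissions, 600 days
  add(121:138, -300L, distribute_integer(424L, 18L)) # earlier pre admissions
  add(121:127, 60L, distribute_integer(180L, 7L))    # their post admissions
  st <- do.call(rbind, stays)
  admit <- start + st$admit
  admissions <- data.frame(
    record_id = sprintf("A%03d", seq_len(nrow(st))),
    user_id = sprintf("P%03d", st$user),
    admit_date = iso(admit),
    discharge_date = iso(admit + st$len),
    stringsAsFactors = FALSE
  )
  list(utilisations = utilisations, admissions = admissions)
}

#' Synthetic utilisation table realising the published selection flow
#'
#' Builds 156 in-window utilisation episodes plus 6 pre-window episodes such
#' that the selection flow excludes 1 repeat use, 6 prior uses and 5
#' episodes shorter than 30 days, leaving 144 included users.
#'
#' @return a character data frame in the [read_utilisations()] CSV schema.
#' @export
fixture_selection_flow <- function() {
  iso <- function(x) format(x, "%Y-%m-%d")
  base <- as.Date("2017-01-01")
  rows <- list()
  add <- function(record_id, user_id, start, dur) {
    rows[[length(rows) + 1L]] <<- data.frame(
      record_id = record_id, user_id = user_id,
      start_date = iso(start), end_date = iso(start + dur),
      end_reason = "withdrawal", stringsAsFactors = FALSE)
  }
  for (i in 1:144) add(sprintf("I%03d", i), sprintf("P%03d", i),
                       base + (i * 3L) %% 400L, 60L)
  # one user's second in-window episode (repeat use)
  add("R901", "P001", as.Date("2018-06-01"), 60L)
  # six users with an episode before the window plus one inside it
  for (i in 1:6) {
    add(sprintf("Q%03da", i), sprintf("Q%03d", i), as.Date("2016-01-01"), 60L)
    add(sprintf("Q%03db", i), sprintf("Q%03d", i), as.Date("2017-05-01") + i, 60L)
  }
  # five episodes shorter than 30 days, started in January 2019
  for (i in 1:5) add(sprintf("S%03d", i), sprintf("S%03d", i),
                     as.Date("2019-01-05") + i, 29L)
  do.call(rbind, rows)
}

#' Write a named fixture as CSV files
#'
#' @param name `"reference"` (utilisations + admissions) or `"selection_flow"`
#'   (utilisations only).
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_fixture <- function(name = c("reference", "selection_flow"), dir = ".") {
  name <- match.arg(name)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(df, file) {
    path <- file.path(dir, file)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    paths <<- c(paths, path)
  }
  if (name == "reference") {
    fx <- fixture_reference_cohort()
    emit(fx$utilisations, "reference_utilisations.csv")
    emit(fx$admissions, "reference_admissions.csv")
  } else {
    emit(fixture_selection_flow(), "selection_flow_utilisations.csv")
  }
  invisible(paths)
}
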