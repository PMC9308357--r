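cfg <- study_config()

test_that("reading closes ongoing episodes at the censor date", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c(
    "record_id,user_id,start_date,end_date",
    "u1,p1,2017-01-01,2017-06-01",
    "u2,p2,2018-10-01,",
    "u3,p3,2017-03-01,2017-04-15"), csv)
  u <- read_utilisations(csv, cfg)
  expect_equal(nrow(u), 3)
  expect_equal(u$end_reason, c("withdrawal", "administrative_censor", "withdrawal"))
  expect_equal(u$end_date[2], as.Date("2019-02-28"))
  expect_equal(u$duration_days, as.integer(u$end_date - u$start_date))
})

test_that("an empty file with a valid header yields an empty table", {
  csv <- tempfile(fileext = ".csv")
  writeLines("record_id,user_id,start_date,end_date", csv)
  u <- read_utilisations(csv, cfg)
  expect_s3_class(u, "ish_utilisations")
  expect_equal(nrow(u), 0)
})

test_that("validation errors name the offending record or column", {
  expect_error(
    read_utilisations(make_util("bad1", "p1", "2017-05-01", "2017-04-01"), cfg),
    "bad1")
  expect_error(
    read_utilisations(make_util("u1", "p1", "2017/05/01", "2017-06-01"), cfg),
    "start_date")
  expect_error(
    read_utilisations(data.frame(record_id = "u1", user_id = "p1",
                                 start_date = "2017-05-01"), cfg),
    "end_date")
  expect_error(
    read_admissions(make_adm("p1", "2018-01-10", "2018-01-05")),
    "a001")
})

test_that("a censor-marked episode must end on the censor date", {
  expect_error(
    read_utilisations(make_util("u1", "p1", "2017-01-01", "2017-06-01",
                                end_reason = "administrative_censor"), cfg),
    "censor")
})

test_that("only the first in-window episode per user is kept", {
  u <- read_utilisations(rbind(
    make_util("b", "p1", "2018-01-01", "2018-03-01"),
    make_util("a", "p1", "2017-01-01", "2017-03-01")), cfg)
  sel <- select_cohort(u, cfg)
  expect_equal(sel$cohort$record_id, "a")
  expect_equal(sel$report$n_excluded_repeat_use, 1)
})

test_that("duration below the minimum is excluded, at the minimum included", {
  u <- read_utilisations(rbind(
    make_util("s29", "p1", "2018-01-01", "2018-01-30"),
    make_util("s30", "p2", "2018-01-01", "2018-01-31")), cfg)
  sel <- select_cohort(u, cfg)
  expect_equal(sel$cohort$record_id, "s30")
  expect_equal(sel$report$n_excluded_short, 1)
})

test_that("prior service use removes the user entirely", {
  u <- read_utilisations(rbind(
    make_util("old", "p1", "2016-01-01", "2016-03-01"),
    make_util("new", "p1", "2017-01-01", "2017-06-01"),
    make_util("ok", "p2", "2017-01-01", "2017-06-01")), cfg)
  sel <- select_cohort(u, cfg)
  expect_equal(sel$cohort$user_id, "p2")
  expect_equal(sel$report$n_excluded_prior_use, 1)
  expect_equal(sel$report$n_extracted, 2)  # the pre-window record is not extracted
})

test_that("tied start dates keep the smallest record id with a warning", {
  u <- read_utilisations(rbind(
    make_util("z9", "p1", "2017-01-01", "2017-06-01"),
    make_util("a1", "p1", "2017-01-01", "2017-05-01")), cfg)
  expect_warning(sel <- select_cohort(u, cfg), "tie")
  expect_equal(sel$cohort$record_id, "a1")
})

test_that("the engineered 156-period selection flow yields 144 included", {
  u <- read_utilisations(fixture_selection_flow(), cfg)
  sel <- select_cohort(u, cfg)
  expect_equal(sel$report$n_extracted, 156)
  expect_equal(sel$report$n_excluded_repeat_use, 1)
  expect_equal(sel$report$n_excluded_prior_use, 6)
  expect_equal(sel$report$n_excluded_short, 5)
  expect_equal(sel$report$n_included, 144)
  expect_equal(length(unique(sel$cohort$user_id)), 144)
})

test_that("selection is idempotent, order-invariant and conserving", {
  u <- read_utilisations(fixture_selection_flow(), cfg)
  sel1 <- select_cohort(u, cfg)
  # idempotent
  sel2 <- select_cohort(sel1$cohort, cfg)
  expect_equal(sel2$cohort$record_id, sel1$cohort$record_id)
  expect_equal(sel2$report$n_included, sel1$report$n_included)
  expect_equal(sel2$report$n_excluded_repeat_use +
                 sel2$report$n_excluded_prior_use +
                 sel2$report$n_excluded_short, 0)
  # order-invariant
  set.seed(42)
  perm <- u[sample.int(nrow(u)), , drop = FALSE]
  class(perm) <- class(u)
  sel3 <- select_cohort(perm, cfg)
  expect_setequal(sel3$cohort$record_id, sel1$cohort$record_id)
  expect_equal(sel3$report$n_extracted, sel1$report$n_extracted)
  expect_equal(sel3$report$n_excluded_repeat_use, sel1$report$n_excluded_repeat_use)
  # conserving: every record is included or mapped to a reason, exactly once
  accounted <- c(sel1$cohort$record_id, sel1$report$exclusions$record_id)
  expect_setequal(accounted, u$record_id)
  expect_equal(anyDuplicated(accounted), 0)
})

test_that("cohort summary computes the documented descriptives", {
  u <- read_utilisations(make_util(c("u1", "u2"), c("p1", "p2"),
                                   c("2017-01-01", "2017-02-01"),
                                   c("2017-04-01", "2017-05-01"),
                                   age_years = c("30", "50"),
                                   sex = c("female", "male")), cfg)
  s <- summarize_cohort(u)
  expect_equal(s$age$mean, 40.0)
  expect_equal(s$age$sd, round(sd(c(30, 50)), 1))
  expect_equal(s$sex$n, c(1, 1))
  expect_equal(s$person_days, sum(u$duration_days))
  expect_equal(s$person_years, round(s$person_days / 365.25, 1))
})

test_that("summary percentages sum to 100 per categorical field", {
  sim <- simulate_cohort(simulation_params(n_users = 144, seed = 5))
  u <- read_utilisations(sim$utilisations, cfg)
  s <- summarize_cohort(select_cohort(u, cfg)$cohort)
  for (tab in list(s$sex, s$diagnosis, s$nationality_swiss, s$civil_status)) {
    if (!is.null(tab)) expect_equal(sum(tab$pct), 100, tolerance = 0.2)
  }
})
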