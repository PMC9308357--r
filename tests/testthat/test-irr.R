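cfg <- study_config()

round2 <- function(x) round(x, 2)

test_that("rate ratio and CI reproduce the published pooled analyses", {
  # (post, pre, irr, lo, hi) for every published row with nonzero counts
  rows <- list(
    c(28, 68, 0.41, 0.27, 0.64),    # admissions, utilisation period
    c(9, 20, 0.45, 0.20, 0.99),     # admissions, 90 days
    c(10, 27, 0.37, 0.18, 0.77),    # admissions, 180 days
    c(12, 33, 0.36, 0.19, 0.70),    # admissions, 270 days
    c(9, 21, 0.43, 0.20, 0.94),     # admissions, 365 days
    c(802, 2113, 0.38, 0.35, 0.41), # person-days, utilisation period
    c(149, 787, 0.19, 0.16, 0.23),  # person-days, 90 days
    c(229, 908, 0.25, 0.22, 0.29),  # person-days, 180 days
    c(233, 939, 0.25, 0.21, 0.29),  # person-days, 270 days
    c(219, 512, 0.43, 0.37, 0.50),  # person-days, 365 days
    c(21, 26, 0.81, 0.45, 1.44),    # sensitivity admissions, utilisation period
    c(30, 225, 0.13, 0.09, 0.20),   # sensitivity person-days, 90 days
    c(177, 299, 0.59, 0.49, 0.71),  # sensitivity person-days, 180 days
    c(211, 230, 0.92, 0.76, 1.11))  # sensitivity person-days, 365 days
  for (r in rows) {
    res <- rate_ratio(r[1], r[2], 1000, 1000)
    expect_equal(round2(res$irr), r[3])
    expect_equal(round2(res$ci_low), r[4])
    expect_equal(round2(res$ci_high), r[5])
    expect_equal(res$significant, r[5] < 1 || r[4] > 1)
  }
})

test_that("equal counts give a ratio of exactly one", {
  for (k in c(1, 7, 500)) {
    r <- rate_ratio(k, k, 123, 123)
    expect_identical(r$irr, 1)
    expect_true(r$ci_low <= 1 && 1 <= r$ci_high)
    expect_false(r$significant)
  }
})

test_that("zero-count policy: undefined with zero pre, point zero with zero post", {
  r0 <- rate_ratio(3, 0, 10, 10)
  expect_true(is.na(r0$irr) && is.na(r0$ci_low) && is.na(r0$ci_high))
  expect_true(is.na(r0$significant))
  rp <- rate_ratio(0, 5, 10, 10)
  expect_identical(rp$irr, 0)
  expect_true(is.na(rp$ci_low) && is.na(rp$ci_high))
})

test_that("invalid inputs are rejected", {
  expect_error(rate_ratio(3, 5, 0, 10), "person-time")
  expect_error(rate_ratio(3, 5, 10, -1), "person-time")
  expect_error(rate_ratio(-1, 5, 10, 10), "non-negative")
  expect_error(rate_ratio(3, 5, 10, 10, alpha = 1.2), "alpha")
})

test_that("the ratio is scale-invariant in equal person-time", {
  for (T in c(1, 90, 44690)) {
    expect_equal(rate_ratio(28, 68, T, T)$irr, 28 / 68)
    expect_equal(rate_ratio(28, 68, T, T)$ci_low, rate_ratio(28, 68, 1, 1)$ci_low)
  }
  # and respects unequal person-time
  expect_equal(rate_ratio(10, 10, 100, 200)$irr, 2)
})

test_that("swapping pre and post inverts the ratio and its interval", {
  r <- rate_ratio(28, 68, 50, 50)
  s <- rate_ratio(68, 28, 50, 50)
  expect_equal(s$irr, 1 / r$irr)
  expect_equal(s$ci_low, 1 / r$ci_high)
  expect_equal(s$ci_high, 1 / r$ci_low)
})

test_that("scaling both counts up narrows the interval at fixed ratio", {
  r1 <- rate_ratio(28, 68, 1, 1)
  r4 <- rate_ratio(112, 272, 1, 1)
  expect_equal(r4$irr, r1$irr)
  expect_lt(r4$ci_high / r4$ci_low, r1$ci_high / r1$ci_low)
})

test_that("the exact conditional interval brackets the point estimate", {
  r <- rate_ratio(28, 68, 50, 50, method = "exact")
  expect_lt(r$ci_low, r$irr)
  expect_gt(r$ci_high, r$irr)
  expect_true(r$significant)
})

test_that("person-day totals convert to person-years at 365.25 days", {
  expect_equal(person_days_to_years(44690), 122.4)
  expect_equal(person_days_to_years(0), 0)
  expect_equal(person_days_to_years(365), 1)
  expect_error(person_days_to_years(-1))
})

test_that("pooled period counts equal explicit per-user summation", {
  sim <- simulate_cohort(simulation_params(n_users = 80, seed = 13))
  cohort <- select_cohort(read_utilisations(sim$utilisations, cfg), cfg)$cohort
  a <- read_admissions(sim$admissions)
  for (period in list("utilisation", 90L, 270L)) {
    w <- mirror_windows(cohort, period)
    pre_n <- post_n <- pre_d <- post_d <- 0
    for (i in seq_len(nrow(w))) {
      ai <- a[a$user_id == w$user_id[i], , drop = FALSE]
      pre_n <- pre_n + count_admissions(ai, w$pre_start[i], w$index_date[i])
      post_n <- post_n + count_admissions(ai, w$index_date[i], w$post_end[i])
      pre_d <- pre_d + count_person_days(ai, w$pre_start[i], w$index_date[i],
                                         cfg$censor_date)
      post_d <- post_d + count_person_days(ai, w$index_date[i], w$post_end[i],
                                           cfg$censor_date)
    }
    res <- analyze_period(cohort, a, period, cfg$censor_date)
    adm <- res[res$outcome == "admissions", ]
    pd <- res[res$outcome == "person_days", ]
    expect_equal(c(adm$pre_count, adm$post_count), c(pre_n, post_n))
    expect_equal(c(pd$pre_count, pd$post_count), c(pre_d, post_d))
    expect_equal(adm$n_users, nrow(w))
    if (pre_n > 0) expect_equal(adm$irr, post_n / pre_n)
  }
})

test_that("identical pre and post histories give a unit ratio through pooling", {
  u <- read_utilisations(make_util(c("u1", "u2"), c("p1", "p2"),
                                   c("2017-06-01", "2017-08-01"),
                                   c("2018-06-01", "2018-08-01")), cfg)
  a <- read_admissions(make_adm(
    c("p1", "p1", "p2", "p2"),
    c("2017-04-01", "2017-08-01", "2017-06-01", "2017-10-01"),
    c("2017-04-11", "2017-08-11", "2017-06-11", "2017-10-11")))
  res <- analyze_period(u, a, "utilisation", cfg$censor_date)
  expect_equal(res$irr[res$outcome == "admissions"], 1)
})

test_that("empty eligible sets yield undefined statistics, not errors", {
  u <- read_utilisations(make_util("u1", "p1", "2017-06-01", "2017-08-01"), cfg)
  res <- analyze_period(u, read_admissions(make_adm(character(0), character(0))),
                        365L, cfg$censor_date)
  expect_equal(res$n_users, c(0L, 0L))
  expect_true(all(is.na(res$irr)))
})

test_that("interval proportions handle degenerate cohorts", {
  u <- read_utilisations(make_util("u1", "p1", "2017-06-01", "2018-06-01"), cfg)
  none <- quarterly_admission_proportions(
    u, read_admissions(make_adm(character(0), character(0))))
  expect_true(all(none$proportion == 0))
  one <- quarterly_admission_proportions(
    u, read_admissions(make_adm("p1", "2017-05-02", "2017-05-10")))
  first_pre <- one[one$side == "pre" & one$interval_index == 1, ]
  expect_equal(first_pre$proportion, 1)
  expect_true(all(one$proportion[!(one$side == "pre" & one$interval_index == 1)] == 0))
})

test_that("interval proportions match a direct per-interval recount", {
  sim <- simulate_cohort(simulation_params(n_users = 60, seed = 21))
  cohort <- select_cohort(read_utilisations(sim$utilisations, cfg), cfg)$cohort
  a <- read_admissions(sim$admissions)
  for (num in c("admissions", "users")) {
    props <- quarterly_admission_proportions(cohort, a, numerator = num)
    for (r in seq_len(nrow(props))) {
      k <- props$interval_index[r]
      eligible <- cohort[cohort$duration_days >= k * 90, , drop = FALSE]
      hits <- character(0); n_events <- 0
      for (i in seq_len(nrow(eligible))) {
        idx <- eligible$start_date[i]
        lo <- if (props$side[r] == "pre") idx - k * 90 else idx + (k - 1) * 90
        ai <- a[a$user_id == eligible$user_id[i], , drop = FALSE]
        cnt <- sum(ai$admit_date >= lo & ai$admit_date < lo + 90)
        n_events <- n_events + cnt
        if (cnt > 0) hits <- c(hits, eligible$user_id[i])
      }
      expected <- if (num == "admissions") n_events else length(hits)
      expect_equal(props$n_events[r], expected)
      expect_equal(props$n_users_observed[r], nrow(eligible))
      expect_equal(props$proportion[r], expected / nrow(eligible))
    }
  }
})
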