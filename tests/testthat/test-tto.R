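# Time-to-onset: onset-day construction, summaries, Weibull fit and
# failure-type classification.

make_tto_case <- function(id, start, onset, window_extra_reac = NULL) {
  build_cases(demo_row(id),
              drug_row(id, dose = 300, start_date = start),
              reac_row(id, "Seizure", onset))
}

test_that("onset days follow the +1 convention and the exclusion rules", {
  q <- demo_query()
  same_day <- make_tto_case("A", "2020-01-01", "2020-01-01")
  smp <- onset_days(same_day, flag_cases(same_day, q))
  expect_equal(smp$days, 1)

  beyond <- make_tto_case("B", "2020-01-01", "2023-06-01")
  smp <- onset_days(beyond, flag_cases(beyond, q))
  expect_equal(length(smp$days), 0L)
  expect_equal(smp$n_excluded_beyond_window, 1L)

  partial <- make_tto_case("C", "2020-01-01", "2020-03")
  smp <- onset_days(partial, flag_cases(partial, q))
  expect_equal(smp$n_excluded_missing_dates, 1L)

  # onset before drug start is a data error, counted with missing dates
  reversed <- make_tto_case("D", "2020-06-01", "2020-01-01")
  smp <- onset_days(reversed, flag_cases(reversed, q))
  expect_equal(smp$n_excluded_missing_dates, 1L)

  # day 1095 is inside the window, 1096 is out
  edge_in <- make_tto_case("E", "2020-01-01", as.character(as.Date("2020-01-01") + 1094))
  expect_equal(onset_days(edge_in, flag_cases(edge_in, q))$days, 1095)
  edge_out <- make_tto_case("F", "2020-01-01", as.character(as.Date("2020-01-01") + 1095))
  expect_equal(onset_days(edge_out, flag_cases(edge_out, q))$n_excluded_beyond_window, 1L)
})

test_that("the halfday convention scores same-day onset as half a day", {
  q <- demo_query()
  same_day <- make_tto_case("A", "2020-01-01", "2020-01-01")
  smp <- onset_days(same_day, flag_cases(same_day, q), convention = "halfday")
  expect_equal(smp$days, 0.5)
})

test_that("onset clock starts at the earliest complete study-drug start date", {
  q <- demo_query()
  cases <- build_cases(demo_row("A"),
                       rbind(drug_row("A", dose = 100, start_date = "2020-02-01"),
                             drug_row("A", dose = 300, start_date = "2020-01-01")),
                       reac_row("A", "Seizure", "2020-01-10"))
  smp <- onset_days(cases, flag_cases(cases, q))
  expect_equal(smp$days, 10)
})

test_that("median and quartiles use inclusive linear interpolation", {
  s <- onset_sample(c(1, 2, 3, 4, 5))
  sm <- onset_summary(s)
  expect_equal(sm$median, 3)
  expect_equal(sm$q1, 2)
  expect_equal(sm$q3, 4)
})

test_that("median of a simulated exponential onset law matches the closed form", {
  set.seed(20230612)
  days <- stats::rweibull(10000, shape = 1, scale = 200)
  s <- onset_sample(pmin(days[days > 0], 1095), window_days = 1095)
  sm <- onset_summary(s)
  expect_equal(sm$median, 200 * log(2), tolerance = 0.04)
})

test_that("the Weibull MLE matches a brute-force grid oracle on tiny samples", {
  f <- fit_weibull(c(1, 2, 3))
  g <- grid_weibull(c(1, 2, 3))
  expect_equal(f$alpha, unname(g["alpha"]), tolerance = 1e-4)
  expect_equal(f$beta, unname(g["beta"]), tolerance = 1e-4)
})

test_that("an exponential sample is recovered as shape 1", {
  set.seed(20230612)
  t <- stats::rweibull(10000, shape = 1, scale = 100)
  f <- fit_weibull(t)
  expect_gt(f$beta, 0.97)
  expect_lt(f$beta, 1.03)
  expect_equal(f$alpha, 100, tolerance = 0.05)
})

test_that("time rescaling scales alpha and leaves beta invariant", {
  set.seed(7)
  t <- stats::rweibull(200, shape = 1.4, scale = 50)
  f1 <- fit_weibull(t)
  f2 <- fit_weibull(t * 10)
  expect_equal(f2$alpha / f1$alpha, 10, tolerance = 1e-6)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-8)
})

test_that("degenerate and undersized samples are rejected", {
  expect_error(fit_weibull(c(1, 2)), "at least 3")
  expect_error(fit_weibull(c(5, 5, 5)), "degenerate")
  expect_error(fit_weibull(c(-1, 2, 3)), "positive")
})

test_that("the MLE agrees with an independent fitting library", {
  skip_if_not_installed("fitdistrplus")
  set.seed(33)
  t <- stats::rweibull(500, shape = 1.2, scale = 180)
  f <- fit_weibull(t)
  ref <- fitdistrplus::fitdist(t, "weibull")
  # the reference optimizer converges less tightly than ours
  expect_equal(f$beta, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(f$alpha, unname(ref$estimate["scale"]), tolerance = 1e-3)
})

test_that("failure classification follows the shape-CI trichotomy, boundaries inclusive", {
  expect_equal(classify_failure(0.9, 1.1), "random")
  expect_equal(classify_failure(1.05, 1.4), "wearout")
  expect_equal(classify_failure(0.6, 0.95), "early")
  expect_equal(classify_failure(1.0, 1.2), "random")   # boundary: includes 1
  expect_equal(classify_failure(0.8, 1.0), "random")
  set.seed(20230612)
  for (i in 1:200) {
    lo <- stats::runif(1, 0.01, 3)
    hi <- lo + stats::runif(1, 0, 2)
    lab <- classify_failure(lo, hi)
    expect_true(lab %in% c("early", "random", "wearout"))
    expect_equal(sum(c(lo > 1, hi < 1, lo <= 1 && hi >= 1)), 1L)
  }
  expect_error(classify_failure(1.2, 0.9))
  expect_error(classify_failure(-1, 2))
})

test_that("histogram bins are half-open, cover the window, and conserve counts", {
  s <- onset_sample(c(10, 20, 40), window_days = 60)
  h <- onset_histogram(s, 30)
  expect_equal(h$count, c(2, 1))
  s2 <- onset_sample(c(5, 10), window_days = 1095)
  h2 <- onset_histogram(s2, 30)
  expect_equal(nrow(h2), ceiling(1095 / 30))
  expect_equal(sum(h2$count), 2)
  # boundary day lands in the upper bin: [30, 60)
  h3 <- onset_histogram(onset_sample(c(30), window_days = 60), 30)
  expect_equal(h3$count, c(0, 1))
  set.seed(1)
  for (i in 1:10) {
    days <- sample(1:1095, sample(1:50, 1), replace = TRUE)
    h <- onset_histogram(onset_sample(days), sample(c(7, 30, 90), 1))
    expect_equal(sum(h$count), length(days))
  }
})
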