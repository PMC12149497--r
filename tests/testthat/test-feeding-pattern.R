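test_that("worked-example intake proportions come out at 3 decimals", {
  # first three visits 0.4, 0.2, 5.3 kg on a 43.8 kg day
  intakes <- c(0.4, 0.2, 5.3, 43.8 - 0.4 - 0.2 - 5.3)
  cc <- cumulativeCurve(c(600, 1200, 1800, 40000), intakes)
  props <- diff(cc$cumprop)[1:3]
  expect_equal(round(props, 3), c(0.009, 0.005, 0.121))
  expect_equal(cc$total_intake_kg, 43.8)
})

test_that("trapezoid AUC reproduces hand-computed and limiting cases", {
  # equal uniform visits give half a day in seconds, for several n
  for (n in c(1L, 4L, 24L, 31L)) {
    cc <- cumulativeCurve(seq_len(n) * 86400 / n, rep(1, n))
    expect_equal(cc$auc, 43200, info = paste("n =", n))
  }
  # hand trapezoid: 5400 + 16200 + 43200
  expect_equal(trapezoidAUC(c(0, 21600, 43200, 86400), c(0, 0.5, 1, 1)),
               64800)
  # all intake at Time 0
  expect_equal(cumulativeCurve(0, 5)$auc, 86400)
  expect_error(trapezoidAUC(c(0, 100, 50), c(0, 0.5, 1)), "non-decreasing")
})

test_that("cumulative curves are anchored, monotone and normalized", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    cc <- cumulativeCurve(sort(runif(n, 1, 86399)), runif(n, 0.1, 3))
    expect_equal(cc$cumprop[1], 0)
    expect_equal(cc$cumprop[length(cc$cumprop)], 1)
    expect_true(all(diff(cc$offsets) >= 0))
    expect_true(all(diff(cc$cumprop) >= -1e-12))
    expect_true(cc$auc >= 0 && cc$auc <= 86400)
  }
  expect_error(cumulativeCurve(c(10, 20), c(0, 0)), "positive")
})

test_that("trapezoid AUC agrees with a fine-grid integration oracle", {
  # oracle: 1-s grid linear interpolation, summed directly
  gridAUC <- function(off, cum) {
    f <- approx(off, cum, xout = seq(0, 86400, by = 1), ties = "ordered")$y
    (sum(f) - (f[1] + f[length(f)]) / 2)
  }
  set.seed(99)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    cc <- cumulativeCurve(sort(runif(n, 1, 86399)), runif(n, 0.05, 4))
    expect_equal(cc$auc, gridAUC(cc$offsets, cc$cumprop),
                 tolerance = 1e-6)
  }
})

test_that("shifting intake mass earlier strictly increases the AUC", {
  base <- cumulativeCurve(c(10000, 30000, 60000), c(1, 1, 1))$auc
  earlier <- cumulativeCurve(c(5000, 30000, 60000), c(1, 1, 1))$auc
  heavier_early <- cumulativeCurve(c(10000, 30000, 60000), c(2, 1, 1))$auc
  expect_gt(earlier, base)
  expect_gt(heavier_early, base)
})

test_that("Time 0 windows anchor at the first visit after delivery", {
  rows <- c(
    "c1,F1,2023-03-01,11:20:00,11:30:00,10,9",   # first visit at delivery
    "c2,F1,2023-03-01,13:00:00,13:10:00,10,8",
    "c1,F1,2023-03-02,11:19:00,11:24:00,10,9",   # before day-2 time0
    "c2,F1,2023-03-02,11:21:00,11:31:00,10,7.5",
    "c1,F1,2023-03-02,15:00:00,15:20:00,10,6")
  v <- readVisits(writeVisitFixture(rows))
  sched <- data.frame(date = as.Date(c("2023-03-01", "2023-03-02")),
                      delivery1 = c("11:20", "11:20"))
  aw <- assignDayWindows(v, sched)
  expect_equal(nrow(aw$windows), 2L)
  expect_equal(format(aw$windows$time0[1], "%H:%M:%S"), "11:20:00")
  expect_equal(format(aw$windows$time0[2], "%H:%M:%S"), "11:21:00")
  # the 11:19 visit on day 2 belongs to day 1's window
  d2pre <- aw$visits[format(aw$visits$entry_dt, "%H:%M") == "11:19", ]
  expect_equal(d2pre$day_index, 1L)
  # single-window data: everything in it
  one <- assignDayWindows(v[v$date == as.Date("2023-03-01"), ], sched[1, ])
  expect_true(all(one$visits$day_index == 1L))
})

test_that("Time 0 can be inferred from the pen-wide lockout gap", {
  # visits cluster after 11:20; a stray early visit at 10:05 precedes the gap
  rows <- c(
    "c1,F1,2023-03-01,10:05:00,10:10:00,10,9.5",
    "c1,F1,2023-03-01,11:20:00,11:30:00,10,9",
    "c2,F1,2023-03-01,11:25:00,11:40:00,10,8",
    "c2,F1,2023-03-01,14:00:00,14:10:00,10,9")
  v <- readVisits(writeVisitFixture(rows))
  aw <- assignDayWindows(v)   # no schedule: infer
  expect_equal(format(aw$windows$time0[1], "%H:%M:%S"), "11:20:00")
})

test_that("day-level filters use the documented boundaries", {
  days <- data.frame(
    cow_id = paste0("c", 1:6), pen_id = "p", day_index = 1L,
    n_visits = c(4L, 5L, 10L, 10L, 10L, 10L),
    total_intake_kg = c(30, 30, 12.0, 12.1, 115.0, 115.1),
    auc = 50000)
  res <- filterDays(days)
  expect_equal(res$days$cow_id, c("c2", "c4", "c5"))
  expect_equal(res$report$removed_few_visits, 1L)
  expect_equal(res$report$removed_intake_low, 1L)
  expect_equal(res$report$removed_intake_high, 1L)
})

test_that("the 3.5 SD outlier rule is a single two-sided pass", {
  # base days with spread, plus one candidate day at a controlled z-score
  mkDays <- function(extreme) {
    set.seed(5)
    a <- c(rnorm(60, 56000, 800), extreme)
    data.frame(cow_id = "c", pen_id = "p", day_index = seq_along(a),
               n_visits = 10L, total_intake_kg = 40, auc = a)
  }
  zOf <- function(d) abs(d$auc[61] - mean(d$auc)) / sd(d$auc)

  d_out <- mkDays(56000 + 4500)   # well beyond 3.5 SD of the pooled stats
  expect_gt(zOf(d_out), 3.5)
  res <- removeOutlierDays(d_out)
  expect_equal(res$report$removed_outlier, 1L)
  expect_false(61 %in% res$days$day_index)

  d_in <- mkDays(56000 + 2600)    # inside 3.5 SD
  expect_lt(zOf(d_in), 3.5)
  expect_equal(removeOutlierDays(d_in)$report$removed_outlier, 0L)

  # identical days: SD 0, nothing removed
  d_same <- transform(d_in, auc = 56000)
  expect_equal(removeOutlierDays(d_same)$report$removed_outlier, 0L)
})

test_that("cow phenotypes are the mean and log-variance of daily AUC", {
  days <- data.frame(cow_id = "c1", pen_id = "p", day_index = 1:2,
                     n_visits = 10L, total_intake_kg = 40,
                     auc = c(55000, 57000))
  out <- summarizeCows(days, minDays = 2)
  expect_equal(out$auc_mean, 56000)
  expect_equal(out$var_dauc, 2e6)
  expect_equal(out$log_var_dauc, log(2e6), tolerance = 1e-10)
  expect_equal(round(out$log_var_dauc, 4), 14.5087)

  # identical days: flagged, log undefined
  same <- transform(days, auc = 56000)
  expect_warning(out2 <- summarizeCows(same, minDays = 2), "zero")
  expect_true(is.na(out2$log_var_dauc))

  # below min days: excluded
  out3 <- suppressWarnings(summarizeCows(days, minDays = 3))
  expect_equal(nrow(out3), 0L)
  expect_equal(attr(out3, "report")$cows_excluded_min_days, 1L)
})
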