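# Round-trip a simulated visit log through the full feeding-pattern
# pipeline and return the per-cow-day AUC table.
pipelineAUCs <- function(log, anchor = "first_visit") {
  path <- tempfile(fileext = ".csv")
  writeVisits(log, path)
  v <- readVisits(path)
  fv <- filterVisits(v)
  # rollover visits create a trailing calendar date whose own delivery
  # window is empty; the skipped-window warning is expected
  aw <- suppressWarnings(assignDayWindows(fv$visits,
    schedule = data.frame(date = unique(v$date), delivery1 = "11:00"),
    anchor = anchor))
  list(days = dailyCurves(aw), filtered = fv)
}

test_that("simulated visit events recover their target AUC end to end", {
  targets <- visitTargets(c(48000, 52000, 56345, 60000, 66000))
  log <- simulateVisitEvents(targets, seed = 21)
  res <- pipelineAUCs(log)
  days <- res$days[order(res$days$cow_id), ]
  expect_equal(nrow(days), 5L)
  expect_true(all(abs(days$auc - targets$target_auc[
    order(targets$cow_id)]) <= 600))
})

test_that("every emitted visit and day survives the cleaning filters", {
  targets <- visitTargets(seq(49000, 64000, length.out = 8))
  log <- simulateVisitEvents(targets, seed = 22)
  res <- pipelineAUCs(log)
  expect_equal(res$filtered$report$read, res$filtered$report$retained)
  fd <- filterDays(res$days)
  expect_equal(fd$report$read, fd$report$retained)
})

test_that("fault injection produces visits that the filters remove", {
  targets <- visitTargets(c(54000, 56000))
  cfg <- feedingSimConfig(faultRate = 0.2)
  log <- simulateVisitEvents(targets, cfg, seed = 23)
  res <- pipelineAUCs(log)
  expect_gt(res$filtered$report$read, res$filtered$report$retained)
})

test_that("the uniform scheme reproduces the half-day construction", {
  # the idealised uniform day: equal intakes, equally spaced, AUC 43,200
  cc <- cumulativeCurve(seq_len(24) * 86400 / 24, rep(43.8 / 24, 24))
  expect_equal(cc$auc, 43200)
  targets <- visitTargets(43200, n_visits = 24L)
  targets$scheme <- "uniform"
  log <- simulateVisitEvents(targets, seed = 24)
  expect_equal(nrow(log), 24L)
  expect_equal(unique(round(log$weight_in_kg - log$weight_out_kg, 3)),
               round(43.8 / 24, 3))
  # anchored at the scheduled delivery, the emitted stream reproduces
  # the construction (the last visit sits 1 s inside the day span)
  days <- pipelineAUCs(log, anchor = "delivery")$days
  expect_equal(days$auc, 43200, tolerance = 1e-4)
})

test_that("the event stream is deterministic under a fixed seed", {
  targets <- visitTargets(c(50000, 58000))
  expect_identical(simulateVisitEvents(targets, seed = 25),
                   simulateVisitEvents(targets, seed = 25))
})

test_that("unattainable targets raise a calibration failure", {
  expect_error(simulateVisitEvents(visitTargets(86000), seed = 26),
               "calibration failure")
  expect_error(simulateVisitEvents(visitTargets(-5), seed = 26))
  bad <- visitTargets(56000); bad$n_visits <- 3L
  expect_error(simulateVisitEvents(bad, seed = 26), "at least 5")
  bad2 <- visitTargets(56000); bad2$total_intake_kg <- 10
  expect_error(simulateVisitEvents(bad2, seed = 26), "intake")
})

test_that("efficiency records carry the configured structure", {
  des <- makeDesign(1200, nCohorts = 10, seed = 31)
  er <- simulateEfficiencyRecords(des, seed = 31)
  # DMI mean lands near the configured herd average
  expect_equal(mean(er$traits$dmi), 24.8, tolerance = 0.05 * 24.8)
  # no missingness: the BW series is complete and imputation a no-op
  er0 <- simulateEfficiencyRecords(des[1:5, ], bwMissingness = 0, seed = 32)
  b1 <- er0$bw[er0$bw$cow_id == "cow0001", ]
  filled <- imputeBW(b1$trial_day, b1$bw_kg)
  expect_false(any(filled$imputed))
  expect_equal(filled$bw_kg, b1$bw_kg)
  # zero true-RFI variance: fitted RFI variance collapses
  erz <- simulateEfficiencyRecords(des, sigmaRFI = 0, seed = 33)
  rf <- fitRFI(cbind(erz$traits,
                     milke = erz$truth$milke, mbw = erz$truth$mbw,
                     dbw = erz$truth$dbw))
  expect_lt(var(rf$rfi), 0.01 * var(erz$traits$dmi))
})
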