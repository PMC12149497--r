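#' Configuration for the feeder-event simulator
#'
#' Defaults emulate a research free-stall pen: fresh feed twice a day at
#' 11:00 and 17:00 with a 30-minute lockout before each delivery, about
#' 31 visits per cow-day and about 43.8 kg as-fed daily intake.
#'
#' The within-day visit-time model is an exponential consumption
#' intensity anchored at each delivery: at offset `t` from first
#' delivery the intensity is `exp(-theta * a(t))` where `a(t)` is the
#' time since the most recent delivery, zero inside lockouts. Positive
#' `theta` concentrates intake just after deliveries (early eater, high
#' AUC); negative `theta` defers it (low AUC); `theta = 0` is uniform.
#' `theta` is the monotone earliness link inverted by bisection so the
#' pipeline-computed AUC of the emitted visits matches a target.
#'
#' @param deliveryTimes clock times of daily feed deliveries, strictly
#'   increasing within the day.
#' @param lockoutMinutes lockout before each delivery.
#' @param visitsPerDayMean mean visits per cow-day (Poisson, floored at
#'   5).
#' @param dailyIntakeMeanKg,dailyIntakeSdKg as-fed daily total intake
#'   distribution (normal, truncated to (12, 115]).
#' @param feedRateKgS eating rate used for visit durations.
#' @param thetaRange search range of the earliness link, 1/s.
#' @param tolS calibration tolerance on the achieved AUC, seconds.
#' @param faultRate opt-in fault injection: fraction of extra visits
#'   violating the visit filters (default 0, off).
#' @return named list of settings.
#' @export
feedingSimConfig <- function(deliveryTimes = c("11:00", "17:00"),
                             lockoutMinutes = 30,
                             visitsPerDayMean = 31,
                             dailyIntakeMeanKg = 43.8,
                             dailyIntakeSdKg = 6,
                             feedRateKgS = 0.003,
                             thetaRange = c(-8e-4, 8e-4),
                             tolS = 200,
                             faultRate = 0) {
  dt <- parseClock(deliveryTimes)
  stopIfNot(all(diff(dt) > 0), "delivery times must be strictly ordered")
  list(deliveryTimes = deliveryTimes, deliverySec = dt,
       lockoutMinutes = lockoutMinutes,
       visitsPerDayMean = visitsPerDayMean,
       dailyIntakeMeanKg = dailyIntakeMeanKg,
       dailyIntakeSdKg = dailyIntakeSdKg,
       feedRateKgS = feedRateKgS,
       thetaRange = thetaRange, tolS = tolS, faultRate = faultRate)
}

# Offsets (s since first delivery) of later deliveries and of lockout
# intervals within the feeding day.
dayLayout <- function(config) {
  d <- config$deliverySec - config$deliverySec[1L]
  lock <- config$lockoutMinutes * 60
  later <- d[-1L]
  list(deliveries = d,
       lock_lo = later - lock, lock_hi = later)
}

# Quantile function of the exponential-intensity visit-time density on a
# 1-s grid over (0, 86400), lockouts excluded.
visitTimeQuantiles <- function(theta, probs, config) {
  lay <- dayLayout(config)
  t <- seq(1, 86399, by = 2)          # 2-s grid is ample for +-200 s tol
  a <- t
  for (dd in lay$deliveries[-1L]) a[t >= dd] <- t[t >= dd] - dd
  w <- exp(pmin(-theta * a, 700))
  if (length(lay$lock_lo))
    for (j in seq_along(lay$lock_lo))
      w[t >= lay$lock_lo[j] & t < lay$lock_hi[j]] <- 0
  cw <- cumsum(w)
  cw <- cw / cw[length(cw)]
  t[findInterval(probs, cw) + 1L]
}

# Emit one calibrated cow-day. Returns data.frame of visits with exit
# offsets from first delivery, plus the realized AUC.
simulateCowDay <- function(targetAUC, totalIntake, nVisits, config) {
  stopIfNot(targetAUC > 0 && targetAUC < 86400,
            "target AUC must lie in (0, 86400)")
  stopIfNot(nVisits >= 5L, "need at least 5 visits per day")
  stopIfNot(totalIntake > 12 && totalIntake <= 115,
            "daily intake must lie in (12, 115] kg")

  # per-visit intake split: Dirichlet with one dominant post-delivery
  # meal (first visit after each delivery upweighted); floored and
  # capped so every visit passes the visit filters by construction
  repeat {
    alpha <- rep(1, nVisits)
    alpha[1L] <- 4
    if (nVisits > 6L) alpha[ceiling(nVisits / 2)] <- 4
    gam <- stats::rgamma(nVisits, shape = alpha)
    p <- gam / sum(gam)
    intakes <- pmax(p * totalIntake, 0.05)
    intakes <- intakes / sum(intakes) * totalIntake
    if (all(intakes > 0 & intakes <= 20)) break
  }

  probs <- (seq_len(nVisits) - 0.5) / nVisits
  dur <- pmin(pmax(round(intakes / config$feedRateKgS), 5), 3000)

  # full emission for a given theta: quantile times, then rounding and
  # disjointness repair; calibration runs on exactly these final times
  emit <- function(theta) {
    off <- visitTimeQuantiles(theta, probs, config)
    off[1L] <- max(off[1L], 30)   # first visit right after Time 0
    exit <- round(cummax(off + seq_len(nVisits)))
    entry <- exit - dur
    entry[1L] <- max(entry[1L], 0)
    for (i in seq_len(nVisits)[-1L]) {
      if (entry[i] <= exit[i - 1L]) entry[i] <- exit[i - 1L] + 1L
      if (exit[i] <= entry[i]) exit[i] <- entry[i] + max(5L, dur[i])
    }
    exit <- pmin(exit, 86399L)
    entry <- pmin(entry, exit - 5L)
    list(entry = entry, exit = exit,
         auc = cumulativeCurve(exit, intakes)$auc)
  }
  lo <- config$thetaRange[1L]; hi <- config$thetaRange[2L]
  e_lo <- emit(lo); e_hi <- emit(hi)
  a_lo <- e_lo$auc; a_hi <- e_hi$auc
  if (targetAUC < min(a_lo, a_hi) - config$tolS ||
      targetAUC > max(a_lo, a_hi) + config$tolS)
    stop("calibration failure: target AUC ", round(targetAUC),
         " outside attainable range [", round(min(a_lo, a_hi)), ", ",
         round(max(a_lo, a_hi)), "]", call. = FALSE)
  best <- if (abs(a_lo - targetAUC) < abs(a_hi - targetAUC)) e_lo else e_hi
  for (it in seq_len(60L)) {
    mid <- (lo + hi) / 2
    e_mid <- emit(mid)
    if (abs(e_mid$auc - targetAUC) < abs(best$auc - targetAUC)) best <- e_mid
    if (abs(e_mid$auc - targetAUC) < config$tolS) break
    if ((e_mid$auc < targetAUC) == (a_lo < targetAUC)) {
      lo <- mid; a_lo <- e_mid$auc
    } else {
      hi <- mid; a_hi <- e_mid$auc
    }
  }
  data.frame(offset_entry = best$entry, offset_exit = best$exit,
             intake_kg = intakes, auc = best$auc)
}

#' Simulate a visit-level feeder event log
#'
#' Emits a delimited-ready visit log for a set of cow-day targets. Every
#' cow-day is calibrated so that the feeding-pattern pipeline recovers
#' its target AUC within `config$tolS` seconds; a synthetic "pen anchor"
#' guarantee is built in — the first visit of every day starts at the
#' moment of first feed delivery, so Time 0 inferred downstream
#' coincides with the delivery. All emitted visits pass the visit-level
#' filters, and all emitted days pass the day-level filters, unless
#' fault injection is switched on.
#'
#' @param targets data.frame with one row per cow-day: `cow_id`, `date`
#'   (Date or ISO-8601), `target_auc` (s), `total_intake_kg`, `n_visits`.
#'   `scheme` may be set to "uniform" per row for the uniform
#'   construction (equal intakes, equally spaced over 24 h, AUC 43,200).
#' @param config from [feedingSimConfig()].
#' @param seed integer seed.
#' @return visit log data.frame with columns `cow_id`, `feeder_id`,
#'   `pen_id`, `date`, `entry_time`, `exit_time`, `weight_in_kg`,
#'   `weight_out_kg`, ready for [readVisits()] round-tripping via
#'   [writeVisits()].
#' @export
simulateVisitEvents <- function(targets, config = feedingSimConfig(),
                                seed = 1L) {
  set.seed(as.integer(seed))
  targets$date <- as.Date(targets$date)
  if (is.null(targets$scheme)) targets$scheme <- "exponential"
  deliv0 <- config$deliverySec[1L]
  out <- vector("list", nrow(targets))
  for (r in seq_len(nrow(targets))) {
    tg <- targets[r, ]
    if (identical(tg$scheme, "uniform")) {
      n <- tg$n_visits
      exit <- round(seq_len(n) * 86400 / n)
      exit[n] <- 86399L   # keep the last visit inside the calendar day span
      entry <- exit - 60L
      cd <- data.frame(offset_entry = entry, offset_exit = exit,
                       intake_kg = rep(tg$total_intake_kg / n, n))
    } else {
      cd <- simulateCowDay(tg$target_auc, tg$total_intake_kg,
                           tg$n_visits, config)
    }
    abs_entry <- as.POSIXct(tg$date, tz = "UTC") + deliv0 + cd$offset_entry
    abs_exit <- as.POSIXct(tg$date, tz = "UTC") + deliv0 + cd$offset_exit
    win <- round(stats::runif(nrow(cd), 5, 40) + cd$intake_kg, 3)
    out[[r]] <- data.frame(
      cow_id = tg$cow_id,
      feeder_id = paste0("F", 1L + (seq_len(nrow(cd)) %% 32L)),
      pen_id = "pen1",
      date = format(as.Date(abs_entry, tz = "UTC")),
      entry_time = formatClock(as.numeric(abs_entry) %% 86400),
      exit_time = formatClock(as.numeric(abs_exit) %% 86400),
      weight_in_kg = win,
      weight_out_kg = round(win - cd$intake_kg, 3),
      stringsAsFactors = FALSE)
  }
  log <- do.call(rbind, out)
  if (config$faultRate > 0) {
    n_bad <- ceiling(config$faultRate * nrow(log))
    bad <- log[sample.int(nrow(log), n_bad, replace = TRUE), , drop = FALSE]
    # violate one filter each: zero intake or over-long duration
    half <- seq_len(n_bad) %% 2L == 0L
    bad$weight_out_kg[half] <- bad$weight_in_kg[half]
    es <- parseClock(bad$entry_time[!half])
    bad$exit_time[!half] <- formatClock(es + 3500)
    log <- rbind(log, bad)
  }
  rownames(log) <- NULL
  log
}

#' Write / read helper for visit logs
#'
#' @param log visit log data.frame from [simulateVisitEvents()].
#' @param path output file.
#' @export
writeVisits <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate weekly milk, body-weight series and daily DMI records
#'
#' Generates, per cow: weekly milk yield with fat, protein and lactose
#' percentages; a body-weight series with a linear trend, measurement
#' noise and configurable missingness; and average daily DMI built as
#' the residual-feed-intake model's systematic part (partial regressions
#' on secreted milk energy, metabolic body weight and body-weight
#' change, plus lactation/DIM/cohort effects) plus a true-RFI residual
#' of known variance. The truth (coefficients and per-cow true RFI) is
#' returned for recovery tests.
#'
#' @param design per-cow factors from [makeDesign()] (or any data.frame
#'   of factors with one row per cow).
#' @param nWeeks trial length in weeks (>= 3).
#' @param b true partial regression coefficients (MilkE Mcal, metabolic
#'   BW kg^0.75, BW change kg).
#' @param dmiMeanKg target mean daily DMI, kg.
#' @param sigmaRFI SD of the true RFI residual, kg.
#' @param bwMissingness fraction of BW days left unmeasured.
#' @param fixedEffectSD SD of the drawn lactation/DIM/cohort effects on
#'   DMI (kg).
#' @param seed integer seed.
#' @return list with `milk` (weekly records), `bw` (measured BW series),
#'   `traits` (per-cow table with true generators), `truth`
#'   (coefficients, intercept, true RFI).
#' @export
simulateEfficiencyRecords <- function(design, nWeeks = 10L,
                                      b = c(milke = 0.35, mbw = 0.09,
                                            dbw = 0.03),
                                      dmiMeanKg = 24.8, sigmaRFI = 1.63,
                                      bwMissingness = 0.6,
                                      fixedEffectSD = 0.5,
                                      seed = 1L) {
  stopIfNot(nWeeks >= 3L, "trial length must be at least 3 weeks")
  n <- nrow(design)
  set.seed(as.integer(seed))
  cow_id <- sprintf("cow%04d", seq_len(n))

  milk <- do.call(rbind, lapply(seq_len(n), function(i) {
    yield <- pmax(stats::rnorm(nWeeks, 35, 5), 5)
    data.frame(cow_id = cow_id[i], week = seq_len(nWeeks),
               milk_yield_kg = round(yield, 2),
               fat_pct = round(pmax(stats::rnorm(nWeeks, 4.0, 0.3), 2), 3),
               protein_pct = round(pmax(stats::rnorm(nWeeks, 3.2, 0.15), 2), 3),
               lactose_pct = round(pmax(stats::rnorm(nWeeks, 4.8, 0.1), 3.5), 3),
               stringsAsFactors = FALSE)
  }))

  n_days <- nWeeks * 7L
  bw0 <- stats::rnorm(n, 650, 55)
  slope <- stats::rnorm(n, 0.12, 0.12)
  bw <- do.call(rbind, lapply(seq_len(n), function(i) {
    day <- 0:(n_days - 1L)
    keep <- if (bwMissingness > 0)
      sort(unique(c(1L, n_days,
        which(stats::runif(n_days) >= bwMissingness))))
    else seq_len(n_days)
    day <- day[keep]
    data.frame(cow_id = cow_id[i], trial_day = day,
               bw_kg = round(bw0[i] + slope[i] * day +
                             stats::rnorm(length(day), 0, 7), 1),
               stringsAsFactors = FALSE)
  }))

  # cow-level derived regressors, as the downstream pipeline computes them
  milke <- vapply(split(milk, milk$cow_id), function(m)
    mean(milkEnergy(m$fat_pct, m$protein_pct, m$lactose_pct,
                    m$milk_yield_kg)), numeric(1))[cow_id]
  mbw_true <- (bw0 + slope * (n_days - 1) / 2)^0.75
  dbw_true <- slope * (n_days - 1)

  eff <- lapply(design, function(f) {
    lv <- levels(factor(f))
    stats::setNames(stats::rnorm(length(lv), 0, fixedEffectSD), lv)
  })
  sys <- rep(0, n)
  for (j in seq_along(design))
    sys <- sys + eff[[j]][as.character(design[[j]])]
  intercept <- dmiMeanKg - mean(b["milke"] * milke + b["mbw"] * mbw_true +
                                b["dbw"] * dbw_true + sys)
  true_rfi <- stats::rnorm(n, 0, sigmaRFI)
  dmi <- intercept + b["milke"] * milke + b["mbw"] * mbw_true +
    b["dbw"] * dbw_true + sys + true_rfi

  traits <- cbind(data.frame(cow_id = cow_id, dmi = dmi,
                             stringsAsFactors = FALSE), design)
  list(milk = milk, bw = bw, traits = traits,
       truth = list(b = b, intercept = intercept, true_rfi = true_rfi,
                    effects = eff, milke = milke, mbw = mbw_true,
                    dbw = dbw_true))
}
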