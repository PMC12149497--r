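#' Assign visits to feeding-day windows anchored at Time 0
#'
#' A feeding day starts at Time 0: the first feeder visit by any cow in
#' the pen after the lockout period that precedes fresh feed delivery.
#' Each pen-date gets one window `[time0, next time0)`; the last window
#' of a pen spans 86,400 s. Visits are assigned to windows by their
#' entry time, so a visit just before a day's Time 0 belongs to the
#' previous feeding day.
#'
#' When a delivery schedule is supplied (`pen_id`, `date`,
#' `delivery1` clock time, one row per pen-date), Time 0 is the earliest
#' visit entry at or after that day's first delivery time (lockout ends
#' when feed is delivered). Without a schedule, Time 0 is inferred as
#' the visit that ends the longest pen-wide gap between consecutive
#' visits inside the nominal delivery window (default 10:00-12:00) —
#' the lockout is the one interval in that window when no cow can eat.
#'
#' @param visits cleaned visit data.frame from [readVisits()] /
#'   [filterVisits()]; a missing `pen_id` column is treated as a single
#'   pen.
#' @param schedule optional delivery schedule data.frame.
#' @param inferWindow nominal clock window (start, end) searched for the
#'   delivery gap when no schedule is given.
#' @param anchor `"first_visit"` (default, the definition above) or
#'   `"delivery"`, which takes the scheduled delivery time itself as
#'   Time 0 — useful for synthetic or diagnostic data where the
#'   schedule is exact; requires a schedule.
#' @return list with `windows` (pen_id, day_index, time0, end) and
#'   `visits` (input plus `day_index`, NA for visits before the pen's
#'   first Time 0).
#' @export
assignDayWindows <- function(visits, schedule = NULL,
                             inferWindow = c("10:00", "12:00"),
                             anchor = c("first_visit", "delivery")) {
  anchor <- match.arg(anchor)
  stopIfNot(anchor == "first_visit" || !is.null(schedule),
            "delivery anchoring requires a schedule")
  if (is.null(visits$pen_id)) visits$pen_id <- "pen1"
  visits <- visits[order(visits$pen_id, visits$entry_dt), , drop = FALSE]
  win_lo <- parseClock(inferWindow[1])
  win_hi <- parseClock(inferWindow[2])

  all_windows <- list()
  visits$day_index <- NA_integer_
  for (pen in unique(visits$pen_id)) {
    vp <- visits$pen_id == pen
    ent <- visits$entry_dt[vp]
    dates <- sort(unique(as.Date(ent, tz = "UTC")))
    t0s <- as.POSIXct(character(0), tz = "UTC")
    for (dte in as.list(dates)) {
      day0 <- as.POSIXct(dte, tz = "UTC")
      if (!is.null(schedule)) {
        pen_ok <- if (is.null(schedule$pen_id)) TRUE else schedule$pen_id == pen
        sc <- schedule[schedule$date == dte & pen_ok, , drop = FALSE]
        if (nrow(sc) == 0L) next
        deliv <- day0 + parseClock(sc$delivery1[1])
        if (anchor == "delivery") {
          t0s <- c(t0s, deliv)
          next
        }
        cand <- ent[ent >= deliv]
        if (length(cand) == 0L) {
          warning("pen ", pen, " ", format(dte),
                  ": no visits after delivery; window skipped", call. = FALSE)
          next
        }
        t0s <- c(t0s, min(cand))
      } else {
        sec <- as.numeric(difftime(ent, day0, units = "secs"))
        in_win <- which(sec >= win_lo & sec <= win_hi)
        if (length(in_win) == 0L) {
          warning("pen ", pen, " ", format(dte),
                  ": no visits in the delivery window; window skipped",
                  call. = FALSE)
          next
        }
        # gap preceding each candidate entry (from the previous entry,
        # or from the start of the nominal window)
        ord <- order(sec)
        sec_o <- sec[ord]
        gaps <- vapply(in_win, function(i) {
          prev <- sec_o[sec_o < sec[i]]
          sec[i] - if (length(prev)) max(prev) else win_lo
        }, numeric(1))
        t0s <- c(t0s, day0 + sec[in_win[which.max(gaps)]])
      }
    }
    t0s <- sort(unique(t0s))
    if (length(t0s) == 0L) next
    ends <- c(t0s[-1L], t0s[length(t0s)] + 86400)
    wdf <- data.frame(pen_id = pen, day_index = seq_along(t0s),
                      time0 = t0s, end = ends, stringsAsFactors = FALSE)
    all_windows[[pen]] <- wdf
    di <- findInterval(as.numeric(ent), as.numeric(t0s))
    di[di == 0L] <- NA_integer_
    visits$day_index[vp] <- di
  }
  windows <- do.call(rbind, all_windows)
  rownames(windows) <- NULL
  list(windows = windows, visits = visits)
}

#' Trapezoid area under a cumulative-proportion curve
#'
#' Integrates a piecewise-linear cumulative intake-proportion curve by
#' the trapezoid rule: `sum over segments of (dt) * (c_k + c_{k+1}) / 2`.
#' Offsets are seconds since Time 0; with the standard anchors the
#' result lies in [0, 86,400].
#'
#' @param offsets non-decreasing numeric vector of time offsets (s).
#' @param cumprop cumulative proportions at those offsets.
#' @return area in seconds (s * proportion).
#' @examples
#' trapezoidAUC(c(0, 21600, 43200, 86400), c(0, 0.5, 1, 1))  # 64800
#' @export
trapezoidAUC <- function(offsets, cumprop) {
  stopIfNot(length(offsets) == length(cumprop) && length(offsets) >= 2L,
            "need at least two curve points")
  stopIfNot(all(diff(offsets) >= 0), "curve offsets must be non-decreasing")
  sum(diff(offsets) * (utils::head(cumprop, -1L) + utils::tail(cumprop, -1L)) / 2)
}

#' Cumulative intake-proportion curve for one cow-day
#'
#' Divides each visit's intake by the cow's total for the day, anchors
#' the cumulative curve at (0, 0) and (86,400, 1), and computes its
#' trapezoid AUC. The curve abscissa of each visit is its exit-time
#' offset from Time 0 (intake is realized at exit; offsets past the
#' horizon are clamped).
#'
#' @param offsets visit exit offsets from Time 0, seconds.
#' @param intakes per-visit intakes, kg.
#' @param horizon integration horizon, s (default 86,400).
#' @return list with `offsets`, `cumprop` (anchored), `n_visits`,
#'   `total_intake_kg`, `auc`.
#' @export
cumulativeCurve <- function(offsets, intakes, horizon = 86400) {
  stopIfNot(length(offsets) == length(intakes) && length(offsets) >= 1L,
            "need at least one visit")
  total <- sum(intakes)
  stopIfNot(total > 0, "total intake must be positive")
  o <- order(offsets)
  offsets <- pmin(pmax(offsets[o], 0), horizon)
  cum <- cumsum(intakes[o]) / total
  stopIfNot(abs(cum[length(cum)] - 1) < 1e-9,
            "cumulative proportions must reach 1")
  off_all <- c(0, offsets, horizon)
  cum_all <- c(0, cum, 1)
  list(offsets = off_all, cumprop = cum_all,
       n_visits = length(intakes), total_intake_kg = total,
       auc = trapezoidAUC(off_all, cum_all))
}

#' Daily AUC table for all cow-days
#'
#' Builds one cumulative curve per cow per feeding-day window and
#' returns the per-cow-day summary used by the downstream filters.
#'
#' @param assigned output of [assignDayWindows()].
#' @param keepCurves if TRUE, attach the full curves as an attribute.
#' @return data.frame with `cow_id`, `pen_id`, `day_index`, `n_visits`,
#'   `total_intake_kg`, `auc`.
#' @export
dailyCurves <- function(assigned, keepCurves = FALSE) {
  v <- assigned$visits
  v <- v[!is.na(v$day_index), , drop = FALSE]
  w <- assigned$windows
  key <- paste(v$pen_id, v$day_index, v$cow_id, sep = "\r")
  groups <- split(seq_len(nrow(v)), key)
  curves <- vector("list", length(groups))
  rows <- vector("list", length(groups))
  t0 <- stats::setNames(w$time0, paste(w$pen_id, w$day_index, sep = "\r"))
  for (k in seq_along(groups)) {
    idx <- groups[[k]]
    pen <- v$pen_id[idx[1L]]
    day <- v$day_index[idx[1L]]
    cow <- v$cow_id[idx[1L]]
    time0 <- t0[[paste(pen, day, sep = "\r")]]
    off <- as.numeric(difftime(v$exit_dt[idx], time0, units = "secs"))
    cc <- cumulativeCurve(off, v$intake_kg[idx])
    curves[[k]] <- cc
    rows[[k]] <- data.frame(cow_id = cow, pen_id = pen, day_index = day,
                            n_visits = cc$n_visits,
                            total_intake_kg = cc$total_intake_kg,
                            auc = cc$auc, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ord <- order(out$cow_id, out$pen_id, out$day_index)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (keepCurves) attr(out, "curves") <- curves[ord]
  out
}

#' Day-level exclusion rules
#'
#' Removes cow-days with fewer than `minVisits` feeder visits and days
#' with total intake <= `minIntakeKg` or > `maxIntakeKg` (retained set:
#' at least 5 visits and intake in (12, 115] kg by default).
#'
#' @param days data.frame from [dailyCurves()].
#' @param minVisits minimum visits per day (inclusive, default 5).
#' @param minIntakeKg exclusive lower bound on daily intake (default 12).
#' @param maxIntakeKg inclusive upper bound on daily intake (default 115).
#' @return list with `days` (retained) and `report` counts.
#' @export
filterDays <- function(days, minVisits = 5L, minIntakeKg = 12,
                       maxIntakeKg = 115) {
  rule <- rep("retained", nrow(days))
  rule[days$total_intake_kg > maxIntakeKg] <- "intake_high"
  rule[days$total_intake_kg <= minIntakeKg] <- "intake_low"
  rule[days$n_visits < minVisits] <- "few_visits"
  report <- list(read = nrow(days),
                 removed_few_visits = sum(rule == "few_visits"),
                 removed_intake_low = sum(rule == "intake_low"),
                 removed_intake_high = sum(rule == "intake_high"),
                 retained = sum(rule == "retained"))
  list(days = days[rule == "retained", , drop = FALSE], report = report)
}

#' Per-cow outlier-day removal (3.5 SD rule)
#'
#' Single pass: for each cow, the mean and sample SD of her daily AUC
#' over the whole period are computed once, and days whose AUC deviates
#' from the mean by more than `z` SDs are removed. Not iterated. Cows
#' with fewer than two days, or zero SD, lose no days.
#'
#' @param days data.frame from [filterDays()].
#' @param z SD multiple (default 3.5).
#' @return list with `days` and `report`.
#' @export
removeOutlierDays <- function(days, z = 3.5) {
  keep <- rep(TRUE, nrow(days))
  for (cow in unique(days$cow_id)) {
    i <- which(days$cow_id == cow)
    if (length(i) < 2L) next
    m <- mean(days$auc[i])
    s <- stats::sd(days$auc[i])
    if (!is.finite(s) || s == 0) next
    keep[i] <- abs(days$auc[i] - m) <= z * s
  }
  report <- list(read = nrow(days), removed_outlier = sum(!keep),
                 retained = sum(keep))
  list(days = days[keep, , drop = FALSE], report = report)
}

#' Per-cow feeding-pattern phenotypes
#'
#' The feeding-pattern phenotype is the arithmetic mean of a cow's daily
#' AUC values over her experimental period; its consistency is the
#' natural log of the sample variance (n-1 denominator) of those daily
#' values (log-Var-dAUC). Cows with fewer than `max(2, minDays)`
#' retained days are excluded; cows whose daily AUCs are all identical
#' have an undefined log-variance and are flagged (`log_var_dauc` NA)
#' with a warning.
#'
#' @param days retained cow-days from [removeOutlierDays()].
#' @param minDays minimum retained days per cow (default 20, matching
#'   herds recorded for several weeks; lower it for short simulations).
#' @return data.frame `cow_id`, `n_days`, `auc_mean`, `var_dauc`,
#'   `log_var_dauc`, with an exclusion report attached as attribute
#'   `"report"`.
#' @export
summarizeCows <- function(days, minDays = 20L) {
  need <- max(2L, as.integer(minDays))
  by_cow <- split(days$auc, days$cow_id)
  rows <- lapply(names(by_cow), function(cow) {
    a <- by_cow[[cow]]
    if (length(a) < need) return(NULL)
    v <- sampleVar(a)
    data.frame(cow_id = cow, n_days = length(a), auc_mean = mean(a),
               var_dauc = v,
               log_var_dauc = if (v > 0) log(v) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cow_id = character(0), n_days = integer(0),
                      auc_mean = numeric(0), var_dauc = numeric(0),
                      log_var_dauc = numeric(0))
  rownames(out) <- NULL
  n_flag <- sum(!is.na(out$var_dauc) & out$var_dauc == 0)
  if (n_flag > 0L)
    warning(n_flag, " cow(s) with zero day-to-day AUC variance; ",
            "log-Var-dAUC undefined for them", call. = FALSE)
  attr(out, "report") <- list(
    cows_seen = length(by_cow),
    cows_excluded_min_days = length(by_cow) - nrow(out),
    cows_flagged_zero_variance = n_flag,
    cows_retained = nrow(out))
  out
}
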