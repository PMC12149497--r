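#' Visit-level exclusion thresholds
#'
#' Defaults follow the standard cleaning rules for roughage-intake
#' feeder data: visits with as-fed intake <= 0 kg or > 20 kg, or with
#' duration < 5 s or > 3000 s, are removed. The retained set is
#' therefore intake in (0, 20] kg and duration in [5, 3000] s.
#'
#' @param minIntakeExclusive kg; visits with intake <= this are removed.
#' @param maxIntakeInclusive kg; visits with intake > this are removed.
#' @param minDurationInclusive s; visits shorter than this are removed.
#' @param maxDurationInclusive s; visits longer than this are removed.
#' @return a named list of thresholds.
#' @export
visitFilterConfig <- function(minIntakeExclusive = 0,
                              maxIntakeInclusive = 20,
                              minDurationInclusive = 5,
                              maxDurationInclusive = 3000) {
  stopIfNot(minIntakeExclusive < maxIntakeInclusive,
            "intake bounds out of order")
  stopIfNot(minDurationInclusive < maxDurationInclusive,
            "duration bounds out of order")
  list(minIntakeExclusive = minIntakeExclusive,
       maxIntakeInclusive = maxIntakeInclusive,
       minDurationInclusive = minDurationInclusive,
       maxDurationInclusive = maxDurationInclusive)
}

visitColumns <- c("cow_id", "feeder_id", "date", "entry_time", "exit_time",
                  "weight_in_kg", "weight_out_kg")
visitOptionalColumns <- c("pen_id", "transponder_id")

#' Read a feeder visit log
#'
#' Reads a delimited visit log with columns `cow_id`, `feeder_id`,
#' `date` (ISO-8601), `entry_time`, `exit_time` (HH:MM:SS),
#' `weight_in_kg`, `weight_out_kg` (plus optional `pen_id`,
#' `transponder_id`), computes per-visit intake (weight in minus weight
#' out) and duration, and resolves visits that cross midnight by placing
#' the exit on the following date.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @return data.frame of visits with `entry_dt`/`exit_dt` POSIXct (UTC),
#'   `intake_kg` and `duration_s` columns added.
#' @export
readVisits <- function(path, sep = ",") {
  stopIfNot(file.exists(path), paste("no such file:", path))
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(raw) == 0L && ncol(raw) <= 1L) {
    # completely empty file (no header)
    raw <- data.frame(matrix(character(0), 0, length(visitColumns),
                             dimnames = list(NULL, visitColumns)),
                      stringsAsFactors = FALSE)
  }
  missing <- setdiff(visitColumns, names(raw))
  stopIfNot(length(missing) == 0L,
            paste("missing required column(s):", paste(missing, collapse = ", ")))
  unknown <- setdiff(names(raw), c(visitColumns, visitOptionalColumns))
  stopIfNot(length(unknown) == 0L,
            paste("unknown column(s):", paste(unknown, collapse = ", ")))
  if (nrow(raw) == 0L) {
    out <- raw
    out$entry_dt <- as.POSIXct(character(0), tz = "UTC")
    out$exit_dt <- as.POSIXct(character(0), tz = "UTC")
    out$intake_kg <- numeric(0)
    out$duration_s <- numeric(0)
    attr(out, "n_read") <- 0L
    return(out)
  }

  date <- as.Date(raw$date, format = "%Y-%m-%d")
  entry_s <- parseClock(raw$entry_time)
  exit_s <- parseClock(raw$exit_time)
  win <- suppressWarnings(as.numeric(raw$weight_in_kg))
  wout <- suppressWarnings(as.numeric(raw$weight_out_kg))
  bad <- which(is.na(date) | is.na(entry_s) | is.na(exit_s) |
               is.na(win) | is.na(wout))
  stopIfNot(length(bad) == 0L,
            paste("malformed row(s) at line(s):",
                  paste(utils::head(bad + 1L, 5L), collapse = ", ")))

  entry_dt <- as.POSIXct(date, tz = "UTC") + entry_s
  rollover <- exit_s < entry_s
  exit_dt <- as.POSIXct(date + ifelse(rollover, 1L, 0L), tz = "UTC") + exit_s

  out <- raw
  out$date <- date
  out$entry_dt <- entry_dt
  out$exit_dt <- exit_dt
  out$intake_kg <- win - wout
  out$duration_s <- as.numeric(difftime(exit_dt, entry_dt, units = "secs"))
  attr(out, "n_read") <- nrow(out)
  out
}

#' Apply visit-level exclusion rules
#'
#' Retains visits with intake in (0, 20] kg and duration in [5, 3000] s
#' (under the default [visitFilterConfig()]). The cleaning report
#' attributes each removed visit to the first matching rule, intake
#' rules before duration rules, and always reconciles:
#' read = retained + sum(removed).
#'
#' @param visits data.frame from [readVisits()] (needs `intake_kg` and
#'   `duration_s`).
#' @param config thresholds from [visitFilterConfig()].
#' @return list with `visits` (retained rows) and `report` (named counts).
#' @export
filterVisits <- function(visits, config = visitFilterConfig()) {
  n <- nrow(visits)
  intk <- visits$intake_kg
  dur <- visits$duration_s
  rule <- rep("retained", n)
  rule[dur > config$maxDurationInclusive] <- "duration_long"
  rule[dur < config$minDurationInclusive] <- "duration_short"
  rule[intk > config$maxIntakeInclusive] <- "intake_excessive"
  rule[intk <= config$minIntakeExclusive] <- "intake_nonpositive"
  report <- list(
    read = n,
    removed_intake_nonpositive = sum(rule == "intake_nonpositive"),
    removed_intake_excessive = sum(rule == "intake_excessive"),
    removed_duration_short = sum(rule == "duration_short"),
    removed_duration_long = sum(rule == "duration_long"),
    retained = sum(rule == "retained"))
  list(visits = visits[rule == "retained", , drop = FALSE], report = report)
}

#' Keep only each cow's first trial
#'
#' For cows enrolled in several trials, retains the visits falling within
#' the window of the earliest trial (by start date) only. Visits dated
#' outside every trial window of their cow are dropped and counted.
#'
#' @param visits data.frame with `cow_id` and `date`.
#' @param trials data.frame with `cow_id`, `trial_id`, `start_date`,
#'   `end_date` (Date or ISO-8601 character).
#' @param onMissing what to do with visits of cows absent from `trials`:
#'   "warn" (drop with a warning) or "error".
#' @return list with `visits` and `report` counts.
#' @export
selectFirstTrial <- function(visits, trials, onMissing = c("warn", "error")) {
  onMissing <- match.arg(onMissing)
  trials$start_date <- as.Date(trials$start_date)
  trials$end_date <- as.Date(trials$end_date)
  first <- do.call(rbind, lapply(split(trials, trials$cow_id), function(tt) {
    tt[which.min(tt$start_date), , drop = FALSE]
  }))
  idx <- match(visits$cow_id, first$cow_id)
  unknown_cow <- is.na(idx)
  if (any(unknown_cow)) {
    msg <- paste(sum(unknown_cow), "visits from cows absent from the trial table")
    if (onMissing == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  inside <- !unknown_cow &
    visits$date >= first$start_date[idx] &
    visits$date <= first$end_date[idx]
  report <- list(read = nrow(visits),
                 removed_no_trial = sum(unknown_cow),
                 removed_outside_first_trial = sum(!inside & !unknown_cow),
                 retained = sum(inside))
  list(visits = visits[inside, , drop = FALSE], report = report)
}
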