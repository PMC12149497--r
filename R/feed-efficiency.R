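#' Secreted milk energy from weekly composition
#'
#' `MilkE (Mcal) = (0.0929 x fat% + 0.0563 x protein% + 0.0395 x
#' lactose%) x milk yield (kg)`, the component energy densities
#' multiplying the week's yield.
#'
#' @param fatPct,proteinPct,lactosePct component percentages.
#' @param milkYieldKg weekly milk yield, kg.
#' @return Mcal, vectorised over weeks.
#' @examples
#' milkEnergy(4.0, 3.2, 4.8, 40)  # 29.6544
#' @export
milkEnergy <- function(fatPct, proteinPct, lactosePct, milkYieldKg) {
  stopIfNot(all(c(fatPct, proteinPct, lactosePct, milkYieldKg) >= 0),
            "milk components and yield must be non-negative")
  (0.0929 * fatPct + 0.0563 * proteinPct + 0.0395 * lactosePct) * milkYieldKg
}

#' Per-cow secreted milk energy
#'
#' MilkE is computed by week and then averaged within cow.
#'
#' @param milk data.frame with `cow_id`, `fat_pct`, `protein_pct`,
#'   `lactose_pct`, `milk_yield_kg`.
#' @return named numeric vector of Mcal per cow.
#' @export
cowMilkE <- function(milk) {
  vapply(split(milk, milk$cow_id), function(m) {
    mean(milkEnergy(m$fat_pct, m$protein_pct, m$lactose_pct,
                    m$milk_yield_kg))
  }, numeric(1))
}

#' Complete a body-weight series by per-cow linear regression
#'
#' Missing trial days are filled with predictions from the ordinary
#' least-squares line of measured BW on day of trial; measured values
#' are kept as observed.
#'
#' @param trialDay,bwKg measured series for one cow (>= 2 points).
#' @param dayRange integer range of trial days to cover (default the
#'   measured range).
#' @return data.frame `trial_day`, `bw_kg`, `imputed` plus the fitted
#'   line as attribute `"fit"` (intercept, slope).
#' @export
imputeBW <- function(trialDay, bwKg, dayRange = range(trialDay)) {
  stopIfNot(length(trialDay) >= 2L,
            "need at least two BW measurements to impute")
  stopIfNot(all(diff(sort(trialDay)) > 0), "trial days must be distinct")
  fit <- stats::lm.fit(cbind(1, trialDay), bwKg)
  days <- seq(dayRange[1L], dayRange[2L])
  measured <- match(days, trialDay)
  bw <- ifelse(is.na(measured), fit$coefficients[1L] +
                 fit$coefficients[2L] * days, bwKg[measured])
  out <- data.frame(trial_day = days, bw_kg = bw,
                    imputed = is.na(measured))
  attr(out, "fit") <- c(intercept = unname(fit$coefficients[1L]),
                        slope = unname(fit$coefficients[2L]))
  out
}

#' Metabolic body weight
#'
#' The cow's average BW^0.75 over the (completed) series: the mean of
#' the daily values each raised to the 0.75 power.
#'
#' @param bwKg completed daily BW values.
#' @return kg^0.75.
#' @examples
#' metabolicBW(rep(625, 10))  # 125
#' @export
metabolicBW <- function(bwKg) {
  stopIfNot(all(bwKg > 0), "BW must be positive")
  mean(bwKg^0.75)
}

#' Body-weight change over the trial
#'
#' The difference between BW at the end and at the beginning of the
#' trial period, read off the per-cow regression line (robust to
#' measurement noise in the raw first/last weights).
#'
#' @param trialDay,bwKg measured series for one cow.
#' @param trialStart,trialEnd trial day endpoints (default measured
#'   range).
#' @return kg.
#' @export
deltaBW <- function(trialDay, bwKg, trialStart = min(trialDay),
                    trialEnd = max(trialDay)) {
  stopIfNot(length(trialDay) >= 2L, "need at least two BW measurements")
  fit <- stats::lm.fit(cbind(1, trialDay), bwKg)
  unname(fit$coefficients[2L]) * (trialEnd - trialStart)
}

#' Days-in-milk class labels
#' @return the nine 16-day class labels in order.
#' @export
dimClassLevels <- function() {
  c("50-66", "67-83", "84-100", "101-117", "118-134", "135-151",
    "152-168", "169-185", ">186")
}

#' Map days in milk to its 16-day class
#'
#' Classes: 50-66, 67-83, 84-100, 101-117, 118-134, 135-151, 152-168,
#' 169-185 and >186, inclusive on both printed ends. Day 186 falls in
#' the gap the printed classes leave and is assigned to ">186".
#'
#' @param dim days in milk (>= 50).
#' @return factor with levels [dimClassLevels()].
#' @examples
#' dimClass(c(55, 185, 186, 200))
#' @export
dimClass <- function(dim) {
  stopIfNot(all(dim >= 50), "days in milk below 50 are outside the study window")
  lv <- dimClassLevels()
  idx <- pmin(1L + (pmax(dim, 50) - 50) %/% 17L, 9L)
  factor(lv[idx], levels = lv)
}

#' Residual feed intake by ordinary least squares
#'
#' Fits `DMI = DIM class + lactation + cohort + b1 MilkE + b2 mBW +
#' b3 dBW + e` with reference-level factor coding and an explicit
#' intercept; the residual of each cow is her RFI phenotype. Factors
#' may be omitted by leaving the columns out of `traits`.
#'
#' @param traits data.frame with `cow_id`, `dmi`, covariates `milke`,
#'   `mbw`, `dbw`, and optional factor columns `dim_class`, `lactation`,
#'   `cohort`.
#' @return list with `rfi` (named per cow), `b` (the three partial
#'   regression coefficients), `coefficients` (all estimates) and the
#'   `lm` fit.
#' @export
fitRFI <- function(traits) {
  needed <- c("cow_id", "dmi", "milke", "mbw", "dbw")
  stopIfNot(all(needed %in% names(traits)),
            paste("traits table must contain:", paste(needed, collapse = ", ")))
  factors <- intersect(c("dim_class", "lactation", "cohort"), names(traits))
  rhs <- paste(c(factors, "milke", "mbw", "dbw"), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste("dmi ~", rhs)), data = traits)
  aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  stopIfNot(length(aliased) == 0L,
            paste("rank-deficient RFI design; aliased columns:",
                  paste(aliased, collapse = ", ")))
  rfi <- stats::setNames(stats::residuals(fit), traits$cow_id)
  b <- stats::coef(fit)[c("milke", "mbw", "dbw")]
  list(rfi = rfi, b = stats::setNames(unname(b), c("b1", "b2", "b3")),
       coefficients = stats::coef(fit), fit = fit)
}

#' Derive the full per-cow efficiency-trait table
#'
#' Convenience wrapper: computes per-cow MilkE, metabolic BW and BW
#' change from raw milk and body-weight records, joins the DMI table and
#' factor metadata, and fits the RFI model.
#'
#' @param milk weekly milk records (see [cowMilkE()]).
#' @param bw measured BW series with `cow_id`, `trial_day`, `bw_kg`.
#' @param dmi data.frame `cow_id`, `dmi`.
#' @param metadata data.frame `cow_id` plus factor columns
#'   (`dim_class`, `lactation`, `cohort`).
#' @return list with `traits` (cow_id, dmi, milke, mbw, dbw, rfi) and
#'   the [fitRFI()] report.
#' @export
efficiencyTraits <- function(milk, bw, dmi, metadata = NULL) {
  milke <- cowMilkE(milk)
  bw_by <- split(bw, bw$cow_id)
  mbw <- vapply(bw_by, function(b) {
    filled <- imputeBW(b$trial_day, b$bw_kg)
    metabolicBW(filled$bw_kg)
  }, numeric(1))
  dbw <- vapply(bw_by, function(b) deltaBW(b$trial_day, b$bw_kg), numeric(1))
  tab <- data.frame(cow_id = dmi$cow_id, dmi = dmi$dmi,
                    milke = milke[dmi$cow_id], mbw = mbw[dmi$cow_id],
                    dbw = dbw[dmi$cow_id], stringsAsFactors = FALSE)
  stopIfNot(!anyNA(tab$milke) && !anyNA(tab$mbw),
            "every cow in the DMI table needs milk and BW records")
  if (!is.null(metadata))
    tab <- merge(tab, metadata, by = "cow_id", sort = FALSE)
  rf <- fitRFI(tab)
  tab$rfi <- rf$rfi[tab$cow_id]
  list(traits = tab, rfi_fit = rf)
}
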