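#' Pipeline configuration
#'
#' Collects every input path, cleaning threshold and chain setting of
#' the full analysis in one validated list. All thresholds default to
#' the standard cleaning rules (visit intake (0, 20] kg, duration
#' [5, 3000] s; day >= 5 visits, intake (12, 115] kg; 3.5 SD outlier
#' rule) and must be present: a configuration with a missing field is
#' rejected by name. The list round-trips losslessly through JSON via
#' [jsonlite::write_json()].
#'
#' @param visits path to the visit log (required).
#' @param outDir output directory (required).
#' @param schedule,trials,milk,bw,dmi,metadata,pedigree optional input
#'   paths; stages needing an absent input are skipped.
#' @param minIntakeKg,maxIntakeKg,minDurationS,maxDurationS visit rules.
#' @param minVisitsDay,minDayIntakeKg,maxDayIntakeKg day rules.
#' @param outlierSD per-cow outlier-day rule, SD multiple.
#' @param minDays minimum retained days per cow.
#' @param nIter,burnIn,thin Gibbs settings for the genetic stage.
#' @param seed global seed.
#' @return validated config list.
#' @export
pipelineConfig <- function(visits, outDir,
                           schedule = NULL, trials = NULL, milk = NULL,
                           bw = NULL, dmi = NULL, metadata = NULL,
                           pedigree = NULL,
                           minIntakeKg = 0, maxIntakeKg = 20,
                           minDurationS = 5, maxDurationS = 3000,
                           minVisitsDay = 5, minDayIntakeKg = 12,
                           maxDayIntakeKg = 115,
                           outlierSD = 3.5, minDays = 20,
                           nIter = 20000L, burnIn = 4000L, thin = 1L,
                           seed = 1L) {
  cfg <- as.list(environment())
  required <- c("visits", "outDir", "minIntakeKg", "maxIntakeKg",
                "minDurationS", "maxDurationS", "minVisitsDay",
                "minDayIntakeKg", "maxDayIntakeKg", "outlierSD",
                "minDays", "nIter", "burnIn", "thin", "seed")
  for (f in required)
    stopIfNot(!is.null(cfg[[f]]) && length(cfg[[f]]) == 1L &&
                !is.na(cfg[[f]]),
              paste("pipeline config field missing or invalid:", f))
  cfg
}

writeTable <- function(x, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Clean visits, derive daily curves and per-cow feeding-pattern
#' phenotypes, derive efficiency traits when milk/BW/DMI inputs are
#' configured, estimate heritabilities when a pedigree is configured,
#' write all tables to the output directory and return a run manifest
#' (config hash, seed, per-stage record counts, output paths). The run
#' is deterministic given the configuration.
#'
#' @param config from [pipelineConfig()].
#' @return the manifest, invisibly; also written as `manifest.json`.
#' @export
runPipeline <- function(config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  outputs <- character(0)

  visits <- readVisits(config$visits)
  counts$visits_read <- attr(visits, "n_read")
  fv <- filterVisits(visits, visitFilterConfig(
    config$minIntakeKg, config$maxIntakeKg,
    config$minDurationS, config$maxDurationS))
  counts$visit_filter <- fv$report
  visits <- fv$visits
  if (!is.null(config$trials)) {
    tr <- selectFirstTrial(visits, utils::read.csv(config$trials))
    counts$first_trial <- tr$report
    visits <- tr$visits
  }
  schedule <- if (!is.null(config$schedule)) {
    sc <- utils::read.csv(config$schedule, stringsAsFactors = FALSE)
    sc$date <- as.Date(sc$date)
    sc
  }
  aw <- assignDayWindows(visits, schedule)
  counts$day_windows <- nrow(aw$windows)
  days <- dailyCurves(aw)
  fd <- filterDays(days, config$minVisitsDay, config$minDayIntakeKg,
                   config$maxDayIntakeKg)
  counts$day_filter <- fd$report
  od <- removeOutlierDays(fd$days, config$outlierSD)
  counts$outlier_days <- od$report
  pheno <- summarizeCows(od$days, config$minDays)
  counts$cows <- attr(pheno, "report")
  outputs <- c(outputs,
               writeTable(days, config$outDir, "daily_auc.csv"),
               writeTable(pheno, config$outDir, "feeding_pattern_phenotypes.csv"))

  eff <- NULL
  if (!is.null(config$milk) && !is.null(config$bw) && !is.null(config$dmi)) {
    eff <- efficiencyTraits(
      utils::read.csv(config$milk), utils::read.csv(config$bw),
      utils::read.csv(config$dmi),
      if (!is.null(config$metadata)) utils::read.csv(config$metadata))
    counts$efficiency_cows <- nrow(eff$traits)
    outputs <- c(outputs,
                 writeTable(eff$traits, config$outDir, "efficiency_traits.csv"))
  }

  if (!is.null(config$pedigree) && nrow(pheno) >= 30L) {
    pt <- utils::read.csv(config$pedigree)
    ped <- Pedigree(sire = pt$sire, dam = pt$dam, label = as.character(pt$animal))
    idx <- match(pheno$cow_id, ped@label)
    ok <- !is.na(idx)
    gsum <- list()
    for (trait in c("auc_mean", "log_var_dauc")) {
      y <- pheno[[trait]][ok]
      use <- is.finite(y)
      ch <- gibbsUnivariate(
        y[use], matrix(1, sum(use), 1), ped, idx[ok][use],
        nIter = config$nIter, burnIn = config$burnIn, thin = config$thin,
        seed = config$seed)
      gsum[[trait]] <- cbind(trait = trait, summarizeChain(ch))
    }
    gsum <- do.call(rbind, gsum)
    outputs <- c(outputs,
                 writeTable(gsum, config$outDir, "genetic_parameters.csv"))
  }

  cfg_path <- file.path(config$outDir, "config.json")
  jsonlite::write_json(config[!vapply(config, is.null, logical(1))],
                       cfg_path, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("feedAUC")),
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    counts = counts,
    outputs = basename(outputs))
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write a self-contained synthetic study to disk
#'
#' Generates a pedigree, true breeding values for the feeding-pattern
#' traits, a calibrated visit log, milk/BW/DMI records and trial
#' metadata, and writes everything (plus truth tables) as delimited
#' text. `scale = "small"` is a fast smoke-test herd; `"medium"` is
#' sized for parameter-recovery runs.
#'
#' @param outDir writable output directory.
#' @param scale "small" (about 30 cows, 8 days) or "medium" (about 300
#'   cows, 20 days).
#' @param seed integer seed.
#' @return named vector of file paths, invisibly.
#' @export
makeDemoData <- function(outDir, scale = c("small", "medium"), seed = 1L) {
  scale <- match.arg(scale)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  nf <- if (scale == "small") 60L else 300L
  ng <- if (scale == "small") 2L else 3L
  n_days <- if (scale == "small") 8L else 20L
  set.seed(as.integer(seed))

  ped <- simulatePedigree(nf, nGenerations = ng, matingScheme = "hierarchical",
                          seed = seed)
  cows_idx <- which(ped@generation == ng & ped@sex == "F")
  n <- length(cows_idx)
  cow_id <- sprintf("cow%04d", seq_len(n))

  # cow-level AUC target around the observed herd scale
  u <- simulateBreedingValues(ped, sigma2A = c(auc = 1315780), seed = seed)
  cow_auc <- 56345 + u[cows_idx, 1] +
    stats::rnorm(n, 0, sqrt(2421331 / 2))
  cow_auc <- pmin(pmax(cow_auc, 49500), 65000)

  targets <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(cow_id = cow_id[i],
               date = as.Date("2023-03-01") + seq_len(n_days) - 1L,
               target_auc = pmin(pmax(
                 stats::rnorm(n_days, cow_auc[i], 1200), 40000), 70000),
               total_intake_kg = round(pmin(pmax(
                 stats::rnorm(n_days, 43.8, 6), 15), 90), 1),
               n_visits = pmax(stats::rpois(n_days, 31), 5),
               stringsAsFactors = FALSE)
  }))
  log <- simulateVisitEvents(targets, feedingSimConfig(), seed = seed)

  design <- makeDesign(n, nCohorts = if (scale == "small") 4L else 10L,
                       seed = seed)
  er <- simulateEfficiencyRecords(design, seed = seed)
  er$milk$cow_id <- cow_id[match(er$milk$cow_id, sprintf("cow%04d", seq_len(n)))]
  er$bw$cow_id <- cow_id[match(er$bw$cow_id, sprintf("cow%04d", seq_len(n)))]
  er$traits$cow_id <- cow_id

  pedtab <- data.frame(animal = ped@label, sire = ifelse(ped@sire > 0,
                       ped@label[pmax(ped@sire, 1)], "0"),
                       dam = ifelse(ped@dam > 0,
                       ped@label[pmax(ped@dam, 1)], "0"))
  pedtab$animal[cows_idx] <- cow_id  # phenotyped cows keep their ids
  relabel <- stats::setNames(pedtab$animal, ped@label)
  pedtab$sire <- ifelse(pedtab$sire == "0", "0", relabel[pedtab$sire])
  pedtab$dam <- ifelse(pedtab$dam == "0", "0", relabel[pedtab$dam])

  paths <- c(
    visits = writeTable(log, outDir, "visits.csv"),
    pedigree = writeTable(pedtab, outDir, "pedigree.csv"),
    milk = writeTable(er$milk, outDir, "milk.csv"),
    bw = writeTable(er$bw, outDir, "bw.csv"),
    dmi = writeTable(er$traits[, c("cow_id", "dmi")], outDir, "dmi.csv"),
    metadata = writeTable(cbind(cow_id = cow_id, design), outDir,
                          "metadata.csv"),
    truth_auc = writeTable(
      data.frame(cow_id = cow_id, true_bv_auc = u[cows_idx, 1],
                 cow_target_auc = cow_auc),
      outDir, "truth_auc.csv"),
    truth_rfi = writeTable(
      data.frame(cow_id = cow_id, true_rfi = er$truth$true_rfi),
      outDir, "truth_rfi.csv"))
  invisible(paths)
}
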