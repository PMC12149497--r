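# Shared in-code fixtures for the test suite.

# Write a small visit log to a temp file and return the path.
writeVisitFixture <- function(rows) {
  path <- tempfile(fileext = ".csv")
  header <- "cow_id,feeder_id,date,entry_time,exit_time,weight_in_kg,weight_out_kg"
  writeLines(c(header, rows), path)
  path
}

# A trio pedigree: two unrelated founders and their offspring.
trioPedigree <- function() Pedigree(sire = c(0L, 0L, 1L), dam = c(0L, 0L, 2L))

# Six-animal pedigree with known tabular A: founders 1,2; full sibs 3,4;
# animal 5 = offspring of the full sibs (F = 0.25); 6 = 5 x 1.
sixPedigree <- function() {
  Pedigree(sire = c(0L, 0L, 1L, 1L, 3L, 5L),
           dam  = c(0L, 0L, 2L, 2L, 4L, 1L))
}

# Deterministic cow-day targets for the visit simulator.
visitTargets <- function(aucs, n_visits = 31L, intake = 43.8,
                         cow = "cowA", start = "2023-03-01") {
  data.frame(cow_id = paste0(cow, seq_along(aucs)),
             date = as.Date(start) + seq_along(aucs) - 1L,
             target_auc = aucs,
             total_intake_kg = intake,
             n_visits = n_visits,
             stringsAsFactors = FALSE)
}

# Small herd simulated under the animal model, for sampler tests.
simulateHerd <- function(nFounders = 80L, nGenerations = 3L,
                         sigma2A = 1, sigma2E = 1, seed = 1L,
                         nCohorts = 5L, phenoGen = nGenerations) {
  ped <- simulatePedigree(nFounders, nGenerations = nGenerations,
                          offspringPerMating = 3L,
                          matingScheme = "hierarchical", seed = seed)
  idx <- which(ped@generation >= phenoGen & ped@sex == "F")
  u <- simulateBreedingValues(ped, sigma2A = sigma2A, seed = seed + 1L)
  des <- makeDesign(length(idx), nCohorts = nCohorts, seed = seed + 2L)
  sim <- simulatePhenotypes(u[idx, , drop = FALSE], sigma2E = sigma2E,
                            design = des, seed = seed + 3L)
  list(ped = ped, idx = idx, u = u, design = des,
       y = sim$phenotypes[, 1L],
       X = stats::model.matrix(~ lactation + dim_class + cohort, des))
}
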