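test_that("milk energy follows the component-sum equation", {
  expect_equal(milkEnergy(4.0, 3.2, 4.8, 40), 29.6544)
  expect_equal(milkEnergy(4.0, 3.2, 4.8, 0), 0)
  expect_equal(milkEnergy(1, 0, 0, 1), 0.0929)
  expect_equal(milkEnergy(0, 1, 0, 1), 0.0563)
  expect_equal(milkEnergy(0, 0, 1, 1), 0.0395)
  expect_error(milkEnergy(-1, 3, 4, 30), "non-negative")
})

test_that("per-cow MilkE is the mean of the weekly values", {
  milk <- data.frame(cow_id = c("a", "a", "b"),
                     fat_pct = c(1, 1, 1), protein_pct = 0,
                     lactose_pct = 0,
                     milk_yield_kg = c(28, 32, 40) / 0.0929)
  out <- cowMilkE(milk)
  expect_equal(unname(out["a"]), 30)
  expect_equal(unname(out["b"]), 40)
})

test_that("BW imputation fits the per-cow least-squares line", {
  filled <- imputeBW(c(0, 10), c(600, 610), dayRange = c(0, 10))
  expect_equal(filled$bw_kg[filled$trial_day == 5], 605)
  expect_true(filled$imputed[filled$trial_day == 5])
  # measured days keep their observed values
  expect_equal(filled$bw_kg[filled$trial_day == 0], 600)
  expect_false(filled$imputed[filled$trial_day == 0])
  # constant series imputes the constant
  cst <- imputeBW(c(0, 3, 9), c(650, 650, 650), dayRange = c(0, 9))
  expect_equal(cst$bw_kg, rep(650, 10))
  expect_error(imputeBW(5, 600), "two")
})

test_that("metabolic BW and BW change follow their definitions", {
  expect_equal(metabolicBW(rep(625, 7)), 125)
  expect_equal(deltaBW(c(0, 20), c(600, 610)), 10)
  expect_equal(deltaBW(c(0, 5, 10), c(650, 650, 650)), 0)
  # regression-line endpoints, not raw first/last values
  set.seed(2)
  day <- 0:40
  bw <- 600 + 0.5 * day + rnorm(41, 0, 3)
  expect_equal(deltaBW(day, bw), 20, tolerance = 0.25 * 20)
})

test_that("DIM classes use the printed boundaries with 186 in the top class", {
  expect_equal(as.character(dimClass(c(50, 55, 66))),
               rep("50-66", 3))
  expect_equal(as.character(dimClass(c(67, 83))), rep("67-83", 2))
  expect_equal(as.character(dimClass(169)), "169-185")
  expect_equal(as.character(dimClass(185)), "169-185")
  expect_equal(as.character(dimClass(c(186, 187, 400))), rep(">186", 3))
  expect_error(dimClass(49), "outside")
  # the nine classes partition everything from 50 up
  expect_false(anyNA(dimClass(50:400)))
})

test_that("RFI residuals satisfy the least-squares identities", {
  des <- makeDesign(500, nCohorts = 8, seed = 41)
  er <- simulateEfficiencyRecords(des, seed = 41)
  tab <- cbind(er$traits, milke = er$truth$milke, mbw = er$truth$mbw,
               dbw = er$truth$dbw)
  rf <- fitRFI(tab)
  expect_lt(abs(mean(rf$rfi)), 1e-8 * sd(tab$dmi))
  # residuals orthogonal to the MilkE covariate
  expect_lt(abs(sum(rf$rfi * tab$milke)) / length(rf$rfi),
            1e-6 * sd(rf$rfi) * sd(tab$milke))
  # translation invariance: adding a constant to DMI leaves RFI unchanged
  tab2 <- tab; tab2$dmi <- tab2$dmi + 5
  expect_equal(fitRFI(tab2)$rfi, rf$rfi, tolerance = 1e-8)
  # variance decomposition
  expect_equal(var(tab$dmi),
               var(fitted(rf$fit)) + var(rf$rfi) +
                 2 * cov(fitted(rf$fit), rf$rfi),
               tolerance = 1e-10)
  expect_lt(abs(cov(fitted(rf$fit), rf$rfi)), 1e-8 * var(tab$dmi))
})

test_that("the RFI fit recovers configured coefficients and variance", {
  des <- makeDesign(1000, nCohorts = 8, seed = 42)
  er <- simulateEfficiencyRecords(des, b = c(milke = 0.35, mbw = 0.09,
                                             dbw = 0.03), seed = 42)
  tab <- cbind(er$traits, milke = er$truth$milke, mbw = er$truth$mbw,
               dbw = er$truth$dbw)
  rf <- fitRFI(tab)
  se_b1 <- summary(rf$fit)$coefficients["milke", "Std. Error"]
  expect_lt(abs(rf$b[["b1"]] - 0.35), 3 * se_b1)
  # fitted RFI SD tracks the configured residual SD
  expect_equal(sd(rf$rfi), 1.63, tolerance = 0.10 * 1.63)
  # rank deficiency is reported with the aliased column
  tab$dup <- tab$milke
  expect_error(
    fitRFI(transform(tab, mbw = milke)), "aliased")
})

test_that("efficiencyTraits wires raw records into the RFI table", {
  des <- makeDesign(80, nCohorts = 4, seed = 43)
  er <- simulateEfficiencyRecords(des, seed = 43)
  md <- cbind(cow_id = er$traits$cow_id, des)
  eff <- efficiencyTraits(er$milk, er$bw,
                          er$traits[, c("cow_id", "dmi")], md)
  expect_equal(nrow(eff$traits), 80L)
  expect_true(all(c("milke", "mbw", "dbw", "rfi") %in% names(eff$traits)))
  expect_lt(abs(mean(eff$traits$rfi)), 1e-8)
  # derived regressors track the generating values
  expect_equal(eff$traits$milke, unname(er$truth$milke), tolerance = 1e-10)
  expect_equal(eff$traits$mbw, unname(er$truth$mbw), tolerance = 0.02)
})
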