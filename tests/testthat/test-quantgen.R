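test_that("relationship matrices match textbook hand computations", {
  trio <- trioPedigree()
  A <- makeA(trio)
  expect_equal(unname(A[3, 1]), 0.5)
  expect_equal(unname(A[3, 3]), 1.0)
  Ai <- as.matrix(buildAInverse(trio))
  expect_equal(unname(diag(Ai)), c(1.5, 1.5, 2.0))
  expect_equal(unname(Ai[1, 3]), -1.0)
  expect_equal(unname(Ai[2, 3]), -1.0)

  # unrelated animals: identity both ways
  un <- Pedigree(sire = rep(0L, 3), dam = rep(0L, 3))
  expect_equal(unname(makeA(un)), diag(3))
  expect_equal(unname(as.matrix(buildAInverse(un))), diag(3))

  # offspring of full sibs: F = 0.25, diagonal 1.25
  six <- sixPedigree()
  expect_equal(unname(diag(makeA(six))[5]), 1.25)
  expect_equal(inbreeding(six)@F[5], 0.25)
})

test_that("Henderson A-inverse times tabular A is the identity", {
  for (seed in 1:4) {
    ped <- simulatePedigree(16, nGenerations = 3, offspringPerMating = 2,
                            matingScheme = sample(c("random", "hierarchical"), 1),
                            seed = seed)
    A <- makeA(ped)
    Ai <- as.matrix(buildAInverse(ped))
    expect_lt(max(abs(Ai %*% A - diag(nAnimals(ped)))), 1e-8)
  }
})

test_that("pedigree tracing keeps the requested ancestral depth", {
  # 7-animal chain: 1 -> 2 -> ... -> 7 (each the sire of the next)
  chain <- Pedigree(sire = c(0L, 1:6), dam = rep(0L, 7))
  tr <- tracePedigree(chain, phenotyped = 7L, generations = 5L)
  expect_equal(nAnimals(tr$pedigree), 6L)       # oldest ancestor dropped
  expect_equal(tr$pedigree@sire[1L], 0L)        # its child became a founder
  # depth 0: phenotyped animals only, parents unknown
  tr0 <- tracePedigree(chain, phenotyped = 7L, generations = 0L)
  expect_equal(nAnimals(tr0$pedigree), 1L)
  expect_equal(tr0$pedigree@sire, 0L)
  # founder-only herd: unchanged
  un <- Pedigree(sire = rep(0L, 4), dam = rep(0L, 4))
  tru <- tracePedigree(un, phenotyped = 1:4)
  expect_equal(nAnimals(tru$pedigree), 4L)
})

test_that("fixed-effect posterior matches the GLS solution at known variances", {
  # toy herd with known variance components: the marginal model is
  # y ~ N(X b, sigma2_a A + sigma2_e I) and flat-prior b has posterior
  # mean equal to generalized least squares
  set.seed(51)
  ped <- simulatePedigree(20, nGenerations = 2, seed = 51)
  idx <- which(ped@generation == 2)
  n <- length(idx)
  X <- cbind(1, rnorm(n))
  u <- simulateBreedingValues(ped, sigma2A = 2, seed = 52)
  y <- drop(X %*% c(5, 1.5)) + u[idx, 1] + rnorm(n, 0, sqrt(1.5))
  V <- 2 * makeA(ped)[idx, idx] + 1.5 * diag(n)
  gls <- solve(t(X) %*% solve(V, X), t(X) %*% solve(V, y))
  draws <- gibbsFixedEffects(y, X, ped, idx, sigma2A = 2, sigma2E = 1.5,
                             nIter = 20000, burnIn = 2000, seed = 53)
  se <- sqrt(diag(solve(t(X) %*% solve(V, X))))
  expect_lt(max(abs(colMeans(draws) - drop(gls)) / se), 0.15)
})

test_that("a heritability-free trait yields a near-zero h2 posterior", {
  herd <- simulateHerd(nFounders = 120, nGenerations = 3, sigma2A = 1e-8,
                       sigma2E = 1, seed = 61, phenoGen = 2)
  ch <- gibbsUnivariate(herd$y, herd$X, herd$ped, herd$idx,
                        nIter = 8000, burnIn = 2000, seed = 62)
  expect_lt(mean(chainSamples(ch)[, "h2"]), 0.1)
})

test_that("univariate recovery works on a moderately sized herd", {
  herd <- simulateHerd(nFounders = 150, nGenerations = 3, sigma2A = 2,
                       sigma2E = 2, seed = 63, phenoGen = 2)
  ch <- gibbsUnivariate(herd$y, herd$X, herd$ped, herd$idx,
                        nIter = 12000, burnIn = 3000, seed = 64)
  h2 <- mean(chainSamples(ch)[, "h2"])
  expect_gt(h2, 0.25); expect_lt(h2, 0.75)  # truth 0.5, small herd
  # chain object integrity
  expect_s4_class(ch, "GibbsChain")
  expect_true(all(chainSamples(ch)[, c("sigma2_a", "sigma2_e")] > 0))
})

test_that("the bivariate sampler recovers degenerate and null correlations", {
  ped <- simulatePedigree(150, nGenerations = 3, offspringPerMating = 3,
                          matingScheme = "hierarchical", seed = 71)
  idx <- which(ped@generation >= 2 & ped@sex == "F")
  n <- length(idx)
  # identical data on both traits: genetic correlation mass near 1
  u <- simulateBreedingValues(ped, sigma2A = 2, seed = 72)
  y <- u[idx, 1] + rnorm(n, 0, 1)
  Y <- cbind(t1 = y, t2 = y)
  X <- matrix(1, n, 1)
  ch <- gibbsBivariate(Y, X, X, ped, idx, nIter = 4000, burnIn = 1000,
                       thin = 2, seed = 73)
  expect_gt(mean(chainSamples(ch)[, "rg"]), 0.9)

  # independent traits: correlation near zero
  u2 <- simulateBreedingValues(ped, sigma2A = c(2, 2), seed = 74)
  Y2 <- u2[idx, ] + matrix(rnorm(2 * n), n, 2)
  ch2 <- gibbsBivariate(Y2, X, X, ped, idx, nIter = 10000, burnIn = 2000,
                        thin = 2, seed = 75)
  expect_lt(abs(mean(chainSamples(ch2)[, "rg"])), 0.2)
})

test_that("bivariate marginals agree with the univariate sampler", {
  herd <- simulateHerd(nFounders = 120, nGenerations = 3, sigma2A = 2,
                       sigma2E = 2, seed = 81, phenoGen = 2)
  n <- length(herd$y)
  set.seed(82)
  y2 <- rnorm(n, 0, 2)   # unrelated second trait
  chU <- gibbsUnivariate(herd$y, herd$X, herd$ped, herd$idx,
                         nIter = 12000, burnIn = 3000, seed = 83)
  chB <- gibbsBivariate(cbind(herd$y, y2), herd$X, matrix(1, n, 1),
                        herd$ped, herd$idx, nIter = 12000, burnIn = 3000,
                        thin = 2, seed = 84)
  h2U <- mean(chainSamples(chU)[, "h2"])
  h2B <- mean(chainSamples(chB)[, "h2_1"])
  expect_equal(h2U, h2B, tolerance = 0.08)
})

test_that("samplers validate their inputs", {
  herd <- simulateHerd(nFounders = 40, nGenerations = 2, seed = 91)
  n <- length(herd$y)
  Xbad <- cbind(herd$X, herd$X[, 2])
  expect_error(gibbsUnivariate(herd$y, Xbad, herd$ped, herd$idx,
                               nIter = 100, burnIn = 10), "rank deficient")
  expect_error(gibbsUnivariate(herd$y, herd$X, herd$ped, herd$idx,
                               nIter = 100, burnIn = 200), "burn-in")
  Yna <- cbind(herd$y, ifelse(seq_len(n) == 1, NA, herd$y))
  expect_error(gibbsBivariate(Yna, herd$X, herd$X, herd$ped, herd$idx,
                              nIter = 100, burnIn = 10), "complete-case")
})

test_that("replicated recovery at the reported truths is unbiased with calibrated HPDs", {
  # 16 seeded replicates of a mid-sized herd at the AUC-trait variance
  # components; short chains (posterior means are insensitive to chain
  # length here, checked separately at full length)
  truth <- 1315780 / (1315780 + 2421331)
  res <- sapply(seq(7, by = 31, length.out = 16), function(s) {
    st <- simulateHeritabilityStudy("auc", seed = s, nFounders = 300)
    ch <- gibbsUnivariate(st$y, st$X, st$ped, st$idx,
                          nIter = 12000, burnIn = 3000, seed = s + 5)
    h2 <- chainSamples(ch)[, "h2"]
    hpd <- hpdInterval(h2, 0.90)
    c(est = mean(h2), cover = hpd[["lower"]] <= truth &&
        truth <= hpd[["upper"]])
  })
  expect_lt(abs(mean(res["est", ]) - truth), 0.03)
  expect_gte(mean(res["cover", ]), 0.70)
})

test_that("posterior summaries are invariant to animal ordering", {
  herd <- simulateHerd(nFounders = 100, nGenerations = 3, sigma2A = 2,
                       sigma2E = 2, seed = 121, phenoGen = 2)
  perm <- sample(seq_along(herd$y))
  ch1 <- gibbsUnivariate(herd$y, herd$X, herd$ped, herd$idx,
                         nIter = 15000, burnIn = 4000, seed = 122)
  ch2 <- gibbsUnivariate(herd$y[perm], herd$X[perm, ], herd$ped,
                         herd$idx[perm], nIter = 15000, burnIn = 4000,
                         seed = 123)
  expect_equal(mean(chainSamples(ch1)[, "h2"]),
               mean(chainSamples(ch2)[, "h2"]), tolerance = 0.05)
})
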