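#' Simulate a multi-generation pedigree
#'
#' Builds a discrete-generation pedigree. Generation 0 holds the
#' founders (alternating female/male). In each later generation every
#' female of the previous generation is mated once and produces
#' `offspringPerMating` offspring; sexes are assigned in a balanced,
#' deterministic alternation so herd size is reproducible. Under the
#' `"random"` scheme each mating draws a sire at random from the previous
#' generation's males; under `"hierarchical"` a small sire subset
#' (`nSires`, default about 10% of available males) is nominated and dams
#' are split evenly across them, which produces the large paternal
#' half-sib families typical of dairy populations and is the more
#' informative design for variance-component estimation.
#'
#' @param nFounders number of founder animals (>= 2).
#' @param nGenerations number of offspring generations (default 5).
#' @param offspringPerMating offspring per mated female (default 2).
#' @param matingScheme "random" or "hierarchical".
#' @param nSires number of sires used per generation under the
#'   hierarchical scheme (default `ceiling(males / 10)`).
#' @param seed integer seed.
#' @return a [Pedigree-class] object with `generation` and `sex` filled.
#' @examples
#' ped <- simulatePedigree(100, nGenerations = 5, seed = 1)
#' nAnimals(ped)  # 600
#' @export
simulatePedigree <- function(nFounders, nGenerations = 5L,
                             offspringPerMating = 2L,
                             matingScheme = c("random", "hierarchical"),
                             nSires = NULL, seed = 1L) {
  matingScheme <- match.arg(matingScheme)
  stopIfNot(nFounders >= 1L, "invalid pedigree spec: need at least one founder")
  stopIfNot(nGenerations >= 1L, "invalid pedigree spec: nGenerations must be >= 1")
  set.seed(as.integer(seed))

  sex <- rep_len(c("F", "M"), nFounders)
  sire <- rep(0L, nFounders)
  dam <- rep(0L, nFounders)
  gen <- rep(0L, nFounders)

  for (g in seq_len(nGenerations)) {
    prev <- which(gen == g - 1L)
    dams <- prev[sex[prev] == "F"]
    males <- prev[sex[prev] == "M"]
    stopIfNot(length(dams) >= 1L && length(males) >= 1L,
              "mating impossible: a generation lacks one sex")
    ns <- if (matingScheme == "hierarchical") {
      min(length(males), if (is.null(nSires)) max(1L, ceiling(length(males) / 10)) else nSires)
    } else length(males)
    # index-based sampling: safe when only one male is available
    sires_pool <- if (matingScheme == "hierarchical")
      males[sample.int(length(males), ns)] else males
    mate_sire <- if (matingScheme == "hierarchical")
      sires_pool[1L + (seq_along(dams) - 1L) %% ns]
    else sires_pool[sample.int(length(sires_pool), length(dams),
                               replace = TRUE)]

    n_off <- length(dams) * offspringPerMating
    off_sire <- rep(mate_sire, each = offspringPerMating)
    off_dam <- rep(dams, each = offspringPerMating)
    sire <- c(sire, off_sire)
    dam <- c(dam, off_dam)
    gen <- c(gen, rep(g, n_off))
    sex <- c(sex, rep_len(c("F", "M"), n_off))
  }
  Pedigree(sire = sire, dam = dam, generation = gen, sex = sex)
}

#' Simulate breeding values down a pedigree
#'
#' Founders are drawn from a zero-mean multivariate normal with the
#' trait-level additive (co)variance matrix; each non-founder is the
#' parent average plus a Mendelian-sampling deviation whose variance is
#' `0.5 * (1 - 0.5 * (F_s + F_d))` times the additive (co)variance (with
#' the usual adjustments when a parent is unknown). Exact inbreeding
#' coefficients from the tabular method are used, so the simulated
#' covariances match `A * sigma2_a` in expectation.
#'
#' @param ped a [Pedigree-class] object.
#' @param sigma2A numeric vector of additive variances, one per trait.
#' @param geneticCorr genetic correlation matrix (default identity);
#'   must be symmetric positive-definite with unit diagonal.
#' @param seed integer seed.
#' @return numeric matrix, animals x traits.
#' @export
simulateBreedingValues <- function(ped, sigma2A, geneticCorr = NULL,
                                   seed = 1L) {
  stopifnot(is(ped, "Pedigree"))
  k <- length(sigma2A)
  stopIfNot(all(sigma2A >= 0), "additive variances must be non-negative")
  if (is.null(geneticCorr)) geneticCorr <- diag(k)
  stopIfNot(isSymmetric(unname(geneticCorr)) &&
            all(abs(diag(geneticCorr) - 1) < 1e-12),
            "geneticCorr must be symmetric with unit diagonal")
  sd_a <- sqrt(sigma2A)
  ev <- eigen(geneticCorr, symmetric = TRUE, only.values = TRUE)$values
  stopIfNot(min(ev) > 1e-10, "genetic covariance is not positive-definite")
  Lc <- chol(geneticCorr)

  ped <- inbreeding(ped)
  n <- nAnimals(ped)
  set.seed(as.integer(seed))
  # rows ~ N(0, SigmaA); zero-variance traits give exact zeros
  Z <- sweep(matrix(stats::rnorm(n * k), n, k) %*% Lc, 2, sd_a, `*`)

  s <- ped@sire; d <- ped@dam; Fi <- ped@F
  u <- matrix(0, n, k)
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (si == 0L && di == 0L) {
      u[i, ] <- Z[i, ]
    } else if (si > 0L && di > 0L) {
      w <- 0.5 * (1 - 0.5 * (Fi[si] + Fi[di]))
      u[i, ] <- 0.5 * (u[si, ] + u[di, ]) + sqrt(w) * Z[i, ]
    } else {
      p <- max(si, di)
      w <- 0.75 - 0.25 * Fi[p]
      u[i, ] <- 0.5 * u[p, ] + sqrt(w) * Z[i, ]
    }
  }
  colnames(u) <- names(sigma2A)
  u
}

#' Assign a balanced fixed-effect design to a set of cows
#'
#' Gives each cow a lactation number (4 levels, 1 to 4+), a days-in-milk
#' class (9 levels of 16-day periods starting at 50) and a trial-treatment
#' cohort, with levels allocated approximately uniformly at random.
#'
#' @param n number of cows.
#' @param nCohorts number of cohort levels (default 15).
#' @param seed integer seed.
#' @return data.frame with factors `lactation`, `dim_class`, `cohort`.
#' @export
makeDesign <- function(n, nCohorts = 15L, seed = 1L) {
  set.seed(as.integer(seed))
  data.frame(
    lactation = factor(sample(c("1", "2", "3", "4+"), n, replace = TRUE),
                       levels = c("1", "2", "3", "4+")),
    dim_class = factor(sample(dimClassLevels(), n, replace = TRUE),
                       levels = dimClassLevels()),
    cohort = factor(sample(paste0("C", seq_len(nCohorts)), n, replace = TRUE),
                    levels = paste0("C", seq_len(nCohorts))),
    stringsAsFactors = FALSE)
}

#' Simulate phenotypes under the animal model
#'
#' `y = mu + fixed effects + breeding value + residual`, with independent
#' residuals of variance `sigma2E` per trait and, optionally, a residual
#' correlation between traits. Fixed-effect level values are drawn once
#' (standard normal scaled by `fixedEffectSD`) per factor level so that
#' the design carries real, estimable systematic effects.
#'
#' @param u breeding-value matrix (cows x traits) for the phenotyped
#'   cows.
#' @param sigma2E residual variance per trait.
#' @param design data.frame of factors as from [makeDesign()]; `NULL`
#'   for an intercept-only model.
#' @param mu overall mean per trait (default 0).
#' @param residCorr residual correlation matrix (default identity).
#' @param fixedEffectSD scale of the drawn level effects, per trait;
#'   default 0.5 genetic SD.
#' @param seed integer seed.
#' @return list with `phenotypes` (cows x traits matrix), `design`, and
#'   `effects` (the drawn level values, per trait).
#' @export
simulatePhenotypes <- function(u, sigma2E, design = NULL, mu = NULL,
                               residCorr = NULL, fixedEffectSD = NULL,
                               seed = 1L) {
  u <- as.matrix(u)
  n <- nrow(u); k <- ncol(u)
  stopIfNot(length(sigma2E) == k, "one residual variance per trait required")
  stopIfNot(all(sigma2E >= 0), "residual variances must be non-negative")
  if (is.null(mu)) mu <- rep(0, k)
  if (is.null(residCorr)) residCorr <- diag(k)
  if (is.null(fixedEffectSD)) fixedEffectSD <- 0.5 * apply(u, 2, stats::sd)
  fixedEffectSD[!is.finite(fixedEffectSD)] <- 0

  set.seed(as.integer(seed))
  sd_e <- sqrt(sigma2E)
  E <- sweep(matrix(stats::rnorm(n * k), n, k) %*% chol(residCorr), 2, sd_e, `*`)

  y <- sweep(u + E, 2, mu, `+`)
  effects <- NULL
  if (!is.null(design)) {
    stopIfNot(nrow(design) == n, "design must have one row per cow")
    effects <- lapply(seq_len(k), function(t) {
      lapply(design, function(f) {
        lv <- levels(factor(f))
        stats::setNames(stats::rnorm(length(lv), 0, fixedEffectSD[t]), lv)
      })
    })
    for (t in seq_len(k))
      for (j in seq_along(design))
        y[, t] <- y[, t] + effects[[t]][[j]][as.character(design[[j]])]
  }
  colnames(y) <- colnames(u)
  list(phenotypes = y, design = design, effects = effects)
}
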