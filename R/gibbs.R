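#' @importFrom stats rnorm rchisq var
NULL

# Shared setup: additive relationship among phenotyped animals and its
# eigendecomposition. Ancestors without records are marginalised
# analytically (the marginal covariance of the phenotyped animals'
# breeding values is the corresponding submatrix of A), after which one
# orthogonal rotation by the eigenvectors makes every genetic full
# conditional diagonal. This is an exact reparameterisation of the
# animal model, chosen over per-iteration sparse factorisation of the
# mixed-model equations for speed; the posterior is identical.
animalModelEigen <- function(ped, phenotyped) {
  stopifnot(is(ped, "Pedigree"))
  A <- makeA(ped)
  Asub <- A[phenotyped, phenotyped, drop = FALSE]
  eig <- eigen(Asub, symmetric = TRUE)
  lam <- pmax(eig$values, 1e-8)
  list(U = eig$vectors, lambda = lam)
}

checkDesign <- function(X, n) {
  X <- as.matrix(X)
  stopIfNot(nrow(X) == n, "design must have one row per phenotyped animal")
  stopIfNot(qr(X)$rank == ncol(X),
            "design is rank deficient after coding; drop aliased columns")
  X
}

#' Univariate Gibbs sampler for the pedigree animal model
#'
#' Samples the additive genetic and residual variances of
#' `y = X b + u + e`, with `u ~ N(0, A sigma2_a)` over the phenotyped
#' animals (ancestors marginalised through A) and `e ~ N(0, I sigma2_e)`.
#' Fixed effects carry a flat prior; both variances carry scaled
#' inverse chi-square priors whose defaults (`nu = -2`, scale 0) make
#' them flat on the variance scale. Each cycle draws the genetic values
#' and fixed effects from their normal full conditionals in the
#' eigenrotated model, then each variance from its scaled inverse
#' chi-square full conditional. Heritability is computed per sample.
#'
#' @param y numeric phenotype vector for the phenotyped animals.
#' @param X fixed-effect design matrix (include the intercept); use
#'   `matrix(1, n, 1)` for an intercept-only model.
#' @param ped a [Pedigree-class] covering all animals.
#' @param phenotyped indices into `ped` of the phenotyped animals, in
#'   the order of `y`.
#' @param nIter,burnIn,thin chain settings (defaults 100,000 / 20,000 /
#'   1; thinning is optional for univariate chains).
#' @param seed integer seed.
#' @param nuA,scaleA,nuE,scaleE prior hyperparameters of the scaled
#'   inverse chi-square priors.
#' @param fixedVariances optional `c(sigma2_a, sigma2_e)`; when given,
#'   the variances are held fixed and only locations are sampled (used
#'   for closed-form cross-checks).
#' @return a [GibbsChain-class] with columns `sigma2_a`, `sigma2_e`,
#'   `h2`.
#' @export
gibbsUnivariate <- function(y, X, ped, phenotyped,
                            nIter = 100000L, burnIn = 20000L, thin = 1L,
                            seed = 1L,
                            nuA = -2, scaleA = 0, nuE = -2, scaleE = 0,
                            fixedVariances = NULL) {
  n <- length(y)
  X <- checkDesign(X, n)
  p <- ncol(X)
  stopIfNot(burnIn < nIter, "burn-in must be smaller than the chain length")
  em <- animalModelEigen(ped, phenotyped)
  U <- em$U; lam <- em$lambda

  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)
  XtX <- crossprod(Xs)
  Rx <- chol(XtX)

  set.seed(as.integer(seed))
  vy <- var(y)
  sa <- vy / 2; se <- vy / 2
  if (!is.null(fixedVariances)) { sa <- fixedVariances[1L]; se <- fixedVariances[2L] }
  b <- backsolve(Rx, backsolve(Rx, crossprod(Xs, ys), transpose = TRUE))
  v <- numeric(n)

  keep <- seq.int(burnIn + thin, nIter, by = thin)
  out <- matrix(NA_real_, length(keep), 3,
                dimnames = list(NULL, c("sigma2_a", "sigma2_e", "h2")))
  ki <- 1L
  for (it in seq_len(nIter)) {
    r <- ys - drop(Xs %*% b)
    varv <- 1 / (1 / se + 1 / (sa * lam))
    v <- varv * r / se + sqrt(varv) * rnorm(n)

    rhs <- crossprod(Xs, ys - v)
    bhat <- backsolve(Rx, backsolve(Rx, rhs, transpose = TRUE))
    b <- bhat + backsolve(Rx, rnorm(p)) * sqrt(se)

    if (is.null(fixedVariances)) {
      Sa <- sum(v * v / lam) + nuA * scaleA
      sa <- Sa / rchisq(1L, df = n + nuA)
      e <- ys - drop(Xs %*% b) - v
      Se <- sum(e * e) + nuE * scaleE
      se <- Se / rchisq(1L, df = n + nuE)
    }
    if (it > burnIn && (it - burnIn) %% thin == 0L) {
      out[ki, ] <- c(sa, se, sa / (sa + se))
      ki <- ki + 1L
    }
  }
  new("GibbsChain", samples = out, model = "univariate",
      traits = "trait", nIter = as.integer(nIter),
      burnIn = as.integer(burnIn), thin = as.integer(thin),
      seed = as.integer(seed))
}

#' Gibbs sampler for fixed effects with known variances
#'
#' Companion to [gibbsUnivariate()] for cross-checks against the
#' generalised-least-squares solution: variances held fixed, the chain
#' records the fixed-effect draws.
#'
#' @inheritParams gibbsUnivariate
#' @param sigma2A,sigma2E the known variances.
#' @return matrix of fixed-effect draws (retained iterations x p).
#' @export
gibbsFixedEffects <- function(y, X, ped, phenotyped, sigma2A, sigma2E,
                              nIter = 5000L, burnIn = 1000L, seed = 1L) {
  n <- length(y)
  X <- checkDesign(X, n)
  p <- ncol(X)
  em <- animalModelEigen(ped, phenotyped)
  ys <- drop(crossprod(em$U, y))
  Xs <- crossprod(em$U, X)
  Rx <- chol(crossprod(Xs))
  lam <- em$lambda
  set.seed(as.integer(seed))
  b <- backsolve(Rx, backsolve(Rx, crossprod(Xs, ys), transpose = TRUE))
  out <- matrix(NA_real_, nIter - burnIn, p)
  for (it in seq_len(nIter)) {
    r <- ys - drop(Xs %*% b)
    varv <- 1 / (1 / sigma2E + 1 / (sigma2A * lam))
    v <- varv * r / sigma2E + sqrt(varv) * rnorm(n)
    rhs <- crossprod(Xs, ys - v)
    bhat <- backsolve(Rx, backsolve(Rx, rhs, transpose = TRUE))
    b <- bhat + backsolve(Rx, rnorm(p)) * sqrt(sigma2E)
    if (it > burnIn) out[it - burnIn, ] <- b
  }
  out
}

#' Bivariate Gibbs sampler for the pedigree animal model
#'
#' Two-trait animal model with trait-specific fixed-effect designs
#' (residual feed intake, whose phenotype is already adjusted, enters
#' with an intercept only). The joint covariance of the genetic effects
#' is `G0 kron A` and of the residuals `R0 kron I`. G0 and R0 carry
#' weakly informative inverse Wishart priors: degrees of freedom
#' `dim + 2`, with diagonal prior scales splitting the phenotypic
#' variance as one third genetic, two thirds residual (about one
#' pseudo-observation per trait at a conventional prior heritability
#' of 1/3). A near-singular scale with minimal degrees of freedom is
#' deliberately avoided: its density spike at singular G0 collapses
#' weakly identified genetic variances toward zero. Chains are thinned
#' (default 10).
#' Complete-case: every phenotyped animal must carry both traits.
#' Per-sample heritabilities and the genetic correlation
#' `g12 / sqrt(g11 g22)` are recorded.
#'
#' @param Y numeric matrix, phenotyped animals x 2 traits.
#' @param X1,X2 per-trait fixed-effect design matrices (with intercept).
#' @param ped a [Pedigree-class].
#' @param phenotyped indices into `ped`, in row order of `Y`.
#' @param nIter,burnIn,thin chain settings (defaults 100,000 / 20,000 /
#'   10).
#' @param seed integer seed.
#' @param nu0 prior degrees of freedom for both inverse Wisharts
#'   (default 4 = dim + 2, the smallest value with a defined prior
#'   mean).
#' @param S0g,S0r prior scale matrices (defaults: one third / two
#'   thirds of each trait's phenotypic variance on the diagonal).
#' @return a [GibbsChain-class] with columns `g11`, `g12`, `g22`,
#'   `r11`, `r12`, `r22`, `h2_1`, `h2_2`, `rg`.
#' @export
gibbsBivariate <- function(Y, X1, X2, ped, phenotyped,
                           nIter = 100000L, burnIn = 20000L, thin = 10L,
                           seed = 1L, nu0 = 4,
                           S0g = NULL, S0r = NULL) {
  Y <- as.matrix(Y)
  stopIfNot(ncol(Y) == 2L, "Y must hold exactly two traits")
  stopIfNot(!anyNA(Y), "complete-case sampler: both traits required per animal")
  n <- nrow(Y)
  X1 <- checkDesign(X1, n); X2 <- checkDesign(X2, n)
  p1 <- ncol(X1); p2 <- ncol(X2)
  stopIfNot(burnIn < nIter, "burn-in must be smaller than the chain length")

  em <- animalModelEigen(ped, phenotyped)
  U <- em$U; lam <- em$lambda
  Ys <- crossprod(U, Y)
  Xs1 <- crossprod(U, X1); Xs2 <- crossprod(U, X2)
  X11 <- crossprod(Xs1); X12 <- crossprod(Xs1, Xs2); X22 <- crossprod(Xs2)

  vy <- apply(Y, 2, var)
  if (is.null(S0g)) S0g <- diag(vy / 3, 2)
  if (is.null(S0r)) S0r <- diag(2 * vy / 3, 2)

  set.seed(as.integer(seed))
  G <- diag(vy / 2, 2); R <- diag(vy / 2, 2)
  b1 <- qr.solve(Xs1, Ys[, 1L]); b2 <- qr.solve(Xs2, Ys[, 2L])
  V <- matrix(0, n, 2)

  keep_n <- length(seq.int(burnIn + thin, nIter, by = thin))
  cols <- c("g11", "g12", "g22", "r11", "r12", "r22", "h2_1", "h2_2", "rg")
  out <- matrix(NA_real_, keep_n, length(cols),
                dimnames = list(NULL, cols))
  ki <- 1L
  for (it in seq_len(nIter)) {
    W <- solve(R)
    Gi <- solve(G)

    # genetic values: independent 2x2 full conditionals per eigenmode
    rho1 <- Ys[, 1L] - drop(Xs1 %*% b1)
    rho2 <- Ys[, 2L] - drop(Xs2 %*% b2)
    a <- W[1, 1] + Gi[1, 1] / lam
    bb <- W[1, 2] + Gi[1, 2] / lam
    cc <- W[2, 2] + Gi[2, 2] / lam
    u1 <- W[1, 1] * rho1 + W[1, 2] * rho2
    u2 <- W[1, 2] * rho1 + W[2, 2] * rho2
    det <- a * cc - bb * bb
    m1 <- (cc * u1 - bb * u2) / det
    m2 <- (a * u2 - bb * u1) / det
    L11 <- sqrt(a); L21 <- bb / L11; L22 <- sqrt(cc - L21 * L21)
    z1 <- rnorm(n); z2 <- rnorm(n)
    x2 <- z2 / L22
    x1 <- (z1 - L21 * x2) / L11
    V[, 1L] <- m1 + x1
    V[, 2L] <- m2 + x2

    # fixed effects: joint draw across traits through R0-inverse
    r1 <- Ys[, 1L] - V[, 1L]
    r2 <- Ys[, 2L] - V[, 2L]
    M <- rbind(cbind(W[1, 1] * X11, W[1, 2] * X12),
               cbind(W[1, 2] * t(X12), W[2, 2] * X22))
    rhs <- c(crossprod(Xs1, W[1, 1] * r1 + W[1, 2] * r2),
             crossprod(Xs2, W[1, 2] * r1 + W[2, 2] * r2))
    Rm <- chol(M)
    bhat <- backsolve(Rm, backsolve(Rm, rhs, transpose = TRUE))
    bb_all <- bhat + backsolve(Rm, rnorm(p1 + p2))
    b1 <- bb_all[seq_len(p1)]
    b2 <- bb_all[p1 + seq_len(p2)]

    # (co)variances: inverse Wishart full conditionals
    Sw <- matrix(c(sum(V[, 1L]^2 / lam), sum(V[, 1L] * V[, 2L] / lam),
                   sum(V[, 1L] * V[, 2L] / lam), sum(V[, 2L]^2 / lam)), 2)
    G <- rInvWishart(nu0 + n, S0g + Sw)
    E <- cbind(Ys[, 1L] - drop(Xs1 %*% b1) - V[, 1L],
               Ys[, 2L] - drop(Xs2 %*% b2) - V[, 2L])
    R <- rInvWishart(nu0 + n, S0r + crossprod(E))

    if (it > burnIn && (it - burnIn) %% thin == 0L) {
      out[ki, ] <- c(G[1, 1], G[1, 2], G[2, 2], R[1, 1], R[1, 2], R[2, 2],
                     G[1, 1] / (G[1, 1] + R[1, 1]),
                     G[2, 2] / (G[2, 2] + R[2, 2]),
                     G[1, 2] / sqrt(G[1, 1] * G[2, 2]))
      ki <- ki + 1L
    }
  }
  trait_names <- colnames(Y)
  if (is.null(trait_names)) trait_names <- c("trait1", "trait2")
  new("GibbsChain", samples = out, model = "bivariate",
      traits = trait_names,
      nIter = as.integer(nIter), burnIn = as.integer(burnIn),
      thin = as.integer(thin), seed = as.integer(seed))
}
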