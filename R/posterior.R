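#' Highest-posterior-density interval
#'
#' The shortest interval containing a `prob` fraction of the sorted
#' samples (empirical HPD). A constant chain collapses to a zero-width
#' interval.
#'
#' @param x numeric samples.
#' @param prob credibility mass (default 0.90).
#' @return named c(lower, upper).
#' @export
hpdInterval <- function(x, prob = 0.90) {
  x <- sort(x)
  n <- length(x)
  stopIfNot(n >= 2L, "need at least two samples for an HPD interval")
  gap <- max(1L, min(n - 1L, round(n * prob)))
  widths <- x[(1L + gap):n] - x[seq_len(n - gap)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + gap])
}

#' Posterior summary of a Gibbs chain
#'
#' Posterior mean, SD and 90% highest-posterior-density interval for
#' every recorded parameter. Heritabilities and genetic correlations
#' were computed per retained sample inside the sampler, so their
#' summaries are summaries of per-sample ratios.
#'
#' @param chain a [GibbsChain-class].
#' @param credibility HPD mass (default 0.90).
#' @return data.frame with `parameter`, `mean`, `sd`, `hpd_lower`,
#'   `hpd_upper`.
#' @export
summarizeChain <- function(chain, credibility = 0.90) {
  stopifnot(is(chain, "GibbsChain"))
  S <- chainSamples(chain)
  stopIfNot(nrow(S) >= 100L,
            "too few retained samples to summarize (need >= 100)")
  rows <- lapply(colnames(S), function(p) {
    h <- hpdInterval(S[, p], credibility)
    data.frame(parameter = p, mean = mean(S[, p]), sd = stats::sd(S[, p]),
               hpd_lower = h[["lower"]], hpd_upper = h[["upper"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' MCMC convergence diagnostics
#'
#' Geweke z-scores (first 10% vs last 50% with spectral-density
#' variance), Heidelberger-Welch stationarity/halfwidth tests, and —
#' when two or more chains with distinct seeds are supplied — the
#' Gelman-Rubin potential scale reduction factor. Computed with the
#' coda package, the standard tool for these tests.
#'
#' @param chain a [GibbsChain-class] (or numeric matrix of samples).
#' @param moreChains optional list of further chains for Gelman-Rubin.
#' @param parameters which columns to diagnose (default all).
#' @return list with `geweke_z` (named vector), `heidelberger`
#'   (data.frame: stationarity pass/fail and p-value per parameter) and
#'   `gelman_rubin` (point PSRF per parameter, or NULL with one chain).
#' @export
chainDiagnostics <- function(chain, moreChains = NULL, parameters = NULL) {
  getS <- function(ch) if (is(ch, "GibbsChain")) chainSamples(ch) else as.matrix(ch)
  S <- getS(chain)
  if (!is.null(parameters)) S <- S[, parameters, drop = FALSE]
  stopIfNot(nrow(S) >= 100L, "chain too short for convergence diagnostics")
  mc <- coda::mcmc(S)

  gw <- coda::geweke.diag(mc, frac1 = 0.1, frac2 = 0.5)$z
  hd <- coda::heidel.diag(mc)
  heid <- data.frame(parameter = colnames(S),
                     stationarity_passed = hd[, "stest"] == 1,
                     p_value = hd[, "pvalue"],
                     stringsAsFactors = FALSE)
  gr <- NULL
  if (!is.null(moreChains) && length(moreChains) >= 1L) {
    ml <- coda::mcmc.list(c(list(mc), lapply(moreChains, function(ch) {
      Si <- getS(ch)
      if (!is.null(parameters)) Si <- Si[, parameters, drop = FALSE]
      coda::mcmc(Si)
    })))
    gr <- coda::gelman.diag(ml, autoburnin = FALSE, multivariate = FALSE)
    gr <- stats::setNames(gr$psrf[, "Point est."], colnames(S))
    # chains with zero between-chain variance (e.g. re-run of the same
    # seed) are perfectly converged; coda's ratio is 0/0 there
    means <- vapply(ml, function(m) colMeans(as.matrix(m)),
                    numeric(ncol(S)))
    zeroB <- apply(matrix(means, nrow = ncol(S)), 1,
                   function(m) stats::var(m) == 0)
    gr[zeroB] <- 1
  }
  list(geweke_z = gw, heidelberger = heid, gelman_rubin = gr)
}
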