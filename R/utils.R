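#' Parse clock times to seconds of day
#'
#' @param x character vector in "HH:MM" or "HH:MM:SS" form.
#' @return integer seconds since midnight.
#' @keywords internal
#' @noRd
parseClock <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- suppressWarnings(as.numeric(p))
    if (length(p) == 2L) p <- c(p, 0)
    if (length(p) != 3L || anyNA(p)) return(NA_real_)
    p[1] * 3600 + p[2] * 60 + p[3]
  }, numeric(1))
}

#' Format seconds of day as HH:MM:SS
#' @keywords internal
#' @noRd
formatClock <- function(s) {
  s <- as.integer(round(s)) %% 86400L
  sprintf("%02d:%02d:%02d", s %/% 3600L, (s %% 3600L) %/% 60L, s %% 60L)
}

#' Sample variance with explicit n-1 denominator
#' @keywords internal
#' @noRd
sampleVar <- function(x) {
  if (length(x) < 2L) return(NA_real_)
  stats::var(x)
}

# Draw from a scaled inverse chi-square full conditional: S / chisq(df).
# With the flat prior (nu = -2, scale 0) df is the data degrees of freedom
# minus 2; callers must ensure df > 0.
rScaledInvChisq <- function(S, df) {
  S / stats::rchisq(1L, df = df)
}

# Draw one matrix from an inverse Wishart IW(df, scale) via the Wishart
# of the inverted scale.
rInvWishart <- function(df, scale) {
  W <- stats::rWishart(1L, df = df, Sigma = solve(scale))[, , 1L]
  solve(W)
}

#' @keywords internal
#' @noRd
stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
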