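#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal
NULL

#' Pedigree of animals with sire and dam links
#'
#' An S4 container for a topologically ordered pedigree. Animals are
#' stored as consecutive integer indices `1..n`; `sire` and `dam` hold
#' the index of each parent or `0L` when the parent is unknown. Parents
#' always precede their offspring, which is what the recursive
#' relationship-matrix algorithms require. Inbreeding coefficients are
#' computed lazily by [inbreeding()] and cached in the `F` slot.
#'
#' @slot id integer animal indices (1..n).
#' @slot sire,dam integer parent indices, 0 = unknown.
#' @slot label character external animal labels (as found in data files).
#' @slot generation integer generation number when the pedigree was
#'   simulated, otherwise `NA`.
#' @slot sex character, "F"/"M" when known.
#' @slot F numeric inbreeding coefficients (NA until computed).
#'
#' @seealso [simulatePedigree()], [makeA()], [buildAInverse()]
#' @export
setClass("Pedigree",
  representation(
    id = "integer",
    sire = "integer",
    dam = "integer",
    label = "character",
    generation = "integer",
    sex = "character",
    F = "numeric"
  )
)

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  msgs <- character(0)
  if (!identical(object@id, seq_len(n)))
    msgs <- c(msgs, "animal ids must be the consecutive integers 1..n")
  if (length(object@sire) != n || length(object@dam) != n)
    msgs <- c(msgs, "sire and dam must have one entry per animal")
  bad <- object@sire > 0L & object@sire >= object@id
  if (any(bad))
    msgs <- c(msgs, "every sire must precede its offspring (topological order)")
  bad <- object@dam > 0L & object@dam >= object@id
  if (any(bad))
    msgs <- c(msgs, "every dam must precede its offspring (topological order)")
  if (any(object@sire < 0L) || any(object@dam < 0L))
    msgs <- c(msgs, "parent codes must be 0 (unknown) or a positive index")
  if (length(object@F) == n && any(!is.na(object@F) &
      (object@F < 0 | object@F >= 1)))
    msgs <- c(msgs, "inbreeding coefficients must lie in [0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Pedigree object
#'
#' @param sire,dam integer parent indices (0 = unknown), parents before
#'   offspring.
#' @param label optional external labels; defaults to `"A<i>"`.
#' @param generation optional integer generation per animal.
#' @param sex optional "F"/"M" per animal.
#' @return a [Pedigree-class] object.
#' @examples
#' trio <- Pedigree(sire = c(0L, 0L, 1L), dam = c(0L, 0L, 2L))
#' makeA(trio)
#' @export
Pedigree <- function(sire, dam, label = NULL, generation = NULL, sex = NULL) {
  n <- length(sire)
  if (is.null(label)) label <- paste0("A", seq_len(n))
  if (is.null(generation)) generation <- rep(NA_integer_, n)
  if (is.null(sex)) sex <- rep(NA_character_, n)
  new("Pedigree",
    id = seq_len(n), sire = as.integer(sire), dam = as.integer(dam),
    label = as.character(label), generation = as.integer(generation),
    sex = as.character(sex), F = rep(NA_real_, n))
}

#' @describeIn Pedigree number of animals
#' @param object,x a Pedigree.
#' @export
nAnimals <- function(object) length(object@id)

#' @describeIn Pedigree parent indices as a data.frame
#' @export
asPedigreeFrame <- function(object) {
  data.frame(
    animal = object@id, sire = object@sire, dam = object@dam,
    label = object@label, generation = object@generation,
    sex = object@sex, stringsAsFactors = FALSE)
}

setMethod("show", "Pedigree", function(object) {
  n <- nAnimals(object)
  founders <- sum(object@sire == 0L & object@dam == 0L)
  cat("Pedigree with", n, "animals (", founders, "founders )\n")
  if (!all(is.na(object@generation)))
    cat("  generations:", paste(range(object@generation, na.rm = TRUE),
        collapse = ".."), "\n")
  if (!anyNA(object@F))
    cat("  mean inbreeding F:", signif(mean(object@F), 4), "\n")
})

#' Retained samples from a Gibbs chain
#'
#' Holds the post burn-in, thinned draws of the variance components of a
#' univariate or bivariate animal model, together with per-sample derived
#' quantities (heritability, genetic correlation). Column layout:
#' univariate chains have `sigma2_a`, `sigma2_e`, `h2`; bivariate chains
#' have the unique elements of G0 and R0 (`g11`, `g12`, `g22`, `r11`,
#' `r12`, `r22`), per-trait heritabilities `h2_1`, `h2_2` and the genetic
#' correlation `rg`.
#'
#' @slot samples numeric matrix, one retained draw per row.
#' @slot model "univariate" or "bivariate".
#' @slot traits character trait names.
#' @slot nIter,burnIn,thin chain settings used.
#' @slot seed integer seed used.
#' @export
setClass("GibbsChain",
  representation(
    samples = "matrix",
    model = "character",
    traits = "character",
    nIter = "integer",
    burnIn = "integer",
    thin = "integer",
    seed = "integer"
  )
)

setValidity("GibbsChain", function(object) {
  msgs <- character(0)
  if (!object@model %in% c("univariate", "bivariate"))
    msgs <- c(msgs, "model must be 'univariate' or 'bivariate'")
  if (object@burnIn >= object@nIter)
    msgs <- c(msgs, "burn-in must be smaller than the chain length")
  if (object@thin < 1L) msgs <- c(msgs, "thin must be >= 1")
  vc <- intersect(colnames(object@samples),
                  c("sigma2_a", "sigma2_e", "g11", "g22", "r11", "r22"))
  if (length(vc) && any(object@samples[, vc] <= 0))
    msgs <- c(msgs, "variance samples must be strictly positive")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn GibbsChain retained samples as a matrix
#' @param object a GibbsChain.
#' @export
chainSamples <- function(object) object@samples

#' @describeIn GibbsChain number of retained samples
#' @export
nRetained <- function(object) nrow(object@samples)

setMethod("show", "GibbsChain", function(object) {
  cat(object@model, "Gibbs chain:", nrow(object@samples),
      "retained samples of", paste(object@traits, collapse = " x "), "\n")
  cat("  iterations", object@nIter, "| burn-in", object@burnIn,
      "| thin", object@thin, "| seed", object@seed, "\n")
  cat("  posterior means:\n")
  print(round(colMeans(object@samples), 4))
})
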