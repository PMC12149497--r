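#' Numerator relationship matrix by the tabular method
#'
#' Builds the dense additive (numerator) relationship matrix A for a
#' topologically ordered pedigree using the classical tabular recursion:
#' the relationship of animal i (with parents s, d) to any older animal j
#' is `0.5 * (A[s, j] + A[d, j])`, and its diagonal is `1 + 0.5 * A[s, d]`
#' (i.e. `1 + F_i`). Unknown parents contribute zero. Intended for
#' pedigrees up to a few thousand animals; the sparse inverse needed by
#' the mixed model is built directly by [buildAInverse()].
#'
#' @param ped a [Pedigree-class] object.
#' @return dense numeric matrix, `nAnimals(ped)` square.
#' @examples
#' trio <- Pedigree(sire = c(0L, 0L, 1L), dam = c(0L, 0L, 2L))
#' makeA(trio)  # offspring-parent entries are 0.5
#' @export
makeA <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  n <- nAnimals(ped)
  s <- ped@sire
  d <- ped@dam
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (si > 0L) row <- row + A[si, j]
      if (di > 0L) row <- row + A[di, j]
      row <- 0.5 * row
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- if (si > 0L && di > 0L) 1 + 0.5 * A[si, di] else 1
  }
  dimnames(A) <- list(ped@label, ped@label)
  A
}

#' Inbreeding coefficients
#'
#' Exact per-animal inbreeding coefficients `F = diag(A) - 1`, computed
#' by the tabular recursion and cached on the returned Pedigree. Founders
#' have `F = 0`.
#'
#' @param ped a [Pedigree-class] object.
#' @return the Pedigree with its `F` slot filled.
#' @export
inbreeding <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  if (!anyNA(ped@F)) return(ped)
  ped@F <- unname(diag(makeA(ped))) - 1
  validObject(ped)
  ped
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Assembles A-inverse directly from the pedigree by Henderson's rules,
#' accounting for inbreeding. For animal i the Mendelian-sampling
#' variance fraction is `0.5 - 0.25 (F_s + F_d)` with both parents known,
#' `0.75 - 0.25 F_p` with one, and 1 with none; its reciprocal `alpha_i`
#' is added at `(i, i)`, `-alpha_i / 2` at each (parent, i) pair, and
#' `alpha_i / 4` between known parents.
#'
#' @param ped a [Pedigree-class] object (topological order enforced by
#'   the class).
#' @return a sparse symmetric [Matrix::dsCMatrix-class].
#' @examples
#' trio <- Pedigree(sire = c(0L, 0L, 1L), dam = c(0L, 0L, 2L))
#' buildAInverse(trio)  # diag 1.5, 1.5, 2; parent-offspring -1
#' @export
buildAInverse <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  ped <- inbreeding(ped)
  n <- nAnimals(ped)
  s <- ped@sire
  d <- ped@dam
  Fi <- ped@F

  Fs <- ifelse(s > 0L, Fi[pmax(s, 1L)], 0)
  Fd <- ifelse(d > 0L, Fi[pmax(d, 1L)], 0)
  both <- s > 0L & d > 0L
  one  <- xor(s > 0L, d > 0L)
  dvar <- ifelse(both, 0.5 - 0.25 * (Fs + Fd),
          ifelse(one, 0.75 - 0.25 * (Fs + Fd), 1))
  alpha <- 1 / dvar

  ii <- list(); jj <- list(); xx <- list()
  add <- function(i, j, x) {
    k <- length(ii) + 1L
    ii[[k]] <<- i; jj[[k]] <<- j; xx[[k]] <<- x
  }
  idx <- seq_len(n)
  add(idx, idx, alpha)
  for (p in list(s, d)) {
    known <- p > 0L
    if (any(known)) {
      add(idx[known], p[known], -alpha[known] / 2)
      add(p[known], idx[known], -alpha[known] / 2)
    }
  }
  if (any(both)) {
    sb <- s[both]; db <- d[both]; ab <- alpha[both]
    add(sb, sb, ab / 4)
    add(db, db, ab / 4)
    add(sb, db, ab / 4)
    add(db, sb, ab / 4)
  }
  Ainv <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = c(n, n), dimnames = list(ped@label, ped@label))
  methods::as(Matrix::forceSymmetric(Ainv), "symmetricMatrix")
}

#' Restrict a pedigree to phenotyped animals and their recent ancestors
#'
#' Keeps the phenotyped animals plus ancestors up to `generations` steps
#' back (a parent is one step). Parents that fall outside the traced set
#' are recoded as unknown, so the result is a self-contained pedigree.
#'
#' @param ped a [Pedigree-class] object.
#' @param phenotyped integer indices (into `ped`) of phenotyped animals.
#' @param generations how many ancestral steps to retain (default 5).
#' @return list with `pedigree` (the traced [Pedigree-class]) and `index`
#'   mapping each kept animal to its position in the original pedigree
#'   (so `index[new] == old`).
#' @export
tracePedigree <- function(ped, phenotyped, generations = 5L) {
  stopifnot(is(ped, "Pedigree"))
  phenotyped <- sort(unique(as.integer(phenotyped)))
  stopIfNot(all(phenotyped >= 1L & phenotyped <= nAnimals(ped)),
            "phenotyped indices outside the pedigree")
  n <- nAnimals(ped)
  depth <- rep(NA_integer_, n)
  depth[phenotyped] <- 0L
  frontier <- phenotyped
  g <- 0L
  while (length(frontier) && g < generations) {
    g <- g + 1L
    parents <- c(ped@sire[frontier], ped@dam[frontier])
    parents <- unique(parents[parents > 0L])
    newly <- parents[is.na(depth[parents])]
    depth[newly] <- g
    frontier <- newly
  }
  keep <- which(!is.na(depth))
  remap <- integer(n)
  remap[keep] <- seq_along(keep)
  sire <- ped@sire[keep]
  dam <- ped@dam[keep]
  sire <- ifelse(sire > 0L & remap[pmax(sire, 1L)] > 0L, remap[pmax(sire, 1L)], 0L)
  dam  <- ifelse(dam  > 0L & remap[pmax(dam, 1L)]  > 0L, remap[pmax(dam, 1L)],  0L)
  out <- Pedigree(sire = as.integer(sire), dam = as.integer(dam),
                  label = ped@label[keep],
                  generation = ped@generation[keep],
                  sex = ped@sex[keep])
  list(pedigree = out, index = keep)
}
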