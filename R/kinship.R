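#' @include AllClasses.R
NULL

#' Kinship coefficients from pedigree structure
#'
#' Standard recursive computation in topological order (parents before
#' children): phi(i,i) = (1 + phi(father_i, mother_i)) / 2 and, for j not a
#' descendant of i, phi(i,j) = (phi(father_i, j) + phi(mother_i, j)) / 2.
#' Founders of a family are treated as mutually unrelated and non-inbred.
#'
#' @param pedigree a \linkS4class{Pedigree} (cyclic pedigrees are rejected by
#'   the class validity check).
#' @return A \linkS4class{KinshipMatrix}, block-diagonal by family.
#' @export
kinshipMatrix <- function(pedigree) {
  m <- pedMembers(pedigree)
  ids <- m$id
  phi <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (fam in unique(m$family)) {
    fm <- m[m$family == fam, ]
    ord <- .topoOrder(fm)
    fm <- fm[ord, ]
    n <- nrow(fm)
    ph <- matrix(0, n, n, dimnames = list(fm$id, fm$id))
    for (i in seq_len(n)) {
      fa <- fm$father[i]; mo <- fm$mother[i]
      if (is.na(fa)) {
        ph[i, i] <- 0.5    # founder: non-inbred, unrelated to prior members
      } else {
        ph[i, i] <- 0.5 * (1 + ph[fa, mo])
        if (i > 1) {
          j <- seq_len(i - 1)
          ph[i, j] <- ph[j, i] <- 0.5 * (ph[fa, j] + ph[mo, j])
        }
      }
    }
    phi[fm$id, fm$id] <- ph
  }
  new("KinshipMatrix", phi = phi,
      family = stats::setNames(m$family, m$id))
}

#' Haldane map function
#'
#' Converts inter-marker distance d (Morgans) to recombination fraction
#' theta = (1 - exp(-2 d)) / 2.
#'
#' @param d numeric vector of distances in Morgans, d >= 0.
#' @return theta in [0, 0.5).
#' @export
haldaneTheta <- function(d) {
  if (any(d < 0)) stop("map distance must be non-negative")
  0.5 * (1 - exp(-2 * d))
}
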