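#' @importFrom methods new validObject is setClass setValidity show slot
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Pedigree: family structures for one or more families
#'
#' Holds per-individual family membership, parental links and sex for a set of
#' independent families. Individual identifiers are globally unique; parents
#' are either both named (and present in the same family) or both missing
#' (founder). Pedigrees must be acyclic and free of inbreeding loops at
#' construction time (loops are rejected downstream where they matter).
#'
#' @slot members data.frame with columns \code{family}, \code{id},
#'   \code{father}, \code{mother} (\code{NA} for founders) and \code{sex}
#'   (one of \code{"male"}, \code{"female"}, \code{"unknown"}).
#' @export
setClass("Pedigree", representation(members = "data.frame"))

.validPedigree <- function(object) {
  m <- object@members
  need <- c("family", "id", "father", "mother", "sex")
  if (!all(need %in% names(m)))
    return(paste("members must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(m$id))
    return(sprintf("duplicated individual id: %s",
                   paste(unique(m$id[duplicated(m$id)]), collapse = ", ")))
  if (!all(m$sex %in% c("male", "female", "unknown")))
    return("sex must be male/female/unknown")
  one <- is.na(m$father) != is.na(m$mother)
  if (any(one))
    return(sprintf("individuals with exactly one named parent: %s",
                   paste(m$id[one], collapse = ", ")))
  for (fam in unique(m$family)) {
    fm <- m[m$family == fam, ]
    nf <- !is.na(fm$father)
    if (!all(fm$father[nf] %in% fm$id) || !all(fm$mother[nf] %in% fm$id))
      return(sprintf("family %s names parents absent from the family", fam))
    if (any(fm$father[nf] == fm$id[nf] | fm$mother[nf] == fm$id[nf]))
      return(sprintf("family %s: individual is its own parent", fam))
    ## sex consistency where known
    pa <- fm$sex[match(fm$father[nf], fm$id)]
    mo <- fm$sex[match(fm$mother[nf], fm$id)]
    if (any(pa == "female") || any(mo == "male"))
      return(sprintf("family %s: parent sex inconsistent with role", fam))
    if (is.null(.topoOrder(fm)))
      return(sprintf("family %s: pedigree is cyclic", fam))
  }
  TRUE
}
setValidity("Pedigree", .validPedigree)

## Topological order (parents before children); NULL if cyclic.
.topoOrder <- function(fm) {
  n <- nrow(fm)
  placed <- rep(FALSE, n)
  ord <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(fm$father) | fm$father %in% fm$id[placed]) &
      (is.na(fm$mother) | fm$mother %in% fm$id[placed])
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (all(placed)) ord else NULL
}

#' GenotypeData: marker genotypes for pedigree members
#'
#' Extends \linkS4class{SummarizedExperiment}: rows are biallelic markers
#' (rowData columns \code{chrom}, \code{bp}, \code{cM}, \code{a1}, \code{a2}),
#' columns are individuals (colData column \code{family}), and the single
#' assay \code{"dosage"} counts copies of allele \code{a2} (0/1/2, \code{NA}
#' for missing). Genetic positions must be non-decreasing within chromosome.
#'
#' @export
setClass("GenotypeData", contains = "SummarizedExperiment")

.validGenotypeData <- function(object) {
  rd <- SummarizedExperiment::rowData(object)
  need <- c("chrom", "bp", "cM", "a1", "a2")
  if (!all(need %in% names(rd)))
    return(paste("rowData must have columns", paste(need, collapse = ", ")))
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dosage' is required")
  if (!"family" %in% names(SummarizedExperiment::colData(object)))
    return("colData must have a 'family' column")
  d <- SummarizedExperiment::assay(object, "dosage")
  if (!all(d[!is.na(d)] %in% 0:2))
    return("dosage must be 0, 1, 2 or NA")
  for (ch in unique(rd$chrom)) {
    cm <- rd$cM[rd$chrom == ch]
    if (is.unsorted(cm)) return(sprintf("cM not non-decreasing on chromosome %s", ch))
  }
  TRUE
}
setValidity("GenotypeData", .validGenotypeData)

#' KinshipMatrix: expected relatedness from pedigree structure
#'
#' Symmetric matrix of kinship coefficients, block-diagonal by family;
#' diagonal 0.5 for non-inbred individuals, and 2*Phi positive semi-definite.
#'
#' @slot phi symmetric numeric matrix with individual ids as dimnames.
#' @slot family named character vector mapping individual id to family.
#' @export
setClass("KinshipMatrix", representation(phi = "matrix", family = "character"))

.validKinship <- function(object) {
  phi <- object@phi
  if (is.null(rownames(phi)) || !identical(rownames(phi), colnames(phi)))
    return("phi must have matching row/col names")
  if (max(abs(phi - t(phi))) > 1e-12) return("phi must be symmetric")
  if (any(diag(phi) < 0.5 - 1e-12)) return("diagonal kinship below 0.5")
  fam <- object@family[rownames(phi)]
  off <- outer(fam, fam, "!=") & abs(phi) > 1e-12
  if (any(off)) return("nonzero kinship between families")
  ev <- eigen(2 * phi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) return("2*phi is not positive semi-definite")
  TRUE
}
setValidity("KinshipMatrix", .validKinship)

#' IBDResult: multipoint expected IBD sharing along a chromosome
#'
#' @slot positions data.frame with columns \code{chrom}, \code{cM},
#'   \code{marker} (marker id or \code{NA} for grid positions).
#' @slot pairs data.frame with columns \code{family}, \code{id1}, \code{id2}
#'   (all within-family unordered pairs).
#' @slot pihat numeric matrix, pairs x positions, expected proportion of
#'   alleles shared identical-by-descent.
#' @slot method character, "exact" or "mc" per family.
#' @export
setClass("IBDResult", representation(positions = "data.frame",
                                     pairs = "data.frame",
                                     pihat = "matrix",
                                     method = "character"))

setValidity("IBDResult", function(object) {
  if (nrow(object@pihat) != nrow(object@pairs)) return("pihat rows != pairs")
  if (ncol(object@pihat) != nrow(object@positions)) return("pihat cols != positions")
  p <- object@pihat
  if (any(p < -1e-9 | p > 1 + 1e-9, na.rm = TRUE)) return("pihat outside [0,1]")
  TRUE
})

#' LinkageCurve: LOD scores along a chromosome
#'
#' @slot scan data.frame with columns \code{chrom}, \code{cM}, \code{lod}
#'   (boundary-clipped, >= 0) and \code{rawLod} (signed log10 LR before
#'   clipping; equals the sum of per-family contributions).
#' @slot perFamily numeric matrix, positions x families, per-family log10
#'   likelihood-ratio contributions evaluated at the overall MLEs.
#' @slot vc numeric matrix, positions x 3, columns sigma2Q, sigma2G, sigma2E
#'   (alternative-model MLEs).
#' @export
setClass("LinkageCurve", representation(scan = "data.frame",
                                        perFamily = "matrix",
                                        vc = "matrix"))

#' MixedModelFit: single-variant family-based association fit
#'
#' Linear mixed model y = X alpha + g beta1 + delta + eps with
#' delta ~ N(0, 2 Phi sigma2G) and eps ~ N(0, I sigma2E), likelihood-ratio
#' tested for beta1 = 0 (maximum likelihood, chi-square with 1 df).
#'
#' @export
setClass("MixedModelFit", representation(beta = "numeric", beta1 = "numeric",
                                         se1 = "numeric",
                                         sigma2G = "numeric", sigma2E = "numeric",
                                         logLikNull = "numeric", logLikAlt = "numeric",
                                         lrt = "numeric", p = "numeric",
                                         carrierCounts = "numeric", n = "integer"))

#' GeneSetResult: burden / SKAT / SKAT-O result for a variant set
#'
#' @slot statistic named numeric (entries among burden, skat, skato).
#' @slot p named numeric p-values.
#' @slot lambda mixture-of-chi-square eigenvalues of the SKAT kernel.
#' @slot rho numeric grid of burden/SKAT mixing weights.
#' @slot rhoP per-rho p-values (score form except where documented).
#' @slot weights per-variant weights used.
#' @slot nVariants integer.
#' @export
setClass("GeneSetResult", representation(statistic = "numeric", p = "numeric",
                                         lambda = "numeric", rho = "numeric",
                                         rhoP = "numeric", weights = "numeric",
                                         nVariants = "integer"))

#' LodDropNull: empirical null for the conditional-linkage LOD drop
#'
#' @slot observed observed MLOD drop when conditioning on the risk score.
#' @slot nullDrops MLOD drops from conditioning on resampled off-region SNPs.
#' @slot p add-one empirical p-value (1 + #\{null >= observed\}) / (1 + N).
#' @export
setClass("LodDropNull", representation(observed = "numeric",
                                       nullDrops = "numeric", p = "numeric"))
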