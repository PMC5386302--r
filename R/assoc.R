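#' @include AllClasses.R vcfit.R
NULL

#' Single-variant family-based association (linear mixed model)
#'
#' Fits y = beta0 + covariates + beta1 g + delta + eps by maximum likelihood,
#' with delta ~ N(0, 2 Phi sigma2G) and eps ~ N(0, I sigma2E), and tests
#' H0: beta1 = 0 by the likelihood-ratio test (chi-square, 1 df). ML (not
#' REML) is used for both models so the LRT is valid. Individuals with a
#' missing genotype are dropped for that variant.
#'
#' @param trait named numeric vector.
#' @param g named dosage vector (0/1/2 copies of the minor allele).
#' @param kinship a \linkS4class{KinshipMatrix}.
#' @param covariates optional matrix/data.frame with id rownames.
#' @param nStarts optimizer starts.
#' @return A \linkS4class{MixedModelFit}.
#' @export
fitLmmAssoc <- function(trait, g, kinship, covariates = NULL, nStarts = 3) {
  if (is.null(names(g))) stop("g must be a named dosage vector")
  ids <- intersect(names(trait)[!is.na(trait)], names(g)[!is.na(g)])
  trait <- trait[ids]
  if (length(unique(g[ids])) < 2) stop("monomorphic variant")
  cv <- cbind(if (!is.null(covariates)) as.matrix(covariates)[ids, , drop = FALSE],
              g = g[ids])
  rownames(cv) <- ids
  datA <- .vcData(trait, kinship, cv)
  dat0 <- .vcData(trait, kinship,
                  if (is.null(covariates)) NULL
                  else as.matrix(covariates)[ids, , drop = FALSE])
  alt <- .vcFit(vcBuild(datA$yl, datA$Xl, datA$K1l), 1L, colnames(datA$X),
                nStarts = nStarts)
  null <- .vcFit(vcBuild(dat0$yl, dat0$Xl, dat0$K1l), 1L, colnames(dat0$X),
                 nStarts = nStarts)
  lrt <- max(0, 2 * (alt$ll - null$ll))
  covB <- alt$sigma2 * solve(alt$XtVX)
  j <- ncol(datA$X)
  cc <- familyCarrierCounts(g[ids], kinship)
  new("MixedModelFit", beta = alt$beta, beta1 = unname(alt$beta[j]),
      se1 = sqrt(covB[j, j]),
      sigma2G = alt$sigma2G, sigma2E = alt$sigma2,
      logLikNull = null$ll, logLikAlt = alt$ll,
      lrt = lrt, p = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
      carrierCounts = cc, n = length(datA$ids))
}

#' Per-family carrier counts for a variant
#'
#' Counts individuals with dosage >= 1 in each family (a homozygous carrier
#' counts once).
#'
#' @param g named dosage vector (0/1/2).
#' @param kinship a \linkS4class{KinshipMatrix} (or a \linkS4class{Pedigree})
#'   supplying the id-to-family map.
#' @return named integer vector over all families.
#' @export
familyCarrierCounts <- function(g, kinship) {
  fam <- if (is(kinship, "Pedigree")) {
    m <- pedMembers(kinship); stats::setNames(m$family, m$id)
  } else kinship@family
  ids <- intersect(names(g), names(fam))
  counts <- stats::setNames(integer(length(unique(fam))), unique(fam))
  carriers <- table(fam[ids[!is.na(g[ids]) & g[ids] >= 1]])
  counts[names(carriers)] <- as.integer(carriers)
  counts
}
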