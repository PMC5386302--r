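#' @include AllClasses.R
NULL

#' Accessors for pedscan classes
#'
#' \code{pedMembers} returns the member table of a \linkS4class{Pedigree};
#' \code{famIDs} the family identifiers; \code{founderIDs} the founder ids;
#' \code{bitComplexity} the per-family founder-reduced complexity
#' 2*nonfounders - founders (the unreduced meiosis-bit count, which governs
#' the exact HMM state space, is 2*nonfounders); \code{phiMatrix} the kinship
#' coefficient matrix; \code{maxLOD} and \code{peakPosition} summarize a
#' \linkS4class{LinkageCurve}.
#'
#' @param x a pedscan object.
#' @param ... unused.
#' @name accessors
#' @aliases pedMembers famIDs founderIDs bitComplexity phiMatrix maxLOD peakPosition
NULL

#' @rdname accessors
#' @export
setGeneric("pedMembers", function(x) standardGeneric("pedMembers"))
#' @rdname accessors
#' @export
setGeneric("famIDs", function(x) standardGeneric("famIDs"))
#' @rdname accessors
#' @export
setGeneric("founderIDs", function(x, ...) standardGeneric("founderIDs"))
#' @rdname accessors
#' @export
setGeneric("bitComplexity", function(x) standardGeneric("bitComplexity"))
#' @rdname accessors
#' @export
setGeneric("phiMatrix", function(x) standardGeneric("phiMatrix"))
#' @rdname accessors
#' @export
setGeneric("maxLOD", function(x) standardGeneric("maxLOD"))
#' @rdname accessors
#' @export
setGeneric("peakPosition", function(x) standardGeneric("peakPosition"))

#' @rdname accessors
#' @export
setMethod("pedMembers", "Pedigree", function(x) x@members)

#' @rdname accessors
#' @export
setMethod("famIDs", "Pedigree", function(x) unique(x@members$family))

#' @rdname accessors
#' @param family optional family id; default all families.
#' @export
setMethod("founderIDs", "Pedigree", function(x, family = NULL) {
  m <- x@members
  if (!is.null(family)) m <- m[m$family %in% family, ]
  m$id[is.na(m$father)]
})

#' @rdname accessors
#' @export
setMethod("bitComplexity", "Pedigree", function(x) {
  m <- x@members
  vapply(split(m, m$family), function(fm) {
    nf <- sum(!is.na(fm$father))
    f <- sum(is.na(fm$father))
    2L * nf - f
  }, integer(1))
})

#' @rdname accessors
#' @export
setMethod("phiMatrix", "KinshipMatrix", function(x) x@phi)

#' @rdname accessors
#' @export
setMethod("maxLOD", "LinkageCurve", function(x) max(x@scan$lod))

#' @rdname accessors
#' @export
setMethod("peakPosition", "LinkageCurve", function(x) {
  i <- which.max(x@scan$lod)   # leftmost maximum
  x@scan$cM[i]
})

setMethod("show", "Pedigree", function(object) {
  m <- object@members
  cat(sprintf("Pedigree: %d individuals in %d families (%d founders)\n",
              nrow(m), length(unique(m$family)), sum(is.na(m$father))))
  bc <- bitComplexity(object)
  cat(sprintf("  family sizes %d-%d; bit-complexity (2n-f) %d-%d\n",
              min(table(m$family)), max(table(m$family)), min(bc), max(bc)))
})

setMethod("show", "GenotypeData", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  cat(sprintf("GenotypeData: %d markers x %d individuals on %d chromosome(s)\n",
              nrow(object), ncol(object), length(unique(rd$chrom))))
  callNextMethod()
})

setMethod("show", "KinshipMatrix", function(object) {
  cat(sprintf("KinshipMatrix: %d individuals, %d families\n",
              nrow(object@phi), length(unique(object@family))))
})

setMethod("show", "IBDResult", function(object) {
  cat(sprintf("IBDResult: %d pairs x %d positions (%s)\n",
              nrow(object@pairs), nrow(object@positions),
              paste(unique(object@method), collapse = "/")))
})

setMethod("show", "LinkageCurve", function(object) {
  cat(sprintf("LinkageCurve: %d positions, MLOD %.3f at %.1f cM\n",
              nrow(object@scan), maxLOD(object), peakPosition(object)))
})

setMethod("show", "MixedModelFit", function(object) {
  cat(sprintf("MixedModelFit: beta1 = %.3f (SE %.3f), LRT = %.3f, p = %.3g, n = %d\n",
              object@beta1, object@se1, object@lrt, object@p, object@n))
})

setMethod("show", "GeneSetResult", function(object) {
  cat(sprintf("GeneSetResult: %d variants\n", object@nVariants))
  for (k in names(object@p))
    cat(sprintf("  %-6s Q = %10.4f  p = %.4g\n", k, object@statistic[k], object@p[k]))
})

setMethod("show", "LodDropNull", function(object) {
  cat(sprintf("LodDropNull: observed drop %.3f vs %d null drops (max %.3f), empirical p = %.4g\n",
              object@observed, length(object@nullDrops),
              max(object@nullDrops), object@p))
})
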