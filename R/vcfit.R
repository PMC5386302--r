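#' @useDynLib pedscan, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @include AllClasses.R
NULL

## ---- internal variance-component ML machinery -------------------------------
##
## The model is y = X alpha + delta + (qtl) + eps with block-diagonal
## covariance sigma2 * (I + gamma1 * 2Phi + gamma2 * Pi). Fixed effects and
## sigma2 are profiled analytically in C++ (vcProfileNll); ML is a bounded
## quasi-Newton search over the variance ratios gamma >= 0.

## Align trait/covariates/kinship into per-family blocks.
.vcData <- function(trait, kinship, covariates = NULL) {
  ids <- names(trait)
  if (is.null(ids)) stop("trait must be a named vector (individual ids)")
  phi <- phiMatrix(kinship)
  ids <- ids[!is.na(trait[ids])]
  ids <- intersect(ids, rownames(phi))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(rownames(covariates)))
      stop("covariates must have individual ids as rownames")
    ids <- intersect(ids, rownames(covariates)[stats::complete.cases(covariates)])
    X <- cbind(`(Intercept)` = 1, covariates[ids, , drop = FALSE])
  } else {
    X <- matrix(1, length(ids), 1, dimnames = list(ids, "(Intercept)"))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("design is rank deficient; collinear columns: ",
         paste(colnames(X)[qrX$pivot[-seq_len(qrX$rank)]], collapse = ", "))
  fam <- kinship@family[ids]
  famLevels <- unique(fam)
  y <- trait[ids]
  list(ids = ids, fam = fam, famLevels = famLevels,
       yl = lapply(famLevels, function(f) unname(y[fam == f])),
       Xl = lapply(famLevels, function(f) X[fam == f, , drop = FALSE]),
       K1l = lapply(famLevels, function(f) 2 * phi[fam == f, fam == f, drop = FALSE]),
       X = X)
}

## ML fit over gamma (length 1 or 2) on a model built by vcBuild (K2 blocks,
## when used, must have been set with vcSetK2). Returns profiled quantities.
## Standalone fits use nStarts deterministic starts; a warm start (e.g. the
## neighbouring scan position's solution) is tried first and, when present,
## only one fresh start is added.
.vcFit <- function(model, nK, xnames, warmStart = NULL, nStarts = 3) {
  cache <- new.env(parent = emptyenv())
  evalAt <- function(par) {
    key <- paste(format(par, digits = 17), collapse = ",")
    if (!is.null(cache$key) && identical(cache$key, key)) return(cache$val)
    val <- vcEval(model, par, nK, FALSE)
    cache$key <- key; cache$val <- val
    val
  }
  starts <- if (nK == 1) list(0.1, 1, 3) else list(c(0.5, 0.2), c(0.1, 0.02), c(2, 1))
  starts <- starts[seq_len(min(nStarts, length(starts)))]
  if (!is.null(warmStart))
    starts <- c(list(pmin(pmax(warmStart, 0), 100)), starts[1])
  best <- NULL
  for (s in starts) {
    o <- try(stats::optim(s, fn = function(p) evalAt(p)$nll,
                          gr = function(p) evalAt(p)$grad,
                          method = "L-BFGS-B", lower = rep(0, nK),
                          upper = rep(200, nK),
                          control = list(factr = 1e7)), silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("variance-component optimization failed to converge")
  fin <- vcEval(model, best$par, nK, TRUE)
  list(gamma = best$par, ll = fin$ll, llFam = as.numeric(fin$llFam),
       beta = stats::setNames(as.numeric(fin$beta), xnames),
       sigma2 = fin$sigma2,
       sigma2G = fin$sigma2 * best$par[1],
       sigma2Q = if (nK == 2) fin$sigma2 * best$par[2] else 0,
       XtVX = fin$XtVX, convergence = best$convergence)
}

## Per-family Pi matrices (diagonal 1, pairwise expected IBD off-diagonal;
## singleton families get the 1x1 matrix 1), prebuilt for a set of position
## indices so that repeated (conditional) scans can share them.
.piCache <- function(ibd, idx, famLevels, fam, ids) {
  pr <- ibd@pairs
  prep <- lapply(famLevels, function(f) {
    fids <- ids[fam == f]
    sel <- which(pr$family == f & pr$id1 %in% fids & pr$id2 %in% fids)
    i <- match(pr$id1[sel], fids); j <- match(pr$id2[sel], fids)
    list(n = length(fids), rows = sel, i = i, j = j)
  })
  lapply(idx, function(t) {
    ph <- ibd@pihat[, t]
    lapply(prep, function(p) {
      P <- diag(1, p$n)
      P[cbind(p$i, p$j)] <- P[cbind(p$j, p$i)] <- ph[p$rows]
      P
    })
  })
}

#' Variance-component linkage scan
#'
#' At every position, maximizes the multivariate-normal likelihood with
#' covariance Pi sigma2Q + 2 Phi sigma2G + I sigma2E (alternative) and with
#' sigma2Q = 0 (null, position-independent), both by maximum likelihood with
#' fixed effects profiled. LOD = (logL_alt - logL_null) / ln 10, clipped at 0
#' (one-sided boundary test); when the sigma2Q MLE is 0 the alternative
#' reduces to the null and the LOD is exactly 0. Per-family LOD contributions
#' are each family's log10 likelihood-ratio evaluated at the overall MLEs and
#' sum to the (unclipped) total.
#'
#' @param trait named numeric vector (typically a residualized trait).
#' @param kinship a \linkS4class{KinshipMatrix}.
#' @param ibd an \linkS4class{IBDResult} for the chromosome scanned.
#' @param covariates optional numeric matrix/data.frame with id rownames,
#'   absorbed into the fixed effects of both models.
#' @param positions optional numeric cM positions (subset of the IBD grid);
#'   default: all IBD positions.
#' @param nStarts optimizer starts per position (plus a warm start from the
#'   neighbouring position).
#' @param piCache prebuilt per-position Pi blocks from an earlier scan over
#'   the same positions and individuals (internal optimization for repeated
#'   conditional scans); normally left NULL.
#' @param nullWarm optional warm start (gamma) for the null fit.
#' @return A \linkS4class{LinkageCurve}.
#' @export
vcLinkageScan <- function(trait, kinship, ibd, covariates = NULL,
                          positions = NULL, nStarts = 3, piCache = NULL,
                          nullWarm = NULL) {
  dat <- .vcData(trait, kinship, covariates)
  posTab <- ibd@positions
  if (is.null(positions)) {
    idx <- seq_len(nrow(posTab))
  } else {
    idx <- match(positions, posTab$cM)
    if (anyNA(idx)) stop("positions not on the IBD grid: ",
                         paste(positions[is.na(idx)], collapse = ", "))
  }
  model <- vcBuild(dat$yl, dat$Xl, dat$K1l)
  null <- .vcFit(model, 1L, colnames(dat$X), warmStart = nullWarm,
                 nStarts = nStarts)
  if (is.null(piCache))
    piCache <- .piCache(ibd, idx, dat$famLevels, dat$fam, dat$ids)
  nPos <- length(idx)
  lod <- raw <- numeric(nPos)
  perFam <- matrix(0, nPos, length(dat$famLevels),
                   dimnames = list(NULL, dat$famLevels))
  vc <- matrix(NA_real_, nPos, 3,
               dimnames = list(NULL, c("sigma2Q", "sigma2G", "sigma2E")))
  warm <- NULL
  for (t in seq_len(nPos)) {
    vcSetK2(model, piCache[[t]])
    alt <- tryCatch(.vcFit(model, 2L, colnames(dat$X),
                           warmStart = warm, nStarts = nStarts),
                    error = function(e) NULL)
    if (is.null(alt)) {
      warning(sprintf("non-convergence at %.2f cM; LOD set to NA",
                      posTab$cM[idx[t]]))
      lod[t] <- raw[t] <- NA_real_
      next
    }
    warm <- alt$gamma
    if (alt$ll < null$ll || alt$gamma[2] == 0) {
      ## boundary: sigma2Q = 0 is the MLE; alternative equals the null
      raw[t] <- 0; lod[t] <- 0
      perFam[t, ] <- 0
      vc[t, ] <- c(0, null$sigma2 * null$gamma[1], null$sigma2)
    } else {
      raw[t] <- (alt$ll - null$ll) / log(10)
      lod[t] <- max(raw[t], 0)
      perFam[t, ] <- (alt$llFam - null$llFam) / log(10)
      vc[t, ] <- c(alt$sigma2Q, alt$sigma2G, alt$sigma2)
    }
  }
  scan <- data.frame(chrom = posTab$chrom[idx], cM = posTab$cM[idx],
                     lod = lod, rawLod = raw, stringsAsFactors = FALSE)
  new("LinkageCurve", scan = scan, perFamily = perFam, vc = vc)
}

#' Conditional linkage scan
#'
#' Re-runs \code{\link{vcLinkageScan}} with an extra covariate (e.g. a
#' genotype risk score) absorbed into the fixed effects of both the null and
#' alternative models. A constant covariate carries no information and is
#' dropped with a warning, reproducing the unconditional curve; a covariate
#' collinear with the existing design is an error.
#'
#' @inheritParams vcLinkageScan
#' @param covariate named numeric vector, aligned by individual id.
#' @param baseline optional unconditional \linkS4class{LinkageCurve}; when
#'   given, the MLOD drop (max baseline LOD minus max conditional LOD over
#'   the scanned positions) is attached as attribute \code{"mlodDrop"}.
#' @return A \linkS4class{LinkageCurve}.
#' @export
conditionalScan <- function(trait, kinship, ibd, covariate, covariates = NULL,
                            positions = NULL, baseline = NULL, nStarts = 3,
                            piCache = NULL, nullWarm = NULL) {
  if (is.null(names(covariate)))
    stop("covariate must be a named vector (individual ids)")
  ids <- intersect(names(trait), names(covariate))
  if (stats::sd(covariate[ids]) == 0) {
    warning("constant conditioning covariate carries no information; dropped")
    cv <- covariates
  } else {
    cv <- cbind(if (!is.null(covariates)) as.matrix(covariates)[ids, , drop = FALSE],
                score = covariate[ids])
    rownames(cv) <- ids
    if (qr(cbind(1, cv))$rank < ncol(cv) + 1)
      stop("conditioning covariate is collinear with existing covariates")
  }
  curve <- vcLinkageScan(trait, kinship, ibd, covariates = cv,
                         positions = positions, nStarts = nStarts,
                         piCache = piCache, nullWarm = nullWarm)
  if (!is.null(baseline)) {
    base <- baseline@scan
    sel <- base$cM %in% curve@scan$cM
    attr(curve, "mlodDrop") <- max(base$lod[sel]) - max(curve@scan$lod)
  }
  curve
}

#' Candidate region from a linkage curve (2-LOD support interval)
#'
#' Extends from the (leftmost) peak in both directions until the LOD falls
#' 2 below the maximum (crossing located by linear interpolation between
#' grid points) or the chromosome end is reached; an interval narrower than
#' \code{targetWidthcM} is widened symmetrically to that width, clipped at
#' the chromosome ends.
#'
#' @param curve a \linkS4class{LinkageCurve}.
#' @param targetWidthcM minimum region width (default 20 cM).
#' @param drop LOD drop defining the support interval (default 2).
#' @return list with elements \code{chrom}, \code{lo}, \code{hi} (cM).
#' @export
region2LOD <- function(curve, targetWidthcM = 20, drop = 2) {
  sc <- curve@scan
  if (max(sc$lod, na.rm = TRUE) <= 0) stop("no peak: flat linkage curve")
  i <- which.max(sc$lod)
  thr <- sc$lod[i] - drop
  cross <- function(dir) {
    j <- i
    repeat {
      k <- j + dir
      if (k < 1 || k > nrow(sc)) return(sc$cM[j])   # chromosome end
      if (!is.na(sc$lod[k]) && sc$lod[k] < thr) {
        ## linear interpolation for the crossing point
        frac <- (sc$lod[j] - thr) / (sc$lod[j] - sc$lod[k])
        return(sc$cM[j] + frac * (sc$cM[k] - sc$cM[j]))
      }
      j <- k
    }
  }
  lo <- cross(-1L); hi <- cross(+1L)
  if (hi - lo < targetWidthcM) {
    mid <- (hi + lo) / 2
    lo <- mid - targetWidthcM / 2
    hi <- mid + targetWidthcM / 2
    lo <- max(lo, min(sc$cM)); hi <- min(hi, max(sc$cM))
  }
  list(chrom = unique(sc$chrom)[1], lo = lo, hi = hi)
}
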