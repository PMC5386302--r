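#' @include AllClasses.R vcfit.R assoc.R
NULL

#' Beta(1,25) rare-variant weights
#'
#' w_j = Beta-density(MAF_j; 1, 25) = 25 (1 - MAF_j)^24, up-weighting rarer
#' variants. A MAF above 0.5 suggests the counted allele is not the minor
#' allele and triggers a warning.
#'
#' @param maf numeric vector of minor allele frequencies in [0, 1).
#' @return numeric weights in (0, 25].
#' @export
betaWeights <- function(maf) {
  if (any(maf < 0 | maf >= 1)) stop("MAF must be in [0, 1)")
  if (any(maf >= 0.5))
    warning("MAF >= 0.5: allele flip suspected for some variants")
  25 * (1 - maf)^24
}

#' Tail probability of a mixture of chi-square(1) variables
#'
#' P(sum_k lambda_k chi2_1 > q). Default: Liu-Tang-Zhang moment matching,
#' refined by a Kuonen saddlepoint approximation when the matched p falls
#' below 1e-3 (where moment matching degrades).
#'
#' @param q observed statistic.
#' @param lambda non-negative mixture weights (eigenvalues).
#' @param method "auto" (default), "liu" or "saddlepoint".
#' @return upper-tail probability in (0, 1].
#' @export
pchisqMixture <- function(q, lambda, method = c("auto", "liu", "saddlepoint")) {
  method <- match.arg(method)
  lambda <- lambda[lambda > max(lambda) * 1e-12]
  if (length(lambda) == 1)
    return(stats::pchisq(q / lambda, df = 1, lower.tail = FALSE))
  p <- .pLiuMod(q, lambda)
  if (method == "liu") return(p)
  if (method == "saddlepoint" || (method == "auto" && p < 1e-3)) {
    ps <- .pSaddle(q, lambda)
    if (!is.na(ps)) p <- ps
  }
  min(max(p, .Machine$double.xmin), 1)
}

## Liu-Tang-Zhang (modified) moment matching to a noncentral chi-square.
.pLiuMod <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2); c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2; a <- sqrt(l); d <- 0
  }
  muQ <- c1; sigmaQ <- sqrt(2 * c2)
  muX <- l + d; sigmaX <- sqrt(2) * a
  stats::pchisq((q - muQ) / sigmaQ * sigmaX + muX, df = l, ncp = d,
                lower.tail = FALSE)
}

## Kuonen saddlepoint approximation for sum lambda_k chi2_1.
.pSaddle <- function(q, lambda) {
  mu <- sum(lambda)
  if (q <= mu) return(NA_real_)  # saddlepoint unstable at the mean; caller keeps Liu
  K <- function(z) -0.5 * sum(log(1 - 2 * z * lambda))
  K1 <- function(z) sum(lambda / (1 - 2 * z * lambda))
  K2 <- function(z) 2 * sum(lambda^2 / (1 - 2 * z * lambda)^2)
  up <- 1 / (2 * max(lambda))
  zhat <- tryCatch(stats::uniroot(function(z) K1(z) - q,
                                  lower = -100, upper = up - 1e-10,
                                  tol = 1e-12)$root,
                   error = function(e) NA_real_)
  if (is.na(zhat)) return(NA_real_)
  w <- sign(zhat) * sqrt(2 * (zhat * q - K(zhat)))
  v <- zhat * sqrt(K2(zhat))
  if (abs(w) < 1e-6) return(NA_real_)
  stats::pnorm(w + log(v / w) / w, lower.tail = FALSE)
}

## Shared null-model pieces for the score-type set tests:
## Vhat = 2 Phi s2G + I s2E from the covariates-only LMM; P = Vi - ViX(X'ViX)^-1X'Vi.
.skatNull <- function(trait, kinship, covariates, nStarts = 3) {
  dat <- .vcData(trait, kinship, covariates)
  fit <- .vcFit(vcBuild(dat$yl, dat$Xl, dat$K1l), 1L, colnames(dat$X),
                nStarts = nStarts)
  ids <- dat$ids
  phi <- phiMatrix(kinship)[ids, ids]
  V <- fit$sigma2 * (diag(length(ids)) + fit$gamma[1] * 2 * phi)
  Vi <- chol2inv(chol(V))
  X <- dat$X
  ViX <- Vi %*% X
  P <- Vi - ViX %*% solve(crossprod(X, ViX), t(ViX))
  y <- trait[ids]
  list(ids = ids, P = P, Py = as.numeric(P %*% y), fit = fit, dat = dat)
}

.alignG <- function(G, ids) {
  if (is.null(rownames(G))) stop("G must have individual ids as rownames")
  miss <- setdiff(ids, rownames(G))
  if (length(miss)) stop("genotype block lacks individuals: ",
                         paste(miss, collapse = ", "))
  G <- as.matrix(G)[ids, , drop = FALSE]
  G[is.na(G)] <- 0
  G
}

#' Family-based burden test
#'
#' Collapses the variant block into the weighted score b_i = sum_j w_j g_ij
#' and tests it as a single covariate in the mixed model of
#' \code{\link{fitLmmAssoc}} (likelihood-ratio test). For a single-variant
#' set the p-value coincides with the single-variant mixed-model p.
#'
#' @param trait named numeric vector.
#' @param G dosage matrix, individuals x variants, id rownames.
#' @param weights per-variant weights (default \code{\link{betaWeights}} on
#'   the observed MAFs).
#' @param kinship a \linkS4class{KinshipMatrix}.
#' @param covariates optional matrix with id rownames.
#' @param nStarts optimizer starts.
#' @return A \linkS4class{GeneSetResult} with the burden entry.
#' @export
burdenTest <- function(trait, G, weights = NULL, kinship, covariates = NULL,
                       nStarts = 3) {
  ids <- intersect(names(trait)[!is.na(trait)], rownames(G))
  G <- .alignG(G, ids)
  poly <- apply(G, 2, function(x) length(unique(x)) > 1)
  if (!any(poly)) stop("all variants monomorphic")
  if (is.null(weights)) weights <- betaWeights(colMeans(G) / 2)
  b <- stats::setNames(as.numeric(G %*% weights), ids)
  fit <- fitLmmAssoc(trait[ids], b, kinship, covariates, nStarts = nStarts)
  new("GeneSetResult",
      statistic = c(burden = fit@lrt), p = c(burden = fit@p),
      lambda = numeric(0), rho = 1, rhoP = c(`1` = fit@p),
      weights = weights, nVariants = ncol(G))
}

#' Family-based SKAT test
#'
#' Variance-component score test under the null mixed model (covariates
#' only): with S = G' Vhat^-1 (y - X alpha-hat), Q = sum_j w_j^2 S_j^2, whose
#' null distribution is the mixture sum_k lambda_k chi2_1 with lambda the
#' eigenvalues of W G' P G W (P the null projection under Vhat). The sum of
#' the eigenvalues equals the trace of the kernel matrix.
#'
#' @inheritParams burdenTest
#' @return A \linkS4class{GeneSetResult} with the skat entry.
#' @export
skatTest <- function(trait, G, weights = NULL, kinship, covariates = NULL,
                     nStarts = 3) {
  ids <- intersect(names(trait)[!is.na(trait)], rownames(G))
  G <- .alignG(G, ids)
  if (!any(apply(G, 2, function(x) length(unique(x)) > 1)))
    stop("all variants monomorphic")
  if (is.null(weights)) weights <- betaWeights(colMeans(G) / 2)
  nl <- .skatNull(trait[ids], kinship, covariates, nStarts = nStarts)
  G <- G[nl$ids, , drop = FALSE]
  S <- as.numeric(crossprod(G, nl$Py))
  Q <- sum((weights * S)^2)
  GW <- sweep(G, 2, weights, `*`)
  kernel <- crossprod(GW, nl$P %*% GW)
  lambda <- eigen(kernel, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > 1e-10 * max(lambda)]
  if (!length(lambda)) stop("eigenvalue computation failed: null kernel")
  p <- pchisqMixture(Q, lambda)
  new("GeneSetResult", statistic = c(skat = Q), p = c(skat = p),
      lambda = lambda, rho = 0, rhoP = c(`0` = p),
      weights = weights, nVariants = ncol(G))
}

#' Family-based SKAT-O (optimal burden/SKAT combination)
#'
#' Evaluates Q_rho = (1 - rho) Q_SKAT + rho Q_burden over a rho grid and
#' combines the per-rho p-values by the one-dimensional min-p integration
#' (conditioning on the common burden-direction chi-square). Singleton grids
#' return the boundary test exactly: rho = 0 gives \code{\link{skatTest}} and
#' rho = 1 gives \code{\link{burdenTest}} (LRT form). Inside a multi-point
#' grid the rho = 1 entry uses the score form (with the standard rho -> 0.999
#' substitution in the integration).
#'
#' @inheritParams burdenTest
#' @param rho grid of mixing weights in [0, 1].
#' @return A \linkS4class{GeneSetResult} with the skato entry (and per-rho
#'   p-values).
#' @export
skatOTest <- function(trait, G, weights = NULL, kinship, covariates = NULL,
                      rho = c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1),
                      nStarts = 3) {
  if (!length(rho)) stop("empty rho grid")
  if (any(rho < 0 | rho > 1)) stop("rho must be in [0, 1]")
  rho <- sort(unique(rho))
  if (length(rho) == 1) {
    res <- if (rho == 0) skatTest(trait, G, weights, kinship, covariates,
                                  nStarts = nStarts)
           else if (rho == 1) burdenTest(trait, G, weights, kinship, covariates,
                                         nStarts = nStarts)
           else NULL
    if (!is.null(res)) {
      res@statistic <- stats::setNames(res@statistic, "skato")
      res@p <- stats::setNames(res@p, "skato")
      return(res)
    }
  }
  ids <- intersect(names(trait)[!is.na(trait)], rownames(G))
  G <- .alignG(G, ids)
  if (!any(apply(G, 2, function(x) length(unique(x)) > 1)))
    stop("all variants monomorphic")
  if (is.null(weights)) weights <- betaWeights(colMeans(G) / 2)
  nl <- .skatNull(trait[ids], kinship, covariates, nStarts = nStarts)
  G <- G[nl$ids, , drop = FALSE]
  GW <- sweep(G, 2, weights, `*`)
  u <- as.numeric(crossprod(GW, nl$Py))      # u ~ N(0, M) under H0
  M <- crossprod(GW, nl$P %*% GW)
  k <- ncol(GW)
  Qs <- sum(u^2); Qb <- sum(u)^2
  Qrho <- (1 - rho) * Qs + rho * Qb

  ## per-rho p by mixture of chi-squares of R_rho^1/2 M R_rho^1/2
  rhoEff <- ifelse(rho >= 1, 0.999, rho)     # keep the remainder non-degenerate
  perRho <- numeric(length(rho))
  lamRho <- vector("list", length(rho))
  for (v in seq_along(rho)) {
    Rr <- (1 - rhoEff[v]) * diag(k) + rhoEff[v] * matrix(1, k, k)
    ev <- eigen(Rr, symmetric = TRUE)
    Rh <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
    lam <- eigen(Rh %*% M %*% Rh, symmetric = TRUE, only.values = TRUE)$values
    lam <- lam[lam > 1e-10 * max(lam)]
    lamRho[[v]] <- lam
    Qv <- (1 - rhoEff[v]) * Qs + rhoEff[v] * Qb
    perRho[v] <- pchisqMixture(Qv, lam)
  }
  pmin.v <- min(perRho)

  ## min-p integration conditional on the burden-direction chi-square
  b <- as.numeric(M %*% rep(1, k)); m1 <- sum(b)
  if (m1 < 1e-12) {
    pOpt <- pmin.v   # degenerate burden direction
  } else {
    tau <- m1 * rhoEff + (1 - rhoEff) * sum(b^2) / m1
    Mrem <- M - tcrossprod(b) / m1
    lamR <- eigen(Mrem, symmetric = TRUE, only.values = TRUE)$values
    lamR <- lamR[lamR > 1e-10 * max(abs(lamR))]
    muR <- sum(lamR)
    varR <- 2 * sum(lamR^2) + 4 * (as.numeric(crossprod(b, M %*% b)) / m1 -
                                     (sum(b^2) / m1)^2)
    sclR <- if (sum(lamR^2) > 0) sqrt(2 * sum(lamR^2) / varR) else 1
    ## per-rho quantiles of Q_rho at level pmin.v (Liu-style inversion)
    qv <- vapply(seq_along(rho), function(v) {
      lam <- lamRho[[v]]
      c1 <- sum(lam); c2 <- sum(lam^2); c3 <- sum(lam^3); c4 <- sum(lam^4)
      s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
      if (s1^2 > s2) { a <- 1 / (s1 - sqrt(s1^2 - s2)); d <- s1 * a^3 - a^2
                       l <- a^2 - 2 * d } else { l <- 1 / s2; a <- sqrt(l); d <- 0 }
      qx <- stats::qchisq(pmin.v, df = l, ncp = d, lower.tail = FALSE)
      c1 + (qx - (l + d)) / (sqrt(2) * a) * sqrt(2 * c2)
    }, numeric(1))
    integrand <- function(x) {
      vapply(x, function(xx) {
        tmin <- min((qv - tau * xx) / (1 - rhoEff))
        if (tmin <= 0) return(0)
        if (!length(lamR)) return(as.numeric(tmin > 0))
        tadj <- muR + (tmin - muR) * sclR
        1 - pchisqMixture(tadj, lamR, method = "liu")
      }, numeric(1)) * stats::dchisq(x, df = 1)
    }
    surv <- try(stats::integrate(integrand, 0, 40, abs.tol = 1e-10,
                                 subdivisions = 500L)$value, silent = TRUE)
    pOpt <- if (inherits(surv, "try-error")) pmin.v * length(rho)
            else 1 - surv
    pOpt <- min(max(pOpt, pmin.v), pmin.v * length(rho), 1)
  }
  new("GeneSetResult",
      statistic = c(skato = min(Qrho)), p = c(skato = pOpt),
      lambda = lamRho[[1]], rho = rho,
      rhoP = stats::setNames(perRho, rho),
      weights = weights, nVariants = k)
}

#' Combine per-study p-values across cohorts
#'
#' Default Fisher's method (-2 sum log p ~ chi-square with 2k df); the
#' sample-size-weighted Stouffer variant is available when per-study sizes
#' are supplied. A p of exactly 0 is clipped to the smallest representable
#' double, with a warning.
#'
#' @param p numeric vector of per-study p-values.
#' @param n optional per-study sample sizes (Stouffer weights sqrt(n)).
#' @param method "fisher" (default) or "stouffer".
#' @return combined p-value.
#' @export
metaCombine <- function(p, n = NULL, method = c("fisher", "stouffer")) {
  method <- match.arg(method)
  if (!length(p)) stop("at least one study required")
  if (any(p <= 0)) {
    warning("p-value of 0 clipped to machine minimum")
    p[p <= 0] <- .Machine$double.xmin
  }
  if (length(p) == 1) return(unname(p))
  if (method == "fisher") {
    stat <- -2 * sum(log(p))
    stats::pchisq(stat, df = 2 * length(p), lower.tail = FALSE)
  } else {
    w <- if (is.null(n)) rep(1, length(p)) else sqrt(n)
    z <- sum(w * stats::qnorm(p, lower.tail = FALSE)) / sqrt(sum(w^2))
    stats::pnorm(z, lower.tail = FALSE)
  }
}
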