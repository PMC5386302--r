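#' @include AllClasses.R vcfit.R assoc.R
NULL

#' Filter candidate variants under a linkage peak
#'
#' A variant passes when (association p <= pThreshold OR |beta1| >=
#' betaThreshold) AND it is carried by at least \code{minCarriers}
#' individuals in some family whose family-specific LOD at the peak is at
#' least \code{minFamilyLod}. Output is deterministic, ordered by position.
#'
#' @param fits named list of \linkS4class{MixedModelFit} (one per variant).
#' @param familyLod named numeric: per-family LOD contribution at the peak.
#' @param positions named numeric: cM position per variant (for ordering).
#' @param pThreshold,betaThreshold,minCarriers,minFamilyLod filter
#'   parameters (defaults 0.1, 5 mmHg, 2 carriers, 0.1 LOD).
#' @return character vector of selected variant ids (possibly empty, with a
#'   warning).
#' @export
filterCandidates <- function(fits, familyLod, positions,
                             pThreshold = 0.1, betaThreshold = 5,
                             minCarriers = 2, minFamilyLod = 0.1) {
  if (!length(fits)) { warning("empty candidate region"); return(character(0)) }
  okFam <- names(familyLod)[familyLod >= minFamilyLod]
  pass <- vapply(fits, function(f) {
    effect <- f@p <= pThreshold || abs(f@beta1) >= betaThreshold
    cc <- f@carrierCounts
    seg <- any(cc[intersect(names(cc), okFam)] >= minCarriers)
    effect && seg
  }, logical(1))
  sel <- names(fits)[pass]
  if (!length(sel)) { warning("no variants pass the candidate filter"); return(character(0)) }
  sel[order(positions[sel])]
}

#' Genotype risk score r_i = x_i' beta
#'
#' Exact inner product of per-individual dosages over the selected variants
#' with their (marginal, single-variant) regression coefficients. A missing
#' genotype contributes 0; per-individual missingness is recorded in the
#' \code{"nMissing"} attribute.
#'
#' @param genotypes a \linkS4class{GenotypeData} (or a dosage matrix,
#'   markers x individuals).
#' @param variants character vector of marker ids.
#' @param beta named numeric coefficients (same variants).
#' @return named numeric score per individual.
#' @export
buildRiskScore <- function(genotypes, variants, beta) {
  dos <- if (is(genotypes, "GenotypeData")) dosageMatrix(genotypes)
         else as.matrix(genotypes)
  miss <- setdiff(variants, rownames(dos))
  if (length(miss)) stop("variants missing from genotype data: ",
                         paste(miss, collapse = ", "))
  X <- t(dos[variants, , drop = FALSE])
  nMissing <- rowSums(is.na(X))
  X[is.na(X)] <- 0
  r <- as.numeric(X %*% beta[variants])
  structure(stats::setNames(r, rownames(X)), nMissing = nMissing)
}

#' Empirical null for the conditional-linkage LOD drop
#'
#' Repeats the conditional linkage scan with randomly sampled off-region
#' SNPs (which cannot contribute to the regional linkage signal) in place of
#' the risk score, and compares the observed MLOD drop with the resulting
#' null distribution. The empirical p uses the add-one rule
#' (1 + #\{null >= observed\}) / (1 + N), so it is never exactly 0.
#'
#' @param trait,kinship,ibd,covariates as in \code{\link{vcLinkageScan}}.
#' @param baseline unconditional \linkS4class{LinkageCurve} over the region.
#' @param score named numeric risk score (the observed conditioning
#'   covariate).
#' @param pool \linkS4class{GenotypeData} of SNPs from chromosomes other
#'   than the linkage chromosome.
#' @param positions cM positions of the regional scan (default: baseline
#'   positions).
#' @param N number of null draws (default 1000).
#' @param k SNPs per null draw (default 1: each null covariate is a single
#'   SNP dosage; for k > 1 a random-coefficient risk score is formed).
#' @param mafMin MAF floor for eligible pool SNPs (default 0.05).
#' @param seed optional integer seed for reproducible sampling.
#' @return A \linkS4class{LodDropNull}.
#' @export
lodDropNull <- function(trait, kinship, ibd, baseline, score, pool,
                        covariates = NULL, positions = NULL, N = 1000,
                        k = 1, mafMin = 0.05, seed = NULL, nStarts = 3) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(positions)) positions <- baseline@scan$cM
  mlod0 <- max(baseline@scan$lod[baseline@scan$cM %in% positions])
  ## build shared per-position IBD blocks once; all conditional scans reuse them
  dat0 <- .vcData(trait, kinship, NULL)
  idx <- match(positions, ibd@positions$cM)
  cache <- .piCache(ibd, idx, dat0$famLevels, dat0$fam, dat0$ids)
  cond <- conditionalScan(trait, kinship, ibd, score, covariates = covariates,
                          positions = positions, nStarts = nStarts,
                          piCache = cache)
  observed <- mlod0 - max(cond@scan$lod)

  dos <- dosageMatrix(pool)
  frq <- rowMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(frq, 1 - frq)
  elig <- rownames(dos)[!is.na(maf) & maf >= mafMin]
  if (length(elig) < N * k) {
    warning(sprintf("pool has %d eligible SNPs < N*k = %d; sampling without replacement up to pool size",
                    length(elig), N * k))
    N <- floor(length(elig) / k)
  }
  picks <- matrix(sample(elig, N * k), nrow = N)
  nullDrops <- numeric(N)
  for (i in seq_len(N)) {
    g <- dos[picks[i, ], , drop = FALSE]
    g[is.na(g)] <- 0
    cv <- if (k == 1) stats::setNames(as.numeric(g[1, ]), colnames(dos))
          else stats::setNames(as.numeric(crossprod(g, stats::rnorm(k))),
                               colnames(dos))
    ci <- tryCatch(suppressWarnings(
      conditionalScan(trait, kinship, ibd, cv, covariates = covariates,
                      positions = positions, nStarts = nStarts,
                      piCache = cache, nullWarm = 1)),
      error = function(e) NULL)
    nullDrops[i] <- if (is.null(ci)) 0 else mlod0 - max(ci@scan$lod)
  }
  p <- (1 + sum(nullDrops >= observed)) / (1 + N)
  new("LodDropNull", observed = observed, nullDrops = nullDrops, p = p)
}

#' Binomial direction-consistency tail probability
#'
#' Probability, under Binomial(n, 1/2), of seeing more direction-consistent
#' results than observed. The default is the strict-greater tail P(X > k);
#' \code{strict = FALSE} gives the inclusive tail P(X >= k). (For n = 23
#' tests of which k = 16 are protective, the strict tail is about 0.0173 and
#' the inclusive tail about 0.0466.)
#'
#' @param n number of tests.
#' @param k number of direction-consistent (e.g. protective) results.
#' @param strict use the strict-greater tail (default TRUE).
#' @return tail probability.
#' @export
directionBinomial <- function(n, k, strict = TRUE) {
  if (length(n) != 1 || length(k) != 1 || k < 0 || k > n)
    stop("need 0 <= k <= n")
  stats::pbinom(if (strict) k else k - 1, size = n, prob = 0.5,
                lower.tail = FALSE)
}

#' Probability of an opposite effect direction in a replication study
#'
#' For a standardized true effect beta* estimated with standard error se,
#' the estimate falls on the other side of zero with probability
#' Phi(-beta*/se). With beta* a quarter of the trait SD and unit
#' standardized SE this is about 0.401.
#'
#' @param beta standardized effect size.
#' @param se standard error on the same scale (> 0).
#' @return probability in (0, 1).
#' @export
oppositeDirectionProb <- function(beta, se) {
  if (any(se <= 0)) stop("se must be positive")
  stats::pnorm(-beta / se)
}
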