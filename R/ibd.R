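#' @include AllClasses.R
NULL

#' Multipoint IBD estimation along a chromosome
#'
#' Lander-Green inheritance-vector hidden Markov model: the hidden state is
#' one bit per non-founder meiosis (paternal/maternal grandparental origin),
#' transitions between adjacent positions flip each bit independently with
#' the Haldane recombination fraction, and emissions sum over founder-allele
#' assignments consistent with the observed genotypes (missing genotypes are
#' marginalized). Forward-backward gives the exact posterior expected
#' proportion of alleles shared identical-by-descent for every within-family
#' pair, at every marker and on a cM grid.
#'
#' Families whose meiosis-bit count (2 x non-founders) exceeds \code{bitCap}
#' cannot be enumerated exactly; with \code{monteCarlo = TRUE} they are
#' handled by a meiosis Gibbs sampler (forward-filtering backward-sampling of
#' each meiosis bit along the chromosome, conditional on all others), which
#' samples inheritance vectors from their posterior given the genotypes.
#' Founder allele frequencies are estimated from founders only, smoothed with
#' a pseudocount of 0.5.
#'
#' @param pedigree a \linkS4class{Pedigree}.
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param chrom chromosome to scan (default: the only chromosome present).
#' @param gridStepcM spacing of the evaluation grid; marker positions are
#'   always evaluated too.
#' @param bitCap maximum meiosis-bit count for exact enumeration (default 16).
#' @param monteCarlo allow the Monte-Carlo sampler for families over the cap.
#' @param mcDraws,mcBurn Gibbs sweeps kept / discarded for MC families.
#' @return An \linkS4class{IBDResult}.
#' @export
multipointIBD <- function(pedigree, genotypes, chrom = NULL, gridStepcM = 1,
                          bitCap = 16, monteCarlo = FALSE,
                          mcDraws = 10000, mcBurn = 200) {
  mk <- markerTable(genotypes)
  if (is.null(chrom)) {
    chrom <- unique(mk$chrom)
    if (length(chrom) > 1)
      stop("genotypes span several chromosomes; give chrom explicitly")
  }
  mk <- mk[mk$chrom == chrom, , drop = FALSE]
  if (nrow(mk) == 0) stop("no markers on chromosome ", chrom)
  mk <- mk[order(mk$cM), , drop = FALSE]
  dos <- dosageMatrix(genotypes)[mk$id, , drop = FALSE]

  ## positions: one slot per marker (coincident markers allowed; theta = 0
  ## between them) plus grid points at cM values with no marker
  grid <- seq(floor(min(mk$cM)), ceiling(max(mk$cM)), by = gridStepcM)
  grid <- setdiff(grid, mk$cM)
  cM <- c(mk$cM, grid)
  markerOf <- c(seq_len(nrow(mk)) - 1L, rep(-1L, length(grid)))
  o <- order(cM, markerOf)
  cM <- cM[o]; markerOf <- markerOf[o]
  theta <- haldaneTheta(pmax(diff(cM), 0) / 100)

  m <- pedMembers(pedigree)
  founders <- is.na(m$father)
  fdos <- dos[, m$id[founders][m$id[founders] %in% colnames(dos)], drop = FALSE]
  cnt2 <- rowSums(fdos, na.rm = TRUE)
  nall <- 2 * rowSums(!is.na(fdos))
  freq2 <- (cnt2 + 0.5) / (nall + 1)

  pairsL <- list(); pihatL <- list(); methodL <- character(0)
  for (fam in unique(m$family)) {
    fm <- m[m$family == fam, , drop = FALSE]
    fm <- fm[.topoOrder(fm), , drop = FALSE]
    n <- nrow(fm)
    if (n < 2) next
    fa <- match(fm$father, fm$id) - 1L; fa[is.na(fa)] <- -1L
    mo <- match(fm$mother, fm$id) - 1L; mo[is.na(mo)] <- -1L
    geno <- matrix(NA_integer_, n, nrow(mk))
    present <- fm$id %in% colnames(dos)
    geno[present, ] <- t(dos[, fm$id[present], drop = FALSE])
    pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pairs <- cbind(pr[, "row"], pr[, "col"]) - 1L
    nBits <- 2L * sum(fa >= 0)
    if (nBits <= bitCap) {
      ph <- ibdExactCpp(fa, mo, geno, freq2, theta, markerOf, pairs)
      methodL <- c(methodL, "exact")
    } else if (monteCarlo) {
      ph <- ibdGibbsCpp(fa, mo, geno, freq2, theta, markerOf, pairs,
                        as.integer(mcDraws), as.integer(mcBurn))
      methodL <- c(methodL, "mc")
    } else {
      stop(sprintf(paste0(
        "family %s needs %d meiosis bits (> bitCap = %d); split the pedigree ",
        "or set monteCarlo = TRUE"), fam, nBits, bitCap))
    }
    pairsL[[fam]] <- data.frame(family = fam,
                                id1 = fm$id[pairs[, 1] + 1L],
                                id2 = fm$id[pairs[, 2] + 1L],
                                stringsAsFactors = FALSE)
    pihatL[[fam]] <- ph
  }
  markerId <- rep(NA_character_, length(cM))
  markerId[markerOf >= 0] <- mk$id[markerOf[markerOf >= 0] + 1L]
  positions <- data.frame(chrom = chrom, cM = cM, marker = markerId,
                          stringsAsFactors = FALSE)
  new("IBDResult", positions = positions,
      pairs = do.call(rbind, c(pairsL, list(make.row.names = FALSE))),
      pihat = do.call(rbind, pihatL), method = methodL)
}
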