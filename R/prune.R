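#' @include AllClasses.R
NULL

#' LD pruning and MAF filtering of a linkage marker panel
#'
#' PLINK-style sliding-window pairwise pruning: markers under the MAF floor
#' (and monomorphic markers, logged) are removed first; then, within each
#' window of \code{windowKb} kilobases advanced by \code{stepVariants}
#' variants, one member of every pair with squared correlation above
#' \code{r2Threshold} is greedily dropped (the lower-MAF member; position
#' order breaks ties). By default r2 is the squared Pearson correlation of
#' genotype dosages across founders, so that family-induced correlation does
#' not inflate apparent LD; set \code{founderOnly = FALSE} to use everyone.
#'
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param pedigree a \linkS4class{Pedigree} (needed for founder dosages).
#' @param windowKb window size in kb (default 50).
#' @param stepVariants window step in variants (default 5).
#' @param r2Threshold r2 above which one of a pair is dropped (default 0.2;
#'   the stricter profile uses 0.1).
#' @param mafMin minor-allele-frequency floor (default 0.2).
#' @param founderOnly compute r2 and MAF on founders only (default TRUE).
#' @return character vector of retained marker ids, sorted by position, with
#'   attributes \code{"removed"} (ids) and \code{"log"} (per-marker reason).
#' @export
pruneLD <- function(genotypes, pedigree, windowKb = 50, stepVariants = 5,
                    r2Threshold = 0.2, mafMin = 0.2, founderOnly = TRUE) {
  stopifnot(r2Threshold > 0, r2Threshold <= 1, windowKb > 0, stepVariants >= 1)
  mk <- markerTable(genotypes)
  dos <- dosageMatrix(genotypes)
  if (founderOnly) {
    f <- intersect(founderIDs(pedigree), colnames(dos))
    dos <- dos[, f, drop = FALSE]
  }
  frq <- rowMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(frq, 1 - frq)
  reason <- stats::setNames(rep("", nrow(mk)), mk$id)
  mono <- !is.na(maf) & maf == 0
  reason[mono] <- "monomorphic"
  lowmaf <- !mono & (is.na(maf) | maf < mafMin)
  reason[lowmaf] <- sprintf("MAF %.3f < %.2f", maf[lowmaf], mafMin)
  keep <- !(mono | lowmaf)

  for (ch in unique(mk$chrom)) {
    idx <- which(mk$chrom == ch & keep)
    idx <- idx[order(mk$bp[idx])]
    start <- 1L
    while (start <= length(idx)) {
      live <- idx[keep[idx]]
      w <- live[live >= idx[start] &
                  mk$bp[live] <= mk$bp[idx[start]] + windowKb * 1000]
      if (length(w) >= 2) {
        repeat {
          D <- t(dos[w, , drop = FALSE])
          r2 <- suppressWarnings(stats::cor(D, use = "pairwise.complete.obs"))^2
          r2[!is.finite(r2)] <- 0
          diag(r2) <- 0
          if (max(r2) <= r2Threshold) break
          hit <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
          pair <- w[sort(hit)]
          victim <- if (maf[pair[1]] < maf[pair[2]]) pair[1]
                    else if (maf[pair[2]] < maf[pair[1]]) pair[2]
                    else pair[2]   # tie: drop the later (position order)
          keep[victim] <- FALSE
          reason[victim] <- sprintf("r2 %.3f > %.2f with %s",
                                    max(r2), r2Threshold,
                                    mk$id[setdiff(pair, victim)])
          w <- setdiff(w, victim)
          if (length(w) < 2) break
        }
      }
      start <- start + stepVariants
    }
  }
  ord <- order(match(mk$chrom, unique(mk$chrom)), mk$bp)
  retained <- mk$id[ord][keep[ord]]
  structure(retained, removed = mk$id[!keep],
            log = reason[reason != ""])
}
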