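# Brute-force inheritance-vector oracle, written independently of the
# package's HMM: emissions enumerate every founder-allele assignment and the
# chain uses dense transition matrices. Only usable for tiny pedigrees.

bruteForceIBD <- function(fm, geno, freq2, cMpos, markerOf) {
  n <- nrow(fm); isF <- is.na(fm$father)
  nF <- sum(isF); b <- 2 * (n - nF)
  fIdx <- cumsum(isF); kIdx <- cumsum(!isF)
  S <- 2^b
  slots <- function(v) {
    pat <- mat <- integer(n)
    for (i in 1:n) {
      if (isF[i]) { pat[i] <- 2 * fIdx[i] - 1; mat[i] <- 2 * fIdx[i] }
      else {
        k <- kIdx[i]
        fi <- match(fm$father[i], fm$id); mi <- match(fm$mother[i], fm$id)
        pb <- bitwAnd(bitwShiftR(v, 2 * (k - 1)), 1)
        mb <- bitwAnd(bitwShiftR(v, 2 * k - 1), 1)
        pat[i] <- if (pb == 0) pat[fi] else mat[fi]
        mat[i] <- if (mb == 0) pat[mi] else mat[mi]
      }
    }
    cbind(pat, mat)
  }
  emit <- function(v, gcol, q) {
    sl <- slots(v); tot <- 0
    asn <- as.matrix(expand.grid(rep(list(0:1), 2 * nF)))
    for (r in seq_len(nrow(asn))) {
      a <- asn[r, ]
      ok <- TRUE
      for (i in 1:n) {
        gi <- gcol[i]; if (is.na(gi)) next
        if (a[sl[i, 1]] + a[sl[i, 2]] != gi) { ok <- FALSE; break }
      }
      if (ok) tot <- tot + prod(ifelse(a == 1, q, 1 - q))
    }
    tot
  }
  nPos <- length(cMpos)
  E <- matrix(1, S, nPos)
  for (t in 1:nPos) if (markerOf[t] > 0)
    for (v in 0:(S - 1)) E[v + 1, t] <- emit(v, geno[, markerOf[t]], freq2[markerOf[t]])
  theta <- 0.5 * (1 - exp(-2 * pmax(diff(cMpos), 0) / 100))
  TT <- lapply(theta, function(th) {
    M <- matrix(0, S, S)
    for (v in 0:(S - 1)) for (w in 0:(S - 1)) {
      fl <- sum(bitwAnd(bitwXor(v, w), 2^(0:(b - 1))) > 0)
      M[v + 1, w + 1] <- th^fl * (1 - th)^(b - fl)
    }
    M
  })
  fwd <- matrix(0, S, nPos); bwd <- matrix(0, S, nPos)
  f <- rep(1 / S, S) * E[, 1]; fwd[, 1] <- f / sum(f)
  for (t in seq_len(nPos)[-1]) {
    f <- as.numeric(t(TT[[t - 1]]) %*% fwd[, t - 1]) * E[, t]
    fwd[, t] <- f / sum(f)
  }
  bwd[, nPos] <- 1
  if (nPos > 1) for (t in (nPos - 1):1) {
    bv <- as.numeric(TT[[t]] %*% (bwd[, t + 1] * E[, t + 1]))
    bwd[, t] <- bv / sum(bv)
  }
  prs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  prs <- prs[order(prs[, 2], prs[, 1]), , drop = FALSE]
  shv <- sapply(0:(S - 1), function(v) {
    sl <- slots(v)
    apply(prs, 1, function(pr) {
      i <- pr[1]; j <- pr[2]
      (sum(sl[i, 1] == sl[j, ]) + sum(sl[i, 2] == sl[j, ])) / 2
    })
  })
  if (nrow(prs) == 1) shv <- matrix(shv, 1)
  pihat <- matrix(0, nrow(prs), nPos)
  for (t in 1:nPos) {
    post <- fwd[, t] * bwd[, t]; post <- post / sum(post)
    pihat[, t] <- shv %*% post
  }
  list(pihat = pihat,
       pairs = data.frame(id1 = fm$id[prs[, 1]], id2 = fm$id[prs[, 2]]))
}

# package-vs-oracle comparison on one family's GenotypeData
compareWithOracle <- function(ped, geno, gridStepcM = 10) {
  ibd <- multipointIBD(ped, geno, gridStepcM = gridStepcM)
  fm <- pedMembers(ped)
  fm <- fm[pedscan:::.topoOrder(fm), ]
  dos <- dosageMatrix(geno)
  fd <- dos[, fm$id[is.na(fm$father)], drop = FALSE]
  freq2 <- (rowSums(fd, na.rm = TRUE) + 0.5) / (2 * rowSums(!is.na(fd)) + 1)
  markerOf <- match(ibd@positions$marker, rownames(dos))
  markerOf[is.na(markerOf)] <- 0
  oracle <- bruteForceIBD(fm, t(dos[, fm$id, drop = FALSE]), freq2,
                          ibd@positions$cM, markerOf)
  max(abs(ibd@pihat - oracle$pihat))
}
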