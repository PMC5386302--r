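## shared fixture: 40 sib-trio families, informative map, IBD on a grid
linkFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    set.seed(101)
    ped <- manyNuclear(40, nKids = 3)
    mk <- markerPanel(seq(0, 50, 5), freq2 = 0.5)
    geno <- geneDrop(ped, mk, seed = 7)
    kin <- kinshipMatrix(ped)
    ibd <- multipointIBD(ped, geno, gridStepcM = 10)
    cache <<- list(ped = ped, geno = geno, kin = kin, ibd = ibd)
    cache
  }
})

test_that("per-family LOD contributions sum to the total at every position", {
  fx <- linkFixture()
  set.seed(5)
  y <- mvnTrait(fx$kin, 30, 70)
  cur <- vcLinkageScan(y, fx$kin, fx$ibd, positions = c(0, 10, 25, 40, 50))
  expect_lt(max(abs(rowSums(cur@perFamily) - cur@scan$rawLod)), 1e-8)
  expect_true(all(cur@scan$lod >= 0))
  expect_false(anyNA(cur@scan$lod))
})

test_that("boundary sigma2Q = 0 gives LOD exactly 0", {
  fx <- linkFixture()
  set.seed(6)
  found <- FALSE
  for (r in 1:10) {
    y <- mvnTrait(fx$kin, 30, 70)
    cur <- vcLinkageScan(y, fx$kin, fx$ibd, positions = 25)
    if (cur@vc[1, "sigma2Q"] == 0) {
      expect_identical(cur@scan$lod[1], 0)
      expect_identical(cur@scan$rawLod[1], 0)
      found <- TRUE
      break
    }
  }
  expect_true(found)   # a null trait hits the boundary about half the time
})

test_that("a planted QTL is localized near its true position", {
  ## 100 sib-quad families, QTL explaining 30% of variance at 25 cM
  set.seed(76)
  ped <- manyNuclear(100, nKids = 4)
  mk <- markerPanel(seq(0, 50, 5), freq2 = 0.5)
  geno <- geneDrop(ped, mk, seed = 76)
  kin <- kinshipMatrix(ped)
  ibd <- multipointIBD(ped, geno, gridStepcM = 10)
  ids <- rownames(phiMatrix(kin))
  q <- dosageMatrix(geno)["m6", ids]          # marker at 25 cM
  set.seed(77)
  hits <- 0; nRep <- 25
  for (r in seq_len(nRep)) {
    qc <- q - mean(q)
    b <- sqrt(0.30 * 100 / stats::var(qc))    # QTL explains ~30% of variance
    y <- stats::setNames(b * qc, ids) + mvnTrait(kin, 20, 50)
    cur <- vcLinkageScan(y, kin, ibd, positions = seq(0, 50, 5))
    if (abs(peakPosition(cur) - 25) <= 10) hits <- hits + 1
  }
  expect_gte(hits / nRep, 0.8)
})

test_that("conditioning on a constant covariate reproduces the curve", {
  fx <- linkFixture()
  set.seed(8)
  y <- mvnTrait(fx$kin, 30, 70)
  pos <- c(0, 25, 50)
  base <- vcLinkageScan(y, fx$kin, fx$ibd, positions = pos)
  expect_warning(cond <- conditionalScan(y, fx$kin, fx$ibd,
                                         stats::setNames(rep(0, length(y)), names(y)),
                                         positions = pos, baseline = base),
                 "constant")
  expect_lt(max(abs(cond@scan$lod - base@scan$lod)), 1e-8)
  expect_equal(attr(cond, "mlodDrop"), 0, tolerance = 1e-8)
})

test_that("collinear conditioning covariates are rejected", {
  fx <- linkFixture()
  set.seed(9)
  y <- mvnTrait(fx$kin, 30, 70)
  cv <- matrix(rnorm(length(y)), dimnames = list(names(y), "x1"))
  expect_error(conditionalScan(y, fx$kin, fx$ibd, covariate = 2 * cv[, 1],
                               covariates = cv, positions = 25),
               "collinear")
})

test_that("conditioning on the causal genotype removes more LOD than noise", {
  fx <- linkFixture()
  phi <- phiMatrix(fx$kin)
  ids <- rownames(phi)
  q <- dosageMatrix(fx$geno)["m6", ids]
  set.seed(31)
  dTrue <- dNoise <- numeric(8)
  for (r in 1:8) {
    qc <- q - mean(q)
    b <- sqrt(0.30 * 100 / stats::var(qc))
    y <- stats::setNames(b * qc, ids) + mvnTrait(fx$kin, 20, 50)
    base <- vcLinkageScan(y, fx$kin, fx$ibd, positions = c(15, 25, 35))
    cT <- conditionalScan(y, fx$kin, fx$ibd, stats::setNames(q, ids),
                          positions = c(15, 25, 35), baseline = base)
    cN <- conditionalScan(y, fx$kin, fx$ibd,
                          stats::setNames(sample(q), ids),
                          positions = c(15, 25, 35), baseline = base)
    dTrue[r] <- attr(cT, "mlodDrop"); dNoise[r] <- attr(cN, "mlodDrop")
  }
  expect_gt(mean(dTrue), mean(dNoise))
})

test_that("2-LOD support interval extraction matches a constructed curve", {
  ## symmetric triangle peaking at 2.81 at 50 cM, slope 0.1 / cM
  cM <- seq(0, 100, 2.5)
  lod <- pmax(2.81 - 0.1 * abs(cM - 50), 0)
  curve <- new("LinkageCurve",
               scan = data.frame(chrom = "16", cM = cM, lod = lod, rawLod = lod),
               perFamily = matrix(0, length(cM), 0), vc = matrix(0, length(cM), 3))
  reg <- region2LOD(curve)
  expect_equal(reg$lo, 30, tolerance = 1e-8)     # crossing of 0.81
  expect_equal(reg$hi, 70, tolerance = 1e-8)

  ## narrow peak widened to the 20 cM target
  lod2 <- pmax(2.81 - 0.7 * abs(cM - 50), 0)
  curve2 <- new("LinkageCurve",
                scan = data.frame(chrom = "16", cM = cM, lod = lod2, rawLod = lod2),
                perFamily = matrix(0, length(cM), 0), vc = matrix(0, length(cM), 3))
  reg2 <- region2LOD(curve2)
  expect_equal(reg2$hi - reg2$lo, 20, tolerance = 1e-8)
  expect_equal((reg2$hi + reg2$lo) / 2, 50, tolerance = 1e-8)

  ## monotone increasing curve: right endpoint is the chromosome end
  lod3 <- 3 * cM / 100
  curve3 <- new("LinkageCurve",
                scan = data.frame(chrom = "16", cM = cM, lod = lod3, rawLod = lod3),
                perFamily = matrix(0, length(cM), 0), vc = matrix(0, length(cM), 3))
  reg3 <- region2LOD(curve3)
  expect_equal(reg3$hi, 100)

  ## flat curve has no peak
  curve4 <- new("LinkageCurve",
                scan = data.frame(chrom = "16", cM = cM, lod = 0 * cM, rawLod = 0 * cM),
                perFamily = matrix(0, length(cM), 0), vc = matrix(0, length(cM), 3))
  expect_error(region2LOD(curve4), "no peak")
})
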