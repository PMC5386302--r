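test_that("with no genotype data the posterior equals the pedigree prior", {
  ped <- nuclearFamily("f1", 2)
  mk <- markerPanel(c(0, 50))
  dos <- matrix(NA_integer_, 2, 4,
                dimnames = list(mk$id, pedMembers(ped)$id))
  ibd <- multipointIBD(ped, GenotypeData(dos, mk, ped), gridStepcM = 25)
  pr <- ibd@pairs
  sib <- pr$id1 == "f1_k1" & pr$id2 == "f1_k2"
  po <- pr$id1 == "f1_fa" & pr$id2 == "f1_k1"
  spouses <- pr$id1 == "f1_fa" & pr$id2 == "f1_mo"
  expect_equal(unname(ibd@pihat[sib, ]), rep(0.5, 3))
  expect_equal(unname(ibd@pihat[po, ]), rep(0.5, 3))
  expect_equal(unname(ibd@pihat[spouses, ]), rep(0, 3))
})

test_that("a fully informative locus pins sib sharing to 0, 1/2 or 1", {
  ## two coincident biallelic markers jointly phase both parents: the father
  ## is het only at m1, the mother only at m2, so each child's transmitted
  ## haplotype is observable and sharing follows from allele bookkeeping
  ped <- nuclearFamily("f1", 3)
  mk <- markerPanel(c(20, 20), chrom = "1")
  ids <- pedMembers(ped)$id
  ## father A/B at m1, B/B at m2; mother A/A at m1, A/B at m2
  ## k1: got fa hap (B at m1) + mo hap (B at m2) -> m1 dosage: fa B + mo A = 1
  dos <- matrix(NA_integer_, 2, 5, dimnames = list(mk$id, ids))
  dos[, "f1_fa"] <- c(1L, 2L)
  dos[, "f1_mo"] <- c(0L, 1L)
  dos[, "f1_k1"] <- c(1L, 2L)   # fa-B, mo-B
  dos[, "f1_k2"] <- c(1L, 2L)   # fa-B, mo-B -> shares both with k1
  dos[, "f1_k3"] <- c(0L, 1L)   # fa-A, mo-A -> shares none with k1
  ibd <- multipointIBD(ped, GenotypeData(dos, mk, ped), gridStepcM = 50)
  at20 <- which(ibd@positions$cM == 20)[1]
  pr <- ibd@pairs
  k12 <- which(pr$id1 == "f1_k1" & pr$id2 == "f1_k2")
  k13 <- which(pr$id1 == "f1_k1" & pr$id2 == "f1_k3")
  k23 <- which(pr$id1 == "f1_k2" & pr$id2 == "f1_k3")
  expect_equal(ibd@pihat[k12, at20], 1)
  expect_equal(ibd@pihat[k13, at20], 0)
  expect_equal(ibd@pihat[k23, at20], 0)
})

test_that("HMM equals brute-force enumeration on small pedigrees", {
  ## nuclear 2 kids (4 bits), nuclear 3 kids with missing data (6 bits),
  ## three-generation family (8 bits)
  set.seed(21)
  cases <- list(
    list(ped = nuclearFamily("a", 2), cM = c(0, 15, 40), miss = 0),
    list(ped = nuclearFamily("b", 3), cM = c(0, 10, 25, 50), miss = 3),
    list(ped = threeGenFamily("c"), cM = c(0, 20, 45), miss = 1))
  for (cs in cases) {
    mk <- markerPanel(cs$cM, freq2 = runif(length(cs$cM), 0.2, 0.6))
    geno <- geneDrop(cs$ped, mk, seed = sample.int(1000, 1))
    dos <- dosageMatrix(geno)
    if (cs$miss > 0) dos[sample(length(dos), cs$miss)] <- NA
    geno <- GenotypeData(dos, mk, cs$ped)
    expect_lt(compareWithOracle(cs$ped, geno, gridStepcM = 10), 1e-10)
  }
})

test_that("HMM is invariant to marker file order and allele relabelling", {
  ped <- nuclearFamily("f1", 3)
  mk <- markerPanel(c(0, 10, 30, 55), freq2 = c(0.5, 0.3, 0.4, 0.25))
  geno <- geneDrop(ped, mk, seed = 17)
  ibd <- multipointIBD(ped, geno, gridStepcM = 25)

  ## unsorted genetic maps are rejected at construction; file input is
  ## sorted on read, so a shuffled MAP gives an identical result
  expect_error(GenotypeData(dosageMatrix(geno)[c(3, 1, 4, 2), ],
                            markerTable(geno)[c(3, 1, 4, 2), ], ped),
               "non-decreasing")
  pedF <- tempfile(fileext = ".ped"); mapF <- tempfile(fileext = ".map")
  writePedMap(ped, geno, pedF, mapF)
  o <- c(3, 1, 4, 2)
  writeLines(readLines(mapF)[o], mapF)
  pl <- strsplit(readLines(pedF), " ")
  pl <- vapply(pl, function(x) {
    gcols <- matrix(x[-(1:6)], nrow = 2)
    paste(c(x[1:6], as.vector(gcols[, o])), collapse = " ")
  }, character(1))
  writeLines(pl, pedF)
  back <- readPedMap(pedF, mapF)
  ibd2 <- multipointIBD(back$pedigree, back$genotypes, gridStepcM = 25)
  expect_equal(ibd@pihat, ibd2@pihat, tolerance = 1e-10)

  ## relabel alleles (swap dosage orientation) at one marker
  dos <- dosageMatrix(geno)
  dos["m2", ] <- 2L - dos["m2", ]
  flipped <- GenotypeData(dos, markerTable(geno), ped)
  ibd3 <- multipointIBD(ped, flipped, gridStepcM = 25)
  expect_equal(ibd@pihat, ibd3@pihat, tolerance = 1e-10)
})

test_that("over-cap pedigrees error unless the Monte-Carlo mode is chosen", {
  ped <- nuclearFamily("f1", 4)          # 8 meiosis bits
  mk <- markerPanel(c(0, 10, 20))
  geno <- geneDrop(ped, mk, seed = 6)
  expect_error(multipointIBD(ped, geno, bitCap = 6), "monteCarlo|split")
  set.seed(30)
  mc <- multipointIBD(ped, geno, bitCap = 6, monteCarlo = TRUE,
                      mcDraws = 4000, mcBurn = 200)
  ex <- multipointIBD(ped, geno)
  expect_lt(max(abs(mc@pihat - ex@pihat)), 0.05)
  expect_true("mc" %in% mc@method)
})
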