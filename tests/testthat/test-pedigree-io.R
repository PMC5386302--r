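test_that("PED/MAP round-trip preserves structure and calls", {
  ped <- nuclearFamily("f1", 3, sex = c("male", "female", "male", "female", "unknown"))
  mk <- markerPanel(c(0, 12.5, 30), freq2 = c(0.5, 0.3, 0.2))
  geno <- geneDrop(ped, mk, seed = 4)
  pedF <- tempfile(fileext = ".ped"); mapF <- tempfile(fileext = ".map")
  writePedMap(ped, geno, pedF, mapF)
  back <- readPedMap(pedF, mapF)
  expect_equal(pedMembers(back$pedigree), pedMembers(ped))
  d0 <- dosageMatrix(geno); d1 <- dosageMatrix(back$genotypes)
  ## allele labelling may flip where only one allele was observed; compare
  ## unordered calls through the marker allele codes
  mk0 <- markerTable(geno); mk1 <- markerTable(back$genotypes)
  for (j in seq_len(nrow(mk0))) {
    same <- identical(mk0$a2[j], mk1$a2[j])
    expect_equal(if (same) d1[j, colnames(d0)] else 2 - d1[j, colnames(d0)],
                 d0[j, ], ignore_attr = TRUE)
  }
  expect_equal(markerTable(back$genotypes)$cM, mk$cM)
})

test_that("unknown sex code and missing-parent modes follow the PED dialect", {
  ped <- tempfile(fileext = ".ped"); map <- tempfile(fileext = ".map")
  writeLines("1 snp1 0 1000", map)
  writeLines(c("f1 a 0 0 0 0 A A",
               "f1 b 0 0 2 0 A B",
               "f1 c a b 1 0 A B"), ped)
  res <- readPedMap(ped, map)
  expect_equal(pedMembers(res$pedigree)$sex, c("unknown", "female", "male"))

  ## child names a father absent from the file
  writeLines(c("f1 b 0 0 2 0 A B",
               "f1 c a b 1 0 A B"), ped)
  expect_error(readPedMap(ped, map, strictParents = TRUE), "strict mode")
  len <- readPedMap(ped, map, strictParents = FALSE)
  m <- pedMembers(len$pedigree)
  expect_true("a" %in% m$id)
  expect_true(is.na(m$father[m$id == "a"]))
  expect_equal(m$sex[m$id == "a"], "unknown")
  expect_true(all(is.na(dosageMatrix(len$genotypes)[, "a"])))
})

test_that("malformed and duplicated PED input is rejected with context", {
  ped <- tempfile(fileext = ".ped"); map <- tempfile(fileext = ".map")
  writeLines("1 snp1 0 1000", map)
  writeLines(c("f1 a 0 0 1 0 A A", "f1 b 0 0 2 0 A"), ped)
  expect_error(readPedMap(ped, map), "line 2")
  writeLines(c("f1 a 0 0 1 0 A A", "f1 a 0 0 2 0 A B"), ped)
  expect_error(readPedMap(ped, map), "duplicated")
})

test_that("Mendelian check flags impossible trios and passes gene drops", {
  ped <- nuclearFamily("f1", 1)
  mk <- markerPanel(c(0, 10))
  ids <- pedMembers(ped)$id
  dos <- matrix(0L, 2, 3, dimnames = list(mk$id, ids))
  geno <- GenotypeData(dos, mk, ped)
  expect_equal(nrow(checkMendelian(ped, geno)), 0)

  dos["m1", "f1_k1"] <- 1L          # AA x AA parents, AB child
  geno <- GenotypeData(dos, mk, ped)
  rep <- checkMendelian(ped, geno)
  expect_equal(nrow(rep), 1)
  expect_equal(rep$marker, "m1")
  expect_equal(rep$child, "f1_k1")

  ## simulated data are Mendelian-consistent by construction
  st <- simulateStudy(3, simConfig(nFamilies = 15, nScanMarkers = 11,
                                   scanLengthcM = 40, nPoolSnps = 10))
  expect_equal(nrow(checkMendelian(st$pedigree, st$genotypes)), 0)
})

test_that("pedigree validity rejects cycles, half-parents and own-ancestors", {
  expect_error(Pedigree("f", c("a", "b"), c("b", "a"), c("b", "a"), "male"),
               "cyclic|parent")
  expect_error(Pedigree("f", c("a", "b", "c"), c(NA, NA, "a"), c(NA, NA, NA),
                        c("male", "female", "male")), "one named parent")
})

test_that("VCF genotypes map onto the PED dosage representation", {
  skip_if_not_installed("vcfR")
  ped <- nuclearFamily("f1", 1)
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "f1_fa", "f1_mo", "f1_k1", sep = "\t"),
               paste("1", "1000000", "rs1", "A", "G", ".", ".", ".", "GT",
                     "0/1", "0/0", "0/1", sep = "\t"),
               paste("1", "2000000", "rs2", "T", "C", ".", ".", ".", "GT",
                     "1/1", "0/1", "./.", sep = "\t")), vcf)
  g <- readGenotypesVCF(vcf, ped)
  d <- dosageMatrix(g)
  expect_equal(d["rs1", ], c(f1_fa = 1L, f1_mo = 0L, f1_k1 = 1L))
  expect_equal(d["rs2", ], c(f1_fa = 2L, f1_mo = 1L, f1_k1 = NA_integer_))
})
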