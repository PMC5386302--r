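smallCfg <- function() simConfig(nFamilies = 20, nScanMarkers = 11,
                                 scanLengthcM = 40, nPoolSnps = 10)

test_that("the same seed reproduces a study byte for byte", {
  s1 <- simulateStudy(77, smallCfg())
  s2 <- simulateStudy(77, smallCfg())
  expect_identical(pedMembers(s1$pedigree), pedMembers(s2$pedigree))
  expect_identical(dosageMatrix(s1$genotypes), dosageMatrix(s2$genotypes))
  expect_identical(s1$pheno, s2$pheno)
  d1 <- tempfile(); d2 <- tempfile()
  writeStudy(s1, d1); writeStudy(s2, d2)
  for (f in c("study.ped", "study.map", "phenotypes.tsv", "truth.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  ## different seeds differ
  s3 <- simulateStudy(78, smallCfg())
  expect_false(identical(dosageMatrix(s1$genotypes), dosageMatrix(s3$genotypes)))
})

test_that("the study emulates the cohort design", {
  cfg <- simConfig()
  sizes <- integer(0); totals <- integer(0)
  for (s in 1:6) {
    ped <- simulatePedigrees(cfg, seed = s)
    tab <- table(pedMembers(ped)$family)
    expect_equal(length(tab), 130)
    expect_equal(sum(tab == 17), 1)               # one 17-member family
    totals <- c(totals, sum(tab))
  }
  expect_lt(abs(mean(totals) - 517), 25)          # ~517 individuals on average
  ## the large family is three-generational
  ped <- simulatePedigrees(cfg, seed = 1)
  m <- pedMembers(ped)
  big <- names(which(table(m$family) == 17))
  fm <- m[m$family == big, ]
  kids <- fm$id[!is.na(fm$father)]
  grandkids <- kids[fm$father[match(kids, fm$id)] %in% kids |
                      fm$mother[match(kids, fm$id)] %in% kids]
  expect_gt(length(grandkids), 0)
})

test_that("gene dropping respects frequencies, linkage and Mendel", {
  ## founder sample frequency approaches the generating frequency
  ids <- paste0("i", 1:500)
  ped <- Pedigree(ids, ids, NA, NA, "unknown")
  mk <- markerPanel(c(0, 0, 10), freq2 = c(0.1, 0.5, 0.3))
  g <- geneDrop(ped, mk, seed = 12)
  fr <- rowMeans(dosageMatrix(g)) / 2
  for (j in 1:3) {
    se <- sqrt(mk$freq2[j] * (1 - mk$freq2[j]) / (2 * 500))
    expect_lt(abs(fr[j] - mk$freq2[j]), 3 * se)
  }
  ## zero-distance markers are co-inherited within every meiosis
  set.seed(13)
  theta <- c(0, haldaneTheta(0.1))
  for (r in 1:50) {
    ind <- pedscan:::.meiosis(mk$chrom, theta)
    expect_equal(ind[1], ind[2])                  # theta = 0 interval
  }
  ## simulated studies contain no Mendelian errors (also by construction)
  st <- simulateStudy(5, smallCfg())
  expect_equal(nrow(checkMendelian(st$pedigree, st$genotypes)), 0)
})

test_that("trait generation mirrors the analysis model", {
  ## no genetics, no noise: observed latent SBP is the fixed-effect surface
  cfg <- smallCfg()
  cfg$sigma2G <- 0; cfg$sigma2E <- 0
  cfg$causal$beta[] <- 0
  cfg$medCenter <- 1e6                      # nobody treated
  st <- simulateStudy(6, cfg)
  ph <- st$pheno
  fx <- cfg$fixed
  expected <- fx[["intercept"]] + fx[["age"]] * ph$age +
    fx[["age2"]] * ph$age^2 + fx[["bmi"]] * ph$bmi +
    fx[["sexMale"]] * (ph$sex == "male")
  expect_equal(ph$sbp, round(expected, 1), tolerance = 1e-8)

  ## heritability recovery: sigma2G / (sigma2G + sigma2E) = 0.4
  cfg2 <- smallCfg()
  cfg2$nFamilies <- 130
  cfg2$sigma2G <- 48; cfg2$sigma2E <- 72
  cfg2$causal$beta[] <- 0
  h2 <- numeric(10)
  for (r in 1:10) {
    st2 <- simulateStudy(100 + r, cfg2)
    kin <- kinshipMatrix(st2$pedigree)
    y <- stats::setNames(attr(st2$pheno, "latent"), st2$pheno$id)
    ph2 <- adjustMedication(st2$pheno)
    tr <- residualizeTrait(ph2, "sbpAdj", c("sex", "age", "age2", "bmi"))
    dat <- pedscan:::.vcData(tr, kin, NULL)
    fit <- pedscan:::.vcFit(pedscan:::vcBuild(dat$yl, dat$Xl, dat$K1l), 1L,
                            "(Intercept)")
    h2[r] <- fit$sigma2G / (fit$sigma2G + fit$sigma2)
  }
  expect_lt(abs(mean(h2) - 0.4), 0.1)

  ## planted one-family variant reproduces the carrier/noncarrier gap
  diffs <- sapply(1:8, function(r) {
    st3 <- simulateStudy(200 + r, smallCfg())
    carr <- dosageMatrix(st3$genotypes)["rv_main", st3$pheno$id] >= 1
    lat <- attr(st3$pheno, "latent")
    mean(lat[carr]) - mean(lat[!carr])
  })
  expect_lt(abs(mean(diffs) + 8), 3 * stats::sd(diffs) / sqrt(length(diffs)))
})

test_that("medication masking is reversed by the adjustment step", {
  st <- simulateStudy(30, smallCfg())
  ph <- adjustMedication(st$pheno)
  lat <- attr(st$pheno, "latent")
  expect_equal(ph$sbpAdj, round(lat, 1), tolerance = 1e-8)
  expect_gt(mean(st$pheno$medication), 0.05)
  expect_lt(mean(st$pheno$medication), 0.6)
})
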