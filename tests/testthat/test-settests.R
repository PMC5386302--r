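test_that("Beta(1,25) weights follow the closed form and are monotone", {
  expect_equal(betaWeights(0), 25)
  expect_equal(betaWeights(0.0036), 25 * (1 - 0.0036)^24)
  expect_equal(round(betaWeights(0.0036), 2), 22.93)
  expect_warning(w5 <- betaWeights(0.5), "flip")
  expect_equal(w5, 25 * 0.5^24)
  expect_lt(abs(w5 - 1.49e-6) / 1.49e-6, 0.01)
  maf <- c(0.2, 0.001, 0.05, 0.01)
  w <- betaWeights(maf)
  expect_equal(order(w, decreasing = TRUE), order(maf))
  expect_error(betaWeights(-0.1), "MAF")
})

test_that("mixture-of-chi-square tail matches simulation and saddlepoint", {
  lambda <- c(3, 1.2, 0.5, 0.1)
  set.seed(4)
  sim <- colSums(lambda * matrix(rchisq(4 * 2e5, 1), 4))
  ## the moment-matched tail is accurate above the mean (where it is used)
  for (q in c(8, 14, 22)) {
    pref <- mean(sim > q)
    expect_lt(abs(pchisqMixture(q, lambda) - pref),
              3 * sqrt(pref * (1 - pref) / 2e5) + 4e-3)
  }
  ## far tail: saddlepoint and Liu agree in order of magnitude, and the
  ## auto rule switches to the saddlepoint
  pS <- pchisqMixture(60, lambda, method = "saddlepoint")
  pA <- pchisqMixture(60, lambda)
  expect_equal(pA, pS)
  expect_lt(pA, 1e-4)
  ## single eigenvalue: exact chi-square
  expect_equal(pchisqMixture(3.84, 1), pchisq(3.84, 1, lower.tail = FALSE))
})

famFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    set.seed(55)
    ped <- manyNuclear(40, nKids = 3)
    kin <- kinshipMatrix(ped)
    ids <- rownames(phiMatrix(kin))
    G <- sapply(c(0.02, 0.04, 0.03, 0.05, 0.01),
                function(q) rbinom(length(ids), 2, q))
    rownames(G) <- ids; colnames(G) <- paste0("v", 1:5)
    cache <<- list(kin = kin, ids = ids, G = G)
    cache
  }
})

test_that("single-variant sets collapse to the single-variant tests", {
  fx <- famFixture()
  set.seed(56)
  y <- mvnTrait(fx$kin, 30, 70)
  G1 <- fx$G[, 2, drop = FALSE]
  w <- betaWeights(mean(G1) / 2)
  single <- fitLmmAssoc(y, stats::setNames(G1[, 1], fx$ids), fx$kin)
  b <- burdenTest(y, G1, w, fx$kin)
  expect_lt(abs(b@p[["burden"]] - single@p), 1e-10)
  ## SKAT-O boundary identities (criteria stated to 1e-10)
  sk <- skatTest(y, G1, w, fx$kin)
  so0 <- skatOTest(y, G1, w, fx$kin, rho = 0)
  so1 <- skatOTest(y, G1, w, fx$kin, rho = 1)
  expect_lt(abs(so0@p[["skato"]] - sk@p[["skat"]]), 1e-10)
  expect_lt(abs(so1@p[["skato"]] - b@p[["burden"]]), 1e-10)
})

test_that("SKAT eigenvalues sum to the kernel trace and p is calibrated-ish", {
  fx <- famFixture()
  set.seed(57)
  y <- mvnTrait(fx$kin, 30, 70)
  w <- betaWeights(colMeans(fx$G) / 2)
  sk <- skatTest(y, fx$G, w, fx$kin)
  ## trace identity: rebuild the kernel from the null model
  nl <- pedscan:::.skatNull(y, fx$kin, NULL)
  GW <- sweep(fx$G[nl$ids, ], 2, w, `*`)
  expect_lt(abs(sum(sk@lambda) - sum(diag(crossprod(GW, nl$P %*% GW)))), 1e-8)
  expect_true(sk@p[["skat"]] > 0 && sk@p[["skat"]] <= 1)
})

test_that("SKAT-O p behaves like a corrected minimum over the rho grid", {
  fx <- famFixture()
  set.seed(58)
  y <- mvnTrait(fx$kin, 30, 70) - 4 * fx$G[, 1] - 3 * fx$G[, 4]
  so <- skatOTest(y, fx$G, kinship = fx$kin)
  expect_gte(so@p[["skato"]], 0.5 * min(so@rhoP))
  expect_lte(so@p[["skato"]], 1)
  expect_equal(unname(so@rhoP[1]),
               unname(skatTest(y, fx$G, kinship = fx$kin)@p[["skat"]]),
               tolerance = 1e-10)
})

test_that("set tests are bit-reproducible on identical inputs", {
  fx <- famFixture()
  set.seed(59)
  y <- mvnTrait(fx$kin, 30, 70)
  r1 <- skatOTest(y, fx$G, kinship = fx$kin)
  r2 <- skatOTest(y, fx$G, kinship = fx$kin)
  expect_identical(r1@p, r2@p)
  expect_identical(burdenTest(y, fx$G, kinship = fx$kin)@p,
                   burdenTest(y, fx$G, kinship = fx$kin)@p)
})

test_that("burden beats any single variant when effects align", {
  fx <- famFixture()
  set.seed(60)
  nRep <- 40
  hitB <- hitS <- matrix(FALSE, nRep, 5)
  for (r in seq_len(nRep)) {
    y <- mvnTrait(fx$kin, 30, 70) + as.numeric(fx$G %*% rep(-6, 5))
    y <- stats::setNames(y, fx$ids)
    hitB[r, ] <- burdenTest(y, fx$G, kinship = fx$kin)@p[["burden"]] <= 0.05
    for (j in 1:5) {
      p <- tryCatch(fitLmmAssoc(y, stats::setNames(fx$G[, j], fx$ids), fx$kin)@p,
                    error = function(e) 1)
      hitS[r, j] <- p <= 0.05
    }
  }
  expect_gte(mean(hitB[, 1]), max(colMeans(hitS)))
})

test_that("meta-analysis combines and degrades as expected", {
  expect_equal(metaCombine(0.03), 0.03)
  expect_equal(metaCombine(rep(0.05, 4)),
               pchisq(-2 * 4 * log(0.05), df = 8, lower.tail = FALSE))
  expect_equal(round(-2 * 4 * log(0.05), 2), 23.97)
  expect_lt(abs(metaCombine(rep(0.05, 4)) - 0.0023), 2e-4)
  ## adding an uninformative study increases the combined p
  expect_gt(metaCombine(c(0.01, 0.02, 1)), metaCombine(c(0.01, 0.02)))
  expect_warning(p0 <- metaCombine(c(0, 0.5)), "clipped")
  expect_gt(p0, 0)
  ## Stouffer variant with sample-size weights
  ps <- metaCombine(c(0.01, 0.5), n = c(1000, 100), method = "stouffer")
  expect_lt(ps, metaCombine(c(0.01, 0.5), n = c(100, 1000), method = "stouffer"))
})
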