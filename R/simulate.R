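#' @include AllClasses.R pedigree-io.R kinship.R
NULL

#' Configuration for the family blood-pressure study simulator
#'
#' Defaults emulate a family-based BP cohort: about 130 families totalling
#' roughly 517 individuals, including one 17-member three-generation family;
#' a pruned linkage marker panel on one scan chromosome; a pool of unlinked
#' off-chromosome SNPs for resampling nulls; a rare protective variant
#' (founder MAF such that ~5 copies segregate in the large family only,
#' carrier effect -8 mmHg) plus additional rare coding variants with small
#' protective effects and inert rare variants in the same region; polygenic
#' and environmental variance; sex/age/age^2/BMI covariate effects; and
#' logistic antihypertensive-treatment masking (~25% treated) of observed BP.
#'
#' @param nFamilies total number of families (default 130).
#' @param includeLargeFamily include the 17-member three-generation family.
#' @param kidProbs distribution of the number of children in nuclear
#'   families (names = counts).
#' @param scanChrom,scanLengthcM,nScanMarkers,scanMafRange linkage panel.
#' @param nPoolSnps,poolMafRange unlinked off-chromosome SNP pool.
#' @param causal data.frame describing causal and inert region variants:
#'   columns id, cM, maf, beta, family (NA = segregates freely; a family id
#'   or placeholder label = private to that family, labels being resolved to
#'   distinct families at simulation time; variants sharing a label land in
#'   the same family), founder (which of the family's founders carries the
#'   forced haplotype; same founder = co-segregating variants), and
#'   minCarriers (rejection-sampling carrier target). A legacy logical
#'   column \code{restricted} is also accepted (TRUE = private to the
#'   largest family).
#' @param sigma2G,sigma2E polygenic and residual variance (mmHg^2).
#' @param fixed named effects: intercept, age, age2, bmi, sexMale.
#' @param medCenter,medSlope logistic treatment model on latent SBP.
#' @param sbpMask,dbpMask mmHg subtracted from observed BP under treatment.
#' @return list of class parameters for \code{\link{simulateStudy}}.
#' @export
simConfig <- function(nFamilies = 130, includeLargeFamily = TRUE,
                      kidProbs = c(`1` = 0.42, `2` = 0.35, `3` = 0.16, `4` = 0.07),
                      scanChrom = "16", scanLengthcM = 100, nScanMarkers = 61,
                      scanMafRange = c(0.2, 0.5),
                      nPoolSnps = 250, poolMafRange = c(0.05, 0.5),
                      causal = NULL,
                      sigma2G = 55, sigma2E = 70,
                      fixed = c(intercept = 102, age = 0.45, age2 = -0.001,
                                bmi = 0.35, sexMale = 4),
                      medCenter = 140, medSlope = 0.1,
                      sbpMask = 15, dbpMask = 10) {
  if (is.null(causal)) {
    ## family-private protective variants (rare coding variants segregating
    ## within single families account for the linkage signal), plus inert
    ## rare variants for the candidate filter to reject
    causal <- data.frame(
      id = c("rv_main",
             paste0("rv_", sprintf("%02d", 2:41)),
             paste0("nv_", sprintf("%02d", 1:6))),
      cM = c(50,
             rep(seq(42.2, 57.8, length.out = 20), each = 2) + c(0, 0.3),
             43, 47, 49.2, 51.2, 54, 56),
      maf = c(rep(0.004, 41), 0.003, 0.008, 0.015, 0.005, 0.020, 0.010),
      beta = c(-8,
               rep(c(-7, -6), 20),
               0, 0, 0, 0, 0, 0),
      ## the index family segregates the single -8 mmHg variant (carriers
      ## about 8 mmHg below noncarriers); each background family carries a
      ## protective haplotype bearing two coding variants (same founder)
      family = c("F001",
                 rep(sprintf("carrier%02d", 1:20), each = 2), rep(NA, 6)),
      founder = c(1L, rep(1L, 40), rep(NA, 6)),
      minCarriers = c(5L, rep(3L, 40), rep(0L, 6)),
      stringsAsFactors = FALSE)
  }
  if (!"family" %in% names(causal))
    causal$family <- if ("restricted" %in% names(causal))
      ifelse(causal$restricted, "F001", NA_character_) else NA_character_
  if (!"minCarriers" %in% names(causal))
    causal$minCarriers <- ifelse(is.na(causal$family), 0L, 2L)
  stopifnot(sigma2G >= 0, sigma2E >= 0, all(causal$maf > 0 & causal$maf <= 0.5))
  list(nFamilies = nFamilies, includeLargeFamily = includeLargeFamily,
       kidProbs = kidProbs, scanChrom = scanChrom,
       scanLengthcM = scanLengthcM, nScanMarkers = nScanMarkers,
       scanMafRange = scanMafRange, nPoolSnps = nPoolSnps,
       poolMafRange = poolMafRange, causal = causal,
       sigma2G = sigma2G, sigma2E = sigma2E, fixed = fixed,
       medCenter = medCenter, medSlope = medSlope,
       sbpMask = sbpMask, dbpMask = dbpMask)
}

#' Simulate pedigree structures
#'
#' Nuclear families (two founders, 1-4 children) drawn from the configured
#' size distribution, plus optionally one 17-member three-generation family
#' (a founding couple, four adult children with married-in spouses, and
#' seven grandchildren).
#'
#' @param config from \code{\link{simConfig}}.
#' @param seed integer seed.
#' @return A \linkS4class{Pedigree}.
#' @export
simulatePedigrees <- function(config = simConfig(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  rows <- list()
  addRow <- function(fam, id, fa, mo, sex)
    rows[[length(rows) + 1L]] <<- data.frame(family = fam, id = id,
                                             father = fa, mother = mo,
                                             sex = sex, stringsAsFactors = FALSE)
  famIds <- sprintf("F%03d", seq_len(config$nFamilies))
  start <- 1L
  if (config$includeLargeFamily) {
    f <- famIds[1]; start <- 2L
    pid <- function(x) paste0(f, "_", x)
    addRow(f, pid("gf"), NA, NA, "male")
    addRow(f, pid("gm"), NA, NA, "female")
    kidsPerBranch <- c(2L, 2L, 2L, 1L)
    for (b in 1:4) {
      child <- pid(paste0("c", b))
      csex <- if (b %% 2 == 1) "male" else "female"
      addRow(f, child, pid("gf"), pid("gm"), csex)
      spouse <- pid(paste0("s", b))
      addRow(f, spouse, NA, NA, if (csex == "male") "female" else "male")
      for (g in seq_len(kidsPerBranch[b])) {
        fa <- if (csex == "male") child else spouse
        mo <- if (csex == "male") spouse else child
        addRow(f, pid(paste0("g", b, g)), fa, mo,
               sample(c("male", "female"), 1))
      }
    }
  }
  nk <- as.integer(names(config$kidProbs))
  for (i in seq(start, config$nFamilies)) {
    f <- famIds[i]
    pid <- function(x) paste0(f, "_", x)
    addRow(f, pid("fa"), NA, NA, "male")
    addRow(f, pid("mo"), NA, NA, "female")
    kids <- sample(nk, 1, prob = config$kidProbs)
    for (g in seq_len(kids))
      addRow(f, pid(paste0("k", g)), pid("fa"), pid("mo"),
             sample(c("male", "female"), 1))
  }
  m <- do.call(rbind, rows)
  new("Pedigree", members = m)
}

## Marker panel implied by a config: scan chromosome grid + region variants
## + unlinked off-chromosome pool. freq2 is the generating founder frequency.
.simMarkers <- function(config) {
  scan <- data.frame(
    id = sprintf("m%s_%03d", config$scanChrom, seq_len(config$nScanMarkers)),
    chrom = config$scanChrom,
    cM = seq(0, config$scanLengthcM, length.out = config$nScanMarkers),
    stringsAsFactors = FALSE)
  scan$bp <- round(scan$cM * 1e6) + 1
  scan$freq2 <- stats::runif(nrow(scan), config$scanMafRange[1],
                             config$scanMafRange[2])
  cz <- config$causal
  region <- data.frame(id = cz$id, chrom = config$scanChrom, cM = cz$cM,
                       bp = round(cz$cM * 1e6) + 501, freq2 = cz$maf,
                       stringsAsFactors = FALSE)
  other <- setdiff(as.character(c(1:15, 17:22)), config$scanChrom)
  pool <- data.frame(
    id = sprintf("p_%03d", seq_len(config$nPoolSnps)),
    chrom = rep(other, length.out = config$nPoolSnps),
    cM = 50, stringsAsFactors = FALSE)
  pool <- pool[order(match(pool$chrom, other)), ]
  pool$cM <- stats::ave(pool$cM, pool$chrom, FUN = function(x) seq_along(x) * 25)
  pool$bp <- round(pool$cM * 1e6) + 1
  pool$freq2 <- stats::runif(nrow(pool), config$poolMafRange[1],
                             config$poolMafRange[2])
  mk <- rbind(scan, region, pool)
  mk$a1 <- "A"; mk$a2 <- "B"
  ord <- order(match(mk$chrom, unique(mk$chrom)), mk$cM, mk$bp)
  mk <- mk[ord, ]
  mk$restrictFamily <- cz$family[match(mk$id, cz$id)]
  mk$restrictFounder <- if ("founder" %in% names(cz))
    cz$founder[match(mk$id, cz$id)] else ifelse(is.na(mk$restrictFamily), NA, 1L)
  mk
}

## one meiosis: grandparental-origin indicator along the marker list,
## recombining within chromosomes (Haldane) and independent across them.
.meiosis <- function(chrom, theta) {
  n <- length(chrom)
  ind <- integer(n)
  newChrom <- c(TRUE, chrom[-1] != chrom[-n])
  cur <- 0L
  for (t in seq_len(n)) {
    if (newChrom[t]) cur <- as.integer(stats::runif(1) < 0.5)
    else if (stats::runif(1) < theta[t - 1]) cur <- 1L - cur
    ind[t] <- cur
  }
  ind
}

#' Gene-dropping genotype simulation
#'
#' Founder haplotypes are drawn from the per-marker founder allele
#' frequencies (linkage equilibrium); transmissions follow Haldane
#' recombination along the genetic map, independently across chromosomes.
#' Family-restricted variants segregate only in their designated family: the
#' designated founder's haplotype carries the allele and the family's drop
#' is rejection-sampled until every restricted variant reaches its carrier
#' target (clamped to what one founder haplotype can reach; capped at 1000
#' attempts, with a warning).
#'
#' @param pedigree a \linkS4class{Pedigree}.
#' @param markers data.frame with columns id, chrom, bp, cM, a1, a2, freq2
#'   and optionally restrictFamily / restrictFounder columns.
#' @param config from \code{\link{simConfig}} (supplies carrier targets);
#'   may be NULL when no variant is family-restricted.
#' @param seed integer seed.
#' @return A \linkS4class{GenotypeData}. Output always passes
#'   \code{\link{checkMendelian}} with zero errors.
#' @export
geneDrop <- function(pedigree, markers, config = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  m <- pedMembers(pedigree)
  nMark <- nrow(markers)
  theta <- rep(0.5, max(nMark - 1, 0))
  same <- markers$chrom[-1] == markers$chrom[-nMark]
  d <- diff(markers$cM) / 100
  theta[same] <- haldaneTheta(pmax(d[same], 0))
  restrictFam <- if ("restrictFamily" %in% names(markers))
    markers$restrictFamily else rep(NA_character_, nMark)
  anyRestr <- which(!is.na(restrictFam))
  minCarr <- if (length(anyRestr) && !is.null(config))
    stats::setNames(config$causal$minCarriers, config$causal$id) else NULL

  dos <- matrix(NA_integer_, nMark, nrow(m),
                dimnames = list(markers$id, m$id))
  for (fam in unique(m$family)) {
    fm <- m[m$family == fam, , drop = FALSE]
    fm <- fm[.topoOrder(fm), , drop = FALSE]
    n <- nrow(fm)
    isF <- is.na(fm$father)
    faIdx <- match(fm$father, fm$id); moIdx <- match(fm$mother, fm$id)
    own <- anyRestr[restrictFam[anyRestr] == fam]
    dropOnce <- function() {
      h1 <- h2 <- matrix(0L, n, nMark)
      for (i in which(isF)) {
        h1[i, ] <- as.integer(stats::runif(nMark) < markers$freq2)
        h2[i, ] <- as.integer(stats::runif(nMark) < markers$freq2)
      }
      ## family-restricted variants carry nothing outside their family; in
      ## it, the designated founder's first haplotype is forced to carry
      ## the allele (variants with the same founder index co-segregate)
      h1[isF, anyRestr] <- 0L; h2[isF, anyRestr] <- 0L
      if (length(own)) {
        fidx <- which(isF)
        fo <- if ("restrictFounder" %in% names(markers))
          markers$restrictFounder[own] else rep(1L, length(own))
        fo[is.na(fo)] <- 1L
        for (j in seq_along(own))
          h1[fidx[min(fo[j], length(fidx))], own[j]] <- 1L
      }
      for (i in which(!isF)) {
        pat <- .meiosis(markers$chrom, theta)
        mat <- .meiosis(markers$chrom, theta)
        fi <- faIdx[i]; mi <- moIdx[i]
        h1[i, ] <- ifelse(pat == 0L, h1[fi, ], h2[fi, ])
        h2[i, ] <- ifelse(mat == 0L, h1[mi, ], h2[mi, ])
      }
      h1 + h2                       # individuals x markers
    }
    g <- dropOnce()
    if (length(own)) {
      ## a single founder haplotype can reach at most 1 + nonfounder carriers
      target <- pmin(pmax(minCarr[markers$id[own]], 2L), 1L + sum(!isF))
      tries <- 1L
      while (any(colSums(g[, own, drop = FALSE] >= 1) < target) &&
             tries < 1000L) {
        g <- dropOnce()
        tries <- tries + 1L
      }
      if (tries >= 1000L)
        warning(sprintf("family %s: carrier target not reached in 1000 drops", fam))
    }
    dos[, fm$id] <- t(g)
  }
  GenotypeData(dos, markers[, c("id", "chrom", "bp", "cM", "a1", "a2")],
               pedigree)
}

#' Simulate blood-pressure phenotypes on a pedigree
#'
#' Latent SBP = fixed covariate effects + sum_j beta_j g_j + delta + eps with
#' delta ~ MVN(0, 2 Phi sigma2G) per family and eps iid N(0, sigma2E).
#' Antihypertensive treatment is assigned by a logistic model in latent SBP
#' (about 25% treated under the defaults) and masks observed pressures by
#' -15/-10 mmHg, which \code{\link{adjustMedication}} later adds back.
#'
#' @param pedigree a \linkS4class{Pedigree}.
#' @param genotypes a \linkS4class{GenotypeData} carrying the causal markers.
#' @param config from \code{\link{simConfig}}.
#' @param seed integer seed.
#' @return data.frame with columns id, family, sex, age, bmi, sbp, dbp,
#'   medication and attribute \code{"latent"} (the unmasked SBP).
#' @export
simulateTraits <- function(pedigree, genotypes, config = simConfig(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  m <- pedMembers(pedigree)
  n <- nrow(m)
  ## generational height above the youngest generation drives age
  height <- stats::setNames(rep(0, n), m$id)
  for (fam in unique(m$family)) {
    fm <- m[m$family == fam, , drop = FALSE]
    fm <- fm[rev(.topoOrder(fm)), , drop = FALSE]    # children first
    for (i in seq_len(nrow(fm)))
      if (!is.na(fm$father[i])) {
        h <- height[fm$id[i]] + 1
        height[fm$father[i]] <- max(height[fm$father[i]], h)
        height[fm$mother[i]] <- max(height[fm$mother[i]], h)
      }
  }
  age <- pmax(round(21 + 27 * height[m$id] + stats::rnorm(n, 0, 4)), 16)
  bmi <- round(stats::rnorm(n, 27, 4), 1)
  sex <- m$sex
  fx <- config$fixed
  y <- fx["intercept"] + fx["age"] * age + fx["age2"] * age^2 +
    fx["bmi"] * bmi + fx["sexMale"] * (sex == "male")
  ## causal genotype effects
  dos <- dosageMatrix(genotypes)
  cz <- config$causal[config$causal$beta != 0, , drop = FALSE]
  for (j in seq_len(nrow(cz))) {
    gj <- dos[cz$id[j], m$id]
    gj[is.na(gj)] <- 0
    y <- y + cz$beta[j] * gj
  }
  ## polygenic + environmental components
  phi <- phiMatrix(kinshipMatrix(pedigree))
  for (fam in unique(m$family)) {
    ids <- m$id[m$family == fam]
    L <- chol(2 * phi[ids, ids] * config$sigma2G +
                diag(1e-10, length(ids)))
    y[match(ids, m$id)] <- y[match(ids, m$id)] +
      as.numeric(crossprod(L, stats::rnorm(length(ids))))
  }
  y <- y + stats::rnorm(n, 0, sqrt(config$sigma2E))
  names(y) <- m$id
  dbpLat <- 40 + 0.25 * y + stats::rnorm(n, 0, 6)
  treated <- as.integer(stats::runif(n) <
                          stats::plogis(config$medSlope * (y - config$medCenter)))
  sbpObs <- round(y - config$sbpMask * treated, 1)
  dbpObs <- round(dbpLat - config$dbpMask * treated, 1)
  out <- data.frame(id = m$id, family = m$family, sex = sex, age = age,
                    bmi = bmi, sbp = sbpObs, dbp = dbpObs,
                    medication = treated, stringsAsFactors = FALSE)
  attr(out, "latent") <- unname(y)
  out
}

#' Simulate a complete family blood-pressure study
#'
#' One global seed fans out into independent sub-streams for the pedigree,
#' genotype and trait stages, so stages can be regenerated independently and
#' the whole study is bit-reproducible.
#'
#' @param seed integer seed.
#' @param config from \code{\link{simConfig}}.
#' @return list with elements \code{pedigree}, \code{genotypes},
#'   \code{pheno} and \code{truth} (causal table, variance components,
#'   stage seeds).
#' @export
simulateStudy <- function(seed, config = simConfig()) {
  set.seed(seed)
  sub <- sample.int(2^31 - 2, 4)
  ped <- simulatePedigrees(config, seed = sub[1])
  set.seed(sub[2])
  ## resolve placeholder family labels (values that are not actual family
  ## ids) to distinct families large enough for their carrier targets;
  ## variants sharing a label land in the same family
  cz <- config$causal
  if (!"founder" %in% names(cz))
    cz$founder <- ifelse(is.na(cz$family), NA_integer_, 1L)
  fams <- famIDs(ped)
  lab <- !is.na(cz$family) & !(cz$family %in% fams)
  if (any(lab)) {
    sizes <- table(pedMembers(ped)$family)
    labels <- unique(cz$family[lab])
    need <- vapply(labels, function(L)
      max(pmax(cz$minCarriers[cz$family == L], 2L)) + 1L, 0)
    pool <- setdiff(names(sizes), cz$family[!lab & !is.na(cz$family)])
    pool <- pool[order(-sizes[pool])]
    map <- stats::setNames(character(length(labels)), labels)
    for (j in order(-need)) {
      ok <- pool[sizes[pool] >= need[j]]
      map[j] <- if (length(ok)) ok[1] else pool[1]
      pool <- setdiff(pool, map[j])
    }
    cz$family[lab] <- map[cz$family[lab]]
  }
  config$causal <- cz
  markers <- .simMarkers(config)
  geno <- geneDrop(ped, markers, config, seed = sub[3])
  pheno <- simulateTraits(ped, geno, config, seed = sub[4])
  truth <- list(seed = seed, stageSeeds = sub, causal = config$causal,
                sigma2G = config$sigma2G, sigma2E = config$sigma2E,
                scanChrom = config$scanChrom)
  list(pedigree = ped, genotypes = geno, pheno = pheno, truth = truth)
}

#' Write a simulated study to disk
#'
#' PED/MAP genotypes, tab-separated phenotypes and a JSON truth file
#' (causal variants, effect sizes, variance components, stage seeds).
#' Byte-identical for identical studies.
#'
#' @param study from \code{\link{simulateStudy}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pedF <- file.path(dir, "study.ped"); mapF <- file.path(dir, "study.map")
  writePedMap(study$pedigree, study$genotypes, pedF, mapF)
  phF <- file.path(dir, "phenotypes.tsv")
  utils::write.table(study$pheno, phF, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  trF <- file.path(dir, "truth.json")
  jsonlite::write_json(study$truth, trF, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(pedF, mapF, phF, trF))
}
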