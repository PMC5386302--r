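#' @include AllClasses.R
NULL

#' Construct a Pedigree
#'
#' @param family,id,father,mother character vectors; \code{father}/\code{mother}
#'   are \code{NA} (or \code{"0"}) for founders.
#' @param sex character (\code{"male"}, \code{"female"}, \code{"unknown"}) or
#'   PLINK codes (1 = male, 2 = female, 0/other = unknown).
#' @return A \linkS4class{Pedigree}.
#' @export
Pedigree <- function(family, id, father, mother, sex = "unknown") {
  sex <- as.character(sex)
  sex[sex == "1"] <- "male"
  sex[sex == "2"] <- "female"
  sex[!sex %in% c("male", "female")] <- "unknown"
  fix0 <- function(x) { x <- as.character(x); x[x %in% c("0", "")] <- NA; x }
  m <- data.frame(family = as.character(family), id = as.character(id),
                  father = fix0(father), mother = fix0(mother),
                  sex = rep_len(sex, length(id)), stringsAsFactors = FALSE)
  new("Pedigree", members = m)
}

#' Construct a GenotypeData object
#'
#' @param dosage integer matrix, markers x individuals, copies of allele
#'   \code{a2} (0/1/2, \code{NA} missing).
#' @param markers data.frame with columns \code{id}, \code{chrom}, \code{bp},
#'   \code{cM}, \code{a1}, \code{a2}.
#' @param pedigree a \linkS4class{Pedigree} covering the individuals in
#'   \code{colnames(dosage)}.
#' @return A \linkS4class{GenotypeData}.
#' @export
GenotypeData <- function(dosage, markers, pedigree) {
  m <- pedMembers(pedigree)
  if (is.null(colnames(dosage))) stop("dosage must have individual ids as colnames")
  miss <- setdiff(colnames(dosage), m$id)
  if (length(miss))
    stop("individuals in genotype data absent from pedigree: ",
         paste(miss, collapse = ", "))
  rd <- S4Vectors::DataFrame(markers[setdiff(names(markers), "id")],
                             row.names = markers$id)
  rownames(dosage) <- markers$id
  cd <- S4Vectors::DataFrame(family = m$family[match(colnames(dosage), m$id)],
                             row.names = colnames(dosage))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage), rowData = rd, colData = cd)
  new("GenotypeData", se)
}

#' Marker table of a GenotypeData object
#' @param geno a \linkS4class{GenotypeData}.
#' @return data.frame with columns id, chrom, bp, cM, a1, a2.
#' @export
markerTable <- function(geno) {
  rd <- SummarizedExperiment::rowData(geno)
  data.frame(id = rownames(geno), chrom = rd$chrom, bp = rd$bp, cM = rd$cM,
             a1 = rd$a1, a2 = rd$a2, stringsAsFactors = FALSE)
}

#' Dosage matrix of a GenotypeData object
#' @param geno a \linkS4class{GenotypeData}.
#' @return integer matrix markers x individuals (copies of allele a2).
#' @export
dosageMatrix <- function(geno) SummarizedExperiment::assay(geno, "dosage")

#' Read pedigree and genotypes from PLINK text PED/MAP files
#'
#' Whitespace-delimited PED (family, id, father, mother, sex, phenotype, then
#' two allele columns per marker; "0" = missing allele or parent) and a
#' 4-column MAP (chromosome, marker id, cM, bp). Allele codes are arbitrary
#' strings; per marker, \code{a1}/\code{a2} are the sorted distinct alleles
#' observed and dosage counts copies of \code{a2}.
#'
#' @param pedFile,mapFile paths.
#' @param strictParents if \code{TRUE} (default) a named parent absent from
#'   the file is an error; if \code{FALSE} a founder of unknown sex is
#'   synthesized with all-missing genotypes.
#' @return list with elements \code{pedigree} and \code{genotypes}.
#' @export
readPedMap <- function(pedFile, mapFile, strictParents = TRUE) {
  map <- tryCatch(utils::read.table(mapFile, header = FALSE,
                                    col.names = c("chrom", "id", "cM", "bp"),
                                    colClasses = c("character", "character",
                                                   "numeric", "numeric")),
                  error = function(e) stop("malformed MAP file ", mapFile, ": ",
                                           conditionMessage(e), call. = FALSE))
  lines <- readLines(pedFile)
  lines <- lines[nzchar(trimws(lines))]
  nmk <- nrow(map)
  want <- 6 + 2 * nmk
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != want))
    stop(sprintf("malformed PED line %d: %d fields, expected %d",
                 which(nf != want)[1], nf[nf != want][1], want), call. = FALSE)
  ped <- t(vapply(fields, function(f) f[1:6], character(6)))
  ids <- ped[, 2]
  if (anyDuplicated(ids))
    stop("duplicated individual id in PED: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  al <- t(vapply(fields, function(f) f[-(1:6)], character(2 * nmk)))
  fam <- ped[, 1]; fa <- ped[, 3]; mo <- ped[, 4]; sex <- ped[, 5]
  fa[fa == "0"] <- NA; mo[mo == "0"] <- NA
  known <- split(ids, fam)
  for (p in c("father", "mother")) {
    pp <- if (p == "father") fa else mo
    bad <- !is.na(pp) & !mapply(function(x, f) x %in% known[[f]], pp, fam)
    if (any(bad)) {
      if (strictParents)
        stop(sprintf("PED line %d: %s '%s' not present in family %s (strict mode)",
                     which(bad)[1], p, pp[which(bad)[1]], fam[which(bad)[1]]),
             call. = FALSE)
      add <- unique(data.frame(family = fam[bad], id = pp[bad],
                               stringsAsFactors = FALSE))
      fam <- c(fam, add$family); ids <- c(ids, add$id)
      fa <- c(fa, rep(NA, nrow(add))); mo <- c(mo, rep(NA, nrow(add)))
      sex <- c(sex, rep("0", nrow(add)))
      al <- rbind(al, matrix("0", nrow(add), ncol(al)))
      known <- split(ids, fam)
    }
  }
  pedigree <- Pedigree(fam, ids, fa, mo, sex)
  ## allele pairs -> dosage
  a1 <- al[, seq(1, 2 * nmk, 2), drop = FALSE]
  a2 <- al[, seq(2, 2 * nmk, 2), drop = FALSE]
  dos <- matrix(NA_integer_, nmk, length(ids),
                dimnames = list(map$id, ids))
  A1 <- A2 <- character(nmk)
  for (j in seq_len(nmk)) {
    x <- a1[, j]; y <- a2[, j]
    miss <- x == "0" | y == "0"
    obs <- sort(unique(c(x[!miss], y[!miss])))
    if (length(obs) > 2)
      stop(sprintf("marker %s has >2 alleles: %s", map$id[j],
                   paste(obs, collapse = ",")), call. = FALSE)
    if (length(obs) == 0) obs <- c("0", "0")
    if (length(obs) == 1) obs <- c(obs, obs)
    A1[j] <- obs[1]; A2[j] <- obs[2]
    dos[j, !miss] <- (x[!miss] == A2[j]) + (y[!miss] == A2[j])
  }
  markers <- data.frame(id = map$id, chrom = map$chrom, bp = map$bp,
                        cM = map$cM, a1 = A1, a2 = A2, stringsAsFactors = FALSE)
  o <- order(match(markers$chrom, unique(markers$chrom)), markers$cM, markers$bp)
  markers <- markers[o, ]; dos <- dos[o, , drop = FALSE]
  list(pedigree = pedigree,
       genotypes = GenotypeData(dos, markers, pedigree))
}

#' Write pedigree and genotypes as PLINK text PED/MAP
#'
#' Inverse of \code{\link{readPedMap}} for non-missing data: unordered allele
#' pairs round-trip exactly (heterozygotes written a1 then a2).
#'
#' @param pedigree a \linkS4class{Pedigree}.
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param pedFile,mapFile output paths.
#' @export
writePedMap <- function(pedigree, genotypes, pedFile, mapFile) {
  mk <- markerTable(genotypes)
  utils::write.table(mk[, c("chrom", "id", "cM", "bp")], mapFile,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  m <- pedMembers(pedigree)
  m <- m[m$id %in% colnames(genotypes), ]
  dos <- dosageMatrix(genotypes)[, m$id, drop = FALSE]
  sexCode <- c(male = "1", female = "2", unknown = "0")[m$sex]
  con <- file(pedFile, "w"); on.exit(close(con))
  for (i in seq_len(nrow(m))) {
    d <- dos[, i]
    g1 <- ifelse(is.na(d), "0", ifelse(d >= 1, mk$a2, mk$a1))
    g2 <- ifelse(is.na(d), "0", ifelse(d == 2, mk$a2, mk$a1))
    ## write het as "a1 a2"
    h <- !is.na(d) & d == 1
    g1[h] <- mk$a1[h]; g2[h] <- mk$a2[h]
    writeLines(paste(c(m$family[i], m$id[i],
                       ifelse(is.na(m$father[i]), "0", m$father[i]),
                       ifelse(is.na(m$mother[i]), "0", m$mother[i]),
                       sexCode[i], "0", rbind(g1, g2)), collapse = " "), con)
  }
  invisible(c(pedFile, mapFile))
}

#' Read genotypes for a pedigree from a VCF file
#'
#' Maps GT fields of a biallelic-site VCF onto the same dosage representation
#' used by \code{\link{readPedMap}}. Genetic positions default to bp/1e6
#' (1 cM per Mb) unless a \code{cM} INFO-style column is supplied via
#' \code{cmPerMb}.
#'
#' @param vcfFile path to an (uncompressed or bgzipped) VCF.
#' @param pedigree a \linkS4class{Pedigree} covering the VCF samples.
#' @param cmPerMb scale for genetic positions (default 1).
#' @return A \linkS4class{GenotypeData}.
#' @export
readGenotypesVCF <- function(vcfFile, pedigree, cmPerMb = 1) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("readGenotypesVCF requires the vcfR package")
  v <- vcfR::read.vcfR(vcfFile, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt))) stop("multiallelic VCF records are not supported")
  dos <- apply(gt, 2, function(col) {
    col <- gsub("\\|", "/", col)
    out <- rep(NA_integer_, length(col))
    out[col == "0/0"] <- 0L; out[col %in% c("0/1", "1/0")] <- 1L
    out[col == "1/1"] <- 2L
    out
  })
  dos <- matrix(as.integer(dos), nrow(gt), ncol(gt), dimnames = dimnames(gt))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  markers <- data.frame(id = ids, chrom = fix[, "CHROM"],
                        bp = as.numeric(fix[, "POS"]),
                        cM = as.numeric(fix[, "POS"]) / 1e6 * cmPerMb,
                        a1 = fix[, "REF"], a2 = alt, stringsAsFactors = FALSE)
  GenotypeData(dos, markers, pedigree)
}

#' Check Mendelian consistency of trio genotypes
#'
#' For every child with both parents present, flags markers where the child
#' dosage cannot arise from one allele of each parent. Report-only; compatible
#' data yield a zero-row report.
#'
#' @param pedigree a \linkS4class{Pedigree}.
#' @param genotypes a \linkS4class{GenotypeData}.
#' @return data.frame with columns family, marker, child, father, mother,
#'   childDosage, fatherDosage, motherDosage.
#' @export
checkMendelian <- function(pedigree, genotypes) {
  m <- pedMembers(pedigree)
  dos <- dosageMatrix(genotypes)
  kids <- m[!is.na(m$father) & m$father %in% colnames(dos) &
              m$mother %in% colnames(dos) & m$id %in% colnames(dos), ]
  out <- list()
  for (i in seq_len(nrow(kids))) {
    c0 <- dos[, kids$id[i]]; f0 <- dos[, kids$father[i]]; m0 <- dos[, kids$mother[i]]
    ## transmissible alleles: dosage 0 -> {0}, 1 -> {0,1}, 2 -> {1}
    fLo <- ifelse(f0 == 2, 1L, 0L); fHi <- ifelse(f0 == 0, 0L, 1L)
    mLo <- ifelse(m0 == 2, 1L, 0L); mHi <- ifelse(m0 == 0, 0L, 1L)
    bad <- !is.na(c0) & !is.na(f0) & !is.na(m0) &
      (c0 < fLo + mLo | c0 > fHi + mHi)
    if (any(bad))
      out[[length(out) + 1L]] <- data.frame(
        family = kids$family[i], marker = rownames(dos)[bad],
        child = kids$id[i], father = kids$father[i], mother = kids$mother[i],
        childDosage = c0[bad], fatherDosage = f0[bad], motherDosage = m0[bad],
        stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(family = character(), marker = character(),
                  child = character(), father = character(), mother = character(),
                  childDosage = integer(), fatherDosage = integer(),
                  motherDosage = integer(), stringsAsFactors = FALSE)
}

#' Read a phenotype table
#'
#' Tab-separated with header; requires an \code{id} column. Conventional
#' columns: \code{sbp}, \code{dbp}, \code{medication} (0/1), \code{sex},
#' \code{age}, \code{bmi}, and optional principal-component columns.
#'
#' @param file path.
#' @return data.frame, one row per individual.
#' @export
readPhenotypes <- function(file) {
  ph <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!"id" %in% names(ph)) stop("phenotype table must have an 'id' column")
  if (anyDuplicated(ph$id)) stop("duplicated id in phenotype table")
  ph
}

#' Write a kinship matrix as a square TSV with ids
#' @param kinship a \linkS4class{KinshipMatrix}.
#' @param file path.
#' @export
writeKinship <- function(kinship, file) {
  utils::write.table(phiMatrix(kinship), file, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(file)
}
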