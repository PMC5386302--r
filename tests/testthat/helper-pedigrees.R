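# Small pedigree/genotype builders shared across tests.

nuclearFamily <- function(famId = "f1", nKids = 2, sex = NULL) {
  ids <- paste0(famId, "_", c("fa", "mo", paste0("k", seq_len(nKids))))
  Pedigree(family = rep(famId, 2 + nKids), id = ids,
           father = c(NA, NA, rep(ids[1], nKids)),
           mother = c(NA, NA, rep(ids[2], nKids)),
           sex = if (is.null(sex)) c("male", "female", rep("unknown", nKids)) else sex)
}

# three-generation 6-member pedigree: grandparents, their daughter, her
# husband (founder), two grandsons (8 meiosis bits)
threeGenFamily <- function(famId = "g1") {
  ids <- paste0(famId, "_", c("gf", "gm", "fa", "mo", "k1", "k2"))
  Pedigree(family = rep(famId, 6), id = ids,
           father = c(NA, NA, NA, ids[1], ids[3], ids[3]),
           mother = c(NA, NA, NA, ids[2], ids[4], ids[4]),
           sex = c("male", "female", "male", "female", "male", "male"))
}

manyNuclear <- function(n, nKids = 4) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    m <- pedMembers(nuclearFamily(sprintf("F%03d", i), nKids))
    m
  })) -> m
  new("Pedigree", members = m)
}

markerPanel <- function(cM, chrom = "1", freq2 = 0.5) {
  data.frame(id = paste0("m", seq_along(cM)), chrom = chrom,
             bp = seq_along(cM) * 1e6, cM = cM, a1 = "A", a2 = "B",
             freq2 = rep_len(freq2, length(cM)), stringsAsFactors = FALSE)
}

# trait with family covariance 2*Phi*s2G + I*s2E (dense oracle construction,
# independent of the fitting code)
mvnTrait <- function(kinship, s2G, s2E, mu = 0) {
  phi <- phiMatrix(kinship)
  n <- nrow(phi)
  L <- chol(2 * phi * s2G + diag(s2E, n))
  stats::setNames(mu + as.numeric(crossprod(L, stats::rnorm(n))), rownames(phi))
}
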