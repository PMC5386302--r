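#' @include AllClasses.R
NULL

#' Medication adjustment and pulse pressure
#'
#' Treated individuals get the standard increments added to observed blood
#' pressure (+15 mmHg systolic, +10 mmHg diastolic); pulse pressure is the
#' difference between adjusted SBP and DBP. A missing medication flag is
#' treated as untreated, with a warning.
#'
#' @param pheno data.frame with columns \code{sbp}, \code{dbp},
#'   \code{medication} (0/1).
#' @param sbpAdd,dbpAdd increments in mmHg (defaults 15 and 10).
#' @return \code{pheno} with columns \code{sbpAdj}, \code{dbpAdj}, \code{pp}
#'   added.
#' @export
adjustMedication <- function(pheno, sbpAdd = 15, dbpAdd = 10) {
  need <- c("sbp", "dbp", "medication")
  if (!all(need %in% names(pheno)))
    stop("pheno must have columns ", paste(need, collapse = ", "))
  if (any(pheno$sbp <= 0 | pheno$dbp <= 0, na.rm = TRUE))
    stop("blood pressure values must be positive")
  med <- pheno$medication
  if (anyNA(med)) {
    warning(sum(is.na(med)), " missing medication flags treated as untreated")
    med[is.na(med)] <- 0
  }
  pheno$sbpAdj <- pheno$sbp + sbpAdd * (med == 1)
  pheno$dbpAdj <- pheno$dbp + dbpAdd * (med == 1)
  pheno$pp <- pheno$sbpAdj - pheno$dbpAdj
  pheno
}

#' Residualize a trait on covariates by ordinary least squares
#'
#' Plain OLS residuals (family structure is deliberately ignored here: the
#' kinship matrix handles relatedness downstream, so the linkage input is
#' identical across methods). Residuals are orthogonal to every design
#' column. Individuals with missing covariates are dropped (listwise), with
#' a message. When the analyzed trait is BMI it must not appear in its own
#' covariate set.
#'
#' @param pheno data.frame with an \code{id} column, the trait, and the
#'   covariates. \code{age2} is derived from \code{age} when requested but
#'   absent.
#' @param trait column name of the trait.
#' @param covariates character vector of covariate column names (default
#'   sex, age, age2, bmi and any \code{pc} columns present).
#' @return named numeric vector of residuals.
#' @export
residualizeTrait <- function(pheno, trait,
                             covariates = c("sex", "age", "age2", "bmi",
                                            grep("^pc", names(pheno),
                                                 value = TRUE))) {
  if (!"id" %in% names(pheno)) stop("pheno must have an 'id' column")
  if (trait %in% covariates)
    stop("trait '", trait, "' must be excluded from its own covariate set")
  if ("age2" %in% covariates && !"age2" %in% names(pheno))
    pheno$age2 <- pheno$age^2
  miss <- setdiff(c(trait, covariates), names(pheno))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  X <- pheno[, covariates, drop = FALSE]
  if ("sex" %in% covariates && !is.numeric(X$sex))
    X$sex <- as.numeric(factor(X$sex, levels = c("female", "male", "unknown"))) - 1
  keep <- stats::complete.cases(X) & !is.na(pheno[[trait]])
  if (!all(keep))
    message(sum(!keep), " individuals dropped for missing trait/covariates")
  Xm <- as.matrix(X[keep, , drop = FALSE])
  qrX <- qr(cbind(1, Xm))
  if (qrX$rank < ncol(Xm) + 1)
    stop("rank-deficient design; collinear columns: ",
         paste(c("(Intercept)", colnames(Xm))[qrX$pivot[-seq_len(qrX$rank)]],
               collapse = ", "))
  r <- stats::lm.fit(cbind(`(Intercept)` = 1, Xm), pheno[[trait]][keep])$residuals
  stats::setNames(r, pheno$id[keep])
}

#' Founder-based principal components (convenience)
#'
#' PCA of standardized founder dosages, with non-founders projected onto the
#' founder axes. This is a convenience utility for simulated or exploratory
#' data, not a reproduction of any dedicated family-aware PC algorithm;
#' externally computed PC columns can always be supplied instead.
#'
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param pedigree a \linkS4class{Pedigree}.
#' @param k number of components (default 10).
#' @return matrix of scores, individuals x k, id rownames.
#' @export
founderPCA <- function(genotypes, pedigree, k = 10) {
  dos <- t(dosageMatrix(genotypes))           # individuals x markers
  f <- intersect(founderIDs(pedigree), rownames(dos))
  Df <- dos[f, , drop = FALSE]
  mu <- colMeans(Df, na.rm = TRUE)
  sdv <- apply(Df, 2, stats::sd, na.rm = TRUE)
  use <- which(!is.na(sdv) & sdv > 0)
  std <- function(D) {
    Z <- sweep(D[, use, drop = FALSE], 2, mu[use], `-`)
    Z <- sweep(Z, 2, sdv[use], `/`)
    Z[is.na(Z)] <- 0
    Z
  }
  pc <- stats::prcomp(std(Df), center = FALSE, scale. = FALSE)
  k <- min(k, ncol(pc$rotation))
  scores <- std(dos) %*% pc$rotation[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("pc", seq_len(k))
  scores
}
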