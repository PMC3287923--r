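#' Covariate-adjust a trait to standardized residuals
#'
#' Ordinary least-squares regression of the trait on an intercept plus age,
#' sex and smoking over the pooled sample; residuals are divided by their
#' sample standard deviation (n - 1 denominator). Relatedness is deliberately
#' ignored at this step: residual correlation is modeled downstream by the
#' variance-component stage.
#'
#' @param y numeric trait values.
#' @param covar data.frame (or matrix) with columns \code{age}, \code{sex},
#'   \code{smoke}.
#' @return numeric vector of standardized residuals (mean 0, variance 1).
#' @export
adjustTrait <- function(y, covar) {
  stopifnot(length(y) >= 5L)
  X <- cbind(intercept = 1, age = covar$age, sex = covar$sex,
             smoke = covar$smoke)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop(sprintf("covariate matrix is rank deficient; collinear column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  r <- stats::lm.fit(X, y)$residuals
  s <- stats::sd(r)
  if (!is.finite(s) || s < 1e-12)
    stop("zero residual variance: trait is fully explained by the covariates")
  r / s
}

#' Adjust replicated phenotypes
#'
#' Applies [adjustTrait()] within each replicate of a long phenotype table,
#' adding a standardized-residual column \code{<trait>_adj}.
#'
#' @param pheno long data.frame from [simulatePhenotypes()] (columns
#'   \code{replicate}, \code{age}, \code{sex}, \code{smoke} and the trait).
#' @param trait trait column name.
#' @return \code{pheno} with an added adjusted column.
#' @export
adjustPhenotypes <- function(pheno, trait) {
  stopifnot(trait %in% names(pheno))
  adj <- numeric(nrow(pheno))
  for (i in split(seq_len(nrow(pheno)), pheno$replicate))
    adj[i] <- adjustTrait(pheno[[trait]][i], pheno[i, ])
  pheno[[paste0(trait, "_adj")]] <- adj
  pheno
}
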