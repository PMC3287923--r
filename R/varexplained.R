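#' Additive genetic score of a gene
#'
#' Per-individual additive value \eqn{\sum_v c_v \beta_v} over the gene's
#' causal variants (allele count times effect, summed), assuming an additive
#' model: the effect of the gene is the sum of all causal variants in it.
#'
#' @param gd a [GenotypeData-class] object.
#' @param gene gene name.
#' @return named numeric vector of scores (trait units), zero for
#'   non-carriers.
#' @export
geneScore <- function(gd, gene) {
  v <- which(variantInfo(gd)$gene == gene)
  if (!length(v)) stop(sprintf("unknown gene '%s'", gene))
  drop(alleleCounts(gd)[, v, drop = FALSE] %*% variantInfo(gd)$beta[v])
}

#' Percent phenotypic variance explained by a gene
#'
#' Mean over replicates of the ratio of the gene-score variance to the raw
#' trait variance within a group (a family or the total sample), times 100.
#' The score is fixed; only the trait varies across replicates. The
#' denominator is the unadjusted trait ("total phenotypic variance"); set
#' \code{useAdjusted = TRUE} to use the standardized residuals instead.
#'
#' @param score named numeric gene score per individual (from [geneScore()]).
#' @param pheno long phenotype data.frame (columns \code{replicate},
#'   \code{fid}, \code{iid} and the trait).
#' @param trait trait column name.
#' @param group a family id, or \code{"total"} for the whole sample.
#' @param useAdjusted use the \code{<trait>_adj} column as denominator.
#' @return percent of phenotypic variance (0-100 scale).
#' @export
pctVariance <- function(score, pheno, trait, group = "total",
                        useAdjusted = FALSE) {
  col <- if (useAdjusted) paste0(trait, "_adj") else trait
  stopifnot(col %in% names(pheno))
  sub <- if (identical(group, "total")) pheno else pheno[pheno$fid == group, ]
  if (!nrow(sub)) stop(sprintf("no individuals in group '%s'", group))
  ratios <- vapply(split(sub, sub$replicate), function(d) {
    if (nrow(d) < 2L) stop("group must have at least 2 members")
    vt <- stats::var(d[[col]])
    if (!is.finite(vt) || vt <= 0)
      stop(sprintf("zero trait variance in replicate %d", d$replicate[1L]))
    stats::var(score[d$iid]) / vt
  }, 0.0)
  100 * mean(ratios)
}

#' Minor allele frequency from a copy count
#'
#' @param count minor-allele copy count.
#' @param n number of diploid individuals.
#' @param percent report as percent.
#' @return allele frequency \eqn{count / (2n)} (fraction, or percent).
#' @examples
#' minorAlleleFrequency(1, 697, percent = TRUE)   # 0.0717%
#' @export
minorAlleleFrequency <- function(count, n, percent = FALSE) {
  stopifnot(count >= 0, n >= 1)
  if (count > 2 * n) stop("count exceeds 2n allele copies")
  f <- count / (2 * n)
  if (percent) 100 * f else f
}
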