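#' Select the family with the largest family-specific LOD
#'
#' Ties are broken deterministically by the lexicographically smallest family
#' id. Selection depends only on the ranking of family LODs, so it is
#' invariant to monotone rescaling within a replicate.
#'
#' @param profile a [FamilyLODProfile-class] object.
#' @return the selected family id.
#' @export
selectFamily <- function(profile) {
  fl <- familyLODs(profile)
  if (!length(fl)) stop("empty family LOD profile")
  cand <- names(fl)[fl == max(fl)]
  sort(cand)[1L]
}

#' Probability that a randomly chosen family carries the rare allele
#'
#' The number of families carrying at least one minor-allele copy of the
#' gene's causal variants (transmitted or not), divided by the number of
#' families.
#'
#' @param counts per-family minor-allele copy counts (numeric vector, or the
#'   data.frame from [countRareAlleles()]).
#' @param K number of families (default: length of \code{counts}).
#' @return probability in \{0, 1/K, ..., 1\}.
#' @export
expectedProbability <- function(counts, K = NULL) {
  if (is.data.frame(counts)) counts <- counts$count
  if (is.null(K)) K <- length(counts)
  stopifnot(K >= 1L, length(counts) == K)
  sum(counts >= 1) / K
}

#' Observed hit rate of max-LOD family selection
#'
#' Fraction of replicates in which the selected family carries at least one
#' causal minor allele.
#'
#' @param carrierFlags logical vector, one flag per replicate (or a
#'   data.frame of selection records with a \code{carrier} column).
#' @return proportion in \eqn{[0, 1]}.
#' @export
observedHitRate <- function(carrierFlags) {
  if (is.data.frame(carrierFlags)) carrierFlags <- carrierFlags$carrier
  stopifnot(length(carrierFlags) >= 1L)
  mean(carrierFlags)
}

#' Enrichment p-value versus random family selection
#'
#' One-sided upper-tail test of the observed hit rate against the expected
#' carrier probability. Default is the normal-approximation one-sample
#' proportion test without continuity correction,
#' \eqn{z = (obs - exp) / \sqrt{exp(1-exp)/n}}; an exact one-sided binomial
#' test is available. Degenerate expectations (0 or 1) give \code{NA}: under
#' them no enrichment is measurable.
#'
#' @param observed observed hit rate in \eqn{[0, 1]}.
#' @param expected expected carrier probability.
#' @param n number of replicates.
#' @param method \code{"ztest"} (default) or \code{"binomial"}.
#' @return one-sided p-value, or \code{NA} when \code{expected} is 0 or 1.
#' @export
enrichmentPvalue <- function(observed, expected, n,
                             method = c("ztest", "binomial")) {
  method <- match.arg(method)
  stopifnot(n >= 1L)
  if (observed < 0 || observed > 1) stop("observed must be in [0, 1]")
  if (expected <= 0 || expected >= 1) return(NA_real_)
  if (method == "ztest") {
    z <- (observed - expected) / sqrt(expected * (1 - expected) / n)
    stats::pnorm(z, lower.tail = FALSE)
  } else {
    x <- round(observed * n)
    stats::pbinom(x - 1, size = n, prob = expected, lower.tail = FALSE)
  }
}

#' Summarize enrichment per gene
#'
#' Builds the per-gene report: LOD and largest family-specific LOD averaged
#' over replicates (the maximum may come from different families across
#' replicates), the expected carrier probability, the observed hit rate, and
#' the enrichment p-value. Genes with no carrier family are flagged as
#' null-hypothesis genes (expected 0, p-value \code{NA}).
#'
#' @param linkage data.frame with columns \code{gene}, \code{replicate},
#'   \code{totalLOD}, \code{maxFamilyLOD}.
#' @param selections data.frame with columns \code{gene}, \code{replicate},
#'   \code{family}, \code{familyLOD}, \code{carrier}.
#' @param countsByGene named list (by gene) of [countRareAlleles()] results.
#' @param method test passed to [enrichmentPvalue()].
#' @return data.frame: \code{gene}, \code{meanLOD}, \code{meanLODmax},
#'   \code{expected}, \code{observed}, \code{pValue}, \code{nullGene}.
#' @export
summarizeEnrichment <- function(linkage, selections, countsByGene,
                                method = "ztest") {
  genes <- unique(linkage$gene)
  if (length(setdiff(genes, unique(selections$gene))) ||
      length(setdiff(genes, names(countsByGene))))
    stop(sprintf("gene(s) missing from selections or allele counts: %s",
                 paste(union(setdiff(genes, unique(selections$gene)),
                             setdiff(genes, names(countsByGene))),
                       collapse = ", ")))
  rows <- lapply(genes, function(g) {
    lk <- linkage[linkage$gene == g, ]
    sel <- selections[selections$gene == g, ]
    expd <- expectedProbability(countsByGene[[g]])
    obs <- observedHitRate(sel$carrier)
    data.frame(gene = g,
               meanLOD = mean(lk$totalLOD),
               meanLODmax = mean(lk$maxFamilyLOD),
               expected = expd,
               observed = obs,
               pValue = enrichmentPvalue(obs, expd, nrow(sel), method),
               nullGene = expd == 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
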