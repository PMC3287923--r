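#' @import methods
NULL

#' Pedigree class
#'
#' A single family: an ordered table of members with parent links. Members are
#' stored in topological order (every parent precedes its offspring), which the
#' constructor establishes; founders are members with both parents missing.
#'
#' @slot famID single family identifier.
#' @slot members data.frame with columns \code{id}, \code{father},
#'   \code{mother} (both \code{NA} for founders), \code{sex}
#'   (\code{"male"}/\code{"female"}) and \code{founder} (logical).
#'
#' @seealso [Pedigree()], [readPedigrees()], [kinship()]
#' @exportClass Pedigree
setClass("Pedigree",
  slots = c(famID = "character", members = "data.frame"))

setValidity("Pedigree", function(object) {
  m <- object@members
  need <- c("id", "father", "mother", "sex", "founder")
  if (!all(need %in% names(m)))
    return(sprintf("members must have columns %s", paste(need, collapse = ", ")))
  if (length(object@famID) != 1L || is.na(object@famID) || !nzchar(object@famID))
    return("famID must be a single non-empty string")
  if (anyDuplicated(m$id))
    return(sprintf("duplicate individual id in family %s: %s", object@famID,
                   m$id[duplicated(m$id)][1L]))
  half <- xor(is.na(m$father), is.na(m$mother))
  if (any(half))
    return(sprintf("individual %s has exactly one missing parent", m$id[half][1L]))
  if (!all(m$sex %in% c("male", "female")))
    return("sex must be 'male' or 'female'")
  pos <- seq_len(nrow(m))
  names(pos) <- m$id
  for (i in which(!m$founder)) {
    for (p in c(m$father[i], m$mother[i])) {
      if (!p %in% m$id)
        return(sprintf("individual %s references parent %s absent from family %s",
                       m$id[i], p, object@famID))
      if (pos[p] >= i)
        return(sprintf("members not in topological order: parent %s listed at or after child %s",
                       p, m$id[i]))
    }
  }
  if (!identical(m$founder, is.na(m$father)))
    return("founder flag inconsistent with missing parents")
  TRUE
})

#' Variance-component model fit
#'
#' Maximum-likelihood fit of the multivariate-normal variance-component model
#' with per-family covariance \eqn{\Omega_f = \sigma^2_q \Pi_f +
#' 2\sigma^2_a \Phi_f + \sigma^2_e I}. The null model constrains
#' \eqn{\sigma^2_q = 0}.
#'
#' @slot params named numeric: \code{mu}, \code{sigma2_q}, \code{sigma2_a},
#'   \code{sigma2_e}.
#' @slot loglik total log-likelihood (nats) at the estimates.
#' @slot familyLoglik named per-family log-likelihood contributions; sums to
#'   \code{loglik}.
#' @slot converged logical convergence flag.
#' @slot model \code{"full"} or \code{"null"}.
#' @slot fingerprint data digest used to guard LOD computation against
#'   mismatched fits.
#'
#' @seealso [vcFit()], [lodScore()], [familyLOD()]
#' @exportClass VCFit
setClass("VCFit",
  slots = c(params = "numeric", loglik = "numeric", familyLoglik = "numeric",
            converged = "logical", model = "character", fingerprint = "character"))

setValidity("VCFit", function(object) {
  p <- object@params
  if (!all(c("mu", "sigma2_q", "sigma2_a", "sigma2_e") %in% names(p)))
    return("params must be named mu, sigma2_q, sigma2_a, sigma2_e")
  v <- p[c("sigma2_q", "sigma2_a", "sigma2_e")]
  if (any(v < 0)) return("variance components must be non-negative")
  if (all(v == 0)) return("at least one variance component must be positive")
  if (!object@model %in% c("full", "null")) return("model must be 'full' or 'null'")
  if (object@model == "null" && p[["sigma2_q"]] != 0)
    return("null model requires sigma2_q = 0")
  if (abs(sum(object@familyLoglik) - object@loglik) > 1e-6)
    return("familyLoglik must sum to loglik")
  TRUE
})

#' Per-family LOD decomposition
#'
#' Family-specific LOD scores: each family's log10 likelihood-ratio
#' contribution evaluated at the whole-sample maximum-likelihood estimates of
#' the full and null models. Contributions sum to the total LOD.
#'
#' @slot familyLOD named numeric, one LOD per family (log10 units).
#' @slot totalLOD total LOD score.
#'
#' @seealso [familyLOD()], [selectFamily()]
#' @exportClass FamilyLODProfile
setClass("FamilyLODProfile",
  slots = c(familyLOD = "numeric", totalLOD = "numeric"))

setValidity("FamilyLODProfile", function(object) {
  if (length(object@familyLOD) &&
      (is.null(names(object@familyLOD)) ||
       anyDuplicated(names(object@familyLOD))))
    return("familyLOD must be uniquely named by family")
  if (abs(sum(object@familyLOD) - object@totalLOD) > 1e-6)
    return("family LODs must sum to the total LOD")
  TRUE
})

#' Genotypes with inheritance labels
#'
#' Minor-allele counts per individual and variant, together with the
#' founder-allele labels each individual carries (from gene dropping). Labels
#' trace every allele copy to a founder chromosome, so exact locus IBD can be
#' computed and every descendant minor allele is accounted for by a planted
#' founder minor allele.
#'
#' @slot counts integer matrix, individuals x variants, values 0/1/2.
#' @slot labels integer array \code{[individual, copy (1:2), variant]} of
#'   founder-allele label ids.
#' @slot labelMinor list, one logical vector per variant: is label id a minor
#'   founder allele.
#' @slot fid family id per individual (aligned with rows of \code{counts}).
#' @slot variants data.frame with columns \code{variant}, \code{gene},
#'   \code{maf}, \code{beta}, \code{trait}.
#'
#' @seealso [buildGenotypeData()], [ibdFromLabels()], [countRareAlleles()]
#' @exportClass GenotypeData
setClass("GenotypeData",
  slots = c(counts = "matrix", labels = "array", labelMinor = "list",
            fid = "character", variants = "data.frame"))

setValidity("GenotypeData", function(object) {
  nv <- nrow(object@variants)
  ni <- nrow(object@counts)
  if (ncol(object@counts) != nv) return("counts columns must match variants")
  if (!identical(dim(object@labels), c(ni, 2L, nv)))
    return("labels must be [individuals, 2, variants]")
  if (length(object@labelMinor) != nv) return("one labelMinor vector per variant")
  if (length(object@fid) != ni) return("one family id per individual")
  if (!all(c("variant", "gene", "maf", "beta", "trait") %in% names(object@variants)))
    return("variants needs columns variant, gene, maf, beta, trait")
  # spot-check count/label consistency on the first variant
  if (nv > 0L && ni > 0L) {
    mino <- object@labelMinor[[1L]]
    cnt <- matrix(mino[object@labels[, , 1L]], ncol = 2L)
    if (!all(rowSums(cnt) == object@counts[, 1L]))
      return("counts inconsistent with allele labels (variant 1)")
  }
  TRUE
})
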