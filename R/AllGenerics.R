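#' @rdname Pedigree-class
#' @param x,object a \code{Pedigree} (or other object with the accessor).
#' @export
setGeneric("famID", function(x) standardGeneric("famID"))

#' @rdname Pedigree-class
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname Pedigree-class
#' @export
setGeneric("nMembers", function(x) standardGeneric("nMembers"))

#' @rdname Pedigree-class
#' @export
setGeneric("founderIDs", function(x) standardGeneric("founderIDs"))

#' Kinship matrix of a pedigree
#'
#' Computes the kinship coefficients \eqn{\Phi_{ij}} by the standard
#' tabular recursion over the topologically ordered members.
#'
#' @param ped a validated [Pedigree-class] object.
#' @return symmetric numeric matrix with member ids as dimnames; founders have
#'   diagonal 0.5 and zero kinship with one another, and
#'   \eqn{\Phi_{ii} = 0.5 (1 + \Phi_{fm})} for offspring of \eqn{f, m}.
#' @examples
#' ped <- Pedigree("fam1",
#'   id = c("p1", "p2", "c1"),
#'   father = c(NA, NA, "p1"), mother = c(NA, NA, "p2"),
#'   sex = c("male", "female", "male"))
#' kinship(ped)["p1", "c1"]   # parent-offspring: 0.25
#' @export
setGeneric("kinship", function(ped) standardGeneric("kinship"))

#' @rdname GenotypeData-class
#' @export
setGeneric("alleleCounts", function(x) standardGeneric("alleleCounts"))

#' @rdname GenotypeData-class
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @rdname VCFit-class
#' @export
setGeneric("vcParams", function(x) standardGeneric("vcParams"))

#' @rdname VCFit-class
#' @export
setGeneric("fitLoglik", function(x) standardGeneric("fitLoglik"))

#' @rdname VCFit-class
#' @export
setGeneric("familyLoglik", function(x) standardGeneric("familyLoglik"))

#' @rdname VCFit-class
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' @rdname FamilyLODProfile-class
#' @export
setGeneric("familyLODs", function(x) standardGeneric("familyLODs"))

#' @rdname FamilyLODProfile-class
#' @export
setGeneric("totalLOD", function(x) standardGeneric("totalLOD"))
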