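#' Construct an extended pedigree with given founder/descendant counts
#'
#' Builds a multi-generation pedigree deterministically: a founding couple has
#' children; while unused founders remain, each child marries a newly added
#' founder spouse and the couple is queued to have children in the next
#' generation (breadth-first), until the target number of descendants is
#' reached. The result has exactly \code{nFounders} founders and
#' \code{nDescendants} non-founders, with depth emerging from the children
#' rate.
#'
#' @param famID family identifier.
#' @param nFounders number of founders (>= 2).
#' @param nDescendants number of non-founders (>= 1).
#' @param childrenPerCouple children per couple (before running out of the
#'   descendant budget).
#' @return a [Pedigree-class] object; member ids are \code{<famID>_I<k>}.
#' @export
makeExtendedPedigree <- function(famID, nFounders, nDescendants,
                                 childrenPerCouple = 3L) {
  stopifnot(nFounders >= 2L, nDescendants >= 1L)
  id <- father <- mother <- sex <- character(0)
  nid <- 0L
  addInd <- function(pat, mat, sx) {
    nid <<- nid + 1L
    id <<- c(id, sprintf("%s_I%03d", famID, nid))
    father <<- c(father, pat); mother <<- c(mother, mat); sex <<- c(sex, sx)
    id[nid]
  }
  foundersUsed <- 2L
  p1 <- addInd(NA, NA, "male")
  p2 <- addInd(NA, NA, "female")
  couples <- list(c(p1, p2))
  nDesc <- 0L
  while (nDesc < nDescendants && length(couples)) {
    cp <- couples[[1L]]
    couples <- couples[-1L]
    for (k in seq_len(childrenPerCouple)) {
      if (nDesc >= nDescendants) break
      sx <- if (nDesc %% 2L == 0L) "male" else "female"
      child <- addInd(cp[1L], cp[2L], sx)
      nDesc <- nDesc + 1L
      if (foundersUsed < nFounders) {
        spouse <- addInd(NA, NA, if (sx == "male") "female" else "male")
        foundersUsed <- foundersUsed + 1L
        couples <- c(couples, list(if (sx == "male") c(child, spouse)
                                   else c(spouse, child)))
      }
    }
  }
  if (nDesc < nDescendants)
    stop("descendant target unreachable: increase childrenPerCouple or founders")
  Pedigree(famID, id, father, mother, sex)
}

#' Default family structures emulating the GAW17 pedigree set
#'
#' Eight extended pedigrees totaling 697 individuals with 202 founders and
#' 495 descendants. The per-family sizes are a configuration choice (the
#' original structures are not public); family 7 is the largest, so
#' single-carrier scenarios with many transmitted copies are expressible
#' there.
#'
#' @param nFounders,nDescendants per-family integer vectors (defaults sum to
#'   202 and 495).
#' @param childrenPerCouple passed to [makeExtendedPedigree()].
#' @return named list of 8 [Pedigree-class] objects.
#' @export
gawPedigrees <- function(nFounders = c(20L, 34L, 25L, 18L, 30L, 22L, 35L, 18L),
                         nDescendants = c(45L, 85L, 60L, 42L, 78L, 55L, 90L, 40L),
                         childrenPerCouple = 3L) {
  stopifnot(length(nFounders) == length(nDescendants))
  fams <- as.character(seq_along(nFounders))
  peds <- mapply(function(f, nf, nd)
    makeExtendedPedigree(f, nf, nd, childrenPerCouple),
    fams, nFounders, nDescendants, SIMPLIFY = FALSE)
  names(peds) <- fams
  peds
}

#' Default causal-variant panel
#'
#' A small panel spanning the scenarios of interest: a rare single-carrier
#' variant transmitted to many descendants of one family (VEGFC-like), a
#' multi-variant moderately rare gene segregating in several families
#' (KDR-like), and a monomorphic gene contributing nothing (a null gene,
#' FLT4-like).
#'
#' @param trait trait name the variants act on.
#' @return data.frame usable with [buildGenotypeData()].
#' @export
gawVariantPanel <- function(trait = "Q1") {
  data.frame(
    variant = c("GA_rare1", "GB_v1", "GB_v2", "GC_null1"),
    gene    = c("GENEA", "GENEB", "GENEB", "GENEC"),
    maf     = c(0, 0.02, 0.02, 0),
    beta    = c(1.25, 0.3, 0.3, 0),
    trait   = trait,
    carrier = c("7_I001", NA, NA, NA),
    nDescCarriers = c(30L, NA, NA, NA),
    stringsAsFactors = FALSE)
}

#' Simulate covariates
#'
#' Age uniform over a range, smoking Bernoulli, sex taken from the pedigree.
#' Covariates are drawn once and held fixed across phenotype replicates.
#'
#' @param peds named list of pedigrees.
#' @param seed integer seed.
#' @param ageRange numeric length-2 (years).
#' @param smokeRate smoking prevalence.
#' @return data.frame: \code{fid}, \code{iid}, \code{age}, \code{sex} (0 =
#'   male, 1 = female), \code{smoke} (0/1).
#' @export
simulateCovariates <- function(peds, seed, ageRange = c(20, 80),
                               smokeRate = 0.25) {
  ids <- unlist(lapply(peds, function(p) members(p)$id), use.names = FALSE)
  fid <- rep(vapply(peds, famID, ""), vapply(peds, nMembers, 0L))
  sex <- unlist(lapply(peds, function(p) members(p)$sex), use.names = FALSE)
  set.seed(seed)
  data.frame(fid = fid, iid = ids,
             age = stats::runif(length(ids), ageRange[1L], ageRange[2L]),
             sex = as.integer(sex == "female"),
             smoke = as.integer(stats::runif(length(ids)) < smokeRate),
             stringsAsFactors = FALSE)
}

#' Simulate replicated phenotypes on fixed genotypes
#'
#' Trait model per individual:
#' \deqn{y = \mu + \beta_{age} age + \beta_{sex} sex + \beta_{smoke} smoke +
#'   \sum_v \beta_v c_v + g + e}
#' with polygenic effects \eqn{g} drawn jointly within each family from
#' \eqn{N(0, 2\Phi\sigma^2_a)} and environmental noise
#' \eqn{e \sim N(0, \sigma^2_e)} independently. Genotypes and covariates are
#' fixed across replicates; only \eqn{g} and \eqn{e} are redrawn, emulating
#' replicated trait simulations on one genotype realization.
#'
#' @param peds named list of pedigrees.
#' @param gd a [GenotypeData-class] object (variants carry \code{beta} and
#'   \code{trait}).
#' @param covar covariate data.frame from [simulateCovariates()].
#' @param nReplicates number of phenotype replicates.
#' @param seed integer seed.
#' @param sigma2_a,sigma2_e polygenic and environmental variances.
#' @param mu trait intercept.
#' @param covBeta named numeric: effects of \code{age}, \code{sex},
#'   \code{smoke}.
#' @param trait trait name (selects which variants contribute).
#' @return long data.frame: \code{replicate}, \code{fid}, \code{iid},
#'   \code{age}, \code{sex}, \code{smoke}, \code{trait} (the simulated value).
#' @export
simulatePhenotypes <- function(peds, gd, covar, nReplicates, seed,
                               sigma2_a = 0.3, sigma2_e = 0.7, mu = 0,
                               covBeta = c(age = 0.01, sex = 0.2, smoke = 0.3),
                               trait = "Q1") {
  stopifnot(sigma2_a >= 0, sigma2_e >= 0, nReplicates >= 1)
  vi <- gd@variants
  use <- vi$trait == trait
  score <- if (any(use))
    as.numeric(gd@counts[, use, drop = FALSE] %*% vi$beta[use])
  else rep(0, nrow(gd@counts))
  names(score) <- rownames(gd@counts)
  covar <- covar[match(rownames(gd@counts), covar$iid), ]
  fixed <- mu + covBeta[["age"]] * covar$age + covBeta[["sex"]] * covar$sex +
    covBeta[["smoke"]] * covar$smoke + score
  # per-family Cholesky factors of 2*Phi*sigma2_a, computed once
  chols <- lapply(peds, function(p) {
    if (sigma2_a == 0) return(NULL)
    chol(2 * kinship(p) * sigma2_a)
  })
  idsByFam <- lapply(peds, function(p) members(p)$id)
  n <- nrow(covar)
  set.seed(seed)
  reps <- lapply(seq_len(nReplicates), function(r) {
    g <- numeric(n)
    names(g) <- covar$iid
    for (k in seq_along(peds)) {
      ids <- idsByFam[[k]]
      if (!is.null(chols[[k]]))
        g[ids] <- as.numeric(crossprod(chols[[k]], stats::rnorm(length(ids))))
    }
    e <- stats::rnorm(n, 0, sqrt(sigma2_e))
    data.frame(replicate = r, fid = covar$fid, iid = covar$iid,
               age = covar$age, sex = covar$sex, smoke = covar$smoke,
               trait = fixed + g + e, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, reps)
  names(out)[names(out) == "trait"] <- trait
  out
}
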