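#' Assign founder allele states for one variant
#'
#' Every founder chromosome across the supplied pedigrees receives a unique
#' integer label; each copy is independently minor with probability
#' \code{maf}. In single-carrier mode (\code{carrier} given) exactly one minor
#' copy is planted on the first chromosome of that founder and all other
#' copies are major, emulating a variant present as a single copy in the
#' founder pool.
#'
#' @param peds named list of [Pedigree-class] objects.
#' @param maf founder minor-allele frequency in \eqn{[0, 0.5]}.
#' @param seed integer seed.
#' @param carrier optional individual id: plant exactly one minor copy there.
#' @return list with \code{founderLabels} (named list: founder id ->
#'   integer pair of label ids) and \code{minor} (logical by label id).
#' @export
assignFounderAlleles <- function(peds, maf, seed, carrier = NULL) {
  stopifnot(maf >= 0, maf <= 0.5)
  fnd <- unlist(lapply(peds, founderIDs), use.names = FALSE)
  nlab <- 2L * length(fnd)
  set.seed(seed)
  minor <- if (is.null(carrier)) {
    stats::runif(nlab) < maf
  } else {
    if (!carrier %in% fnd) stop(sprintf("carrier '%s' is not a founder", carrier))
    lab <- 2L * (match(carrier, fnd) - 1L) + 1L
    seq_len(nlab) == lab
  }
  founderLabels <- split(seq_len(nlab), rep(seq_along(fnd), each = 2L))
  names(founderLabels) <- fnd
  list(founderLabels = founderLabels, minor = minor)
}

#' Drop founder alleles down a pedigree
#'
#' Mendelian gene dropping: each non-founder inherits one uniformly chosen
#' allele label from each parent, independently across meioses.
#'
#' @param ped a [Pedigree-class] object.
#' @param founderStates result of [assignFounderAlleles()] (must cover this
#'   pedigree's founders).
#' @param seed integer seed.
#' @return integer matrix (members x 2) of allele label ids, rownames =
#'   member ids; column 1 is the paternal copy for non-founders.
#' @export
geneDrop <- function(ped, founderStates, seed) {
  m <- members(ped)
  n <- nrow(m)
  lab <- matrix(NA_integer_, n, 2L, dimnames = list(m$id, NULL))
  set.seed(seed)
  pick <- matrix(stats::runif(2L * n) < 0.5, n, 2L)
  pos <- seq_len(n)
  names(pos) <- m$id
  for (i in seq_len(n)) {
    if (m$founder[i]) {
      lab[i, ] <- founderStates$founderLabels[[m$id[i]]]
    } else {
      lab[i, 1L] <- lab[pos[[m$father[i]]], 1L + pick[i, 1L]]
      lab[i, 2L] <- lab[pos[[m$mother[i]]], 1L + pick[i, 2L]]
    }
  }
  lab
}

#' Gene drop conditioned on a descendant carrier count
#'
#' Repeats [geneDrop()] with a deterministic seed stream until exactly
#' \code{nDescCarriers} non-founders carry at least one minor allele
#' (rejection sampling). Used to reproduce scenarios where a known number of
#' descendants inherit a rare allele from a common founder.
#'
#' @inheritParams geneDrop
#' @param nDescCarriers target number of non-founder carriers.
#' @param maxIter iteration cap for the rejection loop.
#' @return as [geneDrop()].
#' @export
geneDropConditioned <- function(ped, founderStates, nDescCarriers, seed,
                                maxIter = 1e5) {
  m <- members(ped)
  for (k in seq_len(maxIter)) {
    lab <- geneDrop(ped, founderStates, seed = seed + k - 1L)
    minor <- founderStates$minor
    carriers <- rowSums(matrix(minor[lab], ncol = 2L)) > 0
    if (sum(carriers & !m$founder) == nDescCarriers) return(lab)
  }
  stop(sprintf("no gene drop with %d descendant carriers found in %d tries",
               nDescCarriers, as.integer(maxIter)))
}

#' Exact locus IBD matrix from inheritance labels
#'
#' Computes the realized proportion of alleles shared identical by descent,
#' \eqn{\hat\pi_{ij} = m/2}, where \eqn{m} is the size of a maximum matching
#' between the two individuals' allele labels under label equality. The
#' diagonal is 1 and parent-offspring pairs are exactly 0.5.
#'
#' @param labels label matrix from [geneDrop()] (members x 2, rownames = ids).
#' @param ids optional subset/ordering of individual ids.
#' @return symmetric numeric matrix of \eqn{\hat\pi} values in \eqn{[0, 1]}.
#' @export
ibdFromLabels <- function(labels, ids = rownames(labels)) {
  missing <- setdiff(ids, rownames(labels))
  if (length(missing))
    stop(sprintf("no allele labels for individual(s): %s",
                 paste(missing, collapse = ", ")))
  lab <- labels[ids, , drop = FALSE]
  a1 <- lab[, 1L]; a2 <- lab[, 2L]
  straight <- outer(a1, a1, "==") + outer(a2, a2, "==")
  crossed  <- outer(a1, a2, "==") + outer(a2, a1, "==")
  pihat <- pmax(straight, crossed) / 2
  dimnames(pihat) <- list(ids, ids)
  pihat
}

#' Build a genotype table by gene dropping a variant panel
#'
#' For each variant, founder alleles are assigned by founder MAF (or
#' single-carrier mode) and dropped through every pedigree; minor-allele
#' counts are derived from the resulting labels, so genotypes, inheritance
#' labels and IBD are mutually consistent. Genotypes are fixed once generated;
#' phenotype replicates reuse them.
#'
#' @param peds named list of [Pedigree-class] objects.
#' @param variants data.frame with columns \code{variant}, \code{gene},
#'   \code{maf}, \code{beta}, \code{trait}; optional columns \code{carrier}
#'   (founder id for single-carrier mode) and \code{nDescCarriers} (condition
#'   the drop in the carrier's family on that many descendant carriers).
#' @param seed integer master seed; per-variant and per-family seeds are
#'   derived from it with [deriveSeed()].
#' @return a [GenotypeData-class] object.
#' @export
buildGenotypeData <- function(peds, variants, seed) {
  stopifnot(all(c("variant", "gene", "maf", "beta", "trait") %in% names(variants)))
  ids <- unlist(lapply(peds, function(p) members(p)$id), use.names = FALSE)
  fid <- rep(vapply(peds, famID, ""), vapply(peds, nMembers, 0L))
  nv <- nrow(variants)
  ni <- length(ids)
  counts <- matrix(0L, ni, nv, dimnames = list(ids, variants$variant))
  labels <- array(NA_integer_, c(ni, 2L, nv),
                  dimnames = list(ids, NULL, variants$variant))
  labelMinor <- vector("list", nv)
  names(labelMinor) <- variants$variant
  for (v in seq_len(nv)) {
    carrier <- if ("carrier" %in% names(variants) && !is.na(variants$carrier[v]))
      variants$carrier[v] else NULL
    fs <- assignFounderAlleles(peds, variants$maf[v],
                               seed = deriveSeed(seed, 101L, v),
                               carrier = carrier)
    labelMinor[[v]] <- fs$minor
    for (k in seq_along(peds)) {
      ped <- peds[[k]]
      dseed <- deriveSeed(seed, 211L, v, k)
      target <- if (!is.null(carrier) && carrier %in% founderIDs(ped) &&
                    "nDescCarriers" %in% names(variants) &&
                    !is.na(variants$nDescCarriers[v]))
        variants$nDescCarriers[v] else NA
      lab <- if (is.na(target)) geneDrop(ped, fs, dseed)
             else geneDropConditioned(ped, fs, target, dseed)
      labels[rownames(lab), , v] <- lab
      counts[rownames(lab), v] <-
        as.integer(rowSums(matrix(fs$minor[lab], ncol = 2L)))
    }
  }
  new("GenotypeData", counts = counts, labels = labels,
      labelMinor = labelMinor, fid = fid, variants = as.data.frame(variants))
}

#' Per-gene IBD matrices
#'
#' One exact IBD matrix per family at a gene, treated as a point locus: the
#' labels of the gene's first variant define descent at the locus (all
#' variants of a gene share the locus).
#'
#' @param gd a [GenotypeData-class] object.
#' @param peds named list of pedigrees.
#' @param gene gene name.
#' @return named list (by family) of \eqn{\hat\pi} matrices.
#' @export
geneIBD <- function(gd, peds, gene) {
  v <- which(gd@variants$gene == gene)
  if (!length(v)) stop(sprintf("unknown gene '%s'", gene))
  lab <- gd@labels[, , v[1L], drop = TRUE]
  lapply(peds, function(p) ibdFromLabels(lab, members(p)$id))
}

#' @rdname GenotypeData-class
#' @export
setMethod("alleleCounts", "GenotypeData", function(x) x@counts)

#' @rdname GenotypeData-class
#' @export
setMethod("variantInfo", "GenotypeData", function(x) x@variants)

setMethod("show", "GenotypeData", function(object) {
  cat(sprintf("GenotypeData: %d individuals x %d variants (%d genes, %d families)\n",
              nrow(object@counts), ncol(object@counts),
              length(unique(object@variants$gene)),
              length(unique(object@fid))))
})

#' Count rare alleles of a gene per family
#'
#' Tallies minor-allele copies of all the gene's variants by family, split
#' into copies carried by founders and by descendants (the per-family totals
#' equal the founder plus descendant portions).
#'
#' @param gd a [GenotypeData-class] object.
#' @param peds named list of pedigrees.
#' @param gene gene name.
#' @return data.frame with columns \code{family}, \code{count},
#'   \code{founder}, \code{descendant}.
#' @export
countRareAlleles <- function(gd, peds, gene) {
  v <- which(gd@variants$gene == gene)
  if (!length(v)) stop(sprintf("unknown gene '%s'", gene))
  cn <- rowSums(gd@counts[, v, drop = FALSE])
  out <- lapply(peds, function(p) {
    m <- members(p)
    data.frame(family = famID(p),
               count = sum(cn[m$id]),
               founder = sum(cn[m$id[m$founder]]),
               descendant = sum(cn[m$id[!m$founder]]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Derive a stream seed from a master seed
#'
#' Counter-based scheme mixing the master seed with stage/stream indices, so
#' pipeline stages can be re-run independently yet reproducibly. Result is a
#' positive 31-bit integer.
#'
#' @param seed master integer seed.
#' @param ... integer stream indices.
#' @return integer seed.
#' @export
deriveSeed <- function(seed, ...) {
  x <- as.double(seed) %% 2147483647
  for (k in as.double(c(...)))
    x <- (x * 48271 + k * 2246822519 + 1) %% 2147483647
  as.integer(x) + 1L
}
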