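# Small pedigrees and independent oracles shared across test files.

trioPed <- function(fam = "t1") {
  Pedigree(fam, id = c("dad", "mom", "kid"),
           father = c(NA, NA, "dad"), mother = c(NA, NA, "mom"),
           sex = c("male", "female", "male"))
}

sibshipPed <- function(fam = "s1", nKids = 4L) {
  kids <- paste0("k", seq_len(nKids))
  Pedigree(fam, id = c("f", "m", kids),
           father = c(NA, NA, rep("f", nKids)),
           mother = c(NA, NA, rep("m", nKids)),
           sex = c("male", "female", rep(c("male", "female"), length.out = nKids)))
}

# 4-generation pedigree with a first-cousin mating; K is inbred (F = 1/16).
cousinPed <- function(fam = "c1") {
  Pedigree(fam,
    id     = c("F1", "M1", "S1", "W1", "S2", "W2", "C1", "C2", "K"),
    father = c(NA, NA, "F1", NA, "F1", NA, "S1", "S2", "C1"),
    mother = c(NA, NA, "M1", NA, "M1", NA, "W1", "W2", "C2"),
    sex    = c("male", "female", "male", "female", "male", "female",
               "male", "female", "male"))
}

# Monte-Carlo gene-dropping kinship estimator, independent of the tabular
# recursion: drops two uniquely labeled alleles per founder and averages the
# 4 allele-pair IBD indicators. Returns list(phi, se).
dropKinshipMC <- function(ped, nrep = 2e5, seed = 42) {
  m <- members(ped)
  n <- nrow(m)
  set.seed(seed)
  a1 <- a2 <- matrix(0L, n, nrep)
  pos <- seq_len(n); names(pos) <- m$id
  lab <- 0L
  for (i in seq_len(n)) {
    if (m$founder[i]) {
      a1[i, ] <- lab + 1L; a2[i, ] <- lab + 2L; lab <- lab + 2L
    } else {
      f <- pos[[m$father[i]]]; mo <- pos[[m$mother[i]]]
      pickF <- stats::runif(nrep) < 0.5
      pickM <- stats::runif(nrep) < 0.5
      a1[i, ] <- ifelse(pickF, a1[f, ], a2[f, ])
      a2[i, ] <- ifelse(pickM, a1[mo, ], a2[mo, ])
    }
  }
  phi <- se <- matrix(0, n, n, dimnames = list(m$id, m$id))
  for (i in seq_len(n)) for (j in i:n) {
    x <- ((a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
          (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ])) / 4
    phi[i, j] <- phi[j, i] <- mean(x)
    se[i, j] <- se[j, i] <- stats::sd(x) / sqrt(nrep)
  }
  list(phi = phi, se = se)
}

# simulate a trait directly from the VC model y ~ N(mu, s2q*Pi + 2*s2a*Phi +
# s2e*I) given per-family Phi/Pi; returns the families list with y filled in
simulateVCData <- function(peds, ibd, mu, s2q, s2a, s2e, seed) {
  set.seed(seed)
  lapply(peds, function(p) {
    ids <- members(p)$id
    Phi <- kinship(p)
    Pi <- ibd[[famID(p)]][ids, ids]
    om <- s2q * Pi + 2 * s2a * Phi + s2e * diag(length(ids))
    y <- mu + as.numeric(crossprod(chol(om), stats::rnorm(length(ids))))
    list(famID = famID(p), y = y, Phi = Phi, Pi = Pi)
  })
}

# one small null-model dataset (no QTL effect anywhere): 8 families of 20
makeNullFamilies <- function(seed, nFam = 8L) {
  peds <- gawPedigrees(nFounders = rep(8L, nFam), nDescendants = rep(12L, nFam))
  vars <- data.frame(variant = "nv", gene = "NULLG", maf = 0.3, beta = 0,
                     trait = "Q1", stringsAsFactors = FALSE)
  gd <- buildGenotypeData(peds, vars, seed = seed)
  covar <- simulateCovariates(peds, seed = deriveSeed(seed, 7L))
  ph <- adjustPhenotypes(
    simulatePhenotypes(peds, gd, covar, 1, seed = deriveSeed(seed, 8L)), "Q1")
  y <- ph$Q1_adj
  names(y) <- ph$iid
  vcFamilies(peds, y, geneIBD(gd, peds, "NULLG"))
}

# compact pipeline configuration for fast end-to-end tests
smallConfig <- function(...) {
  defaultRunConfig(
    nFounders = c(6L, 6L, 6L, 6L),
    nDescendants = c(10L, 10L, 10L, 10L),
    variants = data.frame(
      variant = c("v1", "v2"), gene = c("G1", "G2"),
      maf = c(0.15, 0.1), beta = c(0.9, 0), trait = "Q1",
      stringsAsFactors = FALSE),
    nReplicates = 3L,
    seed = 11L,
    ...)
}
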