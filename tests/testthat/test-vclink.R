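singletonFam <- function(id, y) {
  list(famID = id, y = y, Phi = matrix(0.5, 1, 1, dimnames = list(id, id)),
       Pi = matrix(1, 1, 1, dimnames = list(id, id)))
}

test_that("the VC log-likelihood matches direct multivariate-normal density", {
  # standard normal density at 0 for a lone individual
  p0 <- c(mu = 0, sigma2_q = 0, sigma2_a = 0, sigma2_e = 1)
  expect_equal(vcLoglik(p0, list(singletonFam("a", 0))), -0.5 * log(2 * pi))

  # block independence: two singletons add up
  f1 <- singletonFam("a", 0.3)
  f2 <- singletonFam("b", -1.1)
  p1 <- c(mu = 0.1, sigma2_q = 0.2, sigma2_a = 0.3, sigma2_e = 0.5)
  expect_equal(vcLoglik(p1, list(f1, f2)),
               vcLoglik(p1, list(f1)) + vcLoglik(p1, list(f2)))

  # 3-member family against a dense solve/determinant evaluation
  ped <- trioPed()
  fs <- assignFounderAlleles(list(t1 = ped), maf = 0.3, seed = 1)
  lab <- geneDrop(ped, fs, seed = 2)
  fam <- list(famID = "t1", y = c(0.2, -0.5, 1.1), Phi = kinship(ped),
              Pi = ibdFromLabels(lab))
  om <- p1[["sigma2_q"]] * fam$Pi + 2 * p1[["sigma2_a"]] * fam$Phi +
    p1[["sigma2_e"]] * diag(3)
  d <- fam$y - p1[["mu"]]
  direct <- -0.5 * (3 * log(2 * pi) + log(det(om)) +
                    drop(t(d) %*% solve(om) %*% d))
  expect_equal(vcLoglik(p1, list(fam)), direct, tolerance = 1e-10)
})

test_that("full-model likelihood is never below the null's", {
  for (s in 1:10) {
    fams <- makeNullFamilies(seed = s, nFam = 3L)
    fitN <- vcFit(fams, "null")
    fitF <- vcFit(fams, "full", nullFit = fitN)
    expect_gte(fitLoglik(fitF), fitLoglik(fitN) - 1e-6)
    expect_gte(lodScore(fitF, fitN), 0)
  }
})

test_that("LOD conversion and guards behave", {
  fams <- makeNullFamilies(seed = 77, nFam = 2L)
  fitN <- vcFit(fams, "null")
  fitF <- vcFit(fams, "full", nullFit = fitN)
  # unit conversion: a log-likelihood gap of ln 10 is one LOD
  fake <- fitF
  fake@loglik <- fitN@loglik + log(10)
  fake@familyLoglik <- fitN@familyLoglik +
    log(10) / length(fitN@familyLoglik)
  expect_equal(lodScore(fake, fitN), 1)
  # identical likelihoods give LOD 0
  same <- fitF
  same@loglik <- fitN@loglik
  same@familyLoglik <- fitN@familyLoglik
  expect_equal(lodScore(same, fitN), 0)
  # mismatched data are refused
  other <- vcFit(makeNullFamilies(seed = 78, nFam = 2L), "null")
  expect_error(lodScore(fitF, other), "different data")
  expect_error(familyLOD(fitF, other), "different data")
})

test_that("family LOD decomposition sums to the total and collapses for one family", {
  fams <- makeNullFamilies(seed = 5, nFam = 4L)
  fitN <- vcFit(fams, "null")
  fitF <- vcFit(fams, "full", nullFit = fitN)
  prof <- familyLOD(fitF, fitN)
  expect_equal(sum(familyLODs(prof)), totalLOD(prof), tolerance = 1e-6)
  expect_equal(totalLOD(prof),
               (fitLoglik(fitF) - fitLoglik(fitN)) / log(10),
               tolerance = 1e-9)

  one <- makeNullFamilies(seed = 6, nFam = 1L)
  fN <- vcFit(one, "null")
  fF <- vcFit(one, "full", nullFit = fN)
  p1 <- familyLOD(fF, fN)
  expect_length(familyLODs(p1), 1L)
  expect_equal(unname(familyLODs(p1)[1L]), totalLOD(p1))
})

test_that("null-truth fits put the QTL variance on the boundary often", {
  hatq <- vapply(1:100, function(s) {
    fams <- makeNullFamilies(seed = 300 + s, nFam = 4L)
    fit <- vcFit(fams, "full")
    vcParams(fit)[["sigma2_q"]] / sum(vcParams(fit)[2:4])
  }, 0.0)
  expect_gte(mean(hatq == 0), 0.40)
  expect_equal(stats::median(hatq), 0)
})

test_that("the fit recovers a large simulated QTL variance proportion", {
  peds <- gawPedigrees(nFounders = rep(8L, 4), nDescendants = rep(12L, 4))
  vars <- data.frame(variant = "v", gene = "G", maf = 0.3, beta = 0,
                     trait = "Q1")
  props <- vapply(1:200, function(s) {
    gd <- buildGenotypeData(peds, vars, seed = 900 + s)
    ibd <- geneIBD(gd, peds, "G")
    fams <- simulateVCData(peds, ibd, mu = 0, s2q = 0.5, s2a = 0.2,
                           s2e = 0.3, seed = 5000 + s)
    v <- vcParams(vcFit(fams, "full"))
    v[["sigma2_q"]] / (v[["sigma2_q"]] + v[["sigma2_a"]] + v[["sigma2_e"]])
  }, 0.0)
  se <- stats::sd(props) / sqrt(200)
  expect_lt(abs(mean(props) - 0.5), 3 * se + 0.02)
})

test_that("the optimizer beats a dense parameter grid on two-family toys", {
  peds <- list(t1 = trioPed("t1"), s1 = sibshipPed("s1", nKids = 1L))
  vars <- data.frame(variant = "v", gene = "G", maf = 0.3, beta = 0,
                     trait = "Q1")
  gd <- buildGenotypeData(peds, vars, seed = 31)
  ibd <- geneIBD(gd, peds, "G")
  fams <- simulateVCData(peds, ibd, mu = 0, s2q = 0.3, s2a = 0.2, s2e = 0.5,
                         seed = 32)
  fit <- vcFit(fams, "full")
  grid <- expand.grid(mu = seq(-0.5, 0.5, 0.05),
                      s2q = seq(0, 1, 0.05),
                      s2a = seq(0, 1, 0.05),
                      s2e = seq(0.05, 1, 0.05))
  ll <- apply(as.matrix(grid), 1L, function(g)
    vcLoglik(c(mu = g[[1]], sigma2_q = g[[2]], sigma2_a = g[[3]],
               sigma2_e = g[[4]]), fams))
  expect_gte(fitLoglik(fit), max(ll) - 1e-3)
})

test_that("the MLE dominates random parameter points", {
  fams <- makeNullFamilies(seed = 41, nFam = 3L)
  fit <- vcFit(fams, "full")
  set.seed(42)
  for (k in 1:200) {
    p <- c(mu = stats::runif(1, -1, 1), sigma2_q = stats::runif(1, 0, 2),
           sigma2_a = stats::runif(1, 0, 2), sigma2_e = stats::runif(1, 0.01, 2))
    expect_gte(fitLoglik(fit), vcLoglik(p, fams))
  }
})

test_that("the null LOD mixture has mean 1/(4 ln 10), rounding to 0.11", {
  expect_equal(nullExpectedLod(), 1 / (4 * log(10)))
  expect_equal(round(nullExpectedLod(), 2), 0.11)
  set.seed(7)
  draws <- rLODNull(1e6)
  se <- stats::sd(draws) / sqrt(1e6)
  expect_lt(abs(mean(draws) - nullExpectedLod()), 3 * se)
  expect_equal(stats::median(draws), 0)   # point mass of 1/2 at zero
})

test_that("LOD p-values follow the half-chi-square tail", {
  expect_equal(lodPvalue(0), 0.5)
  # oracle via the standard-normal tail at z = sqrt(2 ln 10 * lod)
  z <- sqrt(2 * log(10) * 3)
  expect_equal(lodPvalue(3), stats::pnorm(z, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(signif(lodPvalue(3), 2), 1.0e-4)
  lods <- seq(0, 5, 0.25)
  expect_true(all(diff(lodPvalue(lods)) < 0))
  expect_error(lodPvalue(-0.1), "non-negative")
})
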