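test_that("founder allele assignment respects MAF and single-carrier mode", {
  peds <- gawPedigrees()
  fs0 <- assignFounderAlleles(peds, maf = 0, seed = 1)
  expect_false(any(fs0$minor))

  fs1 <- assignFounderAlleles(peds, maf = 0, seed = 1, carrier = "7_I001")
  expect_equal(sum(fs1$minor), 1L)
  expect_true(fs1$minor[fs1$founderLabels[["7_I001"]][1L]])
  # a single planted copy among 697 unrelated individuals
  expect_equal(signif(minorAlleleFrequency(1, 697, percent = TRUE), 3), 0.0717)

  expect_error(assignFounderAlleles(peds, 0, 1, carrier = "nobody"),
               "not a founder")
})

test_that("founder minor-copy counts match the binomial expectation", {
  peds <- gawPedigrees()   # 202 founders
  counts <- vapply(1:2000, function(s)
    sum(assignFounderAlleles(peds, maf = 0.01, seed = s)$minor), 0L)
  expected <- 2 * 202 * 0.01
  se <- sqrt(2 * 202 * 0.01 * 0.99 / 2000)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("gene dropping conserves founder origin and Mendelian rates", {
  ped <- sibshipPed(nKids = 1L)
  peds <- list(s1 = ped)
  # founder without minor alleles: no descendant carries one
  fs0 <- assignFounderAlleles(peds, maf = 0, seed = 3)
  lab <- geneDrop(ped, fs0, seed = 4)
  expect_false(any(fs0$minor[lab]))

  # heterozygous parent transmits to half the offspring
  fsh <- assignFounderAlleles(peds, maf = 0, seed = 3, carrier = "f")
  hits <- vapply(1:10000, function(s) {
    l <- geneDrop(ped, fsh, seed = s)
    sum(fsh$minor[l["k1", ]]) > 0
  }, NA)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(mean(hits) - 0.5), 3 * se)
})

test_that("conditioned gene drop hits the requested descendant carrier count", {
  peds <- gawPedigrees()
  ped7 <- peds[["7"]]
  fs <- assignFounderAlleles(peds, maf = 0, seed = 5, carrier = "7_I001")
  lab <- geneDropConditioned(ped7, fs, nDescCarriers = 30L, seed = 6)
  m <- members(ped7)
  carriers <- rowSums(matrix(fs$minor[lab], ncol = 2)) > 0
  expect_equal(sum(carriers & !m$founder), 30L)
  expect_error(
    geneDropConditioned(ped7, fs, nDescCarriers = 200L, seed = 6, maxIter = 10),
    "no gene drop")
})

test_that("label-based IBD gives exact values for canonical relationships", {
  ped <- sibshipPed(nKids = 2L)
  fs <- assignFounderAlleles(list(s1 = ped), maf = 0.2, seed = 7)
  lab <- geneDrop(ped, fs, seed = 8)
  pihat <- ibdFromLabels(lab)
  expect_equal(unname(diag(pihat)), rep(1, 4))          # non-inbred self
  expect_equal(pihat["f", "k1"], 0.5)                   # parent-offspring
  expect_equal(pihat["f", "m"], 0)                      # unrelated founders
  expect_error(ibdFromLabels(lab, ids = c("f", "nope")), "nope")
})

test_that("full-sib IBD follows the (1/4, 1/2, 1/4) segregation law", {
  ped <- sibshipPed(nKids = 2L)
  fs <- assignFounderAlleles(list(s1 = ped), maf = 0.2, seed = 9)
  vals <- vapply(1:10000, function(s)
    ibdFromLabels(geneDrop(ped, fs, seed = s))["k1", "k2"], 0.0)
  expect_true(all(vals %in% c(0, 0.5, 1)))
  se <- sqrt(0.125 / 10000)   # var of pihat = 1/8
  expect_lt(abs(mean(vals) - 0.5), 3 * se)
  p <- c(mean(vals == 0), mean(vals == 0.5), mean(vals == 1))
  se3 <- sqrt(c(.25 * .75, .5 * .5, .25 * .75) / 10000)
  expect_true(all(abs(p - c(0.25, 0.5, 0.25)) < 3 * se3))
})

test_that("genotype tables are consistent, conserved and reproducible", {
  peds <- gawPedigrees(nFounders = c(8L, 10L), nDescendants = c(14L, 16L))
  vars <- data.frame(variant = c("a", "b"), gene = c("G1", "G1"),
                     maf = c(0.2, 0.1), beta = c(0.5, 0.2), trait = "Q1")
  gd <- buildGenotypeData(peds, vars, seed = 10)
  expect_true(validObject(gd))
  # allele conservation: every descendant allele label traces to a founder of
  # the same family, so descendant minor alleles come from planted copies
  for (v in 1:2) {
    expect_lte(max(alleleCounts(gd)[, v]), 2L)
    for (p in peds) {
      m <- members(p)
      founderLabs <- unique(as.vector(gd@labels[m$id[m$founder], , v]))
      descLabs <- as.vector(gd@labels[m$id[!m$founder], , v])
      expect_true(all(descLabs %in% founderLabs))
    }
    # each individual's count equals its minor-labeled copies
    cnt <- rowSums(matrix(gd@labelMinor[[v]][gd@labels[, , v]], ncol = 2))
    expect_equal(unname(alleleCounts(gd)[, v]), as.integer(cnt))
  }
  gd2 <- buildGenotypeData(peds, vars, seed = 10)
  expect_identical(alleleCounts(gd), alleleCounts(gd2))
  expect_identical(gd@labels, gd2@labels)
  gd3 <- buildGenotypeData(peds, vars, seed = 11)
  expect_false(identical(alleleCounts(gd), alleleCounts(gd3)))
})

test_that("locus IBD matrices are positive semi-definite", {
  peds <- gawPedigrees(nFounders = c(8L, 10L), nDescendants = c(14L, 16L))
  vars <- data.frame(variant = "a", gene = "G1", maf = 0.2, beta = 0.5,
                     trait = "Q1")
  for (s in 1:20) {
    gd <- buildGenotypeData(peds, vars, seed = s)
    for (pim in geneIBD(gd, peds, "G1"))
      expect_gte(min(eigen(pim, symmetric = TRUE, only.values = TRUE)$values),
                 -1e-8)
  }
})

test_that("rare-allele counting partitions into founder and descendant copies", {
  peds <- gawPedigrees()
  gd <- buildGenotypeData(peds, gawVariantPanel(), seed = 12)
  for (g in c("GENEA", "GENEB", "GENEC")) {
    cnt <- countRareAlleles(gd, peds, g)
    expect_equal(cnt$count, cnt$founder + cnt$descendant)
  }
  cntC <- countRareAlleles(gd, peds, "GENEC")   # monomorphic null gene
  expect_true(all(cntC$count == 0))
  cntA <- countRareAlleles(gd, peds, "GENEA")   # single-carrier scenario
  expect_equal(sum(cntA$count >= 1), 1L)
  expect_equal(cntA$descendant[cntA$family == "7"], 30)
  expect_error(countRareAlleles(gd, peds, "NOGENE"), "unknown gene")
})

test_that("phenotype replicates redraw noise on fixed genotypes", {
  peds <- gawPedigrees(nFounders = c(6L), nDescendants = c(10L))
  vars <- data.frame(variant = "a", gene = "G1", maf = 0, beta = 0,
                     trait = "Q1")
  gd <- buildGenotypeData(peds, vars, seed = 13)
  covar <- simulateCovariates(peds, seed = 14)
  ph <- simulatePhenotypes(peds, gd, covar, nReplicates = 200, seed = 15,
                           sigma2_a = 0, sigma2_e = 1,
                           covBeta = c(age = 0, sex = 0, smoke = 0))
  # no genetic or covariate effect: variance is sigma2_e
  v <- stats::var(ph$Q1)
  expect_lt(abs(v - 1), 0.08)   # ~3 SE of a sample variance on 3200 draws
  # covariates fixed across replicates
  expect_equal(ph$age[ph$replicate == 1], ph$age[ph$replicate == 2])
  # same seed reproduces, different seed does not
  ph2 <- simulatePhenotypes(peds, gd, covar, nReplicates = 200, seed = 15,
                            sigma2_a = 0, sigma2_e = 1,
                            covBeta = c(age = 0, sex = 0, smoke = 0))
  expect_identical(ph, ph2)
})

test_that("polygenic draws induce kinship-proportional trait covariance", {
  peds <- list(s1 = sibshipPed(nKids = 2L))
  vars <- data.frame(variant = "a", gene = "G1", maf = 0, beta = 0,
                     trait = "Q1")
  gd <- buildGenotypeData(peds, vars, seed = 16)
  covar <- simulateCovariates(peds, seed = 17)
  ph <- simulatePhenotypes(peds, gd, covar, nReplicates = 4000, seed = 18,
                           sigma2_a = 1, sigma2_e = 0,
                           covBeta = c(age = 0, sex = 0, smoke = 0))
  y1 <- ph$Q1[ph$iid == "k1"]
  y2 <- ph$Q1[ph$iid == "k2"]
  # sib covariance = 2 * 0.25 * sigma2_a = 0.5
  expect_lt(abs(stats::cov(y1, y2) - 0.5), 3 * 0.75 / sqrt(4000))
})
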