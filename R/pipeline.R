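#' Default run configuration
#'
#' The default emulation: 8 extended pedigrees totaling 697 individuals with
#' 202 founders, 200 phenotype replicates on fixed genotypes, polygenic
#' variance 0.3 and environmental variance 0.7, and the default causal-variant
#' panel. All entries can be overridden, or loaded from a YAML file with
#' [readRunConfig()].
#'
#' @param ... named overrides of the default entries.
#' @return a list with entries \code{nFounders}, \code{nDescendants},
#'   \code{childrenPerCouple}, \code{variants}, \code{trait},
#'   \code{nReplicates}, \code{sigma2_a}, \code{sigma2_e}, \code{mu},
#'   \code{covBeta}, \code{ageRange}, \code{smokeRate}, \code{seed},
#'   \code{test}, \code{outDir}.
#' @export
defaultRunConfig <- function(...) {
  cfg <- list(
    nFounders = c(20L, 34L, 25L, 18L, 30L, 22L, 35L, 18L),
    nDescendants = c(45L, 85L, 60L, 42L, 78L, 55L, 90L, 40L),
    childrenPerCouple = 3L,
    variants = gawVariantPanel(),
    trait = "Q1",
    nReplicates = 200L,
    sigma2_a = 0.3,
    sigma2_e = 0.7,
    mu = 0,
    covBeta = c(age = 0.01, sex = 0.2, smoke = 0.3),
    ageRange = c(20, 80),
    smokeRate = 0.25,
    seed = 1L,
    test = "ztest",
    outDir = NULL)
  over <- list(...)
  cfg[names(over)] <- over
  validateRunConfig(cfg)
  cfg
}

validateRunConfig <- function(cfg) {
  stopifnot(cfg$nReplicates >= 1L,
            is.data.frame(cfg$variants),
            length(cfg$nFounders) == length(cfg$nDescendants),
            cfg$test %in% c("ztest", "binomial"))
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror [defaultRunConfig()]; \code{variants} may be a list of
#' records or a path to a variant TSV (columns gene, variant, maf, beta,
#' trait, and optionally carrier, nDescCarriers). Unspecified keys keep their
#' defaults.
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$variants)) {
    raw$variants <- if (is.character(raw$variants))
      utils::read.table(raw$variants, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    else do.call(rbind, lapply(raw$variants, as.data.frame))
  }
  if (!is.null(raw$covBeta)) raw$covBeta <- unlist(raw$covBeta)
  do.call(defaultRunConfig, raw)
}

#' Run the full enrichment pipeline
#'
#' Orchestrates simulate -> adjust -> linkage -> select -> evaluate:
#' generates pedigrees, genotypes (gene dropping with exact locus IBD),
#' covariates and replicated phenotypes; adjusts the trait per replicate;
#' fits full and null variance-component models per gene and replicate;
#' selects the max-LOD family per replicate; and summarizes rare-allele
#' enrichment versus random family selection. The same configuration and
#' seed reproduce identical outputs.
#'
#' @param config configuration list from [defaultRunConfig()] or
#'   [readRunConfig()].
#' @param genes genes to analyze (default: all genes in the variant panel).
#' @param verbose print stage progress.
#' @return list with elements \code{peds}, \code{genotypes}, \code{pheno}
#'   (adjusted), \code{linkage}, \code{selections}, \code{counts} (per-gene
#'   rare-allele tables), \code{enrichment} (Table of gene, meanLOD,
#'   meanLODmax, expected, observed, pValue), \code{varianceExplained}
#'   (percent per family and total), and \code{manifest}. If
#'   \code{config$outDir} is set, TSV reports are also written there.
#' @export
runPipeline <- function(config = defaultRunConfig(), genes = NULL,
                        verbose = FALSE) {
  validateRunConfig(config)
  seed <- config$seed
  say <- function(...) if (verbose) message(sprintf(...))

  say("stage simulate: pedigrees + genotypes")
  peds <- gawPedigrees(config$nFounders, config$nDescendants,
                       config$childrenPerCouple)
  if (is.null(genes)) genes <- unique(config$variants$gene)
  if (!all(genes %in% config$variants$gene))
    stop(sprintf("gene(s) not in variant panel: %s",
                 paste(setdiff(genes, config$variants$gene), collapse = ", ")))
  gd <- buildGenotypeData(peds, config$variants, seed = deriveSeed(seed, 1L))
  covar <- simulateCovariates(peds, seed = deriveSeed(seed, 2L),
                              ageRange = config$ageRange,
                              smokeRate = config$smokeRate)
  pheno <- simulatePhenotypes(peds, gd, covar, config$nReplicates,
                              seed = deriveSeed(seed, 3L),
                              sigma2_a = config$sigma2_a,
                              sigma2_e = config$sigma2_e, mu = config$mu,
                              covBeta = config$covBeta, trait = config$trait)

  say("stage adjust: standardized residuals")
  pheno <- adjustPhenotypes(pheno, config$trait)
  adjCol <- paste0(config$trait, "_adj")

  say("stage linkage: %d gene(s) x %d replicate(s)", length(genes),
      config$nReplicates)
  linkage <- list()
  selections <- list()
  for (g in genes) {
    ibd <- geneIBD(gd, peds, g)
    counts <- countRareAlleles(gd, peds, g)
    carrierFams <- counts$family[counts$count >= 1]
    for (r in seq_len(config$nReplicates)) {
      rows <- pheno$replicate == r
      yv <- pheno[[adjCol]][rows]
      names(yv) <- pheno$iid[rows]
      fams <- vcFamilies(peds, yv, ibd)
      fitN <- vcFit(fams, "null")
      fitF <- vcFit(fams, "full", nullFit = fitN)
      if (!converged(fitF) || !converged(fitN))
        warning(sprintf("non-converged fit: gene %s replicate %d", g, r))
      prof <- familyLOD(fitF, fitN)
      selFam <- selectFamily(prof)
      linkage[[length(linkage) + 1L]] <- data.frame(
        gene = g, replicate = r, totalLOD = max(totalLOD(prof), 0),
        maxFamilyLOD = max(familyLODs(prof)), stringsAsFactors = FALSE)
      selections[[length(selections) + 1L]] <- data.frame(
        gene = g, replicate = r, family = selFam,
        familyLOD = familyLODs(prof)[[selFam]],
        carrier = selFam %in% carrierFams, stringsAsFactors = FALSE)
    }
    say("  gene %s done", g)
  }
  linkage <- do.call(rbind, linkage)
  selections <- do.call(rbind, selections)

  say("stage evaluate: enrichment + variance explained")
  countsByGene <- lapply(genes, function(g) countRareAlleles(gd, peds, g))
  names(countsByGene) <- genes
  enr <- summarizeEnrichment(linkage, selections, countsByGene,
                             method = config$test)
  ve <- do.call(rbind, lapply(genes, function(g) {
    sc <- geneScore(gd, g)
    groups <- c(names(peds), "total")
    data.frame(gene = g, group = groups,
               pctVariance = vapply(groups, function(gr)
                 pctVariance(sc, pheno, config$trait, gr), 0.0),
               stringsAsFactors = FALSE)
  }))

  manifest <- list(seed = seed, trait = config$trait,
                   nReplicates = config$nReplicates, genes = genes,
                   nFamilies = length(peds),
                   nIndividuals = sum(vapply(peds, nMembers, 0L)),
                   test = config$test,
                   packageVersion = as.character(utils::packageVersion("famEnrich")))

  res <- list(peds = peds, genotypes = gd, pheno = pheno, linkage = linkage,
              selections = selections, counts = countsByGene,
              enrichment = enr, varianceExplained = ve, manifest = manifest)
  if (!is.null(config$outDir)) writeReports(res, config$outDir, config)
  res
}

#' Write pipeline reports to a directory
#'
#' Emits the rare-allele count table (Table 1 analog), the enrichment table
#' (Table 2 analog), the variance-explained table (Table 3 analog), the
#' per-replicate selection log, the per-replicate linkage table, pedigree /
#' genotype / IBD / phenotype files, and a YAML run manifest.
#'
#' @param res result of [runPipeline()].
#' @param dir output directory (created if needed).
#' @param config the run configuration.
#' @return invisibly, the directory.
#' @export
writeReports <- function(res, dir, config = defaultRunConfig()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  cnt <- do.call(rbind, mapply(function(g, d) cbind(gene = g, d),
                               names(res$counts), res$counts,
                               SIMPLIFY = FALSE))
  tsv(cnt, "rare_allele_counts.tsv")
  tsv(res$enrichment, "enrichment.tsv")
  tsv(res$varianceExplained, "variance_explained.tsv")
  tsv(res$selections, "selection_log.tsv")
  tsv(res$linkage, "linkage.tsv")
  tsv(res$pheno, "phenotypes.tsv")
  writePedigrees(res$peds, file.path(dir, "pedigrees.ped"))
  geno <- data.frame(FID = res$genotypes@fid,
                     IID = rownames(alleleCounts(res$genotypes)),
                     alleleCounts(res$genotypes), check.names = FALSE)
  tsv(geno, "genotypes.tsv")
  ibdRows <- list()
  for (g in unique(variantInfo(res$genotypes)$gene)) {
    ibd <- geneIBD(res$genotypes, res$peds, g)
    for (f in names(ibd)) {
      m <- ibd[[f]]
      idx <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
      ibdRows[[length(ibdRows) + 1L]] <- data.frame(
        gene = g, FID = f, ID1 = rownames(m)[idx[, 1L]],
        ID2 = colnames(m)[idx[, 2L]], pi_hat = m[idx])
    }
  }
  tsv(do.call(rbind, ibdRows), "ibd.tsv")
  yaml::write_yaml(res$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
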