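# famEnrich

Rare causal variants are, by definition, carried by few people: a family
sample drawn at random from the population will often contain no copy of the
allele of interest, which makes it a poor target for follow-up sequencing.
`famEnrich` implements a sampling strategy for quantitative-trait loci:
compute a variance-component linkage LOD score for a set of extended
pedigrees, decompose it into **family-specific LOD scores**, and sequence the
pedigree with the largest family LOD. Because a rare allele segregating
through a family generates locus-specific trait covariance in that family and
nowhere else, the max-LOD family is strongly enriched for carriers of the
causal allele relative to a randomly chosen family.

The package is aimed at statistical geneticists designing family-based
sequencing studies, and at anyone who wants a self-contained, simulation-
backed implementation of family-specific variance-component linkage.

## The model

Traits are first adjusted for age, sex and smoking by ordinary least squares,
and the standardized residuals are analyzed. For family *f* with trait vector
*y_f*, the variance-component model is multivariate normal,

    y_f ~ N( mu 1,  Omega_f ),
    Omega_f = sigma2_q * Pi_f  +  2 * sigma2_a * Phi_f  +  sigma2_e * I,

where `Pi_f` is the matrix of locus-specific IBD sharing proportions
(pi-hat), `Phi_f` the kinship matrix, and `(sigma2_q, sigma2_a, sigma2_e)`
the QTL, polygenic and environmental variances. The LOD score is the log10
likelihood ratio of the full model against the null (`sigma2_q = 0`), both
maximized over all families jointly; the **family-specific LOD** is each
family's log-likelihood-ratio contribution evaluated at those whole-sample
estimates, so the per-family values sum exactly to the total LOD.

Enrichment is quantified per gene by comparing

* **expected** — the fraction of families carrying at least one minor-allele
  copy of the gene's causal variants (the hit rate of random selection), and
* **observed** — the fraction of replicates in which the max-LOD family is a
  carrier family,

with a one-sided proportion z-test (exact binomial available). Under the
null of no linkage the LOD follows a half-half mixture of a point mass at 0
and chi-square(1)/(2 ln 10), with mean `1/(4 ln 10) ~= 0.11`.

A gene-dropping simulator generates the full study design with no external
data: 8 extended pedigrees totaling 697 individuals (202 founders), rare
founder variants (down to a single planted copy, MAF 1/(2*697) = 0.0717%),
Mendelian transmission with exact locus IBD derived from inheritance labels,
covariates, and 200 phenotype replicates on fixed genotypes.

## Worked example

A single-carrier rare-variant scenario: one founder of family 7 carries one
copy of a large-effect variant (gene `GENEA`), transmitted to 30 descendants;
`GENEC` is monomorphic and serves as a null gene.

```r
library(famEnrich)
cfg <- defaultRunConfig(nReplicates = 20L, seed = 7L)
res <- runPipeline(cfg, genes = c("GENEA", "GENEC"))

res$counts[["GENEA"]]
#>   family count founder descendant
#> 1      1     0       0          0
#> ...
#> 7      7    31       1         30
#> 8      8     0       0          0

print(res$enrichment, digits = 3)
#>    gene meanLOD meanLODmax expected observed   pValue nullGene
#> 1 GENEA   2.180      2.750    0.125        1 1.33e-32    FALSE
#> 2 GENEC   0.179      0.146    0.000        0       NA     TRUE
```

Reading this: the 31 allele copies sit in one family out of 8, so a random
pick carries the allele with probability 0.125 (`expected`); selecting the
max-LOD family instead found the carrier family in all 20 replicates
(`observed = 1`), a dramatic enrichment (one-sided p = 1.3e-32). The
monomorphic gene has `expected = 0`, so no enrichment is defined there
(`pValue = NA`) and its mean LOD is at null-noise level. The same gene
explains a far larger share of trait variance inside the carrier family than
overall:

```r
subset(res$varianceExplained, gene == "GENEA" & group %in% c("7", "total"))
#>        gene group pctVariance
#> 7     GENEA     7       22.29
#> total GENEA total        5.83
```

A thin command-line wrapper is provided in `inst/scripts/run_pipeline.R`
(`--config`, `--seed`, `--replicates`, `--genes`, `--out`, `--test`), writing
TSV reports and a YAML manifest per run.

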