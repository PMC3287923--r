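Package: famEnrich
Title: Enriching Rare Variants in Pedigrees Using Family-Specific Linkage LOD Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variance-component linkage analysis of quantitative traits in
    extended pedigrees with a per-family decomposition of the LOD score, and
    tools that use the family-specific LOD to select pedigrees enriched for
    rare causal alleles. Includes a gene-dropping simulator of GAW17-style
    family data (extended pedigrees, rare founder variants with additive
    effects, exact locus identity-by-descent matrices, covariates, and
    replicated phenotypes on fixed genotypes), covariate pre-adjustment of
    traits, enrichment evaluation against random family selection via a
    one-sided proportion test, and additive effect-size accounting (percent
    phenotypic variance explained per family and overall).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
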