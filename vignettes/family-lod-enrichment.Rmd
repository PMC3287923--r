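---
title: "Selecting pedigrees enriched for rare variants with family-specific LOD scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting pedigrees enriched for rare variants with family-specific LOD scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famEnrich)
```

## The problem

Rare variants with sizeable effects are prime candidates for the heritability
that genome-wide association studies leave unexplained, but sequencing a
random sample — even a random family — is inefficient: most samples carry no
copy of the allele. A family in which a rare causal allele is segregating is
a very different object: half the offspring of a heterozygous parent are
expected to inherit the allele, so the allele can be locally common inside
one pedigree while being vanishingly rare in the population. `famEnrich`
implements and evaluates a selection strategy that uses linkage information
to find such families: fit a variance-component (VC) linkage model at a
candidate locus, decompose the LOD score by family, and select the pedigree
with the largest family-specific LOD.

## Model and procedure

### Covariate pre-adjustment

Traits are adjusted by pooled ordinary least squares on intercept, age, sex
and smoking; the residuals are standardized (n − 1 denominator) and used as
the analysis trait. Relatedness is ignored at this stage on purpose:
misspecifying the residual correlation affects efficiency, not unbiasedness,
of the covariate effects, and the correlation structure is modeled
immediately afterwards by the VC stage. Adjustment is done independently in
each phenotype replicate. Degenerate designs fail loudly: rank-deficient
covariates name the collinear column, and a trait fully explained by
covariates raises a zero-residual-variance error rather than returning a
constant trait.

### Variance-component likelihood

Families are independent blocks. For family $f$ with $n_f$ members,

$$y_f \sim N(\mu 1,\ \Omega_f), \qquad
\Omega_f = \sigma^2_q \Pi_f + 2\sigma^2_a \Phi_f + \sigma^2_e I,$$

where $\Pi_f$ holds the realized proportions of alleles shared identical by
descent at the locus and $\Phi_f$ the kinship coefficients. The total
log-likelihood is the sum of per-family multivariate-normal terms, evaluated
via Cholesky factorization; a covariance that fails to factor (or is
extremely ill-conditioned) receives a `1e-8` diagonal jitter before one
retry, and a persistent failure is reported with the family's id. $\mu$ is
kept free in both models even though the trait is standardized — it costs
one parameter and guards against variants of the adjustment that do not
center exactly.

### Fitting

Both models (full, and null with $\sigma^2_q = 0$) are maximized by L-BFGS-B
on the log-variance scale with analytic gradients, from three starting
variance splits of the observed trait variance — (0.1, 0.8, 0.1),
(0.3, 0.3, 0.4) and (0, 0.5, 0.5) for (QTL, polygenic, environmental) — with
the best optimum kept. Because $\log \sigma^2_q$ cannot reach the boundary,
the full model additionally probes $\sigma^2_q = 0$ by comparing against the
null fit and adopting it when it is better; this makes the full-model
likelihood never smaller than the null's, as required for a boundary MLE.
Components smaller than $10^{-9}$ times the trait variance are clamped to
zero. The optimizer tolerance corresponds to roughly $10^{-8}$ nats; a grid
search over the full parameter box on small test problems never beats it by
more than $10^{-3}$ nats (this is exercised in the test suite).

### LOD decomposition and family selection

$\mathrm{LOD} = (\ln L_{full} - \ln L_{null}) / \ln 10$, with values within
$10^{-6}$ below zero clamped to zero. The family-specific LOD is defined as
each family's per-block log-likelihood-ratio contribution **evaluated at the
whole-sample ML estimates of both models** — not by re-maximizing within
each family. This convention was genuinely open; we adopted it because it
makes the decomposition exact (family LODs sum to the total LOD), it is
computable at no extra cost, and it reproduces the qualitative behavior of
published family-specific LOD tables, where the averaged largest family LOD
can fall below the total LOD when several families share the signal and can
exceed it when a single family dominates (the two are averaged over
replicates separately). Individual family contributions can be negative; the
selected family is the arg-max, with ties broken by the lexicographically
smallest family id so that selection is deterministic.

### Null distribution of the LOD

Testing $\sigma^2_q = 0$ places the parameter on the boundary of its space,
so the likelihood-ratio statistic is asymptotically a half-half mixture of a
point mass at zero and $\chi^2_1$. In LOD units the mean is
$\tfrac{1}{2}\,E[\chi^2_1]/(2\ln 10) = 1/(4 \ln 10) \approx 0.1086$,
conventionally quoted as 0.11. `nullExpectedLod()`, `rLODNull()` and
`lodPvalue()` expose the closed form, mixture draws, and the tail
probability $p = \tfrac12 P(\chi^2_1 \ge 2\ln 10 \cdot \mathrm{LOD})$.

### Enrichment evaluation

For a gene, the *expected* probability that a randomly selected family
carries the allele is the number of carrier families divided by the number
of families; a family counts as a carrier if any member — including a
founder who transmitted nothing — carries at least one minor-allele copy of
any of the gene's causal variants. The *observed* rate is the fraction of
replicates in which the max-LOD family is a carrier family. The two are
compared with a one-sided, upper-tail one-sample proportion z-test without
continuity correction. The test is not named in the literature this package
follows; we identified it by recomputing published p-values from their
(expected, observed, n) summaries, all of which match to three significant
figures. An exact one-sided binomial alternative is available via
`method = "binomial"`. Genes with no carrier family are reported with
expected 0, observed 0 and `NA` p-value and flagged as null-hypothesis
genes; no multiple-testing adjustment is applied across genes.

### Effect-size accounting

The additive score of a gene is $\sum_v c_v \beta_v$ over its causal
variants ($c_v$ = minor-allele count). Percent variance explained in a group
is the mean over replicates of $\mathrm{Var}_{group}(\text{score}) /
\mathrm{Var}_{group}(\text{trait}) \times 100$, with the raw (pre-adjustment)
trait in the denominator — "total phenotypic variance" is read as the trait
as measured; an option uses the adjusted residuals instead. For a
single-carrier-family gene this exhibits the characteristic dilution: a
large share within the carrier family, a small share overall.

## The synthetic data generator

The generator emulates a family-based simulation design: 8 extended
pedigrees totaling 697 individuals of whom 202 are founders, fixed
genotypes, and 200 replicated traits. The published description of that
design does not include the individual pedigree structures, so they are
configuration, not constants: the default families are built by a
deterministic breadth-first constructor (founding couple; children marry
new founders while the founder budget lasts; three children per couple)
with per-family founder/descendant counts (20/45, 34/85, 25/60, 18/42,
30/78, 22/55, 35/90, 18/40) summing to the published totals. Family 7 is
made the largest so that a single founder allele can plausibly reach ~30
descendant carriers.

Variants are planted in founders independently at the founder MAF, or in
single-carrier mode as exactly one copy in a chosen founder
(population MAF $1/(2 \cdot 697) = 0.0717\%$). Transmission is Mendelian
gene dropping with labeled founder alleles; the per-locus IBD matrix is
computed exactly from the labels ($\hat\pi_{ij}$ = maximum label matching /
2), not estimated from markers — matching a design in which IBD is provided
as given. One IBD matrix is used per gene, treating the gene as a point
locus. Conditioning on a target number of descendant carriers (for
reproducible single-carrier scenarios) uses rejection sampling over a
deterministic seed stream with an iteration cap of $10^5$.

Phenotypes follow
$y = \mu + \beta_{age}\,\mathrm{age} + \beta_{sex}\,\mathrm{sex} +
\beta_{smoke}\,\mathrm{smoke} + \sum_v \beta_v c_v + g + e$ with per-family
polygenic vectors $g \sim N(0, 2\Phi\sigma^2_a)$ and independent
$e \sim N(0, \sigma^2_e)$; genotypes and covariates are fixed across
replicates. The covariate distributions and trait-model constants of the
emulated design are not public, so defaults were chosen once as
conventional epidemiological values: age uniform on 20–80 years, smoking
prevalence 0.25, covariate effects (0.01 per year, 0.2, 0.3),
$\sigma^2_a = 0.3$, $\sigma^2_e = 0.7$ (unit-scale trait, polygenic
heritability 0.3). The default rare-variant effect $\beta = 1.25$ was set so
that a single-carrier gene with ~30 descendant carriers explains about a
fifth to a quarter of the carrier family's phenotypic variance, the regime
of interest for the selection strategy; the default panel also carries a
two-variant moderately-rare gene and a monomorphic null gene.

What the generator does **not** emulate: real sequence data and linkage
disequilibrium between variants, marker-based (noisy, multipoint) IBD
estimation, ascertainment, non-normal trait distributions, and
gene–environment interaction. Tests passing on these simulations therefore
demonstrate correctness of the statistical machinery under the model's own
assumptions, not robustness to the ways real pedigree data violate them —
in particular, with exact IBD the linkage signal is cleaner than
marker-estimated IBD would give, so observed hit rates here are best-case.

## Numerical choices and degenerate inputs

* Pedigrees are topologically sorted on load; cycles, dangling parents,
  half-missing parents and duplicate ids are structural errors naming the
  offender. Individual ids must be unique across families.
* Kinship uses the standard tabular recursion; inbreeding (e.g.,
  first-cousin matings) is handled by the recursion without special cases.
  Monozygotic twins are not modeled. X-linked kinship is out of scope.
* Seeds: every stochastic stage takes an explicit seed; the pipeline derives
  per-stage seeds from a master seed with a counter-based mixing scheme
  (`deriveSeed`), so stages can be re-run independently and identical
  configurations are bit-reproducible.
* LOD values in $[-10^{-6}, 0)$ are treated as 0; the decomposition identity
  is maintained to $10^{-6}$.
* The enrichment z-test returns `NA` for expected probabilities of exactly
  0 or 1 (no sampling variation under random selection).

## Problem sizes used in the shipped checks

The test suite exercises the full 697-individual, 200-replicate design once
(the single-carrier selection scenario) and otherwise uses scaled-down
designs chosen for statistical adequacy: null-calibration runs use 8
families of 20 individuals (500 datasets; the empirical mean LOD and the
positive part of its distribution are compared against the boundary
mixture), kinship is validated against a $2\times10^5$-replicate
gene-dropping Monte-Carlo oracle, and closed-form variance fractions use 25
independent 600-founder panels. Monte-Carlo assertions use 3-standard-error
tolerances computed from the simulations themselves.

## Known limitations

* Family-specific LODs depend on the whole-sample estimates; they are a
  decomposition, not per-family evidence measures, and can be negative.
* The proportion z-test treats replicates as independent Bernoulli trials;
  replicates share one genotype realization, so "observed" rates are
  conditional on that realization (matching the replicated-phenotype
  design).
* ML (not REML) variance components, as the LOD is a likelihood ratio;
  variance estimates are therefore slightly downward-biased in small
  samples.
* Exact single-locus IBD only; no multipoint or marker-error model.
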