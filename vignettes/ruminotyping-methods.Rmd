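---
title: "Ruminotypes, microbial biomarkers and microbiability: methods"
author: "ruminotyper package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ruminotypes, microbial biomarkers and microbiability: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ruminotyper)
```

## The scientific problem

Enteric methane is both a greenhouse gas and an energy loss for the cow.
Methane yield (CH4y, g CH4 per kg of dry matter intake) varies
substantially between animals, and that variation has two biological
reservoirs: the host genome and the rumen microbial community. This
package implements a complete analysis chain for dissecting that
variation from three inputs — an OTU (or genus/MGS/KEGG-module) count
table, a SNP genotype matrix, and per-animal phenotype records:

1. **Ruminotype discovery.** Enterotype-style clustering of genus
   profiles: square-root Jensen–Shannon divergence, partitioning around
   medoids (PAM), Calinski–Harabasz (CH) model selection, silhouette
   diagnostics, cluster-wise Jaccard bootstrap stability, and
   least-squares-means association of clusters with the adjusted trait.
2. **Differential composition.** Zero-inflated Gaussian (ZIG) mixture
   tests on cumulative-sum-scaled (CSS) abundances, and presence–absence
   Fisher tests, both BH-adjusted.
3. **Biomarker selection.** Sparse PLS in discriminant mode (classes =
   ruminotypes) and regression mode (response = adjusted CH4y), keeping
   only the features selected by *both* models.
4. **Variance partitioning.** A Bayesian mixed model
   `y = 1mu + g + b + e` with `g ~ N(0, G sg2)` and `b ~ N(0, B sb2)`,
   where `G` is a VanRaden genomic relationship matrix and `B` a
   microbial relationship matrix; heritability
   `h2 = sg2/(sg2+sb2+se2)` and microbiability `m2 = sb2/(sg2+sb2+se2)`
   are posterior summaries from a Gibbs sampler.

Because the motivating datasets of this kind are typically under
restricted access, the package ships a synthetic-data generator
(`scenarioConfig()`, `simulateStudy()`) that reproduces the statistical
structure the analysis assumes, with known ground truth.

## Phenotype preparation

Records carry `CH4` (g/day) and `DMI` (kg/day); methane yield is their
ratio. Traits are adjusted for the contemporary group before any
modelling: the batch-by-period cell mean is subtracted, so adjusted
residuals sum to zero within every cell (`preparePhenotypes()`). Animals
measured in two periods are collapsed by averaging their adjusted
records (`perAnimalTrait()`), consistent with designs where one batch is
measured twice.

## Count-table preparation

* `filterOtus()` removes doubleton OTUs (total count at most 2) and then
  OTUs at or below 0.001% of the remaining grand total. The operation is
  idempotent.
* `aggregateTaxon()` sums counts over a lineage prefix; OTUs classified
  only to a shallower rank are pooled per parent as
  `unclassified_<parent>`, conserving the grand total.
* Normalisations: relative abundance (`toRelative()`), centred log-ratio
  with a pseudocount of 1 on natural logs (`clrTransform()`; each sample
  column of the result sums to 0), and CSS (`cssNormalize()`): the
  per-sample scaling factor is the sum of counts at or below the chosen
  quantile (default 0.5) of that sample's nonzero counts, and values are
  `log2(count/factor * 1000 + 1)`. An adaptive quantile rule (relative
  difference of the median quantile profile) is available behind a flag,
  but the fixed default is the reproducible choice.

Genotype QC removes SNPs with minor allele frequency below 5%, missing
rate above 10%, or a Hardy–Weinberg 1-df chi-square p-value below 0.001
(no continuity correction). Missing dosages are never imputed during QC;
the GRM construction imputes them to twice the allele frequency.

## Ruminotype discovery: numerical choices

* **Distance.** `sqrt(JSD)` is used rather than raw JSD because the
  square root is a metric (the triangle inequality is exercised in the
  test suite); zeros are replaced by a pseudo-probability of 1e-9 and
  profiles renormalised. A flag returns raw JSD.
* **PAM.** Greedy BUILD seeding followed by best-improvement SWAP. Only
  strictly improving swaps are accepted, which makes the cost trace
  monotone and guarantees termination under ties; ties in assignment
  break toward the lowest sample index, so the solution is a
  deterministic function of the distance matrix. Single-start PAM has
  well-documented local optima on tiny instances, so for n up to 12 the
  SWAP phase is restarted from every possible BUILD seeding and the best
  local optimum kept; the suite checks the result against exhaustive
  medoid enumeration.
* **CH index.** CH is variance-based, while sqrt-JSD matrices are
  non-Euclidean, so the default embeds the distance matrix by classical
  MDS (PCoA), dropping axes with non-positive eigenvalues, and computes
  between/within sums of squares there. A `"distance"` mode computes the
  same decomposition directly from squared dissimilarities; both are
  exposed because the convention differs between implementations.
* **Stability.** Cluster-wise Jaccard bootstrap (100 repetitions by
  default): each resample is reclustered and every original cluster is
  scored against its best-matching bootstrap cluster on the drawn
  points (maximum-Jaccard matching, not Hungarian assignment). Values
  around 0.6 read as moderate stability, above 0.85 as stable.
* **Association.** The adjusted trait is modelled on cluster membership
  by one-way least squares; all pairwise contrasts are Tukey-adjusted
  (the multiplicity handling is a package choice; with two clusters the
  contrast reduces exactly to the pooled-variance t-test).

## Differential abundance

The ZIG model treats each CSS value as either a structural zero (point
mass at 0, probability logistic in log library size) or Gaussian with a
group-dependent mean. EM alternates weighted least squares and a
fractional-response logistic refit; the M-step keeps the better of the
slope and intercept-only logistic fits (and the previous iterate), so
the observed-data log-likelihood is non-decreasing — this is asserted in
the tests. The group effect is tested by a t-statistic with the weighted
residual degrees of freedom. Unlike the original moderated formulation,
no empirical-Bayes variance shrinkage is applied — a deliberate
simplification; with no zeros the procedure collapses exactly to the
per-feature linear model. Type-I error calibration and 4-fold spike
power are exercised in the acceptance tests.

Presence–absence testing uses Fisher's exact test (two-sided by the
probability-mass rule) with Haldane–Anscombe-corrected sample odds
ratios; the flavour of odds ratio is a package choice since conditional
maximum-likelihood estimates are another common convention.

## Sparse PLS

Per component the dominant singular pair of `X'Y` is found by power
iteration; the X weight vector is soft-thresholded to at most `keepX`
nonzero entries then renormalised (hard cardinality with
soft-threshold shrinkage), scores are `X w`, and both blocks are
deflated by regression on the score (regression-mode deflation in both
modes). Discriminant mode one-hot-encodes the classes and predicts by
the maximum predicted indicator value (max.dist). Tuning uses
stratified 5-fold cross-validation with the balanced error rate in
discriminant mode — folds are laid out in a canonical group order so
BER is invariant to relabelling — and `Q2_h = 1 - PRESS_h/RSS_(h-1)`
with the classical 0.0975 retention threshold in regression mode (the
threshold rule is a package choice). AUROC uses the rank (Mann–Whitney)
formulation with midranks; by default it is computed on training scores
and warns, since resubstitution AUCs are optimistic. The biomarker set
is the intersection of the discriminant and regression selections, with
provenance tags for features selected by only one route.

## Variance components

Kernels: VanRaden `G = ZZ'/(2 sum p(1-p))` on dosages centred by `2p`;
microbial `B` either as `1 - D` with `D` the Bray–Curtis dissimilarity
on relative abundances (with eigenvalue truncation to repair
indefiniteness, flagged when applied, and an explicit guard for samples
empty on a feature subset), or as the covariance of the log(count+1)
table standardised per feature with the (n-1)-denominator SD, divided
by the number of features (mean diagonal `(n-1)/n`).

The Gibbs sampler works in the eigenbases of `G` and `B`, where the
full conditionals of the transformed effects are diagonal normals; this
is distributionally equivalent to direct multivariate sampling but
keeps every update at two matrix-vector products (the tiny-data test
compares the sampler against deterministic numerical integration of the
same posterior). Priors: flat on the intercept; scaled-inverse-chi-square
with 5 degrees of freedom on each variance, with scales that give the
residual half of the sample variance of `y` and each kernel a quarter —
the usual partition of a default total "R2" of one half across two
random terms. Defaults are 30,000 iterations, 2,000 burn-in, thinning
1; `h2` and `m2` are computed per retained draw and then summarised
(posterior mean, SD, 5%/95% quantiles).

With only a few hundred animals the split between two kernels is
genuinely diffuse — the duplicate-kernel check in the test suite shows
the posterior SD widening when `B = G` — so posterior means should be
read with their SDs, as in the motivating literature.

## The synthetic generator

`scenarioConfig()` fixes the study conditions; all downstream draws
derive from its single seed.

* **Community.** 65 samples, 1,200 OTUs in 100 genera, three latent
  clusters with exact design sizes 30/16/19 randomly assigned. Genus
  profiles are Dirichlet with cluster-specific concentration vectors
  `alpha_c = concentration * softmax(log base + separation * delta_c)`,
  where `base` is a rank-1/r power law and the `delta_c` are
  orthogonalised equal-norm directions — the emulated ruminotypes are
  distinct community configurations, not chance-correlated draws.
  `separation = 2` and `concentration = 120` are chosen so that the
  three clusters are clearly resolved by the CH criterion, mirroring
  the sharply peaked cluster-number profiles reported for rumen and gut
  enterotypes; with `separation = 0` or `nClusters = 1` the generator
  produces an honest null. OTU counts are multinomial within genus
  with a fixed within-genus split; library sizes are lognormal (median
  2e4, CV roughly 50%) to exercise CSS scaling and depth-driven zeros.
* **Genotypes.** Independent SNPs with allele frequencies uniform on
  (0.05, 0.5) and Hardy–Weinberg dosages; no LD and no relatedness
  structure, so QC removes essentially nothing and the GRM is close to
  the identity at large SNP counts.
* **Phenotype.** Record-level
  `CH4y = mu + cell + g + m + shift + e` on the scale of the published
  trait (mean 24.1, SD 3.1 g/kg): batch-by-period cell effects (SD 1),
  additive-genetic values from SNP effects on centred dosages scaled to
  `sqrt(h2) * SD`, microbial values from effects on the CLR abundances
  of 30 causal OTUs scaled to `sqrt(m2) * SD`, and a per-cluster offset.
  The microbial component is centred within clusters so that the
  cluster-level contrast is carried by `clusterPhenotypeShift` alone and
  the OTU-level channel by within-cluster variation; realized variance
  fractions are reported over the stochastic components (g, m, e) and
  recorded in `truth`, never assumed equal to their targets. The default
  shift of +4 g/kg (about 1.3 phenotypic SD) on the second cluster makes
  the cluster-trait association detectable in a typical 65-cow
  realization, as in the motivating study; the magnitude is a free
  parameter with no published value behind it. Batch B1 animals receive
  records in both periods, exercising the repeated-record averaging.

What the generator does **not** emulate: phylogenetic correlation among
OTUs, LD and family structure in the genotypes, overdispersion beyond
the Dirichlet-multinomial, read-level artefacts, and any diet or parity
covariates. Passing tests therefore demonstrate correctness of the
statistical machinery under the assumed model, not robustness to every
feature of real rumen data.

## Problem sizes used by the test suite

The acceptance checks run the full stack at the study's own scale
(65 samples, about 1,200 OTUs, 100 genera) over 50 generator seeds for
cluster recovery, 100 bootstrap repetitions for stability, 2,000
features for ZIG calibration, and n = 300 with 30,000 Gibbs iterations
(20 replicates) for variance-component recovery; PERMANOVA calibration
uses 1,000 null simulations at 999 permutations each. Unit tests use
smaller fixtures chosen to finish in seconds while still covering the
oracle comparisons (exhaustive PAM enumeration, hypergeometric
enumeration for Fisher tests, grid-scan posterior integration for the
Gibbs sampler, mixOmics agreement for sPLS-DA).

## Known limitations

* The ZIG variance is not moderated across features; with very few
  samples per group its t-test is slightly conservative.
* PERMANOVA covariate correction follows the sequential
  (Type I) sums-of-squares convention of `vegan::adonis2`, permuting
  raw observations rather than residuals.
* The sampler reports `h2` and `m2` on the three-component denominator;
  if a kernel's mean diagonal deviates strongly from 1 the fractions
  inherit that scaling.
* sPLS confidence is resubstitution-based unless cross-validated scores
  are requested; the reported default warns accordingly.
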