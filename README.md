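# ruminotyper

Rumen microbial community structure, microbial biomarkers of methane
yield, and the partition of phenotypic variance into host-genetic
(heritability, h²) and microbial (microbiability, m²) components — as
one tested R package.

## Who this is for

Quantitative geneticists and microbiome researchers working with
ruminant methane data: an OTU/genus count table (TSV), a SNP genotype
matrix (TSV or VCF), and per-animal records of methane production (CH4,
g/day) and dry matter intake (DMI, kg/day), from which methane yield
CH4y = CH4/DMI is derived and adjusted for the batch × period
contemporary group.

## What it computes

* **Ruminotypes** — enterotype-style clusters of genus profiles:
  `d = sqrt(JSD)` distances, PAM clustering, Calinski–Harabasz choice of
  the cluster number, silhouettes, cluster-wise Jaccard bootstrap
  stability, and Tukey-adjusted least-squares-means contrasts of the
  adjusted trait between clusters.
* **Differential composition** — zero-inflated Gaussian tests on
  CSS-normalized abundances (`fitZig`) and presence–absence Fisher exact
  tests (`presenceAbsence`), both BH-adjusted, plus fold changes.
* **Biomarkers** — sparse PLS-DA on cluster labels and sparse PLS
  regression on CH4y over CLR-transformed OTUs
  (`splsdaFit`, `splsFit`, `tuneCv`, `aurocScores`), intersected
  conservatively (`intersectBiomarkers`).
* **Variance components** — Bayesian mixed model
  `y = 1μ + g + b + ε`, `g ~ N(0, G σg²)`, `b ~ N(0, B σb²)`, with a
  VanRaden GRM and a microbial kernel (Bray–Curtis similarity or
  log-standardized covariance), Gibbs-sampled (30,000 iterations, 2,000
  burn-in by default); reports posterior means and SDs of
  h² = σg²/(σg²+σb²+σε²) and m² = σb²/(σg²+σb²+σε²).
* **Diversity & stability** — Shannon (nats), Whittaker β = γ/ᾱ − 1,
  Bray–Curtis and binary Jaccard distances, the RV coefficient between
  two time points, and PERMANOVA with covariate correction.
* **Synthetic studies** — `simulateStudy()` generates communities with
  three latent ruminotypes (sizes 30/16/19 of 65), HWE genotypes, and
  phenotypes with controlled h²/m², so the whole pipeline runs with
  known ground truth.

## Worked example

```r
library(ruminotyper)

cfg    <- scenarioConfig(seed = 1)          # default synthetic study
study  <- simulateStudy(cfg)
counts <- filterOtus(study$counts)
counts
#> CountTable [otu]: 1119 features x 65 samples, total 1,567,006 counts

genera <- aggregateTaxon(counts, "genus")
sel    <- selectK(jsdDistance(toRelative(genera)), 2:8)
sel$table
#>   k        CH silhouette
#> 1 2  52.22966 0.47497057
#> 2 3 143.30930 0.62255839
#> 3 4  97.52796 0.45539228
#> ...
sel$solution
#> ClusterSolution: k = 3, sizes = 19/16/30, cost = 14.6201
```

The CH index peaks sharply at k = 3: the three simulated ruminotypes are
recovered (here with a perfect label match to the generator's truth).
Associating clusters with the contemporary-group-adjusted methane yield:

```r
pheno <- preparePhenotypes(study$phenotypes)
trait <- perAnimalTrait(pheno, "adj_CH4y")[names(clusterLabels(sel$solution))]
clusterPhenotypeAssoc(clusterLabels(sel$solution), trait)$contrasts
#>  contrast  estimate        SE df t.ratio p.value
#>  R1 - R2  -5.888274 1.0246131 62  -5.747  <.0001
#>  R1 - R3  -1.344710 0.8853669 62  -1.519  0.2892
#>  R2 - R3   4.543564 0.9348049 62   4.860  <.0001
```

Cluster R2 emits significantly more CH4y than R1 and R3, which do not
differ — the pattern the generator was configured to produce. Finally,
the two-kernel mixed model on the same 65 animals:

```r
fit <- gibbsTwoKernel(trait,
                      grmVanRaden(genotypeQC(study$genotypes)),
                      mrmRoss(counts),
                      mcmcConfig(nIter = 30000, burnIn = 2000, seed = 1))
fit
#> PosteriorSummary (two-kernel Bayesian mixed model)
#>   parameter     mean    sd     q05   q95
#> ...
#> 5        h2 0.246386 0.130  0.0824 0.501
#> 6        m2 0.326817 0.127  0.1476 0.561
```

At n = 65 the posterior SDs are large (±0.13) — variance-component
splits at this sample size are intrinsically diffuse, which is why they
are always reported as mean (SD). The parameter-recovery behaviour at
n = 300 is exercised by the test suite and the acceptance script.

The full chain (filter → ruminotype → differential tests → sPLS
biomarkers → variance components) is available as one call:
`runPipeline(pipelineConfig(seed = 1), outDir = "run1")`, which writes
per-stage TSVs and a JSON manifest; a thin command-line wrapper lives in
`inst/scripts/pipeline.R`.

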