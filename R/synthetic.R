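## Synthetic study generator: Dirichlet-multinomial communities with latent
## ruminotype clusters, HWE genotypes, and phenotypes with controlled
## host-genetic and microbial variance fractions.

#' Synthetic scenario configuration
#'
#' Defaults emulate the study design this package targets: 65 cows in three
#' batches measured over two periods, ~1,200 OTUs aggregable to ~100
#' genera, three latent community clusters with the middle cluster shifted
#' upward in methane yield, HWE genotypes, and additive-genetic /
#' microbial phenotypic variance fractions of 0.15 / 0.20.
#'
#' @param nSamples number of animals (default 65).
#' @param nOtus,nGenera community dimensions (1200 OTUs, 100 genera).
#' @param nClusters number of latent community clusters (3).
#' @param clusterMixing cluster membership probabilities (defaults to the
#'   30/16/19 split of 65).
#' @param separation scaling of between-cluster log-abundance divergence.
#' @param concentration Dirichlet concentration controlling within-cluster
#'   compositional variability.
#' @param depthMeanlog,depthSdlog lognormal library-size parameters
#'   (median ~20,000 reads, CV ~50%).
#' @param nSnps,mafRange genotype panel size and allele-frequency range.
#' @param h2True,m2True target additive-genetic and microbial fractions of
#'   phenotypic variance.
#' @param nCausalOtus number of OTUs with phenotypic effects.
#' @param clusterPhenotypeShift per-cluster trait offset in g/kg DMI.
#' @param phenotypeMean,phenotypeSd methane-yield mean and SD (g/kg DMI).
#' @param cellEffectSd SD of batch x period contemporary-group effects.
#' @param seed integer seed anchoring every random draw of the scenario.
#' @return A `ScenarioConfig` list (class `"ScenarioConfig"`).
#' @export
scenarioConfig <- function(nSamples = 65, nOtus = 1200, nGenera = 100,
                           nClusters = 3,
                           clusterMixing = c(30, 16, 19) / 65,
                           separation = 2, concentration = 120,
                           depthMeanlog = log(2e4), depthSdlog = 0.47,
                           nSnps = 2000, mafRange = c(0.05, 0.5),
                           h2True = 0.15, m2True = 0.20,
                           nCausalOtus = 30,
                           clusterPhenotypeShift = c(0, 4, 0),
                           phenotypeMean = 24.1, phenotypeSd = 3.1,
                           cellEffectSd = 1, seed = 1L) {
  if (h2True + m2True >= 1) stop("h2True + m2True must be < 1")
  if (abs(sum(clusterMixing) - 1) > 1e-8) stop("clusterMixing must sum to 1")
  if (length(clusterMixing) != nClusters)
    stop("clusterMixing must have nClusters entries")
  if (length(clusterPhenotypeShift) != nClusters)
    clusterPhenotypeShift <- rep_len(clusterPhenotypeShift, nClusters)
  cfg <- as.list(environment())
  class(cfg) <- "ScenarioConfig"
  cfg
}

# Structural draws shared by every table of one scenario: cluster profiles,
# OTU-to-genus map, within-genus splits, cluster labels, batch layout.
.scenarioStructure <- function(cfg) {
  withr_seed <- function(s, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s); expr
  }
  withr_seed(cfg$seed, {
    base <- (seq_len(cfg$nGenera))^-1
    base <- base / sum(base)
    delta <- matrix(rnorm(cfg$nClusters * cfg$nGenera), cfg$nClusters)
    if (cfg$nClusters > 1) {
      # orthogonalized, equal-norm shift directions: the emulated community
      # types are distinct configurations, not chance-correlated draws
      delta <- t(qr.Q(qr(t(delta)))) * sqrt(cfg$nGenera)
    }
    alpha <- t(apply(delta, 1L, function(d) {
      w <- exp(log(base) + cfg$separation * d)
      cfg$concentration * w / sum(w)
    }))
    genusOf <- c(seq_len(cfg$nGenera),
                 sample.int(cfg$nGenera, cfg$nOtus - cfg$nGenera,
                            replace = TRUE, prob = base))
    split <- rgamma(cfg$nOtus, shape = 1)
    ## exact design sizes (e.g. 30/16/19 of 65), randomly assigned
    sizes <- floor(cfg$clusterMixing * cfg$nSamples)
    rem <- cfg$nSamples - sum(sizes)
    if (rem > 0) {
      frac <- cfg$clusterMixing * cfg$nSamples - sizes
      top <- order(frac, decreasing = TRUE)[seq_len(rem)]
      sizes[top] <- sizes[top] + 1L
    }
    labels <- sample(rep.int(seq_len(cfg$nClusters), sizes))
    nb <- c(floor(cfg$nSamples * 21 / 65), floor(cfg$nSamples * 21 / 65))
    nb <- c(nb, cfg$nSamples - sum(nb))
    batch <- rep(c("B1", "B2", "B3"), times = nb)
    cellEffects <- rnorm(4, 0, cfg$cellEffectSd)  # B1P1, B2P1, B1P2, B3P2
    causal <- sample.int(cfg$nOtus, min(cfg$nCausalOtus, cfg$nOtus))
    list(alpha = alpha, genusOf = genusOf, split = split, labels = labels,
         batch = batch, cellEffects = cellEffects, causal = causal)
  })
}

#' Generate a synthetic community count table
#'
#' Each sample's genus profile is Dirichlet with its cluster's
#' concentration vector; OTU probabilities split each genus with a fixed
#' within-genus composition; counts are multinomial at a lognormal library
#' size. Taxonomy strings encode the genus of every OTU so
#' [aggregateTaxon()] recovers the genus table.
#'
#' @param cfg a [scenarioConfig()].
#' @param timePoint integer; a second time point redraws sample profiles
#'   from the same cluster memberships (for stability analyses).
#' @return list with `counts` (a [CountTable-class]) and `labels`
#'   (true cluster per sample).
#' @export
generateCommunity <- function(cfg, timePoint = 1L) {
  st <- .scenarioStructure(cfg)
  set.seed(cfg$seed + 1000L * timePoint)
  n <- cfg$nSamples
  depth <- round(rlnorm(n, cfg$depthMeanlog, cfg$depthSdlog))
  m <- matrix(0, cfg$nOtus, n)
  for (j in seq_len(n)) {
    a <- st$alpha[st$labels[j], ]
    gp <- rgamma(cfg$nGenera, shape = a)
    gp <- gp / sum(gp)
    pOtu <- gp[st$genusOf] * st$split /
      ave(st$split, st$genusOf, FUN = sum)[seq_along(st$split)]
    m[, j] <- rmultinom(1L, depth[j], pOtu)
  }
  dimnames(m) <- list(sprintf("OTU%04d", seq_len(cfg$nOtus)),
                      sprintf("cow%03d", seq_len(n)))
  tax <- sprintf("d__Bacteria;p__SimPhylum;c__SimClass;o__SimOrder;f__SimFamily%02d;g__Genus%03d",
                 (st$genusOf - 1L) %% 20L + 1L, st$genusOf)
  list(counts = CountTable(m, taxonomy = tax, level = "otu"),
       labels = setNames(st$labels, colnames(m)))
}

#' Generate HWE genotypes
#'
#' Per SNP: allele frequency uniform in `mafRange`, dosages Binomial(2, p)
#' independently across animals (Hardy-Weinberg equilibrium, no LD).
#'
#' @param cfg a [scenarioConfig()].
#' @return A [GenotypeMatrix-class] (SNPs x animals, no missing calls).
#' @export
generateGenotypes <- function(cfg) {
  set.seed(cfg$seed + 77L)
  p <- runif(cfg$nSnps, cfg$mafRange[1], cfg$mafRange[2])
  d <- matrix(rbinom(cfg$nSnps * cfg$nSamples, 2L, rep(p, cfg$nSamples)),
              cfg$nSnps, cfg$nSamples)
  dimnames(d) <- list(sprintf("snp%05d", seq_len(cfg$nSnps)),
                      sprintf("cow%03d", seq_len(cfg$nSamples)))
  GenotypeMatrix(d, snpInfo = data.frame(
    snp_id = rownames(d),
    chrom = sort(rep_len(1:29, cfg$nSnps)),
    pos = seq_len(cfg$nSnps) * 1000L, a1 = "A", a2 = "B"))
}

#' Generate phenotypes with controlled variance fractions
#'
#' Record-level methane yield is built additively: intercept + batch x
#' period contemporary-group effect + additive-genetic value (SNP effects
#' on centred dosages) + microbial value (effects on CLR abundances of the
#' causal OTUs) + per-cluster shift + residual. Genetic and microbial
#' component vectors are rescaled so their variance fractions of the
#' phenotypic variance (exclusive of the group effect and cluster shift)
#' equal `h2True` and `m2True`; the realized fractions of the full
#' phenotype are recorded in `truth`, not assumed.
#'
#' Batch B1 animals get one record in each of the two periods (mirroring
#' the repeated-measurement design); batches B2/B3 one record each.
#'
#' @param cfg a [scenarioConfig()].
#' @param community result of [generateCommunity()].
#' @param genotypes result of [generateGenotypes()].
#' @return list with `phenotypes` (record-level data.frame with
#'   `animal_id,batch,period,CH4,DMI`) and `truth` (components, causal ids
#'   and effects, realized variance fractions).
#' @export
generatePhenotype <- function(cfg, community, genotypes) {
  st <- .scenarioStructure(cfg)
  set.seed(cfg$seed + 2024L)
  n <- cfg$nSamples
  sdP <- cfg$phenotypeSd

  ## genetic component
  Z <- genotypes@dosages
  pA <- rowMeans(Z, na.rm = TRUE) / 2
  Zc <- Z - 2 * pA
  snpEff <- if (cfg$h2True > 0) rnorm(nrow(Z), 0, 1 / sqrt(nrow(Z))) else
    rep(0, nrow(Z))
  gRaw <- as.numeric(crossprod(Zc, snpEff))
  g <- if (cfg$h2True > 0 && sd(gRaw) > 0)
    gRaw / sd(gRaw) * sdP * sqrt(cfg$h2True) else rep(0, n)

  ## microbial component through CLR abundances of causal OTUs
  clrX <- abundanceValues(clrTransform(community$counts))
  otuEff <- if (cfg$m2True > 0) rnorm(length(st$causal)) else
    rep(0, length(st$causal))
  mRaw <- as.numeric(crossprod(clrX[st$causal, , drop = FALSE], otuEff))
  # centred within clusters: the cluster-level trait contrast is carried by
  # clusterPhenotypeShift alone, the OTU effects by within-cluster variation
  mRaw <- mRaw - ave(mRaw, st$labels)
  mVal <- if (cfg$m2True > 0 && sd(mRaw) > 0)
    mRaw / sd(mRaw) * sdP * sqrt(cfg$m2True) else rep(0, n)

  shift <- cfg$clusterPhenotypeShift[st$labels]

  ## records: B1 twice (periods 1 and 2), B2 period 1, B3 period 2
  idx <- c(which(st$batch == "B1"), which(st$batch == "B2"),
           which(st$batch == "B1"), which(st$batch == "B3"))
  period <- rep(c("P1", "P2"),
                c(sum(st$batch != "B3"), sum(st$batch != "B2")))
  cellId <- as.integer(factor(paste(st$batch[idx], period)))
  cellEff <- st$cellEffects[cellId]
  eSd <- sdP * sqrt(1 - cfg$h2True - cfg$m2True)
  e <- rnorm(length(idx), 0, eSd)
  ch4y <- cfg$phenotypeMean + cellEff + g[idx] + mVal[idx] + shift[idx] + e
  dmi <- pmax(rnorm(length(idx), 21.2, 2.2), 10)
  pheno <- data.frame(
    animal_id = colnames(otuCounts(community$counts))[idx],
    batch = st$batch[idx], period = period,
    CH4 = ch4y * dmi, DMI = dmi)

  # fractions over the stochastic components (fixed cluster offsets and
  # contemporary-group effects excluded, as in the mixed-model definition)
  yStoch <- g[idx] + mVal[idx] + e
  truth <- list(
    labels = setNames(st$labels, colnames(clrX)),
    causal_otus = rownames(clrX)[st$causal],
    otu_effects = otuEff, snp_effects = snpEff,
    genetic = setNames(g, colnames(clrX)),
    microbial = setNames(mVal, colnames(clrX)),
    realized_h2 = var(g[idx]) / var(yStoch),
    realized_m2 = var(mVal[idx]) / var(yStoch))
  list(phenotypes = pheno, truth = truth)
}

#' Simulate a complete synthetic study
#'
#' Runs [generateCommunity()], [generateGenotypes()] and
#' [generatePhenotype()] under one configuration; optionally writes the
#' three input files (counts TSV, genotypes TSV, phenotypes CSV) plus a
#' `truth.json` sidecar to `dir`.
#'
#' @param cfg a [scenarioConfig()].
#' @param dir optional output directory.
#' @return list with `counts`, `genotypes`, `phenotypes`, `truth`.
#' @export
simulateStudy <- function(cfg = scenarioConfig(), dir = NULL) {
  com <- generateCommunity(cfg)
  gen <- generateGenotypes(cfg)
  ph <- generatePhenotype(cfg, com, gen)
  study <- list(counts = com$counts, genotypes = gen,
                phenotypes = ph$phenotypes, truth = ph$truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeCountTable(com$counts, file.path(dir, "otu_counts.tsv"))
    gd <- data.frame(gen@snpInfo, gen@dosages, check.names = FALSE)
    write.table(gd, file.path(dir, "genotypes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    utils::write.csv(ph$phenotypes, file.path(dir, "phenotypes.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(labels = unname(ph$truth$labels),
           causal_otus = ph$truth$causal_otus,
           realized_h2 = ph$truth$realized_h2,
           realized_m2 = ph$truth$realized_m2),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  study
}
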