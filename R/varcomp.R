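## Relationship kernels (genomic and microbial) and the Bayesian
## two-kernel mixed model: heritability and microbiability.

#' VanRaden genomic relationship matrix
#'
#' `G = ZZ' / (2 sum p(1-p))` with `Z` the SNP dosages centred by twice
#' the allele frequency (VanRaden method I). Missing dosages are imputed
#' to `2p`.
#'
#' @param g a post-QC [GenotypeMatrix-class].
#' @return A [RelationshipMatrix-class] with `kind = "genomic_vanraden"`.
#' @export
grmVanRaden <- function(g) {
  d <- g@dosages
  p <- rowMeans(d, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1
  if (!all(keep)) {
    d <- d[keep, , drop = FALSE]
    p <- p[keep]
  }
  if (!nrow(d)) stop("no polymorphic SNPs")
  if (anyNA(d)) {
    imput <- 2 * p
    for (i in which(rowSums(is.na(d)) > 0)) d[i, is.na(d[i, ])] <- imput[i]
  }
  Z <- d - 2 * p
  G <- crossprod(Z) / (2 * sum(p * (1 - p)))
  new("RelationshipMatrix", values = .psdRepair(G)$m,
      kind = "genomic_vanraden", psdRepaired = FALSE)
}

#' Microbial relationship matrix from Bray-Curtis similarity
#'
#' `B = 1 - D` with `D` the Bray-Curtis dissimilarity matrix on relative
#' abundances. Because a similarity built this way need not be positive
#' semi-definite, negative eigenvalues are truncated at zero and the
#' matrix reconstructed; the flag records whether that repair changed
#' anything.
#'
#' @param x a [CountTable-class] (relative abundances computed internally)
#'   or an [AbundanceTable-class].
#' @return A [RelationshipMatrix-class] with `kind = "microbial_bray"`;
#'   the maximum elementwise change of the repair is attached as attribute
#'   `"repairDelta"`.
#' @export
mrmBray <- function(x) {
  m <- if (is(x, "CountTable")) otuCounts(x) else abundanceValues(x)
  cs <- colSums(m)
  p <- sweep(m, 2L, pmax(cs, 1), "/")    # zero-total samples stay all-zero
  # empty profiles are handled explicitly below, so vegdist's warnings
  # about them are silenced
  d <- as.matrix(suppressWarnings(vegan::vegdist(t(p), method = "bray")))
  d[is.nan(d)] <- 0                      # two empty profiles: identical
  B <- 1 - d
  rep <- .psdRepair(B)
  out <- new("RelationshipMatrix", values = rep$m, kind = "microbial_bray",
             psdRepaired = rep$repaired)
  attr(out, "repairDelta") <- rep$delta
  out
}

#' Microbial relationship matrix from the log-standardized table
#'
#' The covariance-style kernel: `S = log(count + 1)` with every feature
#' standardized to mean 0 and (n-1)-denominator SD 1 across samples, then
#' `B = S'S / n_features` (samples x samples). Features constant across
#' samples are dropped with a warning. The mean diagonal equals
#' `(n-1)/n`.
#'
#' @param x a [CountTable-class].
#' @return A [RelationshipMatrix-class] with `kind = "microbial_ross"`.
#' @export
mrmRoss <- function(x) {
  S <- log(otuCounts(x) + 1)
  sds <- apply(S, 1L, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant feature(s) dropped")
    S <- S[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (!nrow(S)) stop("no variable features")
  Sz <- (S - rowMeans(S)) / sds
  B <- crossprod(Sz) / nrow(Sz)
  new("RelationshipMatrix", values = .psdRepair(B)$m,
      kind = "microbial_ross", psdRepaired = FALSE)
}

.psdRepair <- function(m, tol = 1e-10) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= -tol * max(abs(e$values), 1))
    return(list(m = m, repaired = FALSE, delta = 0))
  v <- pmax(e$values, 0)
  m2 <- e$vectors %*% (v * t(e$vectors))
  m2 <- (m2 + t(m2)) / 2
  dimnames(m2) <- dimnames(m)
  list(m = m2, repaired = TRUE, delta = max(abs(m2 - m)))
}

#' MCMC configuration for the two-kernel model
#'
#' @param nIter total Gibbs iterations (default 30,000).
#' @param burnIn burn-in rounds discarded (default 2,000).
#' @param thin keep every `thin`-th post-burn-in draw (default 1).
#' @param seed RNG seed.
#' @param df0 prior degrees of freedom of the scaled-inverse-chi-square
#'   variance priors (default 5).
#' @return list of class `"McmcConfig"`.
#' @export
mcmcConfig <- function(nIter = 30000, burnIn = 2000, thin = 1, seed = 1L,
                       df0 = 5) {
  if (burnIn >= nIter) stop("burnIn must be smaller than nIter")
  structure(list(nIter = as.integer(nIter), burnIn = as.integer(burnIn),
                 thin = as.integer(thin), seed = as.integer(seed),
                 df0 = df0), class = "McmcConfig")
}

#' Two-kernel Bayesian mixed model
#'
#' Fits `y = 1 mu + g + b + e` with `g ~ N(0, G sigma_g^2)` and
#' `b ~ N(0, B sigma_b^2)` by Gibbs sampling: flat prior on the intercept,
#' scaled-inverse-chi-square priors (df `df0`, scale set so each prior
#' variance mean is a third of the sample variance of `y`) on the three
#' variance components. `g` and `b` are sampled in the eigenbases of their
#' kernels, where the full conditionals are diagonal. Heritability
#' `h2 = sigma_g^2 / (sigma_g^2 + sigma_b^2 + sigma_e^2)` and
#' microbiability `m2 = sigma_b^2 / (...)` are computed per retained draw
#' and then summarized.
#'
#' @param y numeric phenotype vector (one record per animal, typically the
#'   contemporary-group adjusted trait averaged over periods).
#' @param G,B [RelationshipMatrix-class] kernels (or plain PSD matrices)
#'   in the same animal order as `y`.
#' @param config an [mcmcConfig()].
#' @return A [PosteriorSummary-class].
#' @export
gibbsTwoKernel <- function(y, G, B, config = mcmcConfig()) {
  y <- as.numeric(y)
  if (var(y) == 0) stop("zero-variance phenotype")
  Gm <- as.matrix(G); Bm <- as.matrix(B)
  if (nrow(Gm) != length(y) || nrow(Bm) != length(y))
    stop("kernel dimensions must match the phenotype length")
  eg <- eigen(Gm, symmetric = TRUE)
  eb <- eigen(Bm, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(eg$values) ||
      min(eb$values) < -1e-6 * max(eb$values))
    stop("kernels must be positive semi-definite (apply PSD repair first)")
  ## scaled-inverse-chi-square scales: half the sample variance to the
  ## residual, the other half split equally across the two kernels
  s0e <- var(y) / 2 * (config$df0 - 2) / config$df0
  s0k <- var(y) / 4 * (config$df0 - 2) / config$df0
  set.seed(config$seed)
  draws <- .gibbsTwoKernelCpp(y, eg$vectors, pmax(eg$values, 0),
                              eb$vectors, pmax(eb$values, 0),
                              config$nIter, config$burnIn, config$thin,
                              config$df0, s0k, s0k, s0e)
  tot <- draws[, "sigma_g2"] + draws[, "sigma_b2"] + draws[, "sigma_e2"]
  chains <- cbind(draws, h2 = draws[, "sigma_g2"] / tot,
                  m2 = draws[, "sigma_b2"] / tot)
  summ <- data.frame(
    parameter = colnames(chains),
    mean = colMeans(chains),
    sd = apply(chains, 2L, sd),
    q05 = apply(chains, 2L, quantile, 0.05),
    q95 = apply(chains, 2L, quantile, 0.95),
    row.names = NULL)
  new("PosteriorSummary", summary = summ, chains = chains,
      config = unclass(config))
}

#' Heritability/microbiability table across kernel constructions
#'
#' Runs the two-kernel model for each combination of OTU set (whole table
#' vs a biomarker subset) and microbial kernel construction (Bray-Curtis
#' similarity vs log-standardized covariance), mirroring the usual
#' reporting layout: posterior mean (SD) of h2 and m2 per cell.
#'
#' @param y phenotype vector (one record per animal).
#' @param genotypes a [GenotypeMatrix-class] (post QC) for the GRM.
#' @param counts a [CountTable-class] with all features.
#' @param biomarkers optional character vector of selected feature ids.
#' @param config an [mcmcConfig()].
#' @return data.frame with one row per (otu_set, kernel) combination:
#'   posterior means and SDs of h2 and m2.
#' @export
varianceReport <- function(y, genotypes, counts, biomarkers = NULL,
                           config = mcmcConfig()) {
  G <- grmVanRaden(genotypes)
  sets <- list(whole = counts)
  if (!is.null(biomarkers))
    sets$selected <- counts[rownames(counts) %in% biomarkers, ]
  rows <- list()
  for (sn in names(sets)) {
    for (kn in c("bray", "ross")) {
      B <- if (kn == "bray") mrmBray(sets[[sn]]) else mrmRoss(sets[[sn]])
      fit <- gibbsTwoKernel(y, G, B, config)
      s <- fit@summary
      rows[[paste(sn, kn)]] <- data.frame(
        otu_set = sn, kernel = kn,
        h2 = s$mean[s$parameter == "h2"], h2_sd = s$sd[s$parameter == "h2"],
        m2 = s$mean[s$parameter == "m2"], m2_sd = s$sd[s$parameter == "m2"])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
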