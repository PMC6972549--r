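test_that("VanRaden GRM: hand example, duplicates, HWE expectation", {
  # 2 animals, 1 SNP, dosages (0, 2), p = 0.5 -> G = [[2,-2],[-2,2]]
  g <- GenotypeMatrix(matrix(c(0, 2), 1, 2,
                             dimnames = list("s1", c("a1", "a2"))))
  G <- as.matrix(grmVanRaden(g))
  expect_equal(unname(G), matrix(c(2, -2, -2, 2), 2))

  # duplicated animal: off-diagonal equals both diagonals
  set.seed(107)
  d <- matrix(rbinom(200 * 3, 2, 0.3), 200, 3)
  d[, 3] <- d[, 1]
  colnames(d) <- paste0("a", 1:3); rownames(d) <- paste0("s", 1:200)
  G2 <- as.matrix(grmVanRaden(GenotypeMatrix(d)))
  expect_equal(G2[1, 3], G2[1, 1])
  expect_equal(G2[1, 3], G2[3, 3])

  # under HWE the mean diagonal is ~1
  set.seed(109)
  p <- runif(5000, 0.05, 0.5)
  dd <- matrix(rbinom(5000 * 200, 2, rep(p, 200)), 5000, 200)
  rownames(dd) <- paste0("s", 1:5000); colnames(dd) <- paste0("a", 1:200)
  G3 <- as.matrix(grmVanRaden(GenotypeMatrix(dd)))
  expect_equal(mean(diag(G3)), 1, tolerance = 0.05)

  # missing dosages are imputed to 2p before centring
  dm <- matrix(c(0, 2, NA, 1, 1, 2), 2, 3, byrow = TRUE,
               dimnames = list(c("s1", "s2"), paste0("a", 1:3)))
  expect_silent(grmVanRaden(GenotypeMatrix(dm)))
})

test_that("Bray-Curtis microbial kernel is a PSD similarity", {
  m <- cbind(a = c(5, 5, 0, 0), b = c(5, 5, 0, 0), c = c(0, 0, 3, 7))
  rownames(m) <- paste0("OTU", 1:4)
  B <- mrmBray(makeCounts(m))
  bm <- as.matrix(B)
  expect_equal(bm["a", "b"], 1)       # identical samples
  expect_equal(bm["a", "c"], 0)       # disjoint communities
  set.seed(113)
  m2 <- matrix(rpois(40 * 25, 3), 40, 25)
  m2[, colSums(m2) == 0] <- 1
  B2 <- mrmBray(makeCounts(m2))
  ev <- eigen(as.matrix(B2), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  if (B2@psdRepaired) expect_gt(attr(B2, "repairDelta"), 0)
})

test_that("log-standardized kernel: trace identity and degeneracies", {
  set.seed(127)
  n <- 12
  m <- matrix(rpois(30 * n, 6), 30, n)
  m <- m[apply(m, 1, sd) > 0, ]
  rownames(m) <- paste0("OTU", seq_len(nrow(m)))
  colnames(m) <- paste0("S", 1:n)
  B <- as.matrix(mrmRoss(makeCounts(m)))
  # (n-1)-denominator standardization makes the mean diagonal (n-1)/n
  expect_equal(mean(diag(B)), (n - 1) / n, tolerance = 1e-12)

  # identical samples give identical kernel rows
  m2 <- cbind(m[, 1], m[, 1], m[, 2:5])
  colnames(m2) <- paste0("S", 1:6)
  B2 <- as.matrix(mrmRoss(makeCounts(m2)))
  expect_equal(B2[1, ], B2[2, ], ignore_attr = TRUE)

  # constant features are dropped with a warning
  m3 <- rbind(m[1:5, 1:6], const = 4)
  expect_warning(mrmRoss(makeCounts(m3)), "constant")
})

test_that("two-kernel Gibbs matches a grid-scan posterior on tiny data", {
  # with B = 0 the model reduces to y = mu + g + e; compare the sampler's
  # (sigma_g2, sigma_e2) posterior means with deterministic numerical
  # integration of the same posterior (flat mu integrated analytically)
  set.seed(131)
  n <- 6
  x <- matrix(rbinom(40 * n, 2, 0.4), 40, n)
  G <- as.matrix(grmVanRaden(GenotypeMatrix(
    matrix(x, 40, n, dimnames = list(paste0("s", 1:40), paste0("a", 1:n))))))
  G <- G + diag(1e-6, n)
  y <- c(1.2, -0.5, 0.3, 2.0, -1.1, 0.4)
  df0 <- 5
  s0g <- var(y) / 4 * (df0 - 2) / df0   # kernel-variance prior scale
  s0e <- var(y) / 2 * (df0 - 2) / df0   # residual prior scale

  logPost <- function(sg2, se2) {
    V <- sg2 * G + se2 * diag(n)
    Vi <- solve(V)
    o <- rep(1, n)
    denom <- drop(t(o) %*% Vi %*% o)
    muHat <- drop(t(o) %*% Vi %*% y) / denom
    r <- y - muHat
    ll <- -0.5 * determinant(V)$modulus - 0.5 * log(denom) -
      0.5 * drop(t(r) %*% Vi %*% r)
    lp <- function(s2, S0) -(df0 / 2 + 1) * log(s2) - df0 * S0 / (2 * s2)
    as.numeric(ll + lp(sg2, s0g) + lp(se2, s0e))
  }
  grid <- exp(seq(log(0.005), log(30), length.out = 90))
  lp <- outer(grid, grid, Vectorize(logPost))
  w <- exp(lp - max(lp)) * outer(grid, grid)   # log-spaced quadrature weight
  w <- w / sum(w)
  oracleG <- sum(rowSums(w) * grid)
  oracleE <- sum(colSums(w) * grid)

  fit <- gibbsTwoKernel(y, G, matrix(0, n, n),
                        mcmcConfig(nIter = 60000, burnIn = 5000, seed = 17))
  tab <- posteriorTable(fit)
  expect_equal(tab$mean[tab$parameter == "sigma_g2"], oracleG,
               tolerance = 0.12)
  expect_equal(tab$mean[tab$parameter == "sigma_e2"], oracleE,
               tolerance = 0.12)
})

test_that("sampler guards and chain stationarity", {
  set.seed(137)
  n <- 80
  G <- diag(n); B <- diag(n)
  y <- rnorm(n)
  expect_error(gibbsTwoKernel(rep(1, n), G, B), "zero-variance")
  expect_error(gibbsTwoKernel(y, G - 0.5, B), "positive semi-definite")

  fit <- gibbsTwoKernel(y, G, B, mcmcConfig(nIter = 6000, burnIn = 1000,
                                            seed = 19))
  ch <- fit@chains[, "sigma_e2"]
  half <- length(ch) %/% 2
  m1 <- mean(ch[1:half]); m2 <- mean(ch[(half + 1):length(ch)])
  ess <- function(v) length(v) / (1 + 2 * sum(acf(v, plot = FALSE,
                                                  lag.max = 50)$acf[-1]))
  se <- sd(ch) * sqrt(1 / ess(ch[1:half]) + 1 / ess(ch[(half + 1):length(ch)]))
  expect_lt(abs(m1 - m2), 2.5 * se)

  # h2/m2 summaries respect their bounds
  tab <- posteriorTable(fit)
  h2 <- tab$mean[tab$parameter == "h2"]
  m2v <- tab$mean[tab$parameter == "m2"]
  expect_true(h2 >= 0 && m2v >= 0 && h2 + m2v <= 1)
})

test_that("pure-noise phenotype concentrates h2 near zero", {
  n <- 300
  cfg <- scenarioConfig(nSamples = n, nOtus = 150, nGenera = 30, nSnps = 150,
                        seed = 23)
  G <- grmVanRaden(generateGenotypes(cfg))
  com <- generateCommunity(cfg)
  B <- mrmRoss(com$counts)
  h2s <- sapply(1:10, function(s) {
    set.seed(s)
    y <- rnorm(n)
    fit <- gibbsTwoKernel(y, G, B, mcmcConfig(nIter = 6000, burnIn = 1000,
                                              seed = s))
    tab <- posteriorTable(fit)
    tab$mean[tab$parameter == "h2"]
  })
  expect_lte(mean(h2s), 0.10)
})

test_that("variance report covers kernel constructions and OTU subsets", {
  cfg <- smallScenario(seed = 29)
  st <- simulateStudy(cfg)
  pheno <- preparePhenotypes(st$phenotypes)
  y <- perAnimalTrait(pheno, "adj_CH4y")[colnames(otuCounts(st$counts))]
  qc <- genotypeQC(st$genotypes)
  rep <- varianceReport(y, qc, st$counts,
                        biomarkers = st$truth$causal_otus,
                        config = mcmcConfig(nIter = 1500, burnIn = 300,
                                            seed = 31))
  expect_equal(nrow(rep), 4L)
  expect_setequal(rep$kernel, c("bray", "ross"))
  expect_setequal(rep$otu_set, c("whole", "selected"))
  expect_true(all(rep$h2 >= 0 & rep$h2 <= 1))
  expect_true(all(rep$m2 >= 0 & rep$m2 <= 1))
  # deterministic under the same config
  rep2 <- varianceReport(y, qc, st$counts,
                         biomarkers = st$truth$causal_otus,
                         config = mcmcConfig(nIter = 1500, burnIn = 300,
                                             seed = 31))
  expect_equal(rep, rep2)
})
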