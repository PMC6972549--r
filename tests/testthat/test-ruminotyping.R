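test_that("sqrt-JSD distance: identities and metric property", {
  p <- cbind(a = c(0.2, 0.3, 0.5), b = c(0.2, 0.3, 0.5))
  expect_equal(as.matrix(jsdDistance(p))["a", "b"], 0, tolerance = 1e-6)

  # disjoint supports: JSD = ln 2, distance = sqrt(ln 2)
  q <- cbind(a = c(1, 0), b = c(0, 1))
  expect_equal(as.matrix(jsdDistance(q))[1, 2], sqrt(log(2)),
               tolerance = 1e-4)

  # raw-JSD flag
  expect_equal(as.matrix(jsdDistance(q, sqrt = FALSE))[1, 2], log(2),
               tolerance = 1e-4)

  # symmetry and triangle inequality on random compositions
  set.seed(29)
  m <- matrix(rgamma(5 * 60, 1), 5, 60)
  m <- sweep(m, 2, colSums(m), "/")
  d <- as.matrix(jsdDistance(m))
  expect_equal(d, t(d))
  for (i in 1:300) {
    tri <- sample(60, 3)
    expect_lte(d[tri[1], tri[2]],
               d[tri[1], tri[3]] + d[tri[3], tri[2]] + 1e-12)
  }
})

test_that("PAM recovers separated blobs and respects k bounds", {
  d <- blobDistance(10, 10, sep = 20, seed = 1)
  sol <- pamCluster(d, 2)
  expect_equal(ari(clusterLabels(sol), rep(1:2, each = 10)), 1)
  expect_error(pamCluster(d, 1), "k must")
  expect_error(pamCluster(d, 20), "k must")

  # k = n - 1: exactly one pair shares a medoid; cost is that pair's distance
  set.seed(2)
  x <- matrix(rnorm(10), 5, 2)
  dm <- as.matrix(dist(x))
  sol2 <- pamCluster(DistanceMatrix(dm), 4)
  expect_equal(sol2@cost, min(dm[upper.tri(dm)]))

  # SWAP never increases the cost
  d3 <- blobDistance(12, 12, sep = 2, seed = 3)
  trace <- attr(pamCluster(d3, 3), "costTrace")
  expect_true(all(diff(trace) <= 1e-12))
})

test_that("PAM matches the exhaustive-medoid optimum on small instances", {
  set.seed(31)
  optimal <- 0L
  for (i in 1:100) {
    n <- sample(5:8, 1)
    k <- sample(2:3, 1)
    x <- matrix(rnorm(n * 2), n)
    dm <- as.matrix(dist(x))
    sol <- pamCluster(DistanceMatrix(dm), k)
    best <- min(apply(combn(n, k), 2, function(meds)
      sum(do.call(pmin, lapply(meds, function(m) dm[, m])))))
    expect_lte(sol@cost, 1.05 * best)
    if (sol@cost <= best + 1e-12) optimal <- optimal + 1L
  }
  expect_gte(optimal, 95L)
})

test_that("CH index agrees with the direct computation on Euclidean data", {
  set.seed(37)
  x <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20) + 4, 10))
  labels <- rep(1:2, each = 10)
  d <- DistanceMatrix(as.matrix(dist(x)))
  # oracle: between/within sums of squares on the raw coordinates
  n <- nrow(x); k <- 2
  centroid <- colMeans(x)
  W <- sum(sapply(1:2, function(g)
    sum(sweep(x[labels == g, ], 2, colMeans(x[labels == g, ]))^2)))
  B <- sum(sapply(1:2, function(g)
    nrow(x[labels == g, ]) * sum((colMeans(x[labels == g, ]) - centroid)^2)))
  oracle <- (B / (k - 1)) / (W / (n - k))
  expect_equal(chIndex(d, labels), oracle, tolerance = 1e-8)
  expect_equal(chIndex(d, labels, embed = "distance"), oracle,
               tolerance = 1e-8)
  expect_error(chIndex(d, rep(1, 20)), "2 <= k")
})

test_that("silhouette widths: hand case, blobs, degenerate input", {
  # 4 points on a line: 0, 1, 10, 11 in clusters {1,2},{3,4}
  dm <- as.matrix(dist(c(0, 1, 10, 11)))
  s <- silhouetteWidths(DistanceMatrix(dm), c(1, 1, 2, 2))
  # point 1: a = 1, b = mean(10, 11) = 10.5 -> s = 9.5/10.5
  expect_equal(unname(s$widths[1]), 9.5 / 10.5)
  expect_equal(s$mean, mean(c(9.5 / 10.5, 8.5 / 9.5, 8.5 / 9.5, 9.5 / 10.5)))
  expect_error(silhouetteWidths(DistanceMatrix(dm), rep(1, 4)), ">= 2")

  d <- blobDistance(10, 10, sep = 50, seed = 5)
  expect_gt(silhouetteWidths(d, rep(1:2, each = 10))$mean, 0.95)

  # singleton cluster contributes width 0
  s2 <- silhouetteWidths(DistanceMatrix(dm), c(1, 2, 3, 3))
  expect_equal(unname(s2$widths[1]), 0)
})

test_that("model selection picks three blobs and handles edge ranges", {
  set.seed(41)
  x <- rbind(matrix(rnorm(24), 12), matrix(rnorm(20) + 8, 10),
             cbind(rnorm(11), rnorm(11) + 8))
  d <- DistanceMatrix(as.matrix(dist(x)))
  sel <- selectK(d, 2:6)
  expect_equal(sel$chosenK, 3L)
  expect_equal(ari(clusterLabels(sel$solution), rep(1:3, c(12, 10, 11))), 1)
  # singleton range returns that k
  expect_equal(selectK(d, 4)$chosenK, 4L)
})

test_that("Jaccard bootstrap separates stable from forced clusters", {
  d <- blobDistance(15, 15, sep = 30, seed = 7)
  stable <- jaccardBootstrap(d, 2, nBoot = 20, seed = 1)
  expect_true(all(stable$clusterJaccard >= 0.85))
  expect_true(all(stable$clusterJaccard <= 1))

  # one homogeneous cloud forced to k = 3: moderate-at-best stability
  set.seed(8)
  cloud <- DistanceMatrix(as.matrix(dist(matrix(rnorm(120), 60))))
  forced <- jaccardBootstrap(cloud, 3, nBoot = 20, seed = 2)
  expect_lte(mean(forced$clusterJaccard), 0.75)

  # reproducible under seed
  again <- jaccardBootstrap(d, 2, nBoot = 20, seed = 1)
  expect_identical(stable$clusterJaccard, again$clusterJaccard)
})

test_that("cluster-phenotype contrasts reduce to the pooled t-test for k=2", {
  set.seed(43)
  y <- c(rnorm(12), rnorm(10) + 1)
  lab <- rep(1:2, c(12, 10))
  res <- clusterPhenotypeAssoc(lab, y)
  expect_equal(res$contrasts$p.value,
               t.test(y ~ lab, var.equal = TRUE)$p.value, tolerance = 1e-12)

  # equal means rarely flagged after Tukey adjustment
  set.seed(44)
  flags <- sapply(1:60, function(i) {
    y0 <- rnorm(45)
    any(clusterPhenotypeAssoc(rep(1:3, each = 15), y0)$contrasts$p.value < 0.05)
  })
  expect_lte(mean(flags), 0.12)

  # +2 shift on one of three clusters at n = 65, sd = 1 is detected
  lab3 <- rep(1:3, c(30, 16, 19))
  set.seed(45)
  y3 <- rnorm(65) + ifelse(lab3 == 2, 2, 0)
  ctr <- clusterPhenotypeAssoc(lab3, y3)$contrasts
  hit <- grepl("R2", ctr$contrast)
  expect_true(all(ctr$p.value[hit] < 0.05))
})
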