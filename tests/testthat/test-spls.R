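test_that("dense sPLS equals classic PLS and PCA special cases", {
  set.seed(73)
  X <- matrix(rnorm(30 * 8), 30, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- X[, 1] - 2 * X[, 5] + rnorm(30, 0, 0.3)

  # keepX = p: first weight equals the dominant singular vector of X'y
  fit <- splsFit(X, y, ncomp = 2, keepX = 8)
  Xs <- scale(X); ys <- scale(y)
  u <- drop(crossprod(Xs, ys))
  u <- u / sqrt(sum(u^2))
  expect_equal(abs(fit@weights[, 1]), abs(u), tolerance = 1e-8)

  # successive scores orthogonal
  expect_lt(abs(cor(fit@scores[, 1], fit@scores[, 2])), 1e-8)

  # Y = X with dense keepX reproduces PCA loadings up to sign
  fitP <- splsFit(X, X, ncomp = 2, keepX = 8)
  pc <- prcomp(scale(X))$rotation[, 1:2]
  for (h in 1:2)
    expect_equal(abs(fitP@weights[, h]), abs(pc[, h]), tolerance = 1e-6)
})

test_that("1-sparse component selects the max-covariance feature", {
  set.seed(79)
  X <- matrix(rnorm(40 * 10), 40, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- X[, 4] + rnorm(40, 0, 0.1)
  fit <- splsFit(X, y, ncomp = 1, keepX = 1)
  sel <- selectedFeatures(fit)
  covs <- abs(cov(scale(X), scale(y)))
  expect_equal(sel$feature_id, rownames(covs)[which.max(covs)])
  expect_error(splsFit(X, y, keepX = 11), "keepX exceeds")
  expect_error(splsFit(X, y, ncomp = 50), "ncomp exceeds")
})

test_that("sparse weights respect keepX and stay unit-norm", {
  set.seed(83)
  X <- matrix(rnorm(50 * 60), 50, 60)
  y <- rnorm(50)
  fit <- splsFit(X, y, ncomp = 3, keepX = c(10, 5, 2))
  nz <- colSums(fit@weights != 0)
  expect_true(all(nz <= c(10, 5, 2)))
  expect_equal(unname(sqrt(colSums(fit@weights^2))), rep(1, 3))
})

test_that("sPLS-DA separates classes and predicts with max.dist", {
  set.seed(89)
  n <- 60
  lab <- factor(rep(c("R1", "R2", "R3"), each = 20))
  X <- matrix(rnorm(n * 30), n, 30)
  X[lab == "R2", 1:5] <- X[lab == "R2", 1:5] + 3
  X[lab == "R3", 6:10] <- X[lab == "R3", 6:10] + 3
  fit <- splsdaFit(X, lab, ncomp = 2, keepX = c(10, 10))
  pred <- predict(fit, X)
  expect_equal(mean(pred != lab), 0)

  # single-sample prediction works and is deterministic
  p1 <- predict(fit, X[1, ])
  expect_equal(as.character(p1), "R1")
  expect_identical(predict(fit, X), pred)

  # permuted labels destroy the separation
  set.seed(90)
  perm <- sample(lab)
  fitPerm <- splsdaFit(X, perm, ncomp = 2, keepX = c(10, 10))
  cvPerm <- tuneCv(X, perm, ncomp = 2, keepXGrid = list(c(10, 10)),
                   folds = 5, repeats = 2, seed = 4)
  expect_gt(cvPerm$table$BER, 0.4)
})

test_that("sPLS-DA first component agrees with mixOmics on a fixture", {
  skip_if_not_installed("mixOmics")
  set.seed(97)
  n <- 45
  lab <- factor(rep(c("a", "b", "c"), each = 15))
  X <- matrix(rnorm(n * 25), n, 25, dimnames = list(NULL, paste0("f", 1:25)))
  X[lab == "b", 1:4] <- X[lab == "b", 1:4] + 2.5
  X[lab == "c", 5:8] <- X[lab == "c", 5:8] + 2.5
  fit <- splsdaFit(X, lab, ncomp = 2, keepX = c(6, 6))
  ref <- mixOmics::splsda(X, lab, ncomp = 2, keepX = c(6, 6))
  refSel <- rownames(ref$loadings$X)[ref$loadings$X[, 1] != 0]
  ownSel <- rownames(fit@weights)[fit@weights[, 1] != 0]
  expect_setequal(ownSel, refSel)
  # loading values agree up to sign on the shared support
  ownW <- fit@weights[refSel, 1]
  refW <- ref$loadings$X[refSel, 1]
  s <- sign(sum(ownW * refW))
  expect_equal(unname(ownW), s * unname(refW), tolerance = 1e-4)
})

test_that("cross-validation: Q2, BER at chance, reproducibility", {
  set.seed(101)
  n <- 100
  X <- matrix(rnorm(n * 5), n, 5)
  y <- 3 * X[, 2] + rnorm(n, 0, 0.05)     # nearly noiseless single predictor
  cv <- tuneCv(X, y, ncomp = 2, folds = 5, repeats = 3, seed = 7)
  expect_gte(cv$q2[1], 0.9)
  expect_gte(cv$ncompRetained, 1L)

  # permuted labels in 3 balanced classes: BER at chance (K-1)/K
  set.seed(102)
  lab <- factor(rep(c("a", "b", "c"), each = 20))
  Xr <- matrix(rnorm(60 * 15), 60, 15)
  cvDa <- tuneCv(Xr, lab, ncomp = 2, keepXGrid = list(c(5, 5)),
                 folds = 5, repeats = 10, seed = 9)
  expect_lt(abs(cvDa$table$BER - 2 / 3), 0.05)

  # fixed seed reproduces
  cvDa2 <- tuneCv(Xr, lab, ncomp = 2, keepXGrid = list(c(5, 5)),
                  folds = 5, repeats = 2, seed = 11)
  cvDa3 <- tuneCv(Xr, lab, ncomp = 2, keepXGrid = list(c(5, 5)),
                  folds = 5, repeats = 2, seed = 11)
  expect_identical(cvDa2$table, cvDa3$table)

  # BER invariant to class relabeling
  lab2 <- factor(c(a = "z", b = "y", c = "x")[as.character(lab)])
  cvDa4 <- tuneCv(Xr, lab2, ncomp = 2, keepXGrid = list(c(5, 5)),
                  folds = 5, repeats = 2, seed = 11)
  expect_equal(cvDa4$table$BER, cvDa2$table$BER, tolerance = 1e-12)

  expect_error(tuneCv(Xr[1:21, ], factor(c(rep("a", 20), "b")), ncomp = 1,
                      folds = 5, repeats = 1, seed = 1), "fewer than 2")
})

test_that("AUROC: rank formulation with midranks", {
  expect_equal(rankAuc(c(1, 2, 2, 3), c(FALSE, FALSE, TRUE, TRUE)), 0.875)
  expect_equal(rankAuc(c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE)), 1)
  set.seed(103)
  auc <- replicate(400, rankAuc(rnorm(40), rep(c(TRUE, FALSE), 20)))
  expect_lt(abs(mean(auc) - 0.5), 0.05)

  # model-level AUCs near 1 for separable classes
  lab <- factor(rep(c("p", "q"), each = 20))
  X <- matrix(rnorm(40 * 10), 40, 10)
  X[lab == "q", 1:3] <- X[lab == "q", 1:3] + 4
  fit <- splsdaFit(X, lab, ncomp = 1, keepX = 5)
  expect_warning(a <- aurocScores(fit, X, lab), "resubstitution")
  expect_true(all(a > 0.95))
})

test_that("biomarker intersection carries provenance and ordering", {
  da <- data.frame(feature_id = c("f1", "f2", "f3"), component = 1,
                   weight = c(0.9, -0.5, 0.1))
  reg <- data.frame(feature_id = c("f2", "f4"), component = 1,
                    weight = c(0.7, 0.2))
  out <- intersectBiomarkers(da, reg)
  expect_equal(out$feature_id[out$source == "common"], "f2")
  expect_setequal(out$feature_id[out$source == "da_only"], c("f1", "f3"))
  expect_equal(out$feature_id[out$source == "reg_only"], "f4")

  # identical sets: all common; disjoint: none
  expect_true(all(intersectBiomarkers(da, da)$source == "common"))
  expect_true(!any(intersectBiomarkers(da, reg[2, ])$source == "common"))
})
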