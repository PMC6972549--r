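## Sparse partial least squares: regression and discriminant modes,
## cross-validated tuning (Q2 / BER), max.dist prediction, AUROC, and the
## two-approach biomarker intersection.

.asSamplesByFeatures <- function(x) {
  if (is(x, "AbundanceTable")) t(abundanceValues(x))
  else if (is(x, "CountTable")) t(otuCounts(x))
  else as.matrix(x)
}

#' Fit a sparse PLS model
#'
#' Per component, the dominant singular pair of `X'Y` is computed by power
#' iteration; the X weight vector is soft-thresholded so that at most
#' `keepX[h]` entries stay nonzero, then renormalized to unit length.
#' Scores are `t = X w`; X and Y are deflated by regression on the score
#' (regression-mode deflation for both blocks). Columns of X and Y are
#' centred and scaled internally.
#'
#' @param x samples x features matrix (or an [AbundanceTable-class],
#'   typically CLR-transformed, which is transposed internally).
#' @param y numeric response vector or samples x q matrix.
#' @param ncomp number of components.
#' @param keepX number of X variables to retain per component (recycled to
#'   `ncomp`); `keepX = ncol(x)` gives dense PLS.
#' @param maxIter,tol power-iteration controls.
#' @return An [SplsModel-class] with `mode = "regression"`.
#' @export
splsFit <- function(x, y, ncomp = 1, keepX = NULL, maxIter = 500,
                    tol = 1e-9) {
  X <- .asSamplesByFeatures(x)
  Y <- as.matrix(y)
  .splsCore(X, Y, ncomp, keepX, mode = "regression",
            ylevels = colnames(Y) %||% paste0("Y", seq_len(ncol(Y))),
            maxIter = maxIter, tol = tol)
}

#' Fit a sparse PLS discriminant model
#'
#' The class factor is expanded to a one-hot indicator matrix and fitted
#' with [splsFit()]'s machinery (regression-mode deflation, the mixOmics
#' convention); prediction uses the maximum-distance rule.
#'
#' @param x samples x features matrix or [AbundanceTable-class].
#' @param labels class factor (ruminotype cluster per sample).
#' @inheritParams splsFit
#' @return An [SplsModel-class] with `mode = "da"`.
#' @export
splsdaFit <- function(x, labels, ncomp = 2, keepX = NULL, maxIter = 500,
                      tol = 1e-9) {
  X <- .asSamplesByFeatures(x)
  labels <- factor(labels)
  Y <- stats::model.matrix(~ 0 + labels)
  colnames(Y) <- levels(labels)
  .splsCore(X, Y, ncomp, keepX, mode = "da", ylevels = levels(labels),
            maxIter = maxIter, tol = tol)
}

.splsCore <- function(X, Y, ncomp, keepX, mode, ylevels, maxIter = 500,
                      tol = 1e-9) {
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (is.null(keepX)) keepX <- p
  keepX <- as.integer(rep_len(keepX, ncomp))
  if (any(keepX > p)) stop("keepX exceeds the number of features")
  if (any(keepX < 1L)) stop("keepX must be >= 1")
  ncomp <- as.integer(ncomp)
  if (ncomp > min(n - 1L, p)) stop("ncomp exceeds the rank of X")
  xc <- colMeans(X); xs <- apply(X, 2L, sd); xs[xs == 0] <- 1
  yc <- colMeans(Y); ys <- apply(Y, 2L, sd); ys[ys == 0] <- 1
  Xh <- scale(X, xc, xs); Yh <- scale(Y, yc, ys)
  W <- matrix(0, p, ncomp, dimnames = list(colnames(X), NULL))
  Cl <- matrix(0, p, ncomp, dimnames = list(colnames(X), NULL))
  D <- matrix(0, q, ncomp, dimnames = list(colnames(Y), NULL))
  Tm <- matrix(0, n, ncomp, dimnames = list(rownames(X), NULL))
  for (h in seq_len(ncomp)) {
    M <- crossprod(Xh, Yh)                      # p x q
    v <- svd(crossprod(M), nu = 0, nv = 1)$v[, 1L]
    u <- .sparseNormalize(drop(M %*% v), keepX[h])
    for (it in seq_len(maxIter)) {
      vNew <- drop(crossprod(M, u))
      vNew <- vNew / max(sqrt(sum(vNew^2)), 1e-300)
      uNew <- .sparseNormalize(drop(M %*% vNew), keepX[h])
      if (sum((uNew - u)^2) < tol) { u <- uNew; v <- vNew; break }
      u <- uNew; v <- vNew
    }
    tScore <- drop(Xh %*% u)
    tt <- sum(tScore^2)
    if (tt < 1e-12) stop("degenerate component ", h, ": zero score variance")
    cl <- drop(crossprod(Xh, tScore)) / tt
    dl <- drop(crossprod(Yh, tScore)) / tt
    Xh <- Xh - tcrossprod(tScore, cl)
    Yh <- Yh - tcrossprod(tScore, dl)
    W[, h] <- u; Cl[, h] <- cl; D[, h] <- dl; Tm[, h] <- tScore
  }
  new("SplsModel", mode = mode, ncomp = ncomp, keepX = keepX, weights = W,
      xLoadings = Cl, yWeights = D, scores = Tm, xCenter = xc, xScale = xs,
      yCenter = yc, yScale = ys, ylevels = ylevels)
}

# hard cardinality with soft-threshold shrinkage, then unit-normalize
.sparseNormalize <- function(u, keep) {
  if (keep < length(u)) {
    thr <- sort(abs(u), decreasing = TRUE)[keep + 1L]
    u <- sign(u) * pmax(abs(u) - thr, 0)
  }
  nrm <- sqrt(sum(u^2))
  if (nrm < 1e-300) {                    # all-tied degenerate case: keep top
    idx <- order(abs(u), decreasing = TRUE)[seq_len(keep)]
    u[] <- 0; u[idx] <- 1
    nrm <- sqrt(sum(u^2))
  }
  u / nrm
}

#' Predict from a sparse PLS model
#'
#' Regression mode returns fitted responses on the original Y scale;
#' discriminant mode returns the class whose predicted indicator value is
#' maximal (max.dist rule). Class scores are available via
#' `type = "scores"`.
#'
#' @param object an [SplsModel-class].
#' @param newdata samples x features matrix (a single sample may be given
#'   as a vector); features must match the training features.
#' @param ncomp number of components to use (default: all fitted).
#' @param type `"response"` (default; fitted Y or class labels) or
#'   `"scores"` (predicted indicator values, da mode).
#' @param ... unused.
#' @return Predicted matrix, factor of class labels, or score matrix.
#' @export
setMethod("predict", "SplsModel",
function(object, newdata, ncomp = NULL, type = c("response", "scores"), ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  Xs <- scale(.asSamplesByFeatures(newdata), object@xCenter, object@xScale)
  h <- if (is.null(ncomp)) object@ncomp else as.integer(ncomp)
  W <- object@weights[, seq_len(h), drop = FALSE]
  Cl <- object@xLoadings[, seq_len(h), drop = FALSE]
  D <- object@yWeights[, seq_len(h), drop = FALSE]
  Wstar <- W %*% solve(crossprod(Cl, W))
  predScaled <- Xs %*% Wstar %*% t(D)
  pred <- sweep(sweep(predScaled, 2L, object@yScale, "*"), 2L,
                object@yCenter, "+")
  colnames(pred) <- object@ylevels
  if (object@mode == "da" && type == "response") {
    factor(object@ylevels[max.col(pred, ties.method = "first")],
           levels = object@ylevels)
  } else pred
})

#' Cross-validated tuning of a sparse PLS model
#'
#' Discriminant mode: stratified k-fold cross-validation repeated
#' `repeats` times; reports the overall misclassification error rate and
#' the balanced error rate (BER, the mean of per-class error rates) for
#' every `keepX` configuration in the grid, choosing the BER-minimizing
#' one. Regression mode: plain folds; per-component predictive relevance
#' `Q2_h = 1 - PRESS_h / RSS_(h-1)`, components retained while
#' `Q2_h >= 0.0975`.
#'
#' @param x samples x features matrix or [AbundanceTable-class].
#' @param outcome class factor (da) or numeric response (regression).
#' @param ncomp components to evaluate.
#' @param keepXGrid list of keepX vectors to compare (da mode); a single
#'   vector evaluates one configuration.
#' @param folds number of folds (default 5).
#' @param repeats number of repetitions (default 50; the full protocol
#'   uses 500).
#' @param seed RNG seed for fold assignment.
#' @return Regression: list with `q2` (per-component), `ncompRetained`.
#'   DA: list with `table` (keepX, error rate, BER), `best` (chosen
#'   configuration), `folds`, `repeats`, `seed`.
#' @export
tuneCv <- function(x, outcome, ncomp = 2, keepXGrid = NULL, folds = 5,
                   repeats = 50, seed = 1L) {
  X <- .asSamplesByFeatures(x)
  if (is.factor(outcome) || is.character(outcome)) {
    .tuneCvDa(X, factor(outcome), ncomp, keepXGrid, folds, repeats, seed)
  } else {
    .tuneCvReg(X, as.numeric(outcome), ncomp, keepXGrid, folds, repeats, seed)
  }
}

.stratifiedFolds <- function(labels, folds) {
  idx <- integer(length(labels))
  # canonical group order by first occurrence, so the fold layout (and BER)
  # is invariant to relabeling the classes
  ord <- levels(labels)[order(match(levels(labels), as.character(labels)))]
  for (lv in ord) {
    i <- which(labels == lv)
    if (length(i) < 2L)
      stop("class ", lv, " has fewer than 2 members: cannot stratify folds")
    idx[i] <- sample(rep_len(seq_len(folds), length(i)))
  }
  idx
}

.tuneCvDa <- function(X, labels, ncomp, keepXGrid, folds, repeats, seed) {
  if (is.null(keepXGrid)) keepXGrid <- list(rep(ncol(X), ncomp))
  if (!is.list(keepXGrid)) keepXGrid <- list(keepXGrid)
  set.seed(seed)
  K <- nlevels(labels)
  res <- lapply(keepXGrid, function(kx) {
    err <- ber <- numeric(repeats)
    for (r in seq_len(repeats)) {
      fid <- .stratifiedFolds(labels, folds)
      predAll <- factor(rep(NA, length(labels)), levels = levels(labels))
      for (f in seq_len(folds)) {
        tr <- fid != f
        if (!any(!tr)) next
        fit <- splsdaFit(X[tr, , drop = FALSE], labels[tr], ncomp = ncomp,
                         keepX = kx)
        predAll[!tr] <- predict(fit, X[!tr, , drop = FALSE])
      }
      err[r] <- mean(predAll != labels, na.rm = TRUE)
      perClass <- vapply(levels(labels), function(lv)
        mean(predAll[labels == lv] != lv, na.rm = TRUE), numeric(1L))
      ber[r] <- mean(perClass)
    }
    c(error = mean(err), BER = mean(ber))
  })
  tab <- data.frame(keepX = vapply(keepXGrid, paste, character(1L),
                                   collapse = ","),
                    error = vapply(res, `[[`, numeric(1L), "error"),
                    BER = vapply(res, `[[`, numeric(1L), "BER"))
  list(mode = "da", table = tab, best = keepXGrid[[which.min(tab$BER)]],
       folds = folds, repeats = repeats, seed = seed)
}

.tuneCvReg <- function(X, y, ncomp, keepXGrid, folds, repeats, seed) {
  keepX <- if (is.null(keepXGrid)) rep(ncol(X), ncomp)
           else rep_len(unlist(keepXGrid[1L]), ncomp)
  set.seed(seed)
  press <- matrix(0, repeats, ncomp)
  for (r in seq_len(repeats)) {
    fid <- sample(rep_len(seq_len(folds), length(y)))
    for (f in seq_len(folds)) {
      tr <- fid != f
      fit <- splsFit(X[tr, , drop = FALSE], y[tr], ncomp = ncomp,
                     keepX = keepX)
      for (h in seq_len(ncomp)) {
        ph <- predict(fit, X[!tr, , drop = FALSE], ncomp = h)
        press[r, h] <- press[r, h] + sum((y[!tr] - drop(ph))^2)
      }
    }
  }
  pressMean <- colMeans(press)
  full <- splsFit(X, y, ncomp = ncomp, keepX = keepX)
  rss <- numeric(ncomp + 1L)
  rss[1L] <- sum((y - mean(y))^2)
  for (h in seq_len(ncomp))
    rss[h + 1L] <- sum((y - drop(predict(full, X, ncomp = h)))^2)
  q2 <- 1 - pressMean / rss[seq_len(ncomp)]
  retained <- 0L
  for (h in seq_len(ncomp)) {
    if (q2[h] >= 0.0975) retained <- h else break
  }
  list(mode = "regression", q2 = q2, ncompRetained = retained,
       folds = folds, repeats = repeats, seed = seed, keepX = keepX)
}

#' One-vs-rest AUROC of a discriminant model
#'
#' Per-class area under the ROC curve from predicted class scores, by the
#' rank (Mann-Whitney) formulation with midranks for ties. By default the
#' training scores are used (resubstitution), with a warning.
#'
#' @param model a fitted da-mode [SplsModel-class].
#' @param x samples x features matrix.
#' @param labels true class per sample.
#' @param warn warn that resubstitution AUC is optimistic (default TRUE).
#' @return named numeric vector of per-class AUCs.
#' @export
aurocScores <- function(model, x, labels, warn = TRUE) {
  if (model@mode != "da") stop("aurocScores needs a discriminant model")
  if (warn) warning("AUC computed from training scores (resubstitution)",
                    call. = FALSE)
  sc <- predict(model, x, type = "scores")
  labels <- factor(labels, levels = model@ylevels)
  vapply(model@ylevels, function(lv) {
    rankAuc(sc[, lv], labels == lv)
  }, numeric(1L))
}

#' Rank-based AUC
#'
#' Mann-Whitney AUC of `scores` for separating `positive` from the rest,
#' midranks for ties.
#'
#' @param scores numeric scores (higher = more positive).
#' @param positive logical vector.
#' @return AUC in `[0, 1]`.
#' @export
rankAuc <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) stop("need both positive and negative samples")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Features selected by a sparse PLS model
#'
#' @param model an [SplsModel-class].
#' @return data.frame: `feature_id`, `component` (first component where
#'   the feature has nonzero weight), `weight` (that weight).
#' @export
selectedFeatures <- function(model) {
  W <- model@weights
  sel <- which(rowSums(W != 0) > 0)
  comp <- apply(W[sel, , drop = FALSE] != 0, 1L, which.max)
  wt <- W[cbind(sel, comp)]
  out <- data.frame(feature_id = rownames(W)[sel], component = comp,
                    weight = wt, row.names = NULL)
  out[order(-abs(out$weight)), ]
}

#' Intersect discriminant and regression biomarker selections
#'
#' The conservative two-approach rule: a feature is a biomarker when both
#' the sPLS-DA and the sPLS regression model selected it. Every feature
#' selected by either model is returned with a provenance tag.
#'
#' @param selDa,selReg fitted [SplsModel-class] objects or data.frames as
#'   from [selectedFeatures()].
#' @return data.frame: `feature_id`, `source` (`common`, `da_only`,
#'   `reg_only`), `component`, `weight` (from the DA model when common),
#'   ordered by decreasing `abs(weight)` within source.
#' @export
intersectBiomarkers <- function(selDa, selReg) {
  if (is(selDa, "SplsModel")) selDa <- selectedFeatures(selDa)
  if (is(selReg, "SplsModel")) selReg <- selectedFeatures(selReg)
  common <- intersect(selDa$feature_id, selReg$feature_id)
  src <- function(df, keep, tag) {
    d <- df[df$feature_id %in% keep, ]
    if (nrow(d)) d$source <- tag
    d
  }
  out <- rbind(src(selDa, common, "common"),
               src(selDa, setdiff(selDa$feature_id, common), "da_only"),
               src(selReg, setdiff(selReg$feature_id, common), "reg_only"))
  out <- out[order(match(out$source, c("common", "da_only", "reg_only")),
                   -abs(out$weight)), ]
  rownames(out) <- NULL
  out[, c("feature_id", "source", "component", "weight")]
}
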