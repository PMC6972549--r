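## Alpha/beta diversity, dissimilarities, RV coefficient, PERMANOVA.

#' Shannon diversity (nats)
#'
#' `H = -sum p_i ln p_i` over a relative-abundance vector (zero entries
#' skipped), or per sample of a relative [AbundanceTable-class].
#'
#' @param p relative-abundance numeric vector summing to 1, or an
#'   [AbundanceTable-class] with `transform = "relative"`.
#' @return numeric scalar, or named vector per sample; natural-log base is
#'   recorded in the `"logbase"` attribute.
#' @export
shannonIndex <- function(p) {
  if (is(p, "AbundanceTable")) {
    if (p@transform != "relative") stop("shannonIndex needs relative abundances")
    h <- apply(abundanceValues(p), 2L, .shannon1)
  } else {
    if (abs(sum(p) - 1) > 1e-6) stop("abundance vector must sum to 1")
    h <- .shannon1(p)
  }
  attr(h, "logbase") <- exp(1)
  h
}

.shannon1 <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Whittaker beta diversity
#'
#' Classic multiplicative form `beta = gamma / alpha-bar - 1`, where gamma
#' is the pooled richness and alpha-bar the mean per-sample richness.
#'
#' @param x a [CountTable-class] or presence/abundance matrix
#'   (features x samples) for one group of samples.
#' @return numeric scalar (0 when all samples share one species list,
#'   `n - 1` when the lists of the n samples are disjoint).
#' @export
whittakerBeta <- function(x) {
  m <- if (is(x, "CountTable")) otuCounts(x) else
       if (is(x, "AbundanceTable")) abundanceValues(x) else as.matrix(x)
  pres <- m > 0
  gamma <- sum(rowSums(pres) > 0)
  alphaBar <- mean(colSums(pres))
  if (alphaBar == 0) stop("no species present")
  gamma / alphaBar - 1
}

.sampleMatrix <- function(x) {
  if (is(x, "CountTable")) t(otuCounts(x))
  else if (is(x, "AbundanceTable")) t(abundanceValues(x))
  else as.matrix(x)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(a, b) = sum |a_i - b_i| / sum (a_i + b_i)` between sample columns.
#'
#' @param x a [CountTable-class]/[AbundanceTable-class] (features x
#'   samples) or a samples x features matrix.
#' @return A [DistanceMatrix-class] with `metric = "bray_curtis"`.
#' @export
brayCurtis <- function(x) {
  s <- .sampleMatrix(x)
  d <- as.matrix(vegan::vegdist(s, method = "bray"))
  DistanceMatrix(d, metric = "bray_curtis")
}

#' Binary Jaccard dissimilarity matrix
#'
#' `d = 1 - |A intersect B| / |A union B|` on presence (count > 0) sets.
#'
#' @inheritParams brayCurtis
#' @return A [DistanceMatrix-class] with `metric = "jaccard_binary"`.
#' @export
jaccardBinary <- function(x) {
  s <- .sampleMatrix(x) > 0
  d <- as.matrix(vegan::vegdist(s, method = "jaccard", binary = TRUE))
  DistanceMatrix(d, metric = "jaccard_binary")
}

#' RV coefficient between two multivariate tables
#'
#' Matrix-level correlation on shared samples: with column-centred
#' samples x features matrices X and Y,
#' `RV = trace(XX'YY') / sqrt(trace((XX')^2) trace((YY')^2))`. Zero means
#' no shared co-structure; the coefficient approaches 1 as the two
#' configurations coincide.
#'
#' @param x,y samples x features matrices (or Count/Abundance tables) on
#'   the same samples, in the same order.
#' @return RV coefficient in `[0, 1]`.
#' @export
rvCoefficient <- function(x, y) {
  X <- .sampleMatrix(x); Y <- .sampleMatrix(y)
  if (nrow(X) != nrow(Y)) stop("x and y must share their samples")
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
      !identical(rownames(X), rownames(Y)))
    stop("x and y must share their samples (ids differ)")
  X <- scale(X, center = TRUE, scale = FALSE)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  Sx <- tcrossprod(X); Sy <- tcrossprod(Y)
  den <- sqrt(sum(Sx^2) * sum(Sy^2))
  if (den == 0) stop("zero matrix: RV undefined")
  sum(Sx * Sy) / den
}

#' PERMANOVA on a dissimilarity matrix
#'
#' Permutational multivariate ANOVA via the Gower-centred inner-product
#' decomposition with sequential (Type I) sums of squares: covariates are
#' fitted first, the grouping factor last, so the group test is corrected
#' for the covariates. `p = (1 + #(F_perm >= F_obs)) / (1 + nPerm)`.
#' Implemented through [vegan::adonis2()].
#'
#' @param d a [DistanceMatrix-class] (or square matrix).
#' @param groups grouping factor (>= 2 levels).
#' @param covariates optional data.frame of covariates fitted before
#'   `groups`.
#' @param nPerm number of permutations (default 999).
#' @param seed integer seed making the permutation p-value reproducible.
#' @return list with `F` (pseudo-F for `groups`), `p`, `R2` and the full
#'   `adonis2` table in `$table`.
#' @export
permanovaTest <- function(d, groups, covariates = NULL, nPerm = 999,
                          seed = 1L) {
  dm <- if (is(d, "DistanceMatrix")) as.matrix(d) else as.matrix(d)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("PERMANOVA needs >= 2 groups")
  dat <- data.frame(groups = groups)
  rhs <- "groups"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    dat <- cbind(covariates, dat)
    rhs <- paste(c(colnames(covariates), "groups"), collapse = " + ")
  }
  fm <- stats::as.formula(paste("as.dist(dm) ~", rhs))
  set.seed(seed)
  tab <- vegan::adonis2(fm, data = dat, permutations = nPerm, by = "terms")
  i <- match("groups", rownames(tab))
  list(F = tab$F[i], p = tab$`Pr(>F)`[i], R2 = tab$R2[i], table = tab)
}

#' Temporal stability report between two time points
#'
#' Convenience wrapper for the repeated-sampling design: per-sample Shannon
#' diversity at each time point, Whittaker beta within each time point, and
#' the RV coefficient between the two normalized OTU tables on the shared
#' samples.
#'
#' @param t1,t2 [CountTable-class] objects for the two time points with
#'   identical sample ids.
#' @param normalization `"relative"` (default) or `"clr"` for the RV input.
#' @return list with `shannon` (data.frame), `whittaker` (per time point)
#'   and `rv`.
#' @export
stabilityReport <- function(t1, t2, normalization = c("relative", "clr")) {
  normalization <- match.arg(normalization)
  if (!identical(colnames(otuCounts(t1)), colnames(otuCounts(t2))))
    stop("time points must cover the same samples in the same order")
  norm <- switch(normalization, relative = toRelative, clr = clrTransform)
  list(
    shannon = data.frame(
      sample = colnames(otuCounts(t1)),
      T1 = as.numeric(shannonIndex(toRelative(t1))),
      T2 = as.numeric(shannonIndex(toRelative(t2)))),
    whittaker = c(T1 = whittakerBeta(t1), T2 = whittakerBeta(t2)),
    rv = rvCoefficient(norm(t1), norm(t2)))
}
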