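## Differential abundance between community clusters: zero-inflated
## Gaussian mixture on CSS-normalized values, presence-absence Fisher
## tests, BH adjustment, fold changes.

#' Zero-inflated Gaussian differential abundance
#'
#' Per feature, CSS-normalized log2 abundances are modeled as a mixture of
#' a structural zero (point mass at 0, probability given by a logistic
#' regression on log library size) and a Gaussian whose mean is a linear
#' model on the two-level group factor. Parameters are estimated by EM:
#' the E-step assigns each observed zero a responsibility of being
#' structural, the M-step is a weighted least-squares fit plus a logistic
#' refit. The group effect is tested with a t-statistic on the group
#' coefficient using the weighted residual degrees of freedom, and p-values
#' are BH-adjusted across features. With no zeros the mixture collapses to
#' an ordinary per-feature linear model.
#'
#' @param counts a [CountTable-class] (raw counts; zeros and library sizes
#'   are taken from here).
#' @param groups two-level factor over samples.
#' @param abundance optional precomputed `css_log2` [AbundanceTable-class];
#'   computed with [cssNormalize()] at `quantile` when absent.
#' @param quantile CSS quantile when normalizing internally.
#' @param maxIter maximum EM iterations (default 10).
#' @param tol EM stop tolerance on the observed-data log-likelihood.
#' @return data.frame with one row per feature: `feature_id`, `comparison`,
#'   `log2FC` (group coefficient on the log2 scale), `FC = 2^log2FC`, `t`,
#'   `p`, `adj_p`, `zero_prop`, `converged`. The per-feature log-likelihood
#'   traces are attached as attribute `"loglik_trace"`.
#' @export
fitZig <- function(counts, groups, abundance = NULL, quantile = 0.5,
                   maxIter = 10, tol = 1e-4) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L)
    stop("fitZig tests a two-level group factor; see differentialAbundance()")
  raw <- otuCounts(counts)
  if (ncol(raw) != length(groups)) stop("groups must match samples")
  if (is.null(abundance)) abundance <- cssNormalize(counts, quantile = quantile)
  y <- abundanceValues(abundance)
  ld <- scale(log(colSums(raw)))[, 1L]
  X <- model.matrix(~groups)
  res <- vector("list", nrow(raw))
  traces <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    fit <- .zigOne(y[i, ], raw[i, ] == 0, X, ld, maxIter, tol)
    res[[i]] <- fit$row
    traces[[i]] <- fit$ll
  }
  out <- do.call(rbind, res)
  out <- data.frame(feature_id = rownames(raw),
                    comparison = paste(levels(groups)[2], "vs",
                                       levels(groups)[1]),
                    out, row.names = NULL)
  out$adj_p <- bhAdjust(out$p)
  attr(out, "loglik_trace") <- traces
  out
}

.zigOne <- function(y, zero, X, ld, maxIter, tol) {
  n <- length(y)
  p <- ncol(X)
  r <- numeric(n)
  r[zero] <- 0.5
  ll <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  beta <- NULL; s2 <- NULL; pi <- rep(mean(zero), n)
  for (it in seq_len(maxIter)) {
    ## M-step: weighted least squares for the Gaussian component
    w <- 1 - r
    wlm <- lm.wfit(X, y, w = pmax(w, 1e-8))
    beta <- wlm$coefficients
    mu <- drop(X %*% beta)
    s2 <- max(sum(w * (y - mu)^2) / max(sum(w), 1e-8), 1e-8)
    ## logistic refit of the structural-zero probability on log depth
    pi <- .zigLogistic(r, ld, piPrev = if (it > 1L) pi else NULL)
    ## E-step: responsibilities of observed zeros
    if (any(zero)) {
      dens <- dnorm(0, mu[zero], sqrt(s2))
      r[zero] <- pi[zero] / (pi[zero] + (1 - pi[zero]) * dens)
      r[zero] <- pmin(pmax(r[zero], 1e-12), 1 - 1e-12)
    }
    llNew <- sum(log(pi[zero] + (1 - pi[zero]) * dnorm(0, mu[zero], sqrt(s2)))) +
      sum(log((1 - pi[!zero]) * dnorm(y[!zero], mu[!zero], sqrt(s2))))
    trace <- c(trace, llNew)
    if (is.finite(ll) && abs(llNew - ll) < tol) { converged <- TRUE; ll <- llNew; break }
    ll <- llNew
  }
  ## weighted t-test on the group coefficient
  w <- 1 - r
  W <- diag(w)
  XtWX <- crossprod(X, w * X)
  xwxInv <- tryCatch(solve(XtWX), error = function(e) MASS_ginv(XtWX))
  mu <- drop(X %*% beta)
  dfRes <- max(sum(w) - p, 1)
  s2hat <- sum(w * (y - mu)^2) / dfRes
  se <- sqrt(s2hat * xwxInv[2L, 2L])
  tstat <- if (se > 0) beta[2L] / se else 0
  pval <- 2 * pt(-abs(tstat), df = dfRes)
  list(row = data.frame(log2FC = unname(beta[2L]), FC = 2^unname(beta[2L]),
                        t = tstat, p = pval, zero_prop = mean(zero),
                        converged = converged),
       ll = trace)
}

MASS_ginv <- function(m) {
  s <- svd(m)
  pos <- s$d > max(s$d) * 1e-12
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# fractional-response logistic fit (quasi-likelihood). Both the log-depth
# slope model and the intercept-only model are fitted and the one with the
# higher Bernoulli log-likelihood against the responsibilities is kept, so
# the M-step never decreases the EM objective when the slope fit is
# unstable.
.zigLogistic <- function(r, ld, piPrev = NULL) {
  clamp <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)
  bern <- function(p) sum(r * log(p) + (1 - r) * log(1 - p))
  cand <- list(clamp(rep(mean(r), length(r))))
  if (!is.null(piPrev)) cand <- c(cand, list(clamp(piPrev)))
  fit <- tryCatch(
    suppressWarnings(glm.fit(cbind(1, ld), r,
                             family = stats::quasibinomial())),
    error = function(e) NULL)
  if (!is.null(fit) && fit$converged && !anyNA(fit$coefficients))
    cand <- c(cand, list(clamp(fit$fitted.values)))
  cand[[which.max(vapply(cand, bern, numeric(1L)))]]
}

#' Pairwise zero-inflated Gaussian tests across all cluster pairs
#'
#' Runs [fitZig()] on every pairwise subset of cluster labels.
#'
#' @param counts a [CountTable-class].
#' @param labels cluster assignment per sample.
#' @param ... passed to [fitZig()].
#' @return row-bound data.frame of per-comparison results.
#' @export
differentialAbundance <- function(counts, labels, ...) {
  labels <- factor(labels)
  prs <- utils::combn(levels(labels), 2L, simplify = FALSE)
  do.call(rbind, lapply(prs, function(pr) {
    sel <- labels %in% pr
    fitZig(counts[, sel], droplevels(labels[sel]), ...)
  }))
}

#' Presence-absence tests between clusters
#'
#' Presence is `count > 0`. For each feature and each pairwise cluster
#' comparison, a two-sided Fisher exact test (probability-mass rule: the
#' sum of hypergeometric probabilities no larger than the observed
#' table's) is computed on the 2x2 presence x group table, with the
#' Haldane-Anscombe-corrected sample odds ratio, and BH adjustment across
#' features within each comparison.
#'
#' @param counts a [CountTable-class].
#' @param labels cluster assignment per sample.
#' @param comparisons list of 2-vectors of cluster labels; all pairs by
#'   default.
#' @return data.frame: `feature_id`, `comparison`, presence counts and
#'   group sizes, `odds_ratio`, `p`, `adj_p`.
#' @export
presenceAbsence <- function(counts, labels, comparisons = NULL) {
  labels <- factor(labels)
  m <- otuCounts(counts) > 0
  if (is.null(comparisons))
    comparisons <- utils::combn(levels(labels), 2L, simplify = FALSE)
  out <- lapply(comparisons, function(pr) {
    iA <- which(labels == pr[1]); iB <- which(labels == pr[2])
    nA <- length(iA); nB <- length(iB)
    presA <- rowSums(m[, iA, drop = FALSE])
    presB <- rowSums(m[, iB, drop = FALSE])
    p <- vapply(seq_along(presA), function(i) {
      tab <- matrix(c(presA[i], nA - presA[i], presB[i], nB - presB[i]), 2L)
      fisher.test(tab)$p.value
    }, numeric(1L))
    orr <- ((presA + 0.5) * (nB - presB + 0.5)) /
           ((nA - presA + 0.5) * (presB + 0.5))
    data.frame(feature_id = rownames(m),
               comparison = paste(pr[1], "vs", pr[2]),
               present_A = presA, present_B = presB, n_A = nA, n_B = nB,
               odds_ratio = orr, p = p, adj_p = bhAdjust(p),
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1 (delegates to [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values, elementwise `>=` the input.
#' @export
bhAdjust <- function(p) p.adjust(p, method = "BH")

#' Fold change between two clusters
#'
#' Ratio of group mean abundances on the CSS-normalized linear scale
#' (counts divided by the sample scaling factor, times 1000). When a group
#' mean is zero the ratio is guarded with a pseudocount of half the
#' smallest nonzero normalized value and flagged as capped.
#'
#' @param counts a [CountTable-class].
#' @param labels cluster assignment per sample.
#' @param gA,gB cluster labels: the reported ratio is mean(gA) / mean(gB).
#' @param quantile CSS quantile.
#' @return data.frame: `feature_id`, `mean_A`, `mean_B`, `FC`, `log2FC`,
#'   `capped`.
#' @export
foldChange <- function(counts, labels, gA, gB, quantile = 0.5) {
  labels <- factor(labels)
  raw <- otuCounts(counts)
  fac <- cssFactors(raw, quantile)
  lin <- sweep(raw, 2L, fac, "/") * 1000
  mA <- rowMeans(lin[, labels == gA, drop = FALSE])
  mB <- rowMeans(lin[, labels == gB, drop = FALSE])
  nz <- lin[lin > 0]
  pseudo <- if (length(nz)) min(nz) / 2 else 0.5
  capped <- (mA == 0) | (mB == 0)
  fc <- ifelse(capped, (mA + pseudo) / (mB + pseudo), mA / mB)
  data.frame(feature_id = rownames(raw), mean_A = mA, mean_B = mB,
             FC = fc, log2FC = log2(fc), capped = capped, row.names = NULL)
}
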