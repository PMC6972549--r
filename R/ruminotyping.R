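## Enterotype-style cluster discovery: sqrt-JSD distance, PAM, model
## selection (Calinski-Harabasz, silhouette), bootstrap stability, and
## cluster-phenotype association.

#' Jensen-Shannon divergence distance
#'
#' For relative-abundance profiles p, q:
#' `JSD = KL(p || m)/2 + KL(q || m)/2` with `m = (p + q)/2` and natural
#' logs; zeros are replaced by a small pseudo-probability and each profile
#' renormalized. The returned dissimilarity is `sqrt(JSD)` (a metric), or
#' raw JSD with `sqrt = FALSE`.
#'
#' @param x relative [AbundanceTable-class] (features x samples).
#' @param pseudo replacement for zero probabilities (default 1e-9).
#' @param sqrt return the square root of the divergence (default TRUE).
#' @return A [DistanceMatrix-class] with `metric = "jsd_sqrt"` (or
#'   `"other"` for raw JSD).
#' @export
jsdDistance <- function(x, pseudo = 1e-9, sqrt = TRUE) {
  m <- if (is(x, "AbundanceTable")) {
    if (x@transform != "relative") stop("jsdDistance needs relative abundances")
    abundanceValues(x)
  } else as.matrix(x)
  m[m == 0] <- pseudo
  m <- sweep(m, 2L, colSums(m), "/")
  n <- ncol(m)
  H <- apply(m, 2L, function(p) -sum(p * log(p)))
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1L)) {
    mid <- (m[, i] + m[, (i + 1L):n, drop = FALSE]) / 2
    Hmid <- apply(mid, 2L, function(p) -sum(p * log(p)))
    jsd <- pmax(Hmid - (H[i] + H[(i + 1L):n]) / 2, 0)
    d[i, (i + 1L):n] <- d[(i + 1L):n, i] <- if (sqrt) base::sqrt(jsd) else jsd
  }
  DistanceMatrix(d, metric = if (sqrt) "jsd_sqrt" else "other")
}

#' Partitioning around medoids
#'
#' Classic PAM: greedy BUILD seeding followed by SWAP steps to a local
#' optimum of the total distance to assigned medoids. Deterministic: ties
#' are broken toward the lowest sample index, so the solution depends only
#' on the distance matrix.
#'
#' @param d a [DistanceMatrix-class] (or square matrix).
#' @param k number of clusters, `2 <= k < n`.
#' @return A [ClusterSolution-class]; the per-SWAP cost trace is attached
#'   as attribute `"costTrace"`.
#' @export
pamCluster <- function(d, k) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  k <- as.integer(k)
  if (k < 2L || k >= n) stop("k must satisfy 2 <= k < n")

  ## on small instances, SWAP is run from every possible BUILD seeding to
  ## escape the (well-known) local optima of single-start PAM; larger
  ## instances use the classic single BUILD
  firsts <- if (n <= 12L) seq_len(n) else which.min(colSums(dm))
  best <- NULL
  for (f in firsts) {
    sol <- .pamSwap(dm, .pamBuild(dm, k, f))
    if (is.null(best) || sol$cost < best$cost - 1e-12) best <- sol
  }
  med <- sort(best$med)
  labels <- apply(dm[, med, drop = FALSE], 1L, which.min)
  ids <- rownames(dm) %||% as.character(seq_len(n))
  out <- new("ClusterSolution", k = k,
             labels = setNames(as.integer(labels), ids),
             medoids = ids[med], cost = best$cost)
  attr(out, "costTrace") <- best$trace
  out
}

# greedy BUILD from a given first medoid: each next medoid maximizes the
# total reduction in distance-to-nearest-medoid
.pamBuild <- function(dm, k, first) {
  n <- nrow(dm)
  med <- first
  nearest <- dm[, first]
  while (length(med) < k) {
    gain <- vapply(seq_len(n), function(i) {
      if (i %in% med) return(-Inf)
      sum(pmax(nearest - dm[, i], 0))
    }, numeric(1L))
    med <- c(med, which.max(gain))
    nearest <- pmin(nearest, dm[, med[length(med)]])
  }
  med
}

# best-improvement SWAP to a local optimum; only strict improvements are
# accepted so the cost decreases monotonically and the loop terminates
.pamSwap <- function(dm, med) {
  n <- nrow(dm)
  cost <- function(meds) sum(do.call(pmin, lapply(meds, function(m) dm[, m])))
  cur <- cost(med)
  trace <- cur
  repeat {
    best <- list(delta = 1e-10 * max(cur, 1))
    for (mi in seq_along(med)) {
      for (h in seq_len(n)) {
        if (h %in% med) next
        cand <- med; cand[mi] <- h
        cc <- cost(cand)
        if (cur - cc > best$delta) best <- list(delta = cur - cc,
                                                meds = cand, cost = cc)
      }
    }
    if (is.null(best$meds)) break
    med <- best$meds
    cur <- best$cost
    trace <- c(trace, cur)
  }
  list(med = med, cost = cur, trace = trace)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Calinski-Harabasz index
#'
#' Variance-ratio criterion `CH = [B/(k-1)] / [W/(n-k)]`. Because the
#' criterion is defined on coordinates, the distance matrix is embedded by
#' classical MDS (PCoA) keeping axes with positive eigenvalues
#' (`embed = "pcoa"`, default); `embed = "distance"` instead computes the
#' within/total sums of squares directly from squared dissimilarities.
#'
#' @param d a [DistanceMatrix-class] (or square matrix).
#' @param labels integer cluster assignment per sample.
#' @param embed `"pcoa"` or `"distance"`.
#' @param coords optional precomputed PCoA coordinates (internal reuse).
#' @return CH index (larger = better-separated clusters).
#' @export
chIndex <- function(d, labels, embed = c("pcoa", "distance"),
                    coords = NULL) {
  embed <- match.arg(embed)
  dm <- as.matrix(d)
  n <- nrow(dm)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2L || k > n - 1L) stop("CH index defined for 2 <= k <= n-1")
  if (embed == "pcoa") {
    co <- if (is.null(coords)) .pcoaCoords(dm) else coords
    centr <- colMeans(co)
    W <- 0; B <- 0
    for (g in seq_len(k)) {
      cg <- co[labels == g, , drop = FALSE]
      mg <- colMeans(cg)
      W <- W + sum(sweep(cg, 2L, mg)^2)
      B <- B + nrow(cg) * sum((mg - centr)^2)
    }
  } else {
    tot <- sum(dm^2) / (2 * n)
    W <- sum(vapply(seq_len(k), function(g) {
      i <- which(labels == g)
      sum(dm[i, i, drop = FALSE]^2) / (2 * length(i))
    }, numeric(1L)))
    B <- tot - W
  }
  (B / (k - 1)) / (W / (n - k))
}

# classical-MDS embedding keeping axes with positive eigenvalues
.pcoaCoords <- function(dm) {
  n <- nrow(dm)
  mds <- suppressWarnings(cmdscale(dm, k = n - 1L, eig = TRUE))
  keep <- mds$eig > 1e-9 * max(abs(mds$eig))
  mds$points[, seq_len(min(sum(keep), ncol(mds$points))), drop = FALSE]
}

#' Silhouette widths
#'
#' `s_i = (b_i - a_i) / max(a_i, b_i)` with `a_i` the mean distance to
#' one's own cluster and `b_i` the smallest mean distance to another
#' cluster; members of singleton clusters get `s_i = 0`.
#'
#' @param d a [DistanceMatrix-class] (or square matrix).
#' @param labels cluster assignment per sample (>= 2 clusters).
#' @return list with `mean` and per-sample `widths`.
#' @export
silhouetteWidths <- function(d, labels) {
  dm <- as.matrix(d)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2L) stop("silhouette needs >= 2 clusters")
  n <- nrow(dm)
  s <- numeric(n)
  sizes <- tabulate(labels, k)
  for (i in seq_len(n)) {
    g <- labels[i]
    if (sizes[g] == 1L) { s[i] <- 0; next }
    a <- sum(dm[i, labels == g]) / (sizes[g] - 1L)
    b <- min(vapply(setdiff(seq_len(k), g),
                    function(h) mean(dm[i, labels == h]), numeric(1L)))
    s[i] <- (b - a) / max(a, b)
  }
  list(mean = mean(s), widths = setNames(s, rownames(dm)))
}

#' Choose the number of clusters
#'
#' Runs PAM for every k in `kRange`, scores each solution with the
#' Calinski-Harabasz index (and mean silhouette, reported alongside), and
#' picks the CH-maximizing k.
#'
#' @param d a [DistanceMatrix-class].
#' @param kRange candidate cluster numbers (default 2:8).
#' @param embed passed to [chIndex()].
#' @return list with `table` (k, CH, silhouette), `chosenK`, and
#'   `solution` (the [ClusterSolution-class] at the chosen k).
#' @export
selectK <- function(d, kRange = 2:8, embed = "pcoa") {
  kRange <- sort(unique(as.integer(kRange)))
  sols <- lapply(kRange, function(k) pamCluster(d, k))
  coords <- if (embed == "pcoa") .pcoaCoords(as.matrix(d)) else NULL
  tab <- data.frame(
    k = kRange,
    CH = vapply(sols, function(s) chIndex(d, s@labels, embed = embed,
                                          coords = coords),
                numeric(1L)),
    silhouette = vapply(sols, function(s) silhouetteWidths(d, s@labels)$mean,
                        numeric(1L)))
  best <- which.max(tab$CH)
  list(table = tab, chosenK = kRange[best], solution = sols[[best]])
}

#' Cluster-wise Jaccard bootstrap stability
#'
#' For each of `nBoot` bootstrap resamples (with replacement) the resample
#' is reclustered with PAM at the same k; each original cluster is scored
#' by the Jaccard similarity with its best-matching bootstrap cluster,
#' computed over the drawn points (Hennig's maximum-Jaccard matching).
#' Reported per-cluster values are means over repetitions; values around
#' 0.6 indicate moderate stability, above 0.85 a stable cluster.
#'
#' @param d a [DistanceMatrix-class].
#' @param k number of clusters.
#' @param nBoot bootstrap repetitions (default 100).
#' @param seed RNG seed for resampling.
#' @return list with `clusterJaccard` (per original cluster), `nBoot`, and
#'   the original `solution`.
#' @export
jaccardBootstrap <- function(d, k, nBoot = 100, seed = 1L) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  orig <- pamCluster(dm, k)
  set.seed(seed)
  acc <- matrix(NA_real_, nBoot, k)
  for (b in seq_len(nBoot)) {
    idx <- sample.int(n, n, replace = TRUE)
    sub <- dm[idx, idx, drop = FALSE]
    rownames(sub) <- colnames(sub) <- NULL
    bl <- pamCluster(sub, k)@labels
    ol <- orig@labels[idx]
    for (g in seq_len(k)) {
      A <- which(ol == g)
      if (!length(A)) { acc[b, g] <- 0; next }
      acc[b, g] <- max(vapply(seq_len(k), function(h) {
        C <- which(bl == h)
        length(intersect(A, C)) / length(union(A, C))
      }, numeric(1L)))
    }
  }
  list(clusterJaccard = colMeans(acc, na.rm = TRUE), nBoot = nBoot,
       solution = orig)
}

#' Cluster-phenotype association by least-squares means
#'
#' One-way least-squares model of the (pre-adjusted) trait on cluster
#' membership; all pairwise cluster contrasts with t-tests under Tukey HSD
#' multiplicity adjustment (via \pkg{emmeans}).
#'
#' @param labels cluster assignment per sample.
#' @param trait numeric trait per sample (typically the contemporary-group
#'   adjusted methane yield), aligned with `labels`.
#' @return list with `means` (least-squares mean per cluster) and
#'   `contrasts` (data.frame: contrast, estimate, SE, t, adjusted p).
#' @export
clusterPhenotypeAssoc <- function(labels, trait) {
  cl <- factor(paste0("R", as.integer(factor(labels))))
  if (nlevels(cl) < 2L) stop("need >= 2 clusters")
  fit <- lm(trait ~ cl, data = data.frame(trait = trait, cl = cl))
  em <- emmeans::emmeans(fit, "cl")
  ctr <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                         adjust = "tukey"))
  list(means = as.data.frame(em), contrasts = ctr)
}
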