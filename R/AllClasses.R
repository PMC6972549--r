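#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData assayNames
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata
#' @import stats
#' @importFrom utils read.delim write.table head tail combn
#' @useDynLib ruminotyper, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.LEVELS <- c("otu", "genus", "mgs", "kegg_module")
.TRANSFORMS <- c("relative", "clr", "css_log2", "log_std")

#' Feature-by-sample count table
#'
#' An integer feature x sample matrix (OTUs, genera, metagenomic species or
#' KEGG modules) with optional rank-delimited taxonomy, stored as a
#' [SummarizedExperiment::SummarizedExperiment] with a single `"counts"`
#' assay. Features are rows, samples are columns, throughout the package.
#'
#' @slot level character, one of `"otu"`, `"genus"`, `"mgs"`, `"kegg_module"`.
#' @export
setClass("CountTable",
  contains = "SummarizedExperiment",
  representation(level = "character"),
  prototype(level = "otu")
)

setValidity("CountTable", function(object) {
  msg <- character()
  if (length(object@level) != 1L || !object@level %in% .LEVELS)
    msg <- c(msg, sprintf("level must be one of %s", paste(.LEVELS, collapse = ", ")))
  if (!"counts" %in% assayNames(object))
    return("assay 'counts' is required")
  m <- assay(object, "counts")
  if (length(m) && (anyNA(m) || any(m < 0)))
    msg <- c(msg, "counts must be non-negative and non-missing")
  if (length(m) && any(m != round(m)))
    msg <- c(msg, "counts must be integral")
  if (anyDuplicated(rownames(object))) msg <- c(msg, "duplicate feature ids")
  if (anyDuplicated(colnames(object))) msg <- c(msg, "duplicate sample ids")
  if (length(msg)) msg else TRUE
})

#' Construct a CountTable
#'
#' @param counts non-negative integer matrix, features in rows, samples in
#'   columns; dimnames are used as feature/sample ids.
#' @param taxonomy optional character vector of rank-delimited lineage
#'   strings (e.g. `"d__Bacteria;p__...;g__Prevotella"`), one per feature.
#' @param level abundance level of the features.
#' @return A [CountTable-class] object.
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 7L), 2, 2,
#'             dimnames = list(c("OTU1", "OTU2"), c("S1", "S2")))
#' CountTable(m)
#' @export
CountTable <- function(counts, taxonomy = NULL, level = "otu") {
  counts <- as.matrix(counts)
  if (is.null(dimnames(counts))) dimnames(counts) <- list(NULL, NULL)
  if (is.null(rownames(counts)) && nrow(counts))
    rownames(counts) <- paste0("F", seq_len(nrow(counts)))
  if (is.null(colnames(counts)) && ncol(counts))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  storage.mode(counts) <- "double"
  rd <- DataFrame(row.names = rownames(counts))
  if (!is.null(taxonomy)) {
    if (length(taxonomy) != nrow(counts))
      stop("taxonomy must have one lineage per feature")
    rd$taxonomy <- as.character(taxonomy)
  }
  new("CountTable",
      SummarizedExperiment(assays = list(counts = counts), rowData = rd),
      level = level)
}

#' Transformed abundance table
#'
#' Real-valued feature x sample matrix produced by [toRelative()],
#' [clrTransform()] or [cssNormalize()]; the `transform` slot records which
#' convention the values follow.
#'
#' @slot transform one of `"relative"`, `"clr"`, `"css_log2"`, `"log_std"`.
#' @export
setClass("AbundanceTable",
  contains = "SummarizedExperiment",
  representation(transform = "character"),
  prototype(transform = "relative")
)

setValidity("AbundanceTable", function(object) {
  msg <- character()
  if (length(object@transform) != 1L || !object@transform %in% .TRANSFORMS)
    msg <- c(msg, sprintf("transform must be one of %s",
                          paste(.TRANSFORMS, collapse = ", ")))
  if (!"abundance" %in% assayNames(object))
    return("assay 'abundance' is required")
  m <- assay(object, "abundance")
  if (length(m) && ncol(m)) {
    cs <- colSums(m)
    if (identical(object@transform, "relative") && any(abs(cs - 1) > 1e-9))
      msg <- c(msg, "relative abundance columns must each sum to 1")
    if (identical(object@transform, "clr") && any(abs(cs) > 1e-9 * nrow(m)))
      msg <- c(msg, "clr columns must each sum to 0")
  }
  if (length(msg)) msg else TRUE
})

.AbundanceTable <- function(values, transform, template = NULL) {
  rd <- if (!is.null(template)) rowData(template)[rownames(values), , drop = FALSE]
        else DataFrame(row.names = rownames(values))
  new("AbundanceTable",
      SummarizedExperiment(assays = list(abundance = values), rowData = rd),
      transform = transform)
}

#' SNP genotype matrix
#'
#' Allele dosages coded 0/1/2 (`NA` missing), SNPs in rows, animals in
#' columns, with per-SNP map information.
#'
#' @slot dosages numeric matrix, SNPs x animals.
#' @slot snpInfo data.frame with columns `snp_id`, `chrom`, `pos`, `a1`, `a2`.
#' @export
setClass("GenotypeMatrix",
  representation(dosages = "matrix", snpInfo = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  d <- object@dosages
  if (!all(d[!is.na(d)] %in% c(0, 1, 2)))
    msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  if (anyDuplicated(rownames(d))) msg <- c(msg, "duplicate SNP ids")
  if (anyDuplicated(colnames(d))) msg <- c(msg, "duplicate animal ids")
  if (nrow(object@snpInfo) != nrow(d))
    msg <- c(msg, "snpInfo must have one row per SNP")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosages numeric matrix coded 0/1/2 with `NA` for missing; SNPs in
#'   rows (rownames = SNP ids), animals in columns (colnames = animal ids).
#' @param snpInfo optional data.frame with `snp_id`, `chrom`, `pos`, `a1`,
#'   `a2`; a stub map is created when absent.
#' @return A [GenotypeMatrix-class].
#' @export
GenotypeMatrix <- function(dosages, snpInfo = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("snp", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("A", seq_len(ncol(dosages)))
  if (is.null(snpInfo)) {
    snpInfo <- data.frame(snp_id = rownames(dosages),
                          chrom = 1L, pos = seq_len(nrow(dosages)),
                          a1 = "A", a2 = "B")
  }
  new("GenotypeMatrix", dosages = dosages, snpInfo = snpInfo)
}

#' Symmetric sample dissimilarity matrix
#'
#' @slot values symmetric matrix with zero diagonal.
#' @slot metric one of `"jsd_sqrt"`, `"bray_curtis"`, `"jaccard_binary"`, `"other"`.
#' @export
setClass("DistanceMatrix",
  representation(values = "matrix", metric = "character"))

setValidity("DistanceMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (max(abs(v - t(v))) > 1e-8) msg <- c(msg, "matrix must be symmetric")
  if (any(abs(diag(v)) > 1e-12)) msg <- c(msg, "diagonal must be zero")
  if (any(v < -1e-12)) msg <- c(msg, "dissimilarities must be non-negative")
  if (object@metric %in% c("bray_curtis", "jaccard_binary") && any(v > 1 + 1e-9))
    msg <- c(msg, "bounded metric exceeds 1")
  if (!identical(rownames(v), colnames(v)))
    msg <- c(msg, "row and column sample ids must agree")
  if (length(msg)) msg else TRUE
})

#' Construct a DistanceMatrix
#'
#' @param values square symmetric dissimilarity matrix (small negative
#'   rounding noise and diagonal values are cleaned up).
#' @param metric metric tag.
#' @return A [DistanceMatrix-class].
#' @export
DistanceMatrix <- function(values, metric = "other") {
  values <- as.matrix(values)
  values[values < 0 & values > -1e-12] <- 0
  diag(values) <- 0
  values <- (values + t(values)) / 2
  new("DistanceMatrix", values = values, metric = metric)
}

#' Sample relationship kernel
#'
#' Positive semi-definite n x n similarity matrix entering the mixed model:
#' a VanRaden genomic relationship matrix or a microbial relationship
#' matrix (Bray-Curtis similarity, or covariance of the log-transformed
#' standardized table).
#'
#' @slot values symmetric numeric matrix.
#' @slot kind `"genomic_vanraden"`, `"microbial_bray"` or `"microbial_ross"`.
#' @slot psdRepaired whether negative eigenvalues were truncated.
#' @export
setClass("RelationshipMatrix",
  representation(values = "matrix", kind = "character",
                 psdRepaired = "logical"),
  prototype(psdRepaired = FALSE))

setValidity("RelationshipMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (max(abs(v - t(v))) > 1e-8) msg <- c(msg, "matrix must be symmetric")
  ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    msg <- c(msg, "kernel must be positive semi-definite")
  if (length(msg)) msg else TRUE
})

#' Partitioning-around-medoids clustering solution
#'
#' @slot k number of clusters.
#' @slot labels integer cluster assignment per sample (named).
#' @slot medoids sample ids of the k medoids.
#' @slot cost total distance of samples to their assigned medoid.
#' @export
setClass("ClusterSolution",
  representation(k = "integer", labels = "integer", medoids = "character",
                 cost = "numeric"))

setValidity("ClusterSolution", function(object) {
  msg <- character()
  if (anyDuplicated(object@medoids)) msg <- c(msg, "medoids must be distinct")
  if (length(object@medoids) != object@k) msg <- c(msg, "need k medoids")
  if (!all(object@labels %in% seq_len(object@k)))
    msg <- c(msg, "labels must reference medoids 1..k")
  if (length(msg)) msg else TRUE
})

#' Sparse partial least squares model
#'
#' Fitted sPLS (regression mode) or sPLS-DA (discriminant mode) model with
#' per-component sparse X weights.
#'
#' @slot mode `"regression"` or `"da"`.
#' @slot ncomp number of latent components.
#' @slot keepX number of X variables retained per component.
#' @slot weights p x ncomp sparse X weight matrix (unit columns).
#' @slot xLoadings p x ncomp regression loadings used for deflation.
#' @slot yWeights q x ncomp Y weight/loading matrix.
#' @slot scores n x ncomp X score matrix.
#' @slot xCenter,xScale,yCenter,yScale centering/scaling vectors.
#' @slot ylevels class levels (da mode) or response names.
#' @export
setClass("SplsModel",
  representation(mode = "character", ncomp = "integer", keepX = "integer",
                 weights = "matrix", xLoadings = "matrix", yWeights = "matrix",
                 scores = "matrix", xCenter = "numeric", xScale = "numeric",
                 yCenter = "numeric", yScale = "numeric",
                 ylevels = "character"))

setValidity("SplsModel", function(object) {
  msg <- character()
  nz <- colSums(object@weights != 0)
  if (any(nz > object@keepX)) msg <- c(msg, "weight sparsity exceeds keepX")
  nrm <- sqrt(colSums(object@weights^2))
  if (any(abs(nrm - 1) > 1e-6)) msg <- c(msg, "weight columns must have unit norm")
  if (length(msg)) msg else TRUE
})

#' Posterior summary of the two-kernel mixed model
#'
#' @slot summary data.frame of posterior means and SDs for the variance
#'   components, heritability and microbiability.
#' @slot chains retained post-burn-in draws (one row per draw).
#' @slot config the MCMC configuration used.
#' @export
setClass("PosteriorSummary",
  representation(summary = "data.frame", chains = "matrix", config = "list"))

## ---- accessors & show methods -------------------------------------------

#' Extract the count matrix
#' @param x a CountTable
#' @return numeric matrix, features x samples.
#' @export
otuCounts <- function(x) assay(x, "counts")

#' Extract the transformed abundance matrix
#' @param x an AbundanceTable
#' @return numeric matrix, features x samples.
#' @export
abundanceValues <- function(x) assay(x, "abundance")

#' Taxonomy lineages of a CountTable
#' @param x a CountTable
#' @return character vector of lineage strings or NULL.
#' @export
taxonomyOf <- function(x) {
  rd <- rowData(x)
  if ("taxonomy" %in% colnames(rd)) setNames(rd$taxonomy, rownames(x)) else NULL
}

#' @describeIn DistanceMatrix-class dense matrix of dissimilarities
#' @param x,... coercion arguments
#' @export
setMethod("as.matrix", "DistanceMatrix", function(x, ...) x@values)

#' @describeIn RelationshipMatrix-class dense kernel matrix
#' @param x,... coercion arguments
#' @export
setMethod("as.matrix", "RelationshipMatrix", function(x, ...) x@values)

#' Cluster labels of a ClusterSolution
#' @param x a ClusterSolution
#' @return named integer vector of cluster assignments.
#' @export
clusterLabels <- function(x) x@labels

setMethod("show", "CountTable", function(object) {
  cat(sprintf("CountTable [%s]: %d features x %d samples, total %s counts\n",
              object@level, nrow(object), ncol(object),
              format(sum(assay(object, "counts")), big.mark = ",")))
})

setMethod("show", "AbundanceTable", function(object) {
  cat(sprintf("AbundanceTable [%s]: %d features x %d samples\n",
              object@transform, nrow(object), ncol(object)))
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d SNPs x %d animals (%.2f%% missing)\n",
              nrow(object@dosages), ncol(object@dosages),
              100 * mean(is.na(object@dosages))))
})

setMethod("show", "DistanceMatrix", function(object) {
  cat(sprintf("DistanceMatrix [%s]: %d samples\n",
              object@metric, nrow(object@values)))
})

setMethod("show", "RelationshipMatrix", function(object) {
  cat(sprintf("RelationshipMatrix [%s]: %d animals, mean diagonal %.3f%s\n",
              object@kind, nrow(object@values), mean(diag(object@values)),
              if (object@psdRepaired) " (PSD-repaired)" else ""))
})

setMethod("show", "ClusterSolution", function(object) {
  cat(sprintf("ClusterSolution: k = %d, sizes = %s, cost = %.4f\n",
              object@k, paste(tabulate(object@labels, object@k),
                              collapse = "/"), object@cost))
})

setMethod("show", "SplsModel", function(object) {
  cat(sprintf("SplsModel [%s]: %d component(s), keepX = %s\n",
              object@mode, object@ncomp,
              paste(object@keepX, collapse = ",")))
})

setMethod("show", "PosteriorSummary", function(object) {
  cat("PosteriorSummary (two-kernel Bayesian mixed model)\n")
  print(object@summary, digits = 3)
})

#' Posterior summary table
#' @param x a PosteriorSummary
#' @return data.frame of posterior means and SDs.
#' @export
posteriorTable <- function(x) x@summary
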