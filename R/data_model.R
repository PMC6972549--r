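## Count-table I/O, filtering, aggregation and normalization.

#' Read a feature x sample count table from TSV
#'
#' Expects a header row of sample ids, first column of feature ids and an
#' optional final `taxonomy` column holding rank-delimited lineages.
#' Orientation is auto-detected (features-in-rows is the default and the
#' tie-break); pass `orientation` to force it.
#'
#' @param path TSV file path.
#' @param orientation `"auto"`, `"features_in_rows"` or `"samples_in_rows"`.
#' @param level abundance level tag for the result.
#' @return A [CountTable-class].
#' @export
readCountTable <- function(path, orientation = c("auto", "features_in_rows",
                                                 "samples_in_rows"),
                           level = "otu") {
  orientation <- match.arg(orientation)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) stop("duplicate feature ids in ", path)
  df <- df[, -1L, drop = FALSE]
  taxonomy <- NULL
  if (ncol(df) && tolower(colnames(df)[ncol(df)]) == "taxonomy") {
    taxonomy <- df[[ncol(df)]]
    df <- df[, -ncol(df), drop = FALSE]
  }
  if (anyDuplicated(colnames(df))) stop("duplicate sample ids in ", path)
  m <- matrix(suppressWarnings(as.numeric(as.matrix(df))), nrow = nrow(df),
              ncol = ncol(df), dimnames = list(ids, colnames(df)))
  if (anyNA(m)) stop("non-numeric cell in count table ", path)
  if (any(m < 0)) stop("negative values in count table ", path)
  if (any(m != round(m))) stop("non-integral count in ", path)
  if (orientation == "samples_in_rows" ||
      (orientation == "auto" && .looksTransposed(ids, colnames(m)))) {
    m <- t(m)
    taxonomy <- NULL
  }
  CountTable(m, taxonomy = taxonomy, level = level)
}

# Heuristic: sample-style row ids together with OTU/feature-style column ids
.looksTransposed <- function(rowIds, colIds) {
  featLike <- function(x) mean(grepl("^(OTU|otu|F|feat|MGS|M0|g__)", x)) > 0.5
  featLike(colIds) && !featLike(rowIds)
}

#' Write a CountTable to TSV
#'
#' Inverse of [readCountTable()]: feature ids in the first column
#' (`feature_id`), one column per sample, and a trailing `taxonomy` column
#' when lineages are present.
#'
#' @param x a [CountTable-class]
#' @param path output path
#' @return `path`, invisibly.
#' @export
writeCountTable <- function(x, path) {
  m <- otuCounts(x)
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
  tax <- taxonomyOf(x)
  if (!is.null(tax)) df$taxonomy <- unname(tax)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Retain non-rare OTUs
#'
#' Drops doubleton features (total count over all samples less than or equal
#' to 2), then drops features whose total is at most 0.001% (1e-5) of the
#' remaining grand total. Feature order is preserved and the operation is
#' idempotent.
#'
#' @param x a [CountTable-class] at OTU level.
#' @param minTotal features with total count `<= minTotal` are removed first.
#' @param minFraction features at or below this fraction of the grand total
#'   are then removed.
#' @return Filtered [CountTable-class]; counts of removed/retained features
#'   are attached as `metadata(x)$filter_otus`.
#' @export
filterOtus <- function(x, minTotal = 2, minFraction = 1e-5) {
  m <- otuCounts(x)
  tot <- rowSums(m)
  keep1 <- tot > minTotal
  grand <- sum(tot[keep1])
  keep2 <- keep1 & (if (grand > 0) tot / grand > minFraction else FALSE)
  out <- x[keep2, ]
  S4Vectors::metadata(out)$filter_otus <- list(
    input = nrow(x), doubletons_removed = sum(!keep1),
    rare_removed = sum(keep1) - sum(keep2), retained = sum(keep2))
  out
}

.RANKS <- c("domain", "phylum", "class", "order", "family", "genus")
.RANK_PREFIX <- c(domain = "d__", phylum = "p__", class = "c__",
                  order = "o__", family = "f__", genus = "g__")

#' Aggregate counts to a higher taxonomic rank
#'
#' Sums counts over features sharing the lineage prefix at `rank`. Features
#' whose lineage stops short of `rank` are pooled into an
#' `unclassified_<parent>` bucket named after their deepest classified taxon.
#'
#' @param x a [CountTable-class] with taxonomy.
#' @param rank target rank, one of domain, phylum, class, order, family, genus.
#' @return A [CountTable-class] at the requested level (genus-level tables
#'   are tagged `level = "genus"`).
#' @export
aggregateTaxon <- function(x, rank = "genus") {
  if (!rank %in% .RANKS) stop("unknown rank: ", rank)
  tax <- taxonomyOf(x)
  if (is.null(tax)) stop("CountTable has no taxonomy")
  depth <- match(rank, .RANKS)
  key <- vapply(tax, function(lin) {
    parts <- strsplit(lin, ";", fixed = TRUE)[[1L]]
    parts <- parts[nzchar(sub("^[a-z]__", "", parts))]
    if (length(parts) >= depth) {
      paste(parts[seq_len(depth)], collapse = ";")
    } else {
      parent <- if (length(parts)) sub("^[a-z]__", "", parts[length(parts)])
                else "root"
      paste0("unclassified_", parent)
    }
  }, character(1L), USE.NAMES = FALSE)
  m <- otuCounts(x)
  agg <- rowsum(m, group = key, reorder = FALSE)
  label <- vapply(rownames(agg), function(k) {
    if (startsWith(k, "unclassified_")) k
    else sub("^[a-z]__", "", utils::tail(strsplit(k, ";", fixed = TRUE)[[1L]], 1L))
  }, character(1L))
  dup <- duplicated(label) | duplicated(label, fromLast = TRUE)
  label[dup] <- gsub(";", ".", rownames(agg)[dup])
  rownames(agg) <- label
  CountTable(agg, taxonomy = rownames(agg),
             level = if (rank == "genus") "genus" else x@level)
}

#' Convert counts to relative abundances
#'
#' Each sample column is divided by its library size.
#'
#' @param x a [CountTable-class].
#' @return An [AbundanceTable-class] with `transform = "relative"`.
#' @export
toRelative <- function(x) {
  if (!is(x, "CountTable")) stop("toRelative expects a CountTable")
  m <- otuCounts(x)
  cs <- colSums(m)
  if (any(cs == 0)) stop("zero library size in sample(s): ",
                         paste(colnames(m)[cs == 0], collapse = ", "))
  .AbundanceTable(sweep(m, 2L, cs, "/"), "relative", template = x)
}

#' Centred log-ratio transform
#'
#' Per sample: natural log of (count + pseudocount), centred by the sample
#' mean of those logs; each column of the result sums to zero.
#'
#' @param x a [CountTable-class].
#' @param pseudocount positive value added to every count before the log.
#' @return An [AbundanceTable-class] with `transform = "clr"`.
#' @export
clrTransform <- function(x, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  m <- log(otuCounts(x) + pseudocount)
  .AbundanceTable(sweep(m, 2L, colMeans(m), "-"), "clr", template = x)
}

#' Cumulative sum scaling normalization
#'
#' Per-sample scaling factor = the sum of that sample's counts at or below
#' the chosen quantile of its nonzero count distribution; normalized values
#' are `log2(count / factor * 1000 + 1)`. With `quantile = 1` the factor is
#' the library size (total-sum scaling). With `adaptive = TRUE` the quantile
#' is chosen data-dependently as the smallest quantile at which the median
#' across samples of the per-sample quantile values departs from the
#' low-quantile reference by more than `relTol` relative difference.
#'
#' @param x a [CountTable-class].
#' @param quantile quantile of the nonzero count distribution (default 0.5).
#' @param adaptive choose the quantile from the data instead.
#' @param relTol relative-difference threshold for the adaptive rule.
#' @return An [AbundanceTable-class] with `transform = "css_log2"`; scaling
#'   factors are attached as `metadata()$css_factors`.
#' @export
cssNormalize <- function(x, quantile = 0.5, adaptive = FALSE, relTol = 0.1) {
  m <- otuCounts(x)
  if (any(colSums(m) == 0)) stop("sample with no nonzero counts")
  if (adaptive) quantile <- .cssAdaptiveQuantile(m, relTol)
  fac <- cssFactors(m, quantile)
  v <- log2(sweep(m, 2L, fac, "/") * 1000 + 1)
  out <- .AbundanceTable(v, "css_log2", template = x)
  S4Vectors::metadata(out)$css_factors <- fac
  S4Vectors::metadata(out)$css_quantile <- quantile
  out
}

#' Per-sample CSS scaling factors
#' @param m count matrix (features x samples)
#' @param quantile quantile of each sample's nonzero count distribution
#' @return named numeric vector of scaling factors.
#' @export
cssFactors <- function(m, quantile = 0.5) {
  vapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    nz <- v[v > 0]
    ql <- stats::quantile(nz, probs = quantile, names = FALSE, type = 7)
    sum(v[v <= ql])
  }, numeric(1L)) |> setNames(colnames(m))
}

# smallest quantile where the median per-sample quantile value starts to
# diverge (relative difference > relTol) from the stable low-quantile regime
.cssAdaptiveQuantile <- function(m, relTol = 0.1) {
  probs <- seq(0.05, 0.95, by = 0.05)
  qmat <- vapply(seq_len(ncol(m)), function(j) {
    nz <- m[, j][m[, j] > 0]
    stats::quantile(nz, probs = probs, names = FALSE, type = 7)
  }, numeric(length(probs)))
  med <- apply(qmat, 1L, stats::median)
  rel <- abs(diff(med)) / pmax(med[-length(med)], 1)
  idx <- which(rel > relTol)
  if (length(idx)) probs[min(idx)] else 0.5
}
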