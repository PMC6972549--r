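## Genotype I/O and quality control.

#' Read a genotype TSV
#'
#' Expected columns: `snp_id, chrom, pos, a1, a2`, then one column of 0/1/2
#' dosages per animal with `NA` for missing calls.
#'
#' @param path TSV file path.
#' @return A [GenotypeMatrix-class].
#' @export
readGenotypes <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  need <- c("snp_id", "chrom", "pos", "a1", "a2")
  if (!all(need %in% colnames(df)))
    stop("genotype TSV must have columns ", paste(need, collapse = ", "))
  dos <- as.matrix(df[, setdiff(colnames(df), need), drop = FALSE])
  rownames(dos) <- df$snp_id
  GenotypeMatrix(dos, snpInfo = df[, need])
}

#' Read genotypes from a VCF (GT field mapped to dosage)
#'
#' Thin convenience reader for diploid biallelic records; the ALT allele is
#' counted, phased and unphased genotypes are treated alike and missing
#' genotypes become `NA`.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @return A [GenotypeMatrix-class].
#' @export
readGenotypesVcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean == "0/0"] <- 0
  dos[clean %in% c("0/1", "1/0")] <- 1
  dos[clean == "1/1"] <- 2
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  rownames(dos) <- make.unique(ids)
  GenotypeMatrix(dos, snpInfo = data.frame(
    snp_id = rownames(dos), chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]), a1 = fix[, "REF"], a2 = fix[, "ALT"]))
}

#' SNP quality control
#'
#' Removes SNPs with minor allele frequency below `mafMin`, missing-call
#' rate above `maxMissing`, or departure from Hardy-Weinberg equilibrium at
#' `hweAlpha` (1-df chi-square on observed vs expected genotype counts,
#' no continuity correction). Rules are evaluated independently on the
#' input, so removal sets do not depend on SNP order. Dosages are not
#' imputed here.
#'
#' @param g a [GenotypeMatrix-class].
#' @param mafMin minimum minor allele frequency (SNPs with MAF `< mafMin`
#'   are removed).
#' @param maxMissing maximum tolerated missing rate (strictly above removes).
#' @param hweAlpha Hardy-Weinberg chi-square p-value threshold (strictly
#'   below removes).
#' @return Filtered [GenotypeMatrix-class] with a `qc` attribute listing
#'   counts removed per rule.
#' @export
genotypeQC <- function(g, mafMin = 0.05, maxMissing = 0.10, hweAlpha = 0.001) {
  d <- g@dosages
  nObs <- rowSums(!is.na(d))
  if (any(nObs == 0)) stop("SNP(s) with no observed genotypes")
  p <- rowMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  missRate <- rowMeans(is.na(d))
  hweP <- vapply(seq_len(nrow(d)), function(i) .hweChisqP(d[i, ]), numeric(1L))
  failMaf <- maf < mafMin
  failMiss <- missRate > maxMissing
  failHwe <- hweP < hweAlpha
  keep <- !(failMaf | failMiss | failHwe)
  out <- GenotypeMatrix(d[keep, , drop = FALSE],
                        snpInfo = g@snpInfo[keep, , drop = FALSE])
  qc <- list(input = nrow(d), fail_maf = sum(failMaf),
             fail_missing = sum(failMiss), fail_hwe = sum(failHwe),
             retained = sum(keep))
  if (sum(keep) && all(pmin(p, 1 - p)[keep] == 0))
    warning("only monomorphic SNPs retained")
  attr(out, "qc") <- qc
  out
}

# 1-df chi-square HWE test on observed genotype counts (monomorphic -> p = 1)
.hweChisqP <- function(dos) {
  dos <- dos[!is.na(dos)]
  n <- length(dos)
  obs <- c(sum(dos == 0), sum(dos == 1), sum(dos == 2))
  p <- (2 * obs[3] + obs[2]) / (2 * n)
  if (p %in% c(0, 1)) return(1)
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((obs - expd)^2 / expd)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}
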