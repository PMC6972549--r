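# Small fixtures built in code, shared across test files.

makeCounts <- function(m, taxonomy = NULL, level = "otu") {
  if (is.null(rownames(m))) rownames(m) <- paste0("OTU", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("S", seq_len(ncol(m)))
  CountTable(m, taxonomy = taxonomy, level = level)
}

# two well-separated blobs in Euclidean space, returned as a DistanceMatrix
blobDistance <- function(n1 = 10, n2 = 10, sep = 20, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n1 * 2), n1), matrix(rnorm(n2 * 2) + sep, n2))
  DistanceMatrix(as.matrix(dist(x)), metric = "other")
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  s <- sum(choose(tab, 2))
  r <- sum(choose(rowSums(tab), 2))
  c2 <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  ex <- r * c2 / choose(n, 2)
  (s - ex) / ((r + c2) / 2 - ex)
}

# small scenario for fast end-to-end tests
smallScenario <- function(seed = 1, ...) {
  scenarioConfig(nSamples = 40, nOtus = 200, nGenera = 40, nSnps = 400,
                 seed = seed, ...)
}
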