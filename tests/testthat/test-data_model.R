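test_that("count table TSV round-trips with taxonomy and validates input", {
  m <- matrix(c(5L, 0L, 2L, 7L, 1L, 3L), 3, 2,
              dimnames = list(c("OTU1", "OTU2", "OTU3"), c("S1", "S2")))
  tax <- c("d__Bacteria;p__P;c__C;o__O;f__F1;g__G1",
           "d__Bacteria;p__P;c__C;o__O;f__F1;g__G2",
           "d__Bacteria;p__P;c__C;o__O;f__F2")
  x <- CountTable(m, taxonomy = tax)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeCountTable(x, path)
  y <- readCountTable(path)
  expect_equal(otuCounts(y), otuCounts(x))
  expect_equal(unname(taxonomyOf(y)), tax)

  # non-integral and negative cells are rejected
  writeLines("feature_id\tS1\nOTU1\t2.5", path)
  expect_error(readCountTable(path), "non-integral")
  writeLines("feature_id\tS1\nOTU1\t-3", path)
  expect_error(readCountTable(path), "negative")

  # degenerate: header-only table is valid with zero features
  writeLines("feature_id\tS1\tS2", path)
  z <- readCountTable(path)
  expect_s4_class(z, "CountTable")
  expect_equal(nrow(z), 0L)

  # invariants enforced at construction
  expect_error(CountTable(matrix(-1, 1, 1)), "non-negative")
  expect_error(CountTable(matrix(1.5, 1, 1)), "integral")
})

test_that("rare-OTU filtering applies the doubleton and 0.001% rules", {
  # doubleton (total 2) removed even though fraction rule would keep it
  m <- cbind(a = c(1, 5, 10), b = c(1, 5, 10))
  f <- filterOtus(makeCounts(m))
  expect_equal(rownames(f), c("OTU2", "OTU3"))

  # grand total 1e7 after doubleton removal: total 99 at/below 1e-5, 101 above
  m2 <- matrix(0, 3, 2, dimnames = list(c("rare99", "rare101", "big"), NULL))
  m2["rare99", ] <- c(99, 0)
  m2["rare101", ] <- c(101, 0)
  m2["big", ] <- c(1e7 - 300, 100)
  f2 <- filterOtus(makeCounts(m2))
  expect_equal(rownames(f2), c("rare101", "big"))

  # identity when nothing is rare
  m3 <- matrix(100, 4, 3)
  f3 <- filterOtus(makeCounts(m3))
  expect_equal(nrow(f3), 4L)

  # idempotence on random tables
  set.seed(42)
  for (i in 1:5) {
    m4 <- matrix(rpois(300, 2), 60, 5)
    once <- filterOtus(makeCounts(m4))
    twice <- filterOtus(once)
    expect_equal(otuCounts(twice), otuCounts(once))
  }
})

test_that("taxonomic aggregation sums counts and pools unclassified", {
  m <- rbind(c(3, 4), c(1, 2), c(7, 1))
  tax <- c("d__B;p__P;c__C;o__O;f__F;g__G1",
           "d__B;p__P;c__C;o__O;f__F;g__G1",
           "d__B;p__P;c__C;o__O;f__F")        # stops at family
  g <- aggregateTaxon(makeCounts(m, taxonomy = tax), "genus")
  expect_equal(nrow(g), 2L)
  expect_equal(unname(otuCounts(g)["G1", ]), c(4, 6))
  expect_true("unclassified_F" %in% rownames(g))
  expect_equal(unname(otuCounts(g)["unclassified_F", ]), c(7, 1))
  # grand total conserved
  expect_equal(sum(otuCounts(g)), sum(m))
  expect_error(aggregateTaxon(makeCounts(m, taxonomy = tax), "strain"),
               "unknown rank")
  # single OTU: identity
  one <- aggregateTaxon(makeCounts(m[1, , drop = FALSE],
                                   taxonomy = tax[1]), "genus")
  expect_equal(unname(otuCounts(one)[1, ]), c(3, 4))
})

test_that("relative abundance normalizes columns to 1", {
  x <- makeCounts(matrix(c(2, 2, 4), 3, 1))
  r <- toRelative(x)
  expect_equal(unname(abundanceValues(r)[, 1]), c(0.25, 0.25, 0.5))
  expect_error(toRelative(r), "CountTable")      # already-relative rejected
  expect_error(toRelative(makeCounts(matrix(0, 2, 1))), "zero library")
  set.seed(1)
  y <- makeCounts(matrix(rpois(60, 5) + 1, 6, 10))
  expect_equal(unname(colSums(abundanceValues(toRelative(y)))), rep(1, 10))
})

test_that("CLR centres natural-log abundances per sample", {
  x <- makeCounts(matrix(c(1, 1, 1), 3, 1))
  expect_equal(unname(abundanceValues(clrTransform(x))[, 1]), c(0, 0, 0))
  # hand-derived: counts (3,0), pseudocount 1 -> values (4,1), geometric
  # mean 2 -> clr = (ln 2, -ln 2)
  x2 <- makeCounts(matrix(c(3, 0), 2, 1))
  expect_equal(unname(abundanceValues(clrTransform(x2))[, 1]),
               c(log(2), -log(2)), tolerance = 1e-12)
  expect_error(clrTransform(x2, pseudocount = 0), "positive")
  set.seed(2)
  y <- clrTransform(makeCounts(matrix(rpois(80, 3), 8, 10)))
  expect_true(all(abs(colSums(abundanceValues(y))) < 1e-9))
})

test_that("CLR and relative transforms commute with sample permutation", {
  set.seed(7)
  m <- matrix(rpois(60, 4), 6, 10,
              dimnames = list(paste0("OTU", 1:6), paste0("S", 1:10)))
  x <- makeCounts(m)
  perm <- sample(10)
  for (f in list(clrTransform, toRelative)) {
    direct <- abundanceValues(f(makeCounts(m[, perm])))
    permuted <- abundanceValues(f(x))[, perm]
    expect_equal(direct, permuted)
  }
})

test_that("CSS factors follow the quantile rule and its limiting cases", {
  set.seed(11)
  m <- matrix(rpois(100, 3), 20, 5,
              dimnames = list(paste0("OTU", 1:20), paste0("S", 1:5)))
  m[sample(100, 30)] <- 0
  m <- m[rowSums(m) > 0, ]
  x <- makeCounts(m)

  # independent brute-force recomputation of the rule
  oracle <- sapply(seq_len(ncol(m)), function(j) {
    nz <- sort(m[m[, j] > 0, j])
    ql <- quantile(nz, 0.5, names = FALSE)
    sum(m[m[, j] <= ql, j])
  })
  expect_equal(unname(cssFactors(m, 0.5)), oracle)

  # quantile 1 reduces to total-sum scaling
  expect_equal(unname(cssFactors(m, 1)), unname(colSums(m)))

  # scalar-multiple samples normalize identically
  m2 <- cbind(A = c(2, 4, 0, 6), B = 3 * c(2, 4, 0, 6))
  rownames(m2) <- paste0("OTU", 1:4)
  v <- abundanceValues(cssNormalize(makeCounts(m2)))
  expect_equal(unname(v[, 1]), unname(v[, 2]))

  expect_error(cssNormalize(makeCounts(cbind(c(0, 0), c(1, 2)))),
               "no nonzero")
})
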