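# Independent predicate oracle: per-variant if-chains, evaluated one
# variant at a time, kept deliberately separate from the vectorized
# implementation.
oracleHardFilter <- function(info) {
  vapply(seq_len(nrow(info)), function(i) {
    r <- info[i, ]
    gt <- function(x, t) !is.na(x) && x > t
    lt <- function(x, t) !is.na(x) && x < t
    pass <- function(x, t) is.na(x) || x > t     # absent rank sums pass
    gt(r$QUAL, 30) && gt(r$QD, 5) && lt(r$FS, 60) && gt(r$MQ, 40) &&
      pass(r$MQRankSum, -12.5) && pass(r$ReadPosRankSum, -8)
  }, TRUE)
}

oracleClusterFilter <- function(pos, window = 10, minCount = 3) {
  # any window holding >= minCount SNPs can be slid right until its left
  # edge touches a SNP, so windows anchored at SNP positions suffice
  drop <- rep(FALSE, length(pos))
  for (w in unique(pos)) {
    members <- which(pos >= w & pos <= w + window - 1)
    if (length(members) >= minCount) drop[members] <- TRUE
  }
  !drop
}

mkVariants <- function(pos, ..., gt = NULL, nSamples = 2) {
  info <- data.frame(chrom = "chr1", pos = pos, QUAL = 50, QD = 10,
                     FS = 1, MQ = 60, ...)
  if (is.null(gt)) gt <- matrix("0/1", length(pos), nSamples)
  VariantTable(info, gt)
}

test_that("hard filters use strict inequalities at the printed thresholds", {
  info <- data.frame(
    chrom = "chr1", pos = 1:6,
    QUAL = c(29.9, 30.0, 50, 50, 50, 50),
    QD = c(10, 10, 5.0, 10, 10, 10),
    FS = c(1, 1, 1, 60.0, 1, 1),
    MQ = c(60, 60, 60, 60, 40.0, 60),
    MQRankSum = c(0, 0, 0, 0, 0, -12.5),
    ReadPosRankSum = 0)
  f <- applyHardFilters(VariantTable(info, matrix("0/1", 6, 1)))
  expect_equal(f$report$verdict,
               c("QUAL", "QUAL", "QD", "FS", "MQ", "MQRankSum"))
  expect_equal(nVariants(f$variants), 0)
  expect_equal(sum(f$counts), 6)
})

test_that("absent rank-sum annotations do not fail their rules", {
  info <- data.frame(chrom = "chr1", pos = 1, QUAL = 50, QD = 10, FS = 1,
                     MQ = 60, MQRankSum = NA_real_,
                     ReadPosRankSum = NA_real_)
  f <- applyHardFilters(VariantTable(info, matrix("0/1", 1, 1)))
  expect_equal(f$report$verdict, "PASS")
})

test_that("malformed annotations get their own rejection label", {
  d <- withr::local_tempdir()
  vt <- mkVariants(c(100, 200))
  p <- file.path(d, "v.vcf")
  writeVariantVcf(vt, p)
  lines <- readLines(p)
  lines[length(lines)] <- sub("QD=10", "QD=abc", lines[length(lines)])
  writeLines(lines, p)
  back <- readVariantVcf(p)
  expect_identical(variantInfo(back)$malformed, c(FALSE, TRUE))
  f <- applyHardFilters(back)
  expect_equal(f$report$verdict[2], "MALFORMED")
})

test_that("hard-filter survivors equal the brute-force predicate oracle", {
  vt <- randomVariants(10000, nSamples = 4, seed = 31)
  f <- applyHardFilters(vt)
  expect_identical(f$report$verdict == "PASS", oracleHardFilter(variantInfo(vt)))
  expect_equal(sum(f$counts), 10000)
})

test_that("cluster rule matches a brute-force sliding-window scan", {
  expect_equal(variantInfo(removeClusteredSnps(
    mkVariants(c(100, 105, 109))))$pos, numeric(0))
  expect_equal(variantInfo(removeClusteredSnps(
    mkVariants(c(100, 105, 120))))$pos, c(100, 105, 120))
  expect_equal(variantInfo(removeClusteredSnps(mkVariants(500)))$pos, 500)
  expect_error(removeClusteredSnps(mkVariants(c(200, 100, 300))), "sort")

  withr::with_seed(17, {
    for (rep_i in 1:20) {
      pos <- sort(sample.int(300, 60))
      vt <- mkVariants(pos)
      kept <- variantInfo(removeClusteredSnps(vt))$pos
      expect_identical(kept, pos[oracleClusterFilter(pos)])
    }
  })
})

test_that("call-rate filter applies the 0.8 boundary as specified", {
  gtRow <- function(nCalled, nTotal)
    matrix(c(rep("0/1", nCalled), rep("./.", nTotal - nCalled)), 1)
  v63 <- mkVariants(100, gt = gtRow(63, 79))
  v64 <- mkVariants(100, gt = gtRow(64, 79))
  expect_equal(nVariants(applyCallRateFilter(v63)), 0)   # 63/79 < 0.8
  expect_equal(nVariants(applyCallRateFilter(v64)), 1)   # 64/79 > 0.8
  vAll <- mkVariants(100, gt = gtRow(5, 5))
  expect_equal(nVariants(applyCallRateFilter(vAll)), 1)
  expect_error(applyCallRateFilter(VariantTable(
    data.frame(chrom = "chr1", pos = 1), matrix(character(0), 1, 0))))
})

test_that("all three filters are idempotent and jointly match their oracles", {
  vt <- randomVariants(2000, nSamples = 10, seed = 32)
  hard <- applyHardFilters(vt)$variants
  expect_identical(applyHardFilters(hard)$variants@info, hard@info)
  uncl <- removeClusteredSnps(hard)
  expect_identical(removeClusteredSnps(uncl)@info, uncl@info)
  cr <- applyCallRateFilter(uncl)
  expect_identical(applyCallRateFilter(cr)@info, cr@info)

  # survivor set equals the independently composed oracles
  info <- variantInfo(vt)
  keep1 <- oracleHardFilter(info)
  pos1 <- info$pos[keep1]
  keep2 <- oracleClusterFilter(pos1)
  gt <- genotypes(vt)[keep1, , drop = FALSE][keep2, , drop = FALSE]
  keep3 <- rowMeans(gt != "./.") >= 0.8
  expect_identical(variantInfo(cr)$pos, pos1[keep2][keep3])
})

test_that("hard filters and call-rate filter commute", {
  vt <- randomVariants(1500, nSamples = 8, seed = 33)
  a <- applyCallRateFilter(applyHardFilters(vt)$variants)
  b <- applyHardFilters(applyCallRateFilter(vt))$variants
  expect_identical(a@info, b@info)
  expect_identical(a@genotypes, b@genotypes)
})
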