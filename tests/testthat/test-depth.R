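mkAln <- function(pos, mappedLen, sample = "s1", rname = "chr1") {
  n <- length(pos)
  data.frame(qname = sprintf("q%d", seq_len(n)), sample = sample,
             rname = rname, mapped = TRUE, pos = pos,
             mappedLen = mappedLen, leftClip = 0, rightClip = 0,
             strand = "+", seq = "", qual = "", matePos = pos,
             mateMapped = TRUE, isize = mappedLen, first = TRUE,
             properPair = TRUE, stringsAsFactors = FALSE)
}

test_that("pooled depth counts mapped non-clipped bases", {
  ref <- ReferenceRegion("chr1", 1, strrep("A", 1000))
  d <- pooledDepth(mkAln(101, 150), "s1", ref)
  expect_equal(d[100], 0)
  expect_true(all(d[101:250] == 1))
  expect_equal(d[251], 0)
  expect_equal(sum(d), 150)

  d2 <- pooledDepth(mkAln(c(101, 201), c(150, 150)), "s1", ref)
  expect_true(all(d2[201:250] == 2))

  # soft-clipped bases never contribute
  a <- mkAln(101, 100)
  a$rightClip <- 50
  expect_equal(sum(pooledDepth(a, "s1", ref)), 100)
})

test_that("depth conservation: total depth equals total mapped read bases", {
  st <- toyStudy(len = 30000, offset = 1, delStart = 15001, delLen = 2000,
                 ins = "GGTGCGGTGA", seed = 14)
  sim <- simulateReadPairs("s1", list(st$del, st$wt), coverage = 8,
                           readLen = 100, fragMean = 300, fragSd = 30,
                           seed = 15)
  a <- sim$alignments
  d <- pooledDepth(a, "s1", st$ref)
  expect_equal(sum(d), sum(a$mappedLen[a$mapped]))
})

test_that("log ratio is zero for equal pools, symmetric and scale-invariant", {
  dA <- c(rep(10, 50), rep(0, 20), rep(10, 30))
  dB <- rep(10, 100)
  expect_true(all(logDepthRatio(dB, dB) == 0))
  r <- logDepthRatio(dA, dB, normalize = FALSE)
  expect_equal(logDepthRatio(dB, dA, normalize = FALSE), -r)
  # doubling both pools leaves the normalized ratio unchanged up to the
  # pseudocount's influence (dominant only where a pool has zero depth)
  r1 <- logDepthRatio(dA, dB, pseudocount = 0.01)
  r2 <- logDepthRatio(2 * dA, 2 * dB, pseudocount = 0.01)
  nz <- dA > 0 & dB > 0
  expect_equal(r1[nz], r2[nz], tolerance = 0.02)
  expect_true(all(r2[!nz] <= r1[!nz]))   # zeros only get more extreme
  expect_error(logDepthRatio(dA, dB[1:10]), "equal length")
  expect_error(logDepthRatio(dA, dB, pseudocount = 0), "pseudocount")
})

test_that("deletion depth signature: zero in del/del pools, halved in het pools", {
  cfg <- smallConfig(seed = 16, nCases = 4, nControls = 4, coverage = 5)
  cfg$cohort$hetFractionControls <- 1          # controls all wt/del
  sim <- simulateStudy(cfg)
  lyPool <- sim$cohort$sample_id[sim$cohort$phenotype == "LY"]
  drPool <- sim$cohort$sample_id[sim$cohort$phenotype == "DR"]
  dLY <- pooledDepth(sim$alignments, lyPool, sim$ref)
  dDR <- pooledDepth(sim$alignments, drPool, sim$ref)
  inside <- (cfg$edit$delStart:(cfg$edit$delEnd - 1)) - cfg$region$offset + 1
  inside <- inside[500:(length(inside) - 500)]  # clear of junction edges
  flank <- 1:4000
  expect_equal(mean(dLY[inside]), 0)
  expect_equal(mean(dDR[inside]) / mean(dDR[flank]), 0.5, tolerance = 0.15)
})

test_that("candidate segments recover the deleted interval", {
  cfg <- smallConfig(seed = 17, nCases = 4, nControls = 4, coverage = 5)
  sim <- simulateStudy(cfg)
  lyPool <- sim$cohort$sample_id[sim$cohort$phenotype == "LY"]
  drPool <- sim$cohort$sample_id[sim$cohort$phenotype == "DR"]
  ratio <- logDepthRatio(pooledDepth(sim$alignments, drPool, sim$ref),
                         pooledDepth(sim$alignments, lyPool, sim$ref))
  segs <- callCandidateSegments(ratio, sim$ref)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$direction, "A>B")
  truth <- c(cfg$edit$delStart, cfg$edit$delEnd - 1)
  overlap <- min(segs$end, truth[2]) - max(segs$start, truth[1]) + 1
  expect_gt(overlap / (7638), 0.9)

  # flat or sub-threshold tracks yield nothing
  expect_equal(nrow(callCandidateSegments(rep(0, 5000), sim$ref)), 0)
  expect_equal(nrow(callCandidateSegments(ratio, sim$ref,
                                          threshold = max(abs(ratio)) + 1)),
               0)
})

test_that("segment recovery holds across seeded simulations (Jaccard >= 0.8)", {
  hits <- 0
  nSeeds <- 20
  for (seed in seq_len(nSeeds)) {
    cfg <- smallConfig(seed = 1000 + seed, nCases = 5, nControls = 5,
                       coverage = 5, length = 60000L, offset = 51010000)
    sim <- simulateStudy(cfg)
    lyPool <- sim$cohort$sample_id[sim$cohort$phenotype == "LY"]
    drPool <- sim$cohort$sample_id[sim$cohort$phenotype == "DR"]
    ratio <- logDepthRatio(pooledDepth(sim$alignments, drPool, sim$ref),
                           pooledDepth(sim$alignments, lyPool, sim$ref))
    segs <- callCandidateSegments(ratio, sim$ref)
    if (nrow(segs) == 0) next
    seg <- segs[which.max(abs(segs$meanRatio)), ]
    truth <- c(cfg$edit$delStart, cfg$edit$delEnd - 1)
    ov <- max(0, min(seg$end, truth[2]) - max(seg$start, truth[1]) + 1)
    un <- max(seg$end, truth[2]) - min(seg$start, truth[1]) + 1
    if (ov / un >= 0.8) hits <- hits + 1
  }
  expect_gte(hits, 18)
})
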