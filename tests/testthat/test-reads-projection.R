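test_that("pair count follows the coverage formula and output is deterministic", {
  st <- toyStudy(len = 200000, offset = 50935000, delStart = 51035106,
                 delLen = 7638, ins = "GGTGCGGTGA", seed = 1)
  sim <- simulateReadPairs("wt01", list(st$wt, st$wt), coverage = 5,
                           readLen = 150, fragMean = 500, fragSd = 50,
                           seed = 3)
  expect_equal(nrow(sim$reads), 5 * 200000 / (2 * 150), tolerance = 0.05)

  sim2 <- simulateReadPairs("wt01", list(st$wt, st$wt), coverage = 5,
                            readLen = 150, fragMean = 500, fragSd = 50,
                            seed = 3)
  expect_identical(sim, sim2)

  # byte-identical FASTQ under a fixed seed
  d <- withr::local_tempdir()
  writeReadsFastq(sim$reads, file.path(d, "a"))
  writeReadsFastq(sim2$reads, file.path(d, "b"))
  expect_identical(readLines(file.path(d, "a_1.fastq")),
                   readLines(file.path(d, "b_1.fastq")))
  expect_error(simulateReadPairs("x", list(st$wt, st$wt), readLen = 600,
                                 fragMean = 500), "fragMean")
})

test_that("realized depth matches nominal coverage", {
  st <- toyStudy(len = 60000, offset = 1, delStart = 30001, delLen = 5000,
                 ins = "", seed = 2)
  sim <- simulateReadPairs("s1", list(st$wt, st$wt), coverage = 5,
                           readLen = 150, fragMean = 500, fragSd = 50,
                           seed = 4)
  depth <- pooledDepth(sim$alignments, "s1", st$ref)
  expect_equal(mean(depth), 5.0, tolerance = 0.3 / 5)
  expect_lt(abs(mean(depth) - 5.0), 0.3)
})

test_that("apparent insert equals fragment span, inflated across the deletion", {
  st <- toyStudy(len = 200000, offset = 50935000, delStart = 51035106,
                 delLen = 7638, ins = "GGTGCGGTGA", seed = 1)
  map <- st$del$map
  A <- 51035106 - 50935000 + 1 - 1   # hap position of last left-flank base

  # fragment of length 500 entirely left of the deletion
  p <- data.frame(qname = "f1", s1 = 1000, e1 = 1149, s2 = 1350, e2 = 1499)
  a <- projectAlignment(map, p)
  expect_equal(a$isize, c(500, -500))
  expect_true(all(a$mapped), info = "no edit crossed")
  expect_true(all(a$leftClip == 0 & a$rightClip == 0))

  # fragment of length 500 with mates flanking the full edit
  p2 <- data.frame(qname = "f2", s1 = A - 200, e1 = A - 51,
                   s2 = A + 150, e2 = A + 299)
  a2 <- projectAlignment(map, p2)
  expect_equal(a2$isize, c(500 + 7638 - 10, -(500 + 7638 - 10)))
})

test_that("junction-crossing reads are clipped correctly at every offset", {
  st <- toyStudy(len = 2000, offset = 1, delStart = 901, delLen = 150,
                 ins = "GGTGCGGTGA", seed = 6)
  map <- st$del$map
  A <- 900           # last left-flank haplotype position
  readLen <- 100
  insLen <- 10
  for (k in 1:(readLen - 1)) {     # k bases of the read precede the junction
    s <- A - k + 1; e <- s + readLen - 1
    a <- projectAlignment(map, data.frame(qname = "r", s1 = s, e1 = e,
                                          s2 = s, e2 = e))[1, ]
    lenL <- k
    lenR <- max(0, readLen - k - insLen)
    if (max(lenL, lenR) < 20) {
      expect_false(a$mapped)
      next
    }
    if (lenL >= lenR) {            # anchored left, clipped on the right
      expect_true(a$mapped)
      expect_equal(a$mappedLen, lenL)
      expect_equal(a$rightClip, readLen - lenL)
      expect_equal(a$pos, s)       # offset 1: hap == ref left of the edit
    } else {                       # anchored right, clipped on the left
      expect_true(a$mapped)
      expect_equal(a$mappedLen, lenR)
      expect_equal(a$leftClip, readLen - lenR)
      expect_equal(a$pos, 901 + 150)  # first retained reference base
    }
  }
})

test_that("projected alignments agree with brute-force alignment on a toy edit", {
  st <- toyStudy(len = 2000, offset = 1, delStart = 1001, delLen = 180,
                 ins = "TTGGCCAA", seed = 7)
  refChar <- as.character(refSequence(st$ref))
  sim <- simulateReadPairs("s1", list(st$del, st$del), coverage = 20,
                           readLen = 80, fragMean = 200, fragSd = 20,
                           errorRate = 0, seed = 8)
  a <- sim$alignments
  expect_gt(sum(a$mapped), 0)
  for (i in which(a$mapped)) {
    mappedPart <- substr(a$seq[i], a$leftClip[i] + 1,
                         a$leftClip[i] + a$mappedLen[i])
    refPart <- substr(refChar, a$pos[i], a$pos[i] + a$mappedLen[i] - 1)
    expect_identical(mappedPart, refPart)
  }
  # exhaustive-scan oracle for fully mapped reads: the projected position
  # is among the exact occurrences of the read in the reference
  full <- which(a$mapped & a$leftClip == 0 & a$rightClip == 0)
  for (i in full) {
    hits <- Biostrings::start(Biostrings::matchPattern(a$seq[i],
                                                       refSequence(st$ref)))
    expect_true(a$pos[i] %in% hits)
  }
})

test_that("reads entirely inside a long insertion are flagged unmapped", {
  st <- toyStudy(len = 2000, offset = 1, delStart = 1001, delLen = 100,
                 ins = strrep("ACGT", 50), seed = 9)   # 200 bp insertion
  map <- st$del$map
  # 80 bp read fully inside the 200 bp insertion: hap [1001, 1200]
  a <- projectAlignment(map, data.frame(qname = "r", s1 = 1050, e1 = 1129,
                                        s2 = 1050, e2 = 1129))
  expect_false(any(a$mapped))
  expect_equal(a$isize, c(0, 0))
})
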