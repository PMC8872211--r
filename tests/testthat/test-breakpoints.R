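test_that("clip clusters form only at the junction, one per side", {
  st <- toyStudy(len = 30000, offset = 1, delStart = 12001, delLen = 3000,
                 ins = "GGTGCGGTGA", seed = 40)
  sim <- simulateReadPairs("s1", list(st$del, st$del), coverage = 20,
                           readLen = 150, fragMean = 400, fragSd = 40,
                           errorRate = 0, seed = 41)
  cl <- collectClipClusters(sim$alignments, minSupport = 2)
  sides <- vapply(cl, `[[`, "", "side")
  edges <- vapply(cl, `[[`, 0, "edge")
  expect_setequal(sides, c("left", "right"))
  expect_equal(sort(unique(edges)), c(12000, 15001))
  expect_equal(sum(sides == "right"), 1)   # right-clipped: left flank end
  expect_equal(sum(sides == "left"), 1)    # left-clipped: right flank start

  # unclipped alignments produce no clusters; short clips are ignored
  wt <- simulateReadPairs("s2", list(st$wt, st$wt), coverage = 5,
                          readLen = 150, fragMean = 400, fragSd = 40,
                          errorRate = 0, seed = 42)
  expect_length(collectClipClusters(wt$alignments), 0)
  expect_length(collectClipClusters(sim$alignments, minClip = 200), 0)
})

test_that("junction consensus spells left flank + insertion + right flank", {
  st <- toyStudy(len = 30000, offset = 1, delStart = 12001, delLen = 3000,
                 ins = "GGTGCGGTGA", seed = 40)
  sim <- simulateReadPairs("s1", list(st$del, st$del), coverage = 30,
                           readLen = 150, fragMean = 400, fragSd = 40,
                           errorRate = 0, seed = 43)
  cl <- collectClipClusters(sim$alignments)
  sides <- vapply(cl, `[[`, "", "side")
  cons <- junctionConsensus(cl[sides == "left"][[1]],
                            cl[sides == "right"][[1]])
  refChar <- as.character(refSequence(st$ref))
  core <- paste0(substr(refChar, 11971, 12000), "GGTGCGGTGA",
                 substr(refChar, 15001, 15030))   # 30 bp flanks + insertion
  expect_true(grepl(core, as.character(cons), fixed = TRUE))
  # swapped argument order is detected and handled
  cons2 <- junctionConsensus(cl[sides == "right"][[1]],
                             cl[sides == "left"][[1]])
  expect_identical(as.character(cons), as.character(cons2))
  expect_error(junctionConsensus(cl[sides == "left"][[1]],
                                 cl[sides == "left"][[1]]),
               "left-clipped")
})

test_that("a minority substituted base does not change the consensus", {
  cluster <- function(side, edge, clips, anchors)
    list(side = side, edge = edge, clips = clips, anchors = anchors,
         support = length(clips))
  right <- cluster("right", 100, clips = rep("GGTGCGGTGAACGT", 10),
                   anchors = rep("TTTTTCCCCCGGGGGAAAAA", 10))
  corrupt <- right
  corrupt$clips[3] <- "GGTGCGGTGAACGA"        # one substituted base
  left <- cluster("left", 200, clips = rep("AACCGGTTGGTGCGGTGA", 10),
                  anchors = rep("CCCCCTTTTTAAAAAGGGGG", 10))
  expect_identical(as.character(junctionConsensus(left, right)),
                   as.character(junctionConsensus(left, corrupt)))
})

test_that("breakpoints and insertion are recovered exactly for random edits", {
  # 50 random deletion-with-insertion edits on toy references
  withr::with_seed(1234, {
    nExact <- 0
    for (k in 1:50) {
      len <- 20000
      delLen <- sample(200:2000, 1)
      insLen <- sample(0:20, 1)
      ins <- paste(sample(c("A", "C", "G", "T"), insLen, replace = TRUE),
                   collapse = "")
      s <- sample(5000:10000, 1)
      ref <- buildReference(len, offset = 1, gc = 0.45,
                            seed = sample.int(1e6, 1))
      edit <- HaplotypeEdit(s, s + delLen, ins)
      del <- applyEdit(ref, edit)
      sim <- simulateReadPairs("s1", list(del, del), coverage = 30,
                               readLen = 150, fragMean = 400, fragSd = 40,
                               errorRate = 0, seed = sample.int(1e6, 1))
      call <- resolveDeletion(sim$alignments, ref)
      truth <- canonicalEdit(ref, edit)
      if (call@status == "resolved" &&
          call@delStart == delStart(truth) &&
          call@delEnd == delEnd(truth) &&
          call@insertedSeq == insertedSeq(truth)) nExact <- nExact + 1
    }
    expect_equal(nExact, 50)
  })
})

test_that("recovery tolerates sequencing errors at deep coverage", {
  withr::with_seed(777, {
    nExact <- 0
    for (k in 1:25) {
      ref <- buildReference(20000, offset = 1, gc = 0.45,
                            seed = sample.int(1e6, 1))
      edit <- HaplotypeEdit(8000, 8000 + sample(500:1500, 1), "GGTGCGGTGA")
      del <- applyEdit(ref, edit)
      sim <- simulateReadPairs("s1", list(del, del), coverage = 30,
                               readLen = 150, fragMean = 400, fragSd = 40,
                               errorRate = 0.001, seed = sample.int(1e6, 1))
      call <- resolveDeletion(sim$alignments, ref)
      truth <- canonicalEdit(ref, edit)
      if (call@status == "resolved" &&
          call@delStart == delStart(truth) &&
          call@delEnd == delEnd(truth) &&
          call@insertedSeq == insertedSeq(truth)) nExact <- nExact + 1
    }
    # >= 95% exact recovery at 0.1% substitution error and 30X
    expect_gte(nExact / 25, 0.95)
  })
})

test_that("missing evidence yields an informative no-call, never a bogus call", {
  st <- toyStudy(len = 20000, offset = 1, delStart = 9001, delLen = 800,
                 ins = "", seed = 50)
  wt <- simulateReadPairs("s1", list(st$wt, st$wt), coverage = 10,
                          readLen = 150, fragMean = 400, fragSd = 40,
                          errorRate = 0, seed = 51)
  call <- resolveDeletion(wt$alignments, st$ref)
  expect_equal(call@status, "no_call")
  expect_match(call@diagnostic, "cluster")
  # consensus too short to anchor
  short <- resolveBreakpoints("ACGTACGT", st$ref)
  expect_equal(short@status, "no_call")
})

test_that("deletion length is consistent with the insert-size estimate", {
  cfg <- smallConfig(seed = 52, nCases = 4, nControls = 4, coverage = 8)
  sim <- simulateStudy(cfg)
  ly <- sim$cohort$sample_id[sim$cohort$phenotype == "LY"]
  dr <- sim$cohort$sample_id[sim$cohort$phenotype == "DR"]
  caseAln <- sim$alignments[sim$alignments$sample %in% ly, ]
  call <- resolveDeletion(caseAln, sim$ref)
  expect_equal(call@status, "resolved")
  region <- c(cfg$edit$delStart - 2000, cfg$edit$delEnd + 2000)
  sv <- classifySV(
    extractApparentInserts(sim$alignments, region, "LY", ly),
    extractApparentInserts(sim$alignments, region, "DR", dr),
    cfg$reads$fragMean, cfg$reads$fragSd)
  expect_equal(call@deletionLength,
               netSize(sv) + nchar(call@insertedSeq),
               tolerance = 2 * cfg$reads$fragSd /
                 sqrt(sv@support) / call@deletionLength * 3)
})
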