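# Shared fixtures: small references, edits and cohorts built in code.

toyStudy <- function(len = 2000, offset = 1, delStart = 801, delLen = 200,
                     ins = "GGTGCGGTGA", seed = 101) {
  ref <- buildReference(len, offset = offset, gc = 0.5, seed = seed)
  edit <- HaplotypeEdit(delStart, delStart + delLen, ins)
  list(ref = ref, edit = edit,
       wt = applyEdit(ref, HaplotypeEdit(delStart, delStart, "")),
       del = applyEdit(ref, edit))
}

# A small synthetic study configuration scaled for unit tests.
smallConfig <- function(seed = 5, nCases = 3, nControls = 3,
                        coverage = 5, length = 40000L,
                        offset = 51030000) {
  cfg <- defaultConfig(seed)
  cfg$region$length <- as.integer(length)
  cfg$region$offset <- offset
  cfg$cohort <- list(nCases = nCases, nControls = nControls,
                     hetFractionControls = 0.5)
  cfg$snps$n <- 40L
  cfg$reads$coverage <- coverage
  cfg$depth$poolSize <- min(nCases, nControls)
  cfg
}

# Random 2x2 allele table with positive margins.
randomAlleleTable <- function() {
  repeat {
    tab <- matrix(sample(0:40, 4, replace = TRUE), 2, 2)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) return(tab)
  }
}

# Random VariantTable with annotations drawn from a 50/50 pass/fail
# mixture per rule and genotypes with missingness.
randomVariants <- function(n, nSamples = 10, seed = 1) {
  withr::with_seed(seed, {
    pick <- function(passLo, passHi, failLo, failHi) {
      ifelse(runif(n) < 0.5, runif(n, passLo, passHi),
             runif(n, failLo, failHi))
    }
    info <- data.frame(
      chrom = "chr1", pos = sort(sample.int(n * 50, n)),
      id = sprintf("v%d", seq_len(n)), ref = "A", alt = "C",
      QUAL = pick(30.01, 500, 0, 30), QD = pick(5.01, 40, 0, 5),
      FS = pick(0, 59.99, 60, 150), MQ = pick(40.01, 70, 0, 40),
      MQRankSum = pick(-12.49, 10, -25, -12.5),
      ReadPosRankSum = pick(-7.99, 8, -20, -8),
      stringsAsFactors = FALSE)
    info$MQRankSum[runif(n) < 0.1] <- NA
    info$ReadPosRankSum[runif(n) < 0.1] <- NA
    gt <- matrix(sample(c("0/0", "0/1", "1/1", "./."), n * nSamples,
                        replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1)),
                 n, nSamples)
    colnames(gt) <- sprintf("s%02d", seq_len(nSamples))
    VariantTable(info, gt)
  })
}
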