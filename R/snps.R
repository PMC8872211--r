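#' Construct a VariantTable
#'
#' @param info data.frame of per-variant fields (see
#'   [VariantTable-class]); missing annotation columns are filled with NA
#'   and `malformed` defaults to FALSE.
#' @param genotypes Character matrix (variants x samples) of VCF-style
#'   diploid genotype codes.
#' @return A [VariantTable-class].
#' @export
VariantTable <- function(info, genotypes) {
  defaults <- list(id = ".", ref = "N", alt = "N", QUAL = NA_real_,
                   QD = NA_real_, FS = NA_real_, MQ = NA_real_,
                   MQRankSum = NA_real_, ReadPosRankSum = NA_real_,
                   malformed = FALSE)
  for (nm in names(defaults))
    if (is.null(info[[nm]])) info[[nm]] <- defaults[[nm]]
  genotypes <- as.matrix(genotypes)
  if (is.null(colnames(genotypes)) && ncol(genotypes) > 0)
    colnames(genotypes) <- sprintf("S%03d", seq_len(ncol(genotypes)))
  rownames(genotypes) <- NULL
  rownames(info) <- NULL
  new("VariantTable", info = info, genotypes = genotypes)
}

#' Plant SNPs in linkage disequilibrium with a deletion allele
#'
#' Assigns `nSnps` positions outside the deleted interval and draws
#' per-sample genotypes so that each SNP's squared correlation with the
#' deletion allele decays with distance from the nearest breakpoint as
#' `r2AtZero * exp(-distance / decayBp)`. On each haplotype the SNP
#' allele copies the deletion indicator with a copy probability, and is
#' otherwise an independent draw at the deletion-allele frequency; the
#' copy probability is calibrated so the realized genotype-level r2
#' matches the target, accounting for the within-sample haplotype
#' correlation a case-control cohort induces, while preserving the
#' marginal allele frequency.
#'
#' @param ref A [ReferenceRegion-class].
#' @param edit The causal [HaplotypeEdit-class].
#' @param cohort Sample sheet from [simulateCohort()].
#' @param nSnps Number of SNPs (>= 1).
#' @param r2AtZero LD with the deletion at distance zero, in [0, 1].
#' @param decayBp Exponential decay scale of LD with distance (bp).
#' @param seed Integer seed.
#' @param missingRate Fraction of genotypes set to missing ("./.").
#' @return A [VariantTable-class] with one row per SNP, annotation fields
#'   NA (use [simulateAnnotations()] to fill them), and attribute
#'   `truth`: a data.frame of position, distance and target r2.
#' @export
plantLinkedSnps <- function(ref, edit, cohort, nSnps, r2AtZero = 1.0,
                            decayBp = 20000, seed = 1, missingRate = 0.02) {
  if (nSnps < 1) stop("'nSnps' must be >= 1")
  if (r2AtZero < 0 || r2AtZero > 1) stop("'r2AtZero' must lie in [0, 1]")
  off <- refOffset(ref)
  L <- regionLength(ref)
  refChar <- as.character(refSequence(ref))
  hapDel <- delHaplotypes(cohort)
  p <- mean(hapDel)                       # deletion-allele frequency
  n <- nrow(cohort)
  ## In a case-control cohort the two haplotypes of a sample are
  ## correlated (cases are all del/del), which would inflate the realized
  ## genotype-level r2 above the haplotype copy probability squared.
  ## Calibrate the copy probability so the genotype-level r2 hits the
  ## target: with V0 = 2p(1-p) and C = 2 cov(hapA, hapB),
  ## r2(q) = q^2 (V0 + C) / (V0 + q^2 C), solved for q^2 below.
  V0 <- 2 * p * (1 - p)
  C <- 2 * (mean(hapDel[, 1] * hapDel[, 2]) - p^2)
  qFor <- function(r2) {
    if (V0 <= 0) return(0)
    sqrt(pmin(1, r2 * V0 / (V0 + C * (1 - r2))))
  }

  withSeed(seed, {
    ## positions: uniform over the region, redrawn on collision with the
    ## deleted interval
    pos <- numeric(0)
    while (length(pos) < nSnps) {
      cand <- off + sample.int(L, nSnps - length(pos), replace = FALSE) - 1
      cand <- cand[cand < delStart(edit) | cand >= delEnd(edit)]
      pos <- unique(c(pos, cand))
    }
    pos <- sort(pos[seq_len(nSnps)])
    dist <- pmin(abs(pos - delStart(edit)), abs(pos - delEnd(edit)))
    dist[pos >= delStart(edit) & pos < delEnd(edit)] <- 0
    r2 <- r2AtZero * exp(-dist / decayBp)
    q <- qFor(r2)                         # calibrated copy probability

    gt <- matrix("", nrow = nSnps, ncol = n)
    for (i in seq_len(nSnps)) {
      copyA <- runif(n) < q[i]
      copyB <- runif(n) < q[i]
      yA <- ifelse(copyA, hapDel[, "A"], rbinom(n, 1, p))
      yB <- ifelse(copyB, hapDel[, "B"], rbinom(n, 1, p))
      gt[i, ] <- paste(pmin(yA, yB), pmax(yA, yB), sep = "/")
    }
    if (missingRate > 0) {
      miss <- matrix(runif(nSnps * n) < missingRate, nSnps, n)
      gt[miss] <- "./."
    }
  })
  colnames(gt) <- cohort$sample_id

  refBase <- substring(refChar, pos - off + 1, pos - off + 1)
  altBase <- vapply(refBase, function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                    "", USE.NAMES = FALSE)
  info <- data.frame(chrom = refName(ref), pos = pos,
                     id = sprintf("snp%05d", seq_len(nSnps)),
                     ref = refBase, alt = altBase,
                     stringsAsFactors = FALSE)
  vt <- VariantTable(info, gt)
  attr(vt, "truth") <- data.frame(pos = pos, distance = dist, r2 = r2)
  vt
}

#' Draw variant-calling annotations for filter testing
#'
#' Fills QUAL/QD/FS/MQ/MQRankSum/ReadPosRankSum with values drawn either
#' from a passing range or, independently per rule with probability
#' `failRate`, from a failing range, so hard-filter behaviour can be
#' exercised with a known expected outcome. Rank-sum annotations are set
#' to NA (undefined) with probability `absentRate` instead.
#'
#' @param variants A [VariantTable-class].
#' @param failRate Per-rule probability of a failing value.
#' @param absentRate Probability that a rank-sum annotation is absent.
#' @param seed Integer seed.
#' @return The [VariantTable-class] with annotation columns filled.
#' @export
simulateAnnotations <- function(variants, failRate = 0.05,
                                absentRate = 0.1, seed = 1) {
  n <- nVariants(variants)
  draw <- function(passLo, passHi, failLo, failHi) {
    fail <- runif(n) < failRate
    ifelse(fail, runif(n, failLo, failHi), runif(n, passLo, passHi))
  }
  info <- variants@info
  withSeed(seed, {
    info$QUAL <- draw(30.01, 2000, 0, 30)        # rule: QUAL > 30
    info$QD <- draw(5.01, 40, 0, 5)              # rule: QD > 5
    info$FS <- draw(0, 59.9, 60, 200)            # rule: FS < 60
    info$MQ <- draw(40.01, 70, 0, 40)            # rule: MQ > 40
    info$MQRankSum <- draw(-12.4, 12.5, -30, -12.5)   # rule: > -12.5
    info$ReadPosRankSum <- draw(-7.9, 8, -20, -8)     # rule: > -8
    absent <- runif(n) < absentRate
    info$MQRankSum[absent] <- NA
    info$ReadPosRankSum[absent] <- NA
  })
  variants@info <- info
  validObject(variants)
  variants
}

#' Subset a VariantTable by row index
#'
#' @param x A [VariantTable-class].
#' @param i Integer or logical row index.
#' @return The subset [VariantTable-class].
#' @export
subsetVariants <- function(x, i) {
  VariantTable(x@info[i, , drop = FALSE],
               x@genotypes[i, , drop = FALSE])
}
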