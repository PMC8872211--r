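#' Default hard-filter thresholds for SNP calls
#'
#' The six thresholds applied by [applyHardFilters()]: a variant survives
#' only if QUAL > 30, QD > 5, FS < 60, MQ > 40, MQRankSum > -12.5 and
#' ReadPosRankSum > -8, all inequalities strict. Absent (NA) rank-sum
#' annotations do not fail their rule: those statistics are undefined at
#' sites without the heterozygous reads needed to compute them.
#'
#' @return Named list of thresholds.
#' @export
defaultHardFilters <- function() {
  list(qual = 30.0, qd = 5.0, fs = 60.0, mq = 40.0,
       mqRankSum = -12.5, readPosRankSum = -8.0)
}

#' Apply the six hard filters to SNP calls
#'
#' Each variant gets a verdict: "PASS", the label of the first failing
#' rule in the fixed order QUAL, QD, FS, MQ, MQRankSum, ReadPosRankSum,
#' or "MALFORMED" when an annotation could not be parsed as a number.
#'
#' @param variants A [VariantTable-class].
#' @param thresholds Named list as from [defaultHardFilters()].
#' @return List with `variants` (the survivors, a [VariantTable-class]),
#'   `report` (data.frame: id, pos, verdict) and `counts` (named verdict
#'   tally summing to the input size).
#' @examples
#' info <- data.frame(chrom = "chr1", pos = c(10, 20),
#'                    QUAL = c(29.9, 31), QD = 10, FS = 1, MQ = 50)
#' vt <- VariantTable(info, matrix("0/1", 2, 1))
#' applyHardFilters(vt)$counts
#' @export
applyHardFilters <- function(variants, thresholds = defaultHardFilters()) {
  info <- variantInfo(variants)
  n <- nrow(info)
  verdict <- rep("PASS", n)
  fail <- function(x, bad) !is.na(x) & bad      # NA annotation never fails
  rules <- list(
    QUAL = fail(info$QUAL, !(info$QUAL > thresholds$qual)) |
      is.na(info$QUAL),                          # QUAL is mandatory
    QD = fail(info$QD, !(info$QD > thresholds$qd)),
    FS = fail(info$FS, !(info$FS < thresholds$fs)),
    MQ = fail(info$MQ, !(info$MQ > thresholds$mq)),
    MQRankSum = fail(info$MQRankSum,
                     !(info$MQRankSum > thresholds$mqRankSum)),
    ReadPosRankSum = fail(info$ReadPosRankSum,
                          !(info$ReadPosRankSum > thresholds$readPosRankSum)))
  for (nm in rev(names(rules))) verdict[rules[[nm]]] <- nm
  verdict[isTRUE_v(info$malformed)] <- "MALFORMED"

  counts <- table(factor(verdict,
                         levels = c("PASS", names(rules), "MALFORMED")))
  list(variants = subsetVariants(variants, verdict == "PASS"),
       report = data.frame(id = info$id, pos = info$pos, verdict = verdict,
                           stringsAsFactors = FALSE),
       counts = counts)
}

isTRUE_v <- function(x) !is.na(x) & x

#' Remove clustered SNPs
#'
#' Any SNP that belongs to a set of at least `minCount` SNPs falling
#' within any `window`-bp stretch (positions p, q cluster when
#' `|p - q| <= window - 1`) is treated as a likely alignment artefact and
#' removed. Input must be sorted by (chrom, pos).
#'
#' @param variants A [VariantTable-class], position-sorted.
#' @param window Window size in bp (default 10).
#' @param minCount Minimum SNPs in a window to trigger removal (default 3).
#' @return The surviving [VariantTable-class].
#' @examples
#' info <- data.frame(chrom = "chr1", pos = c(100, 105, 109, 300),
#'                    QUAL = 50, QD = 10, FS = 1, MQ = 50)
#' vt <- VariantTable(info, matrix("0/1", 4, 1))
#' variantInfo(removeClusteredSnps(vt))$pos  # 300 survives
#' @export
removeClusteredSnps <- function(variants, window = 10, minCount = 3) {
  info <- variantInfo(variants)
  if (nrow(info) < 2) return(variants)
  o <- order(info$chrom, info$pos)
  if (any(o != seq_len(nrow(info))))
    stop("variants must be sorted by (chrom, pos); sort before filtering")
  drop <- rep(FALSE, nrow(info))
  for (chr in unique(info$chrom)) {
    idx <- which(info$chrom == chr)
    pos <- info$pos[idx]
    ## window anchored at each SNP: [pos_i, pos_i + window - 1]
    hi <- findInterval(pos + window - 1, pos)
    bad <- (hi - seq_along(pos) + 1) >= minCount
    for (i in which(bad)) drop[idx[i:hi[i]]] <- TRUE
  }
  subsetVariants(variants, !drop)
}

#' Remove SNPs with a low genotype call rate
#'
#' A variant survives when the fraction of samples with a non-missing
#' genotype is at least `minRate`.
#'
#' @param variants A [VariantTable-class].
#' @param minRate Minimum call rate (default 0.8).
#' @return The surviving [VariantTable-class].
#' @export
applyCallRateFilter <- function(variants, minRate = 0.8) {
  gt <- genotypes(variants)
  if (ncol(gt) == 0) stop("call-rate filter needs at least one sample")
  rate <- rowMeans(gt != "./." & gt != ".")
  subsetVariants(variants, rate >= minRate)
}

#' Run the full SNP filter chain
#'
#' Hard filters, then the clustered-SNP rule, then the call-rate rule —
#' the pipeline order used throughout the package.
#'
#' @param variants A [VariantTable-class].
#' @param thresholds Hard-filter thresholds ([defaultHardFilters()]).
#' @param clusterWindow,clusterCount Clustered-SNP rule parameters.
#' @param callRate Minimum genotype call rate.
#' @return List with `variants` (survivors) and `report` (stage counts).
#' @export
filterVariants <- function(variants, thresholds = defaultHardFilters(),
                           clusterWindow = 10, clusterCount = 3,
                           callRate = 0.8) {
  hard <- applyHardFilters(variants, thresholds)
  unclustered <- removeClusteredSnps(hard$variants, clusterWindow,
                                     clusterCount)
  final <- applyCallRateFilter(unclustered, callRate)
  list(variants = final,
       report = list(
         input = nVariants(variants),
         hardFilterCounts = hard$counts,
         afterHardFilters = nVariants(hard$variants),
         afterClusterRule = nVariants(unclustered),
         afterCallRate = nVariants(final)))
}
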