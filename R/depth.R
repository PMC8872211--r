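#' Pooled per-base read depth over a region
#'
#' Depth at a base is the number of mapped, non-clipped read bases
#' covering it, summed over the pool's samples. Soft-clipped bases are
#' unaligned sequence and never contribute.
#'
#' @param alignments Alignment record data.frame (see
#'   [projectAlignment()]).
#' @param samples Sample ids forming the pool (default: all).
#' @param ref A [ReferenceRegion-class] giving the coordinate frame.
#' @return Numeric depth vector of length `regionLength(ref)`; element
#'   `i` is the depth at genomic position `refOffset(ref) + i - 1`.
#' @export
pooledDepth <- function(alignments, samples = NULL, ref) {
  a <- alignments[alignments$mapped, , drop = FALSE]
  if (!is.null(samples)) a <- a[a$sample %in% samples, , drop = FALSE]
  L <- regionLength(ref)
  if (nrow(a) == 0) return(numeric(L))
  start <- a$pos - refOffset(ref) + 1
  ir <- IRanges::IRanges(start, width = a$mappedLen)
  ir <- IRanges::restrict(ir, start = 1L, end = L)
  ir <- ir[IRanges::width(ir) > 0]
  as.numeric(IRanges::coverage(ir, width = L))
}

#' Per-base log2 depth ratio between two pools
#'
#' `log2((depthA + pseudocount) / (depthB + pseudocount))`, optionally
#' after scaling each pool to the common mean depth so unequal sequencing
#' yield does not masquerade as copy-number change. The pseudocount
#' guards the log where a pool has zero depth (e.g. a deletion
#' homozygote pool inside the deleted interval).
#'
#' @param depthA,depthB Equal-length depth vectors (see [pooledDepth()]).
#' @param pseudocount Positive guard added to both depths.
#' @param normalize Scale both arrays to their common mean first.
#' @return Numeric log2-ratio vector.
#' @export
logDepthRatio <- function(depthA, depthB, pseudocount = 1,
                          normalize = TRUE) {
  if (length(depthA) != length(depthB))
    stop("depth arrays must have equal length")
  if (pseudocount <= 0 && (any(depthA == 0) || any(depthB == 0)))
    stop("'pseudocount' must be positive when any depth is zero")
  if (normalize) {
    target <- mean(c(mean(depthA), mean(depthB)))
    if (mean(depthA) > 0) depthA <- depthA * target / mean(depthA)
    if (mean(depthB) > 0) depthB <- depthB * target / mean(depthB)
  }
  log2((depthA + pseudocount) / (depthB + pseudocount))
}

## Centered moving mean with shrinking windows at the edges.
runningMean <- function(x, window) {
  if (window <= 1) return(x)
  half <- floor(window / 2)
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Call candidate copy-number segments from a log-ratio track
#'
#' Smooths the track with a centered moving mean and reports maximal
#' runs where the smoothed absolute ratio reaches `threshold` and the
#' run is at least `minLen` bp, each labelled with its direction
#' ("A>B" for positive ratio, "B>A" for negative).
#'
#' @param ratio Log2-ratio track from [logDepthRatio()].
#' @param ref The [ReferenceRegion-class] the track was computed on.
#' @param threshold Minimum smoothed |log2 ratio| (default 1, i.e.
#'   2-fold).
#' @param minLen Minimum segment length in bp (default 500).
#' @param smoothWindow Moving-mean window in bp (default 201).
#' @return data.frame with columns `start`, `end` (1-based genomic,
#'   inclusive), `meanRatio`, `direction`; zero rows when nothing
#'   qualifies.
#' @export
callCandidateSegments <- function(ratio, ref, threshold = 1, minLen = 500,
                                  smoothWindow = 201) {
  if (threshold <= 0) stop("'threshold' must be positive")
  if (!length(ratio))
    return(data.frame(start = numeric(0), end = numeric(0),
                      meanRatio = numeric(0), direction = character(0)))
  sm <- runningMean(ratio, smoothWindow)
  state <- ifelse(sm >= threshold, 1L, ifelse(sm <= -threshold, -1L, 0L))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values != 0L & r$lengths >= minLen
  off <- refOffset(ref)
  if (!any(keep))
    return(data.frame(start = numeric(0), end = numeric(0),
                      meanRatio = numeric(0), direction = character(0)))
  out <- data.frame(
    start = off + starts[keep] - 1, end = off + ends[keep] - 1,
    meanRatio = mapply(function(s, e) mean(ratio[s:e]),
                       starts[keep], ends[keep]),
    direction = ifelse(r$values[keep] > 0, "A>B", "B>A"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
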