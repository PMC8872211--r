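#' Extract apparent insert sizes of pairs over a region
#'
#' One entry per pair (counted at its leftmost mate): the absolute outer
#' reference-coordinate span of the two mapped mates, for every pair
#' whose outer span intersects the candidate region. A deletion lying
#' between the mates inflates the apparent insert by its net size.
#'
#' @param alignments Alignment record data.frame.
#' @param region Numeric `c(start, end)` genomic interval, or a
#'   [ReferenceRegion-class] (its full extent).
#' @param group Label stored on the profile.
#' @param samples Optional sample ids to restrict to.
#' @return List of class fields: `group`, `sizes` (numeric vector),
#'   `median`, `mad`, `max`, `n`.
#' @export
extractApparentInserts <- function(alignments, region, group = "pool",
                                   samples = NULL) {
  if (is(region, "ReferenceRegion"))
    region <- c(refOffset(region), refOffset(region) + regionLength(region) - 1)
  a <- alignments[alignments$mapped & alignments$mateMapped &
                    alignments$isize > 0, , drop = FALSE]
  if (!is.null(samples)) a <- a[a$sample %in% samples, , drop = FALSE]
  outerStart <- a$pos
  outerEnd <- a$pos + a$isize - 1
  keep <- outerEnd >= region[1] & outerStart <= region[2]
  sizes <- abs(a$isize[keep])
  list(group = group, sizes = sizes,
       median = if (length(sizes)) median(sizes) else NA_real_,
       mad = if (length(sizes)) mad(sizes) else NA_real_,
       max = if (length(sizes)) max(sizes) else NA_real_,
       n = length(sizes))
}

#' Classify a structural variant from case/control insert profiles
#'
#' Pairs whose apparent insert exceeds `fragMean + discordantZ * fragSd`
#' are discordant-long (evidence for a deletion between the mates);
#' pairs below `fragMean - discordantZ * fragSd` are discordant-short
#' (duplication-type evidence). A DELETION is called when the case
#' group's discordant-long fraction exceeds the control's by at least
#' `margin` with at least `minSupport` supporting pairs; the net size
#' estimate is `median(discordant case sizes) - fragMean`, i.e. the
#' deletion length minus any junction insertion. DUPLICATION is the
#' symmetric call on discordant-short excess; otherwise NONE.
#'
#' @param caseProfile,controlProfile Profiles from
#'   [extractApparentInserts()]; both must be non-empty.
#' @param fragMean,fragSd Fragment-length model of the library (bp).
#' @param discordantZ Discordance threshold in fragment-sd units
#'   (default 5).
#' @param margin Minimum excess discordant fraction (default 0.05).
#' @param minSupport Minimum supporting pairs (default 3).
#' @return An [SVCall-class].
#' @export
classifySV <- function(caseProfile, controlProfile, fragMean, fragSd,
                       discordantZ = 5, margin = 0.05, minSupport = 3) {
  for (p in list(caseProfile, controlProfile))
    if (p$n == 0) stop("empty insert profile for group '", p$group, "'")
  longCut <- fragMean + discordantZ * fragSd
  shortCut <- fragMean - discordantZ * fragSd
  fr <- function(sizes, cut, op) mean(op(sizes, cut))
  caseLong <- caseProfile$sizes[caseProfile$sizes > longCut]
  details <- list(
    longCut = longCut,
    caseLongFrac = fr(caseProfile$sizes, longCut, `>`),
    controlLongFrac = fr(controlProfile$sizes, longCut, `>`),
    caseShortFrac = fr(caseProfile$sizes, shortCut, `<`),
    controlShortFrac = fr(controlProfile$sizes, shortCut, `<`))

  if (details$caseLongFrac - details$controlLongFrac >= margin &&
      length(caseLong) >= minSupport) {
    return(new("SVCall", type = "DELETION",
               netSize = median(caseLong) - fragMean,
               support = length(caseLong), details = details))
  }
  caseShort <- caseProfile$sizes[caseProfile$sizes < shortCut]
  if (details$caseShortFrac - details$controlShortFrac >= margin &&
      length(caseShort) >= minSupport) {
    return(new("SVCall", type = "DUPLICATION",
               netSize = fragMean - median(caseShort),
               support = length(caseShort), details = details))
  }
  new("SVCall", type = "NONE", netSize = NA_real_, support = 0,
      details = details)
}

#' Per-sample discordant-long pair counts over a region
#'
#' Counts, for each sample, pairs spanning the region whose apparent
#' insert exceeds `fragMean + discordantZ * fragSd`. At equal coverage a
#' deletion homozygote carries roughly twice the count of a heterozygote
#' (two deletion-bearing haplotypes versus one).
#'
#' @param alignments Alignment record data.frame.
#' @param region Numeric `c(start, end)` or [ReferenceRegion-class].
#' @param fragMean,fragSd,discordantZ Fragment model and threshold.
#' @return Named integer vector of counts, one per sample present.
#' @export
perSampleDiscordance <- function(alignments, region, fragMean, fragSd,
                                 discordantZ = 5) {
  if (is(region, "ReferenceRegion"))
    region <- c(refOffset(region), refOffset(region) + regionLength(region) - 1)
  a <- alignments[alignments$mapped & alignments$mateMapped &
                    alignments$isize > 0, , drop = FALSE]
  outerEnd <- a$pos + a$isize - 1
  span <- outerEnd >= region[1] & a$pos <= region[2]
  long <- a$isize > fragMean + discordantZ * fragSd
  counts <- table(factor(a$sample[span & long],
                         levels = sort(unique(a$sample))))
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}
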