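#' Collect soft-clip clusters from alignments
#'
#' Groups clipped reads by the reference position of the clip edge. A
#' read clipped on its left has its edge at the first mapped base (side
#' "left": the clipped sequence spells what precedes the edge on the
#' sample haplotype); a read clipped on its right has its edge at the
#' last mapped base (side "right"). Clips shorter than `minClip` are
#' ignored; clusters with fewer than `minSupport` reads are dropped.
#'
#' @param alignments Alignment record data.frame with `seq` available.
#' @param segment Optional numeric `c(start, end)` genomic interval;
#'   only edges inside it are considered.
#' @param minClip Minimum clip length in bp (default 20).
#' @param minSupport Minimum reads per cluster (default 2).
#' @return List of clusters ordered by decreasing support; each is a
#'   list with `side`, `edge` (genomic position), `clips` (clipped
#'   sequences), `anchors` (mapped-part sequences) and `support`.
#' @export
collectClipClusters <- function(alignments, segment = NULL, minClip = 20,
                                minSupport = 2) {
  a <- alignments[alignments$mapped, , drop = FALSE]
  clusters <- list()
  addSide <- function(side) {
    if (side == "left") {
      sel <- a$leftClip >= minClip
      edge <- a$pos[sel]
      clips <- substr(a$seq[sel], 1, a$leftClip[sel])
    } else {
      sel <- a$rightClip >= minClip
      edge <- a$pos[sel] + a$mappedLen[sel] - 1
      clips <- substr(a$seq[sel], a$leftClip[sel] + a$mappedLen[sel] + 1,
                      nchar(a$seq[sel]))
    }
    anchors <- substr(a$seq[sel], a$leftClip[sel] + 1,
                      a$leftClip[sel] + a$mappedLen[sel])
    if (!is.null(segment)) {
      inSeg <- edge >= segment[1] & edge <= segment[2]
      edge <- edge[inSeg]; clips <- clips[inSeg]; anchors <- anchors[inSeg]
    }
    for (e in unique(edge)) {
      i <- edge == e
      if (sum(i) >= minSupport)
        clusters[[length(clusters) + 1L]] <<- list(
          side = side, edge = e, clips = clips[i], anchors = anchors[i],
          support = sum(i))
    }
  }
  addSide("left")
  addSide("right")
  clusters[order(vapply(clusters, `[[`, 0, "support"), decreasing = TRUE)]
}

## Majority-vote consensus of variable-length strings sharing one aligned
## end. Ties go to the lexicographically smallest base (base qualities are
## constant in the simulator, so summed quality cannot break ties).
## Returns the consensus string and the per-column read depth.
consensusAligned <- function(strings, align = c("left", "right")) {
  align <- match.arg(align)
  lens <- nchar(strings)
  width <- max(lens)
  if (align == "right")
    strings <- vapply(strings, function(s)
      paste0(strrep(" ", width - nchar(s)), s), "", USE.NAMES = FALSE)
  chars <- matrix(" ", length(strings), width)
  for (i in seq_along(strings)) {
    v <- strsplit(strings[i], "")[[1]]
    chars[i, seq_along(v)] <- v
  }
  cons <- character(width); depth <- integer(width)
  for (j in seq_len(width)) {
    col <- chars[, j]
    col <- col[col != " "]
    depth[j] <- length(col)
    tab <- sort(table(col), decreasing = TRUE)
    best <- names(tab)[tab == tab[1]]
    cons[j] <- sort(best)[1]
  }
  list(seq = paste(cons, collapse = ""), depth = depth)
}

## Trim low-depth outer columns (sequencing errors dominate columns seen by
## a single read). For left-aligned strings the ragged end is on the right,
## for right-aligned on the left.
trimByDepth <- function(cons, side = c("right", "left"), minDepth = 2) {
  side <- match.arg(side)
  ok <- cons$depth >= min(minDepth, max(cons$depth))
  if (!any(ok)) return(list(seq = "", depth = integer(0)))
  if (side == "right") {
    last <- which(!ok)[1]
    keep <- if (is.na(last)) seq_along(ok) else seq_len(last - 1)
  } else {
    rev_bad <- which(!rev(ok))[1]
    keep <- if (is.na(rev_bad)) seq_along(ok)
      else (length(ok) - rev_bad + 2):length(ok)
  }
  list(seq = substr(cons$seq, keep[1], keep[length(keep)]),
       depth = cons$depth[keep])
}

#' Build a junction consensus from two clip clusters
#'
#' Combines a right-clipped cluster (reads anchored on the left flank,
#' clipped tails spelling the junction insertion and the right flank)
#' with a left-clipped cluster (anchored on the right flank, clipped
#' heads spelling the left flank and the insertion) into a single
#' majority-vote consensus across the junction:
#' left flank + inserted sequence + right flank.
#'
#' @param leftCluster Cluster with side "left" (left-clipped reads).
#' @param rightCluster Cluster with side "right". Order of the two
#'   arguments is detected from the `side` fields.
#' @return Character consensus sequence with attributes `support`
#'   (minimum of the two cluster supports) and `depth` (per-column read
#'   depth).
#' @export
junctionConsensus <- function(leftCluster, rightCluster) {
  if (leftCluster$side == rightCluster$side)
    stop("junction consensus needs one left-clipped and one right-clipped cluster")
  if (leftCluster$side == "right") {      # swapped arguments
    tmp <- leftCluster; leftCluster <- rightCluster; rightCluster <- tmp
  }
  ## right-clipped cluster: mapped anchors end at the junction's left edge
  m1 <- trimByDepth(consensusAligned(rightCluster$anchors, "right"), "left")
  f <- trimByDepth(consensusAligned(rightCluster$clips, "left"), "right")
  ## left-clipped cluster: clipped heads end just before the right flank
  b <- trimByDepth(consensusAligned(leftCluster$clips, "right"), "left")
  m2 <- trimByDepth(consensusAligned(leftCluster$anchors, "left"), "right")

  s1 <- paste0(m1$seq, f$seq); d1 <- c(m1$depth, f$depth)
  s2 <- paste0(b$seq, m2$seq); d2 <- c(b$depth, m2$depth)
  merged <- mergeConsensus(s1, d1, s2, d2)
  attr(merged, "support") <- min(rightCluster$support, leftCluster$support)
  merged
}

## Align s2 against s1 at every ungapped offset, keep the best-identity
## overlap (>= 15 bp, >= 90% identity), and merge: higher-depth columns
## win, ties go to s1. Falls back to s1 when no reliable overlap exists.
mergeConsensus <- function(s1, d1, s2, d2, minOverlap = 15) {
  v1 <- strsplit(s1, "")[[1]]; v2 <- strsplit(s2, "")[[1]]
  n1 <- length(v1); n2 <- length(v2)
  best <- NULL; bestScore <- -Inf
  for (d in (minOverlap - n2):(n1 - minOverlap)) {
    i2 <- seq_len(n2)
    i1 <- i2 + d
    ok <- i1 >= 1 & i1 <= n1
    ov <- sum(ok)
    if (ov < minOverlap) next
    matches <- sum(v1[i1[ok]] == v2[ok])
    if (matches / ov < 0.9) next
    score <- matches - (ov - matches) * 4
    if (score > bestScore) { bestScore <- score; best <- d }
  }
  if (is.null(best)) return(s1)
  lo <- min(1, 1 + best); hi <- max(n1, n2 + best)
  out <- character(hi - lo + 1)
  for (k in seq_along(out)) {
    p1 <- lo + k - 1                      # index in s1 frame
    p2 <- p1 - best                       # index in s2
    has1 <- p1 >= 1 && p1 <= n1
    has2 <- p2 >= 1 && p2 <= n2
    out[k] <- if (has1 && (!has2 || d1[p1] >= d2[p2])) {
      if (has1) v1[p1] else v2[p2]
    } else v2[p2]
  }
  paste(out, collapse = "")
}

noCall <- function(diagnostic) {
  new("BreakpointCall", delStart = NA_real_, delEnd = NA_real_,
      insertedSeq = "", deletionLength = NA_real_, support = 0,
      status = "no_call", diagnostic = diagnostic)
}

#' Resolve deletion breakpoints from a junction consensus
#'
#' Anchors the consensus flanks to the reference by exact matching: the
#' left flank is the longest exact extension of a `minAnchor`-bp prefix
#' seed, the right flank of a suffix seed (seeds slide inward by up to
#' `minAnchor` bases to step over a ragged consensus end). The
#' unanchored middle is the non-templated junction insertion. When the
#' two extensions overlap (junction micro-homology) the deletion is
#' placed leftmost. The right flank must anchor within `searchWindow`
#' bp of the left anchor; ambiguous or failed anchoring gives a no-call
#' with a diagnostic.
#'
#' @param consensus Junction consensus from [junctionConsensus()] (or
#'   any sequence spanning the junction with >= `minAnchor` exact flank
#'   bases).
#' @param ref The [ReferenceRegion-class].
#' @param searchWindow Maximum deletion span searched (bp).
#' @param minAnchor Seed length for exact-match anchoring (default 20).
#' @return A [BreakpointCall-class]; `deletionLength` follows the
#'   `delEnd - delStart` convention.
#' @export
resolveBreakpoints <- function(consensus, ref, searchWindow = 20000,
                               minAnchor = 20) {
  support <- attr(consensus, "support")
  if (is.null(support)) support <- NA_real_
  cons <- as.character(consensus)
  n <- nchar(cons)
  if (n < 2 * minAnchor + 1)
    return(noCall("consensus shorter than two anchors"))
  refChar <- as.character(refSequence(ref))
  refDNA <- refSequence(ref)
  off <- refOffset(ref)
  L <- nchar(refChar)

  ## left flank: seed at consensus index 1 + k, slide inward on failure
  left <- NULL
  for (k in 0:minAnchor) {
    seedStart <- 1 + k
    seed <- substr(cons, seedStart, seedStart + minAnchor - 1)
    if (nchar(seed) < minAnchor) break
    hits <- Biostrings::start(Biostrings::matchPattern(seed, refDNA))
    if (length(hits) == 0) next
    ext <- vapply(hits, function(p)
      commonExtension(cons, seedStart, refChar, p, +1L), 0)
    bestExt <- max(ext)
    if (sum(ext == bestExt) > 1)
      return(noCall("left flank anchors ambiguously"))
    p <- hits[ext == bestExt]
    left <- list(consStart = seedStart, refStart = p, len = bestExt)
    break
  }
  if (is.null(left)) return(noCall("left flank failed to anchor"))

  ## right flank: seed ending at consensus index n - k
  right <- NULL
  winLo <- left$refStart
  winHi <- min(L, left$refStart + searchWindow)
  for (k in 0:minAnchor) {
    seedEnd <- n - k
    seed <- substr(cons, seedEnd - minAnchor + 1, seedEnd)
    if (nchar(seed) < minAnchor) break
    hits <- Biostrings::start(Biostrings::matchPattern(seed, refDNA))
    hits <- hits[hits >= winLo & hits <= winHi]
    if (length(hits) == 0) next
    ext <- vapply(hits, function(q)
      commonExtension(cons, seedEnd, refChar, q + minAnchor - 1, -1L), 0)
    bestExt <- max(ext)
    if (sum(ext == bestExt) > 1)
      return(noCall("right flank anchors ambiguously within the search window"))
    q0 <- hits[ext == bestExt]
    right <- list(consEnd = seedEnd,
                  refEnd = q0 + minAnchor - 1, len = bestExt)
    break
  }
  if (is.null(right)) return(noCall("right flank failed to anchor"))

  ## consensus index just after the left match / first index of right match
  a <- left$consStart + left$len - 1          # last left-matched cons index
  j <- right$consEnd - right$len + 1          # first right-matched cons index
  split <- min(a + 1, j)                      # leftmost placement
  delStartG <- off + (left$refStart - left$consStart + split) - 1
  refJ <- right$refEnd - (right$consEnd - j)  # ref local of cons index j
  delEndG <- off + refJ - 1
  ins <- if (j > split) substr(cons, split, j - 1) else ""
  if (is.na(delEndG) || delEndG < delStartG)
    return(noCall("flanks overlap inconsistently"))
  new("BreakpointCall", delStart = delStartG, delEnd = delEndG,
      insertedSeq = ins, deletionLength = delEndG - delStartG,
      support = as.numeric(support), status = "resolved", diagnostic = "")
}

## Length of the exact common run between cons (from index ci) and ref
## (from local index ri), walking in direction dir (+1 right, -1 left).
commonExtension <- function(cons, ci, ref, ri, dir) {
  n <- nchar(cons); L <- nchar(ref)
  len <- 0L
  while (ci >= 1 && ci <= n && ri >= 1 && ri <= L &&
         substr(cons, ci, ci) == substr(ref, ri, ri)) {
    len <- len + 1L
    ci <- ci + dir; ri <- ri + dir
  }
  len
}

#' Resolve a deletion end-to-end from alignments
#'
#' Convenience wrapper: collects clip clusters, picks the dominant
#' right-clipped and left-clipped clusters (right edge left of left
#' edge), builds the junction consensus and resolves breakpoints.
#'
#' @param alignments Alignment record data.frame.
#' @param ref The [ReferenceRegion-class].
#' @param segment Optional genomic interval to restrict clustering.
#' @param minClip,minSupport See [collectClipClusters()].
#' @param searchWindow,minAnchor See [resolveBreakpoints()].
#' @return A [BreakpointCall-class].
#' @export
resolveDeletion <- function(alignments, ref, segment = NULL, minClip = 20,
                            minSupport = 2, searchWindow = 20000,
                            minAnchor = 20) {
  cl <- collectClipClusters(alignments, segment, minClip, minSupport)
  sides <- vapply(cl, `[[`, "", "side")
  rightCl <- cl[sides == "right"]
  leftCl <- cl[sides == "left"]
  if (!length(rightCl) || !length(leftCl))
    return(noCall("missing a clip cluster on one junction side"))
  r <- rightCl[[1]]; l <- leftCl[[1]]
  if (l$edge <= r$edge)
    return(noCall("clip clusters are not in deletion orientation"))
  cons <- junctionConsensus(l, r)
  resolveBreakpoints(cons, ref, searchWindow, minAnchor)
}
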