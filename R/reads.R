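## Alignment records are kept as a plain data.frame with one row per read:
## qname, sample, rname, mapped, pos (1-based genomic leftmost mapped base),
## mappedLen, leftClip, rightClip, strand, seq/qual (reference orientation),
## matePos, mateMapped, isize (TLEN-style outer span, signed), first,
## properPair. This mirrors the SAM fields the downstream scans consume.

alignmentColumns <- c("qname", "sample", "rname", "mapped", "pos",
                      "mappedLen", "leftClip", "rightClip", "strand",
                      "seq", "qual", "matePos", "mateMapped", "isize",
                      "first", "properPair")

## Project one set of haplotype intervals [s, e] through a CoordinateMap.
## Returns pos/mappedLen/leftClip/rightClip/mapped vectors. A read crossing
## the junction is anchored on the side with the longer mapped run (ties to
## the left); an anchor shorter than minAnchor on both sides is unmapped.
projectInterval <- function(map, s, e, minAnchor = 20) {
  n <- length(s)
  readLen <- e - s + 1
  b <- map@blocks
  if (nrow(b) == 1L && b$hapStart[1] == 1 && b$hapEnd[1] == map@hapLength) {
    return(list(pos = b$refStart[1] + (s - 1), mappedLen = readLen,
                leftClip = rep(0, n), rightClip = rep(0, n),
                mapped = rep(TRUE, n)))
  }
  hasLeft <- b$hapStart[1] == 1
  A <- if (hasLeft) b$hapEnd[1] else 0              # last hap pos of left block
  B <- if (nrow(b) > if (hasLeft) 1L else 0L)
    b$hapStart[nrow(b)] else Inf                    # first hap pos of right block
  lenL <- pmax(0, pmin(e, A) - s + 1)
  lenR <- pmax(0, e - pmax(s, B) + 1)

  pos <- rep(NA_real_, n); mappedLen <- rep(0, n)
  leftClip <- rep(0, n); rightClip <- rep(0, n)
  mapped <- rep(FALSE, n)

  full <- lenL == readLen | lenR == readLen
  pos[full] <- hapToRef(map, s[full])
  mappedLen[full] <- readLen[full]
  mapped[full] <- TRUE

  cross <- !full
  if (any(cross)) {
    left <- cross & lenL >= lenR
    right <- cross & lenL < lenR
    anchor <- pmax(lenL, lenR)
    ok <- cross & anchor >= minAnchor
    li <- left & ok
    pos[li] <- hapToRef(map, s[li])
    mappedLen[li] <- lenL[li]
    rightClip[li] <- readLen[li] - lenL[li]
    ri <- right & ok
    mappedLen[ri] <- lenR[ri]
    leftClip[ri] <- readLen[ri] - lenR[ri]
    pos[ri] <- hapToRef(map, e[ri]) - lenR[ri] + 1
    mapped[ok] <- TRUE
  }
  list(pos = pos, mappedLen = mappedLen, leftClip = leftClip,
       rightClip = rightClip, mapped = mapped)
}

#' Project simulated read pairs onto the reference
#'
#' Turns fragments simulated on a haplotype into truth alignments by
#' coordinate projection through the haplotype's [CoordinateMap-class] —
#' no heuristic aligner is involved, so downstream stages see exactly
#' the alignments the geometry implies. Reads fully inside a collinear
#' block are ungapped; reads crossing the deletion junction are
#' soft-clipped at the junction and placed on the side with the longer
#' mapped anchor (at least `minAnchor` bases, default 20, else unmapped).
#' The apparent insert size is the outer reference-coordinate span of the
#' projected pair (TLEN semantics), signed positive on the leftmost mate.
#'
#' @param map A [CoordinateMap-class] for the haplotype the pair came from.
#' @param pairs data.frame with columns `qname`, `s1`, `e1`, `s2`, `e2`
#'   (haplotype intervals of read 1 and read 2, read 2 on the reverse
#'   strand), and optionally `seq1`, `seq2`, `qual1`, `qual2` in
#'   haplotype (reference) orientation, and `sample`.
#' @param minAnchor Minimum mapped anchor on one side of a junction.
#' @return data.frame of alignment records, two rows per pair.
#' @export
projectAlignment <- function(map, pairs, minAnchor = 20) {
  n <- nrow(pairs)
  p1 <- projectInterval(map, pairs$s1, pairs$e1, minAnchor)
  p2 <- projectInterval(map, pairs$s2, pairs$e2, minAnchor)

  end1 <- p1$pos + p1$mappedLen - 1
  end2 <- p2$pos + p2$mappedLen - 1
  both <- p1$mapped & p2$mapped
  leftmost <- pmin(p1$pos, p2$pos)
  rightmost <- pmax(end1, end2)
  span <- rightmost - leftmost + 1
  isize1 <- rep(0, n); isize2 <- rep(0, n)
  firstLeft <- both & (p1$pos <= p2$pos)
  isize1[both] <- ifelse(firstLeft[both], span[both], -span[both])
  isize2[both] <- -isize1[both]

  blank <- function(x, n) if (is.null(x)) rep("", n) else x
  sample <- if (is.null(pairs$sample)) rep(NA_character_, n) else pairs$sample
  mk <- function(p, first, seq, qual, matePos, mateMapped, isize, strand) {
    data.frame(qname = pairs$qname, sample = sample, rname = map@refName,
               mapped = p$mapped, pos = p$pos, mappedLen = p$mappedLen,
               leftClip = p$leftClip, rightClip = p$rightClip,
               strand = strand, seq = blank(seq, n), qual = blank(qual, n),
               matePos = matePos, mateMapped = mateMapped, isize = isize,
               first = first, properPair = both, stringsAsFactors = FALSE)
  }
  out <- rbind(
    mk(p1, TRUE, pairs$seq1, pairs$qual1, p2$pos, p2$mapped, isize1, "+"),
    mk(p2, FALSE, pairs$seq2, pairs$qual2, p1$pos, p1$mapped, isize2, "-"))
  out[order(rep(seq_len(n), 2), !out$first), , drop = FALSE]
}

#' Simulate paired-end reads from a diploid sample
#'
#' Draws fragments from the two haplotypes (in proportion to haplotype
#' length), with lengths from a normal distribution resampled below the
#' read length, cuts `readLen`-bp reads from both fragment ends (read 2
#' reverse-complemented), applies uniform substitution noise, assigns
#' constant Q30 base qualities, and produces truth alignments by
#' coordinate projection.
#'
#' @param sampleId Sample identifier recorded on reads and alignments.
#' @param haplotypes List of two haplotypes, each a list with `sequence`
#'   (character) and `map` (a [CoordinateMap-class]), e.g. from
#'   [applyEdit()].
#' @param coverage Target mean read-base depth over the reference region.
#' @param readLen Read length (bp).
#' @param fragMean,fragSd Fragment-length normal distribution (bp);
#'   `fragMean` must be >= `readLen`.
#' @param errorRate Per-base substitution error rate.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param minAnchor Minimum junction anchor, see [projectAlignment()].
#' @return List with `reads` (data.frame: qname, haplotype, fragStart,
#'   fragLen, seq1/qual1/seq2/qual2 in sequencing orientation) and
#'   `alignments` (truth alignment records).
#' @export
simulateReadPairs <- function(sampleId, haplotypes, coverage = 5,
                              readLen = 150, fragMean = 500, fragSd = 50,
                              errorRate = 0.001, seed = 1, minAnchor = 20) {
  if (fragMean < readLen) stop("'fragMean' must be >= 'readLen'")
  if (coverage <= 0) stop("'coverage' must be positive")
  hapLens <- vapply(haplotypes, function(h) nchar(h$sequence), 0)
  ## pairs sized to the sequenced genome (the haplotypes), so realized
  ## depth over non-deleted sequence equals the nominal coverage
  nPairs <- round(coverage * mean(hapLens) / (2 * readLen))

  withSeed(seed, {
    hapIdx <- sample.int(2L, nPairs, replace = TRUE, prob = hapLens)
    fragLen <- round(rnorm(nPairs, fragMean, fragSd))
    for (rep_i in 1:50) {
      bad <- fragLen < readLen | fragLen > hapLens[hapIdx]
      if (!any(bad)) break
      fragLen[bad] <- round(rnorm(sum(bad), fragMean, fragSd))
    }
    fragLen <- pmin(pmax(fragLen, readLen), hapLens[hapIdx])
    fragStart <- floor(runif(nPairs) * (hapLens[hapIdx] - fragLen + 1)) + 1

    s1 <- fragStart; e1 <- fragStart + readLen - 1
    e2 <- fragStart + fragLen - 1; s2 <- e2 - readLen + 1
    seq1 <- character(nPairs); seq2 <- character(nPairs)
    for (h in 1:2) {
      i <- hapIdx == h
      seq1[i] <- substring(haplotypes[[h]]$sequence, s1[i], e1[i])
      seq2[i] <- substring(haplotypes[[h]]$sequence, s2[i], e2[i])
    }
    seq1 <- injectSubstitutions(seq1, readLen, errorRate)
    seq2 <- injectSubstitutions(seq2, readLen, errorRate)
  })

  qual <- strrep("?", readLen)            # constant Phred Q30
  qname <- sprintf("%s_p%06d", sampleId, seq_len(nPairs))
  pairs <- data.frame(qname = qname, sample = sampleId,
                      s1 = s1, e1 = e1, s2 = s2, e2 = e2,
                      seq1 = seq1, seq2 = seq2,
                      qual1 = qual, qual2 = qual,
                      stringsAsFactors = FALSE)
  aln <- vector("list", 2)
  for (h in 1:2) {
    sub <- pairs[hapIdx == h, , drop = FALSE]
    if (nrow(sub))
      aln[[h]] <- projectAlignment(haplotypes[[h]]$map, sub, minAnchor)
  }
  alignments <- do.call(rbind, aln[!vapply(aln, is.null, TRUE)])
  rownames(alignments) <- NULL

  reads <- data.frame(
    qname = qname, haplotype = hapIdx,
    fragStart = fragStart, fragLen = fragLen,
    seq1 = seq1, qual1 = qual,
    seq2 = as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seq2))),
    qual2 = qual, stringsAsFactors = FALSE)
  list(reads = reads, alignments = alignments)
}

## Uniform substitution noise over a vector of equal-length sequences.
injectSubstitutions <- function(seqs, readLen, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  total <- length(seqs) * readLen
  nErr <- rbinom(1, total, rate)
  if (nErr == 0) return(seqs)
  idx <- sample.int(total, nErr)
  readIdx <- (idx - 1) %/% readLen + 1
  posIdx <- (idx - 1) %% readLen + 1
  bases <- c("A", "C", "G", "T")
  for (k in seq_len(nErr)) {
    cur <- substr(seqs[readIdx[k]], posIdx[k], posIdx[k])
    substr(seqs[readIdx[k]], posIdx[k], posIdx[k]) <-
      sample(setdiff(bases, cur), 1)
  }
  seqs
}

#' Simulate reads for a whole cohort
#'
#' Calls [simulateReadPairs()] for every sample in a sample sheet, using
#' the wildtype or edited haplotype pair implied by each sample's
#' deletion genotype. Per-sample seeds are derived from `seed` with
#' [deriveSeed()].
#'
#' @param cohort Sample sheet from [simulateCohort()].
#' @param ref A [ReferenceRegion-class].
#' @param edit The deletion [HaplotypeEdit-class].
#' @param seed Master integer seed.
#' @param ... Passed to [simulateReadPairs()] (coverage, readLen, ...).
#' @return List with `alignments` (row-bound truth alignments for all
#'   samples) and `reads` (named list of per-sample read data.frames).
#' @export
simulateCohortReads <- function(cohort, ref, edit, seed = 1, ...) {
  wt <- applyEdit(ref, HaplotypeEdit(delStart(edit), delStart(edit), ""))
  del <- applyEdit(ref, edit)
  hapFor <- list("wt/wt" = list(wt, wt), "wt/del" = list(wt, del),
                 "del/del" = list(del, del))
  out <- lapply(seq_len(nrow(cohort)), function(i) {
    simulateReadPairs(cohort$sample_id[i],
                      hapFor[[cohort$del_genotype[i]]],
                      seed = deriveSeed(seed, cohort$sample_id[i]), ...)
  })
  alignments <- do.call(rbind, lapply(out, `[[`, "alignments"))
  rownames(alignments) <- NULL
  reads <- lapply(out, `[[`, "reads")
  names(reads) <- cohort$sample_id
  list(alignments = alignments, reads = reads)
}
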