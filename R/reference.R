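#' Construct a ReferenceRegion
#'
#' @param name Reference (chromosome) name.
#' @param offset Genomic coordinate of the first base (1-based).
#' @param sequence Character string or [Biostrings::DNAString] over A/C/G/T.
#' @return A [ReferenceRegion-class] object.
#' @examples
#' ReferenceRegion("chr1", 100, "ACGTACGT")
#' @export
ReferenceRegion <- function(name, offset, sequence) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  new("ReferenceRegion", name = name, offset = as.numeric(offset),
      sequence = sequence)
}

#' Construct a HaplotypeEdit
#'
#' @param delStart First deleted base (1-based genomic coordinate).
#' @param delEnd First retained base after the deletion; the reported
#'   deletion length is `delEnd - delStart`.
#' @param insertedSeq Junction insertion sequence, "" for none.
#' @return A [HaplotypeEdit-class] object.
#' @examples
#' HaplotypeEdit(51035106, 51042744, "GGTGCGGTGA")
#' @export
HaplotypeEdit <- function(delStart, delEnd, insertedSeq = "") {
  new("HaplotypeEdit", delStart = as.numeric(delStart),
      delEnd = as.numeric(delEnd), insertedSeq = toupper(insertedSeq))
}

#' Construct a PrimerPair
#'
#' @param forward,reverse Primer sequences, 5'->3'.
#' @return A [PrimerPair-class] object.
#' @export
PrimerPair <- function(forward, reverse) {
  new("PrimerPair", forward = toupper(forward), reverse = toupper(reverse))
}

#' Simulate a random reference region
#'
#' Draws an i.i.d. nucleotide sequence with a target GC content and wraps
#' it in a coordinate frame anchored at `offset`, so that genomic
#' coordinates of interest fall inside a short synthetic region.
#'
#' @param length Region length in bp (>= 1000).
#' @param offset Genomic coordinate of the first base.
#' @param gc Target GC fraction, strictly between 0 and 1.
#' @param seed Integer seed; the output is deterministic given the seed.
#' @param name Reference name.
#' @return A [ReferenceRegion-class].
#' @examples
#' ref <- buildReference(2000, offset = 1000, gc = 0.42, seed = 1)
#' regionLength(ref)
#' @export
buildReference <- function(length, offset = 1, gc = 0.42, seed = 1,
                           name = "chr1") {
  if (length < 1000) stop("'length' must be at least 1000 bp")
  if (gc <= 0 || gc >= 1) stop("'gc' must lie strictly between 0 and 1")
  withSeed(seed, {
    bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  })
  ReferenceRegion(name, offset, paste(bases, collapse = ""))
}

#' Overwrite reference bases at a genomic position
#'
#' Plants a fixed subsequence (e.g. a primer binding site) into a
#' reference region, replacing the bases starting at genomic coordinate
#' `at`. Used so diagnostic primers designed against published
#' coordinates find their sites on synthetic sequence.
#'
#' @param ref A [ReferenceRegion-class].
#' @param at Genomic coordinate of the first replaced base.
#' @param sequence Replacement sequence (A/C/G/T).
#' @return The modified [ReferenceRegion-class].
#' @export
plantSequence <- function(ref, at, sequence) {
  sequence <- toupper(sequence)
  i <- at - refOffset(ref) + 1
  j <- i + nchar(sequence) - 1
  if (i < 1 || j > regionLength(ref))
    stop("planted sequence falls outside the reference region")
  s <- as.character(refSequence(ref))
  substr(s, i, j) <- sequence
  ReferenceRegion(refName(ref), refOffset(ref), s)
}

#' Apply a deletion-with-insertion edit to a reference
#'
#' Produces the edited haplotype sequence together with a
#' [CoordinateMap-class] relating haplotype positions to genomic
#' positions. Reference bases `[delStart, delEnd - 1]` are removed and
#' `insertedSeq` is placed at the junction, so the haplotype length is
#' `regionLength(ref) - deletionLength(edit) + nchar(insertedSeq(edit))`.
#'
#' @param ref A [ReferenceRegion-class].
#' @param edit A [HaplotypeEdit-class]; its interval must lie inside `ref`.
#' @return A list with elements `sequence` (character haplotype) and
#'   `map` (a [CoordinateMap-class]).
#' @examples
#' ref <- buildReference(2000, offset = 1, gc = 0.5, seed = 3)
#' hap <- applyEdit(ref, HaplotypeEdit(500, 700, "GGTGCGGTGA"))
#' nchar(hap$sequence)  # 2000 - 200 + 10
#' @export
applyEdit <- function(ref, edit) {
  L <- regionLength(ref)
  off <- refOffset(ref)
  s <- delStart(edit) - off + 1   # local, first deleted base
  e <- delEnd(edit) - off + 1     # local, first retained base after del
  if (s < 1 || e > L + 1 || delEnd(edit) > off + L)
    stop("edit interval falls outside the reference region")
  ins <- insertedSeq(edit)
  ni <- nchar(ins)
  refChar <- as.character(refSequence(ref))

  if (deletionLength(edit) == 0 && ni == 0) {
    blocks <- data.frame(hapStart = 1, hapEnd = L,
                         refStart = off, refEnd = off + L - 1)
    map <- new("CoordinateMap", blocks = blocks, hapLength = L,
               refName = refName(ref), refOffset = off, refLength = L,
               insHapStart = 1, insHapEnd = 0)
    return(list(sequence = refChar, map = map))
  }

  left <- if (s > 1) substr(refChar, 1, s - 1) else ""
  right <- if (e <= L) substr(refChar, e, L) else ""
  hap <- paste0(left, ins, right)

  blocks <- data.frame(hapStart = numeric(0), hapEnd = numeric(0),
                       refStart = numeric(0), refEnd = numeric(0))
  if (s > 1)
    blocks <- rbind(blocks, data.frame(hapStart = 1, hapEnd = s - 1,
                                       refStart = off, refEnd = off + s - 2))
  if (e <= L)
    blocks <- rbind(blocks,
                    data.frame(hapStart = (s - 1) + ni + 1,
                               hapEnd = (s - 1) + ni + (L - e + 1),
                               refStart = off + e - 1, refEnd = off + L - 1))
  map <- new("CoordinateMap", blocks = blocks, hapLength = nchar(hap),
             refName = refName(ref), refOffset = off, refLength = L,
             insHapStart = s, insHapEnd = (s - 1) + ni)
  list(sequence = hap, map = map)
}

#' Map haplotype positions to genomic reference positions
#'
#' @param map A [CoordinateMap-class].
#' @param pos Vector of 1-based haplotype positions.
#' @return Numeric vector of genomic positions; `NA` for positions inside
#'   the junction insertion (no reference homolog).
#' @export
hapToRef <- function(map, pos) {
  b <- map@blocks
  out <- rep(NA_real_, length(pos))
  for (k in seq_len(nrow(b))) {
    in_k <- !is.na(pos) & pos >= b$hapStart[k] & pos <= b$hapEnd[k]
    out[in_k] <- b$refStart[k] + (pos[in_k] - b$hapStart[k])
  }
  out
}

#' Map genomic reference positions to haplotype positions
#'
#' @param map A [CoordinateMap-class].
#' @param pos Vector of genomic reference positions.
#' @return Numeric vector of haplotype positions; `NA` for deleted bases.
#' @export
refToHap <- function(map, pos) {
  b <- map@blocks
  out <- rep(NA_real_, length(pos))
  for (k in seq_len(nrow(b))) {
    in_k <- !is.na(pos) & pos >= b$refStart[k] & pos <= b$refEnd[k]
    out[in_k] <- b$hapStart[k] + (pos[in_k] - b$refStart[k])
  }
  out
}

#' Canonical representation of a deletion-with-insertion edit
#'
#' A deletion with a junction insertion has many sequence-identical
#' representations: whenever the last deleted base equals the last
#' insertion base (or the first deleted base equals the first insertion
#' base), one base can move between the deletion and the insertion
#' without changing the edited haplotype. The canonical form used by the
#' breakpoint resolver is the minimal insertion, with a pure deletion
#' additionally left-normalized (shifted to the smallest `delStart`
#' over junction micro-homology). Truth comparisons against resolved
#' breakpoints should use this form.
#'
#' @param ref The [ReferenceRegion-class] the edit applies to.
#' @param edit A [HaplotypeEdit-class].
#' @return The equivalent canonical [HaplotypeEdit-class].
#' @export
canonicalEdit <- function(ref, edit) {
  s <- delStart(edit); e <- delEnd(edit)
  ins <- insertedSeq(edit)
  off <- refOffset(ref)
  refChar <- as.character(refSequence(ref))
  base <- function(g) substr(refChar, g - off + 1, g - off + 1)
  repeat {
    ni <- nchar(ins)
    if (ni > 0 && e > s && base(e - 1) == substr(ins, ni, ni)) {
      e <- e - 1; ins <- substr(ins, 1, ni - 1)
    } else if (ni > 0 && e > s && base(s) == substr(ins, 1, 1)) {
      s <- s + 1; ins <- substr(ins, 2, ni)
    } else break
  }
  if (nchar(ins) == 0) {
    while (s - 1 >= off && e > s && base(s - 1) == base(e - 1)) {
      s <- s - 1; e <- e - 1
    }
  }
  HaplotypeEdit(s, e, ins)
}

## Run an expression under a local RNG state seeded with `seed`.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Derive a per-stage seed from a master seed
#'
#' Deterministically combines a master integer seed with a stage label so
#' that pipeline stages can be re-run in isolation with the same streams.
#' The result always lies in `[0, 2^31 - 2]`.
#'
#' @param master Integer master seed.
#' @param stage Character stage label.
#' @return Integer seed.
#' @export
deriveSeed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% (2^31 - 1))
}
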