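#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement matchPattern
#'   QualityScaledDNAStringSet PhredQuality writeXStringSet readDNAStringSet
#' @importFrom IRanges IRanges coverage restrict width start end
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom stats rbinom rnorm runif pchisq setNames median mad
#' @importFrom utils write.table read.table head tail
NULL

#' Reference sequence region with an anchored coordinate frame
#'
#' A named genomic segment whose first base sits at genomic coordinate
#' `offset`, so that published coordinates (tens of megabases into a
#' chromosome) can be used directly on a short synthetic sequence.
#' Position `g` on the genome corresponds to local index `g - offset + 1`.
#'
#' @slot name Character scalar, the reference (chromosome) name.
#' @slot offset Numeric scalar >= 1, genomic coordinate of the first base.
#' @slot sequence A [Biostrings::DNAString] restricted to A/C/G/T.
#'
#' @seealso [buildReference()], [applyEdit()]
#' @export
setClass("ReferenceRegion",
  representation(name = "character", offset = "numeric", sequence = "DNAString"))

setValidity("ReferenceRegion", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a non-empty string")
  if (length(object@offset) != 1L || object@offset < 1 ||
      object@offset != round(object@offset))
    msg <- c(msg, "'offset' must be a single integer >= 1")
  if (length(object@sequence) < 1L)
    msg <- c(msg, "sequence must have length >= 1")
  if (grepl("[^ACGT]", as.character(object@sequence)))
    msg <- c(msg, "sequence alphabet restricted to A/C/G/T")
  if (length(msg)) msg else TRUE
})

#' Deletion-with-insertion allele
#'
#' Describes a structural edit that removes the reference bases
#' `[delStart, delEnd - 1]` (genomic, 1-based) and places `insertedSeq`
#' (possibly empty) at the junction. The reported deletion length follows
#' the convention `delEnd - delStart`: the breakpoint pair
#' (51,035,106; 51,042,744) therefore yields a length of 7638 bp.
#'
#' @slot delStart Numeric, first deleted base (1-based genomic).
#' @slot delEnd Numeric, first retained base after the deletion;
#'   `delEnd - delStart` is the deletion length.
#' @slot insertedSeq Character, non-templated junction insertion ("" if none).
#'
#' @export
setClass("HaplotypeEdit",
  representation(delStart = "numeric", delEnd = "numeric",
                 insertedSeq = "character"))

setValidity("HaplotypeEdit", function(object) {
  msg <- character()
  if (object@delEnd < object@delStart)
    msg <- c(msg, "'delEnd' must be >= 'delStart'")
  if (length(object@insertedSeq) != 1L)
    msg <- c(msg, "'insertedSeq' must be a single string (possibly empty)")
  else if (nzchar(object@insertedSeq) &&
           grepl("[^ACGT]", object@insertedSeq))
    msg <- c(msg, "'insertedSeq' alphabet restricted to A/C/G/T")
  if (length(msg)) msg else TRUE
})

#' Bidirectional haplotype/reference coordinate map
#'
#' Piecewise-linear, strictly increasing mapping between 1-based positions
#' on an edited haplotype and genomic positions on the reference it was
#' derived from. Inserted haplotype bases and deleted reference bases map
#' to `NA`. The junction is marked by the haplotype interval occupied by
#' the insertion (empty when the insertion is empty).
#'
#' @slot blocks A data.frame with columns `hapStart`, `hapEnd`, `refStart`,
#'   `refEnd` (ref columns in genomic coordinates), one row per collinear
#'   block, ordered and non-overlapping.
#' @slot hapLength Numeric, total haplotype length.
#' @slot refName,refOffset,refLength Reference frame of the map.
#' @slot insHapStart,insHapEnd Haplotype interval of the junction insertion
#'   (`insHapEnd < insHapStart` when the insertion is empty).
#'
#' @seealso [applyEdit()], [hapToRef()], [refToHap()]
#' @export
setClass("CoordinateMap",
  representation(blocks = "data.frame", hapLength = "numeric",
                 refName = "character", refOffset = "numeric",
                 refLength = "numeric",
                 insHapStart = "numeric", insHapEnd = "numeric"))

setValidity("CoordinateMap", function(object) {
  b <- object@blocks
  msg <- character()
  need <- c("hapStart", "hapEnd", "refStart", "refEnd")
  if (!all(need %in% names(b))) return("blocks must have hap/ref start/end")
  if (nrow(b) > 1L) {
    if (any(diff(b$hapStart) <= 0) || any(diff(b$refStart) <= 0))
      msg <- c(msg, "blocks must be strictly increasing")
  }
  if (any(b$hapEnd - b$hapStart != b$refEnd - b$refStart))
    msg <- c(msg, "block lengths must agree between haplotype and reference")
  if (length(msg)) msg else TRUE
})

#' Resolved structural-variant breakpoints
#'
#' Output of [resolveBreakpoints()]: the deletion breakpoints (genomic,
#' 1-based), any non-templated junction insertion, the deletion length
#' under the `delEnd - delStart` convention, and the read support behind
#' the call. `status` is `"resolved"` or `"no_call"`; a no-call carries a
#' human-readable `diagnostic` and NA coordinates.
#'
#' @slot delStart,delEnd Numeric breakpoint coordinates (NA for no-call).
#' @slot insertedSeq Character junction insertion ("" if none).
#' @slot deletionLength Numeric, `delEnd - delStart`.
#' @slot support Numeric, supporting clipped reads (min over the two sides).
#' @slot status Character, "resolved" or "no_call".
#' @slot diagnostic Character, reason for a no-call ("" otherwise).
#'
#' @export
setClass("BreakpointCall",
  representation(delStart = "numeric", delEnd = "numeric",
                 insertedSeq = "character", deletionLength = "numeric",
                 support = "numeric", status = "character",
                 diagnostic = "character"))

setValidity("BreakpointCall", function(object) {
  if (object@status == "resolved" &&
      !isTRUE(all.equal(object@deletionLength,
                        object@delEnd - object@delStart)))
    return("deletionLength must equal delEnd - delStart")
  TRUE
})

#' Structural-variant type call from insert-size evidence
#'
#' @slot type Character, one of "DELETION", "DUPLICATION", "NONE".
#' @slot netSize Numeric net size estimate in bp (NA when type is "NONE");
#'   for a deletion with a junction insertion this estimates
#'   deletion length minus insertion length.
#' @slot support Numeric, number of supporting discordant pairs.
#' @slot details List of diagnostic quantities (discordant fractions etc.).
#'
#' @export
setClass("SVCall",
  representation(type = "character", netSize = "numeric",
                 support = "numeric", details = "list"))

setValidity("SVCall", function(object) {
  if (!object@type %in% c("DELETION", "DUPLICATION", "NONE"))
    return("type must be DELETION, DUPLICATION or NONE")
  if (object@type == "NONE" && isTRUE(object@netSize > 0))
    return("netSize must not be positive when type is NONE")
  TRUE
})

#' Table of biallelic SNPs with calling annotations and genotypes
#'
#' Container pairing per-variant annotation fields used by hard filtering
#' (QUAL, QD, FS, MQ, MQRankSum, ReadPosRankSum; the rank-sum fields may be
#' NA when undefined) with a variants x samples diploid genotype matrix
#' using VCF-style codes ("0/0", "0/1", "1/1", "./.").
#'
#' @slot info data.frame with columns chrom, pos, id, ref, alt, QUAL, QD,
#'   FS, MQ, MQRankSum, ReadPosRankSum, malformed (logical: TRUE when an
#'   annotation could not be parsed as a number).
#' @slot genotypes Character matrix, one row per variant, one column per
#'   sample (column names are sample ids).
#'
#' @seealso [applyHardFilters()], [associationScan()]
#' @export
setClass("VariantTable",
  representation(info = "data.frame", genotypes = "matrix"))

setValidity("VariantTable", function(object) {
  msg <- character()
  need <- c("chrom", "pos", "id", "ref", "alt", "QUAL", "QD", "FS", "MQ",
            "MQRankSum", "ReadPosRankSum", "malformed")
  if (!all(need %in% names(object@info)))
    msg <- c(msg, paste("info must have columns:", paste(need, collapse = ", ")))
  else {
    if (any(object@info$pos < 1)) msg <- c(msg, "pos must be >= 1")
    if (any(!is.na(object@info$QUAL) & object@info$QUAL < 0))
      msg <- c(msg, "QUAL must be >= 0")
    if (any(!is.na(object@info$FS) & object@info$FS < 0))
      msg <- c(msg, "FS must be >= 0")
  }
  if (nrow(object@genotypes) != nrow(object@info))
    msg <- c(msg, "genotypes must have one row per variant")
  if (length(msg)) msg else TRUE
})

#' PCR primer pair
#'
#' Forward and reverse primers, both written 5'->3'. The reverse primer
#' binds the bottom strand, so its site on the top strand is the reverse
#' complement of `reverse`.
#'
#' @slot forward,reverse Character primer sequences (A/C/G/T, length >= 15).
#' @export
setClass("PrimerPair",
  representation(forward = "character", reverse = "character"))

setValidity("PrimerPair", function(object) {
  for (p in c(object@forward, object@reverse)) {
    if (nchar(p) < 15L) return("primers must be at least 15 bases")
    if (grepl("[^ACGT]", p)) return("primer alphabet restricted to A/C/G/T")
  }
  TRUE
})
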