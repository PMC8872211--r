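#' Write a ReferenceRegion to FASTA
#'
#' The coordinate offset is recorded on the header line
#' (`>name offset=N`) so [readReferenceFasta()] can restore the frame.
#'
#' @param ref A [ReferenceRegion-class].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
writeReferenceFasta <- function(ref, path) {
  x <- Biostrings::DNAStringSet(as.character(refSequence(ref)))
  names(x) <- sprintf("%s offset=%d", refName(ref), as.integer(refOffset(ref)))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a ReferenceRegion from FASTA
#'
#' @param path FASTA path; an `offset=N` token on the header line is
#'   honoured, otherwise `offset` is used.
#' @param offset Fallback coordinate offset (default 1).
#' @return A [ReferenceRegion-class] (first record).
#' @export
readReferenceFasta <- function(path, offset = 1) {
  x <- Biostrings::readDNAStringSet(path)
  header <- names(x)[1]
  nm <- strsplit(header, "\\s+")[[1]][1]
  m <- regmatches(header, regexpr("offset=\\d+", header))
  if (length(m)) offset <- as.numeric(sub("offset=", "", m))
  ReferenceRegion(nm, offset, as.character(x[[1]]))
}

#' Write simulated read pairs as a FASTQ pair
#'
#' @param reads data.frame from [simulateReadPairs()].
#' @param prefix Output prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` (Phred+33).
#' @return Character vector of the two paths, invisibly.
#' @export
writeReadsFastq <- function(reads, prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (mate in 1:2) {
    seqs <- Biostrings::DNAStringSet(reads[[paste0("seq", mate)]])
    quals <- Biostrings::PhredQuality(reads[[paste0("qual", mate)]])
    x <- Biostrings::QualityScaledDNAStringSet(seqs, quals)
    names(x) <- paste0(reads$qname, "/", mate)
    Biostrings::writeXStringSet(x, paths[mate], format = "fastq",
                                qualities = quals)
  }
  invisible(paths)
}

#' Write alignment records as SAM
#'
#' Emits a valid SAM file (one @SQ line sized to cover the anchored
#' coordinate frame) with soft-clip CIGARs and TLEN set to the signed
#' outer span of each pair.
#'
#' @param alignments Alignment record data.frame.
#' @param ref A [ReferenceRegion-class] (defines the @SQ line).
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
writeSam <- function(alignments, ref, path) {
  a <- alignments
  seqLen <- as.integer(refOffset(ref) + regionLength(ref) - 1)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", refName(ref), seqLen))
  cigar <- ifelse(!a$mapped, "*", paste0(
    ifelse(a$leftClip > 0, paste0(a$leftClip, "S"), ""),
    a$mappedLen, "M",
    ifelse(a$rightClip > 0, paste0(a$rightClip, "S"), "")))
  ## FR library: the mate of a forward read is reverse and vice versa
  flag <- 1L + ifelse(a$properPair, 2L, 0L) + ifelse(a$mapped, 0L, 4L) +
    ifelse(a$mateMapped, 0L, 8L) + ifelse(a$strand == "-", 16L, 0L) +
    ifelse(a$mateMapped & a$strand == "+", 32L, 0L) +
    ifelse(a$first, 64L, 128L)
  lines <- paste(a$qname, flag, ifelse(a$mapped, a$rname, "*"),
                 ifelse(a$mapped, a$pos, 0L),
                 ifelse(a$mapped, 60L, 0L), cigar,
                 ifelse(a$mateMapped, "=", "*"),
                 ifelse(a$mateMapped, a$matePos, 0L),
                 ifelse(is.na(a$isize), 0L, a$isize),
                 ifelse(nzchar(a$seq), a$seq, "*"),
                 ifelse(nzchar(a$qual), a$qual, "*"),
                 paste0("RG:Z:", a$sample),
                 sep = "\t")
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a SAM/BAM file into alignment records
#'
#' Uses Rsamtools to parse the file (SAM input is converted to BAM in a
#' temporary location first) and reconstructs the package's alignment
#' record columns from FLAG, CIGAR and TLEN. Only M/S CIGAR operations
#' are expected (the simulator emits no indel alignments).
#'
#' @param path SAM or BAM path.
#' @return Alignment record data.frame.
#' @export
readSam <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "mpos", "isize",
             "seq", "qual"),
    tag = "RG")
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- b$flag
  mapped <- bitwAnd(flag, 4L) == 0L
  cig <- b$cigar
  leftClip <- rep(0, length(cig))
  hasL <- !is.na(cig) & grepl("^\\d+S", cig)
  leftClip[hasL] <- as.numeric(sub("^(\\d+)S.*", "\\1", cig[hasL]))
  rightClip <- rep(0, length(cig))
  hasR <- !is.na(cig) & grepl("\\d+S$", cig)
  rightClip[hasR] <- as.numeric(sub(".*?(\\d+)S$", "\\1", cig[hasR]))
  mlen <- vapply(cig, function(cc) {
    if (is.na(cc)) return(0)
    ops <- regmatches(cc, gregexpr("\\d+[MIDNSHP=X]", cc))[[1]]
    sum(as.numeric(sub("[A-Z=]$", "", ops[grepl("[MD=X]$", ops)])))
  }, 0, USE.NAMES = FALSE)
  rg <- b$tag$RG
  if (is.null(rg)) rg <- rep(NA_character_, length(flag))
  data.frame(
    qname = b$qname, sample = rg, rname = as.character(b$rname),
    mapped = mapped, pos = ifelse(mapped, b$pos, NA_real_),
    mappedLen = ifelse(mapped, mlen, 0),
    leftClip = ifelse(mapped, leftClip, 0),
    rightClip = ifelse(mapped, rightClip, 0),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    seq = as.character(b$seq), qual = as.character(b$qual),
    matePos = as.numeric(b$mpos),
    mateMapped = bitwAnd(flag, 8L) == 0L,
    isize = as.numeric(b$isize),
    first = bitwAnd(flag, 64L) > 0L,
    properPair = bitwAnd(flag, 2L) > 0L,
    stringsAsFactors = FALSE)
}

#' Write a VariantTable as VCF v4.2
#'
#' Annotations go to QUAL and the INFO column (QD, FS, MQ, MQRankSum,
#' ReadPosRankSum; absent values omitted); genotypes to per-sample GT
#' fields.
#'
#' @param variants A [VariantTable-class].
#' @param path Output VCF path.
#' @return `path`, invisibly.
#' @export
writeVariantVcf <- function(variants, path) {
  info <- variantInfo(variants)
  gt <- genotypes(variants)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=PlumageSV",
           '##INFO=<ID=QD,Number=1,Type=Float,Description="Qual by depth">',
           '##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher strand">',
           '##INFO=<ID=MQ,Number=1,Type=Float,Description="Mapping quality">',
           '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="MQ rank sum">',
           '##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="Read pos rank sum">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(gt)), collapse = "\t"))
  fmtInfo <- function(i) {
    fields <- c(QD = info$QD[i], FS = info$FS[i], MQ = info$MQ[i],
                MQRankSum = info$MQRankSum[i],
                ReadPosRankSum = info$ReadPosRankSum[i])
    fields <- fields[!is.na(fields)]
    if (!length(fields)) return(".")
    paste(sprintf("%s=%.4g", names(fields), fields), collapse = ";")
  }
  infoCol <- vapply(seq_len(nrow(info)), fmtInfo, "")
  body <- paste(info$chrom, as.integer(info$pos), info$id, info$ref,
                info$alt,
                ifelse(is.na(info$QUAL), ".", sprintf("%.4g", info$QUAL)),
                ".", infoCol, "GT",
                apply(gt, 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into a VariantTable
#'
#' Parses with vcfR; annotation fields that are present but not numeric
#' are flagged `malformed` so the hard filter can reject them with a
#' distinct label.
#'
#' @param path VCF path.
#' @return A [VariantTable-class].
#' @export
readVariantVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  malformed <- rep(FALSE, nrow(fix))
  num <- function(x) {
    out <- suppressWarnings(as.numeric(x))
    malformed <<- malformed | (!is.na(x) & x != "." & is.na(out))
    out
  }
  getInfo <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    num(x)
  }
  gtRaw <- vcfR::extract.gt(v, element = "GT")
  gtRaw[is.na(gtRaw)] <- "./."
  gtRaw <- gsub("\\|", "/", gtRaw)
  rownames(gtRaw) <- NULL
  info <- data.frame(
    chrom = fix$CHROM, pos = as.numeric(fix$POS),
    id = ifelse(is.na(fix$ID), ".", fix$ID),
    ref = fix$REF, alt = fix$ALT,
    QUAL = num(fix$QUAL), QD = getInfo("QD"), FS = getInfo("FS"),
    MQ = getInfo("MQ"), MQRankSum = getInfo("MQRankSum"),
    ReadPosRankSum = getInfo("ReadPosRankSum"),
    stringsAsFactors = FALSE)
  info$malformed <- malformed
  VariantTable(info, gtRaw)
}

#' Write a depth or log-ratio track as bedGraph
#'
#' Consecutive equal values are collapsed into one 0-based half-open
#' interval.
#'
#' @param values Numeric per-base track over the region.
#' @param ref The [ReferenceRegion-class] coordinate frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(values, ref, path) {
  r <- rle(values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  off <- refOffset(ref)
  lines <- sprintf("%s\t%d\t%d\t%g", refName(ref),
                   as.integer(off + starts - 2),
                   as.integer(off + ends - 1), r$values)
  writeLines(lines, path)
  invisible(path)
}

#' Write candidate segments or regions as BED
#'
#' @param segments data.frame with 1-based inclusive `start`/`end`
#'   columns (e.g. from [callCandidateSegments()]), or a
#'   [GenomicRanges::GRanges].
#' @param chrom Chromosome name used for data.frame input.
#' @param path Output path (0-based half-open intervals).
#' @return `path`, invisibly.
#' @export
writeBed <- function(segments, chrom, path) {
  if (is(segments, "GRanges")) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(segments)),
                     start = GenomicRanges::start(segments),
                     end = GenomicRanges::end(segments))
  } else {
    df <- data.frame(chrom = chrom, start = segments$start,
                     end = segments$end)
  }
  if (nrow(df) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  writeLines(sprintf("%s\t%d\t%d", df$chrom, as.integer(df$start - 1),
                     as.integer(df$end)), path)
  invisible(path)
}

#' Write a BreakpointCall as a symbolic-allele VCF record
#'
#' One SVTYPE=DEL record: POS is the base before the deletion, the ALT
#' carries that base followed by any junction insertion, and INFO gives
#' END and SVLEN.
#'
#' @param call A resolved [BreakpointCall-class].
#' @param ref The [ReferenceRegion-class] (for the anchor base).
#' @param path Output VCF path.
#' @return `path`, invisibly.
#' @export
writeBreakpointVcf <- function(call, ref, path) {
  if (call@status != "resolved") stop("cannot write an unresolved call")
  anchorPos <- call@delStart - 1
  i <- anchorPos - refOffset(ref) + 1
  anchor <- substr(as.character(refSequence(ref)), i, i)
  hdr <- c("##fileformat=VCFv4.2",
           '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
           '##INFO=<ID=END,Number=1,Type=Integer,Description="Deletion end">',
           '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO"), collapse = "\t"))
  rec <- sprintf("%s\t%d\tDEL1\t%s\t%s\t.\tPASS\tSVTYPE=DEL;END=%d;SVLEN=-%d",
                 refName(ref), as.integer(anchorPos), anchor,
                 paste0(anchor, call@insertedSeq),
                 as.integer(call@delEnd - 1),
                 as.integer(call@deletionLength))
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Write and read the cohort sample sheet
#'
#' @param cohort Sample sheet data.frame.
#' @param path TSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
writeSampleSheet <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSampleSheet
#' @export
readSampleSheet <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
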