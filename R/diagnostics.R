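#' Predict PCR amplicons on a set of haplotype sequences
#'
#' In-silico PCR with exact primer matching: a haplotype yields a
#' product when the forward primer site and the reverse-complemented
#' reverse primer site occur in order within `maxLen` bp. A haplotype
#' with no site, multiple candidate sites for either primer, or only an
#' over-long product gives a no-product result rather than an error.
#'
#' @param haplotypes Named character vector (or
#'   [Biostrings::DNAStringSet]) of template sequences; names label the
#'   alleles (e.g. "wt", "del").
#' @param primers A [PrimerPair-class].
#' @param maxLen Maximum product length searched (default 20000 bp).
#' @return data.frame with columns `allele`, `status` ("product",
#'   "no_site", "multiple_sites", "too_long"), `length` (NA when no
#'   product) and `sequence`.
#' @examples
#' p <- PrimerPair("ACGTACGTACGTACGTA", "TTTTCCCCGGGGAAAAT")
#' tmpl <- paste0("ACGTACGTACGTACGTA", strrep("G", 30),
#'                as.character(Biostrings::reverseComplement(
#'                  Biostrings::DNAString("TTTTCCCCGGGGAAAAT"))))
#' predictAmplicons(c(wt = tmpl), p)$length
#' @export
predictAmplicons <- function(haplotypes, primers, maxLen = 20000) {
  seqs <- if (is(haplotypes, "DNAStringSet")) as.character(haplotypes)
    else haplotypes
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("hap%d", seq_along(seqs))
  fwd <- Biostrings::DNAString(primers@forward)
  revSite <- Biostrings::reverseComplement(
    Biostrings::DNAString(primers@reverse))
  out <- lapply(names(seqs), function(nm) {
    subj <- Biostrings::DNAString(seqs[[nm]])
    fHits <- Biostrings::start(Biostrings::matchPattern(fwd, subj))
    rHits <- Biostrings::end(Biostrings::matchPattern(revSite, subj))
    res <- data.frame(allele = nm, status = "no_site", length = NA_real_,
                      sequence = NA_character_, stringsAsFactors = FALSE)
    if (length(fHits) == 0 || length(rHits) == 0) return(res)
    if (length(fHits) > 1 || length(rHits) > 1) {
      res$status <- "multiple_sites"
      return(res)
    }
    if (rHits <= fHits) return(res)
    len <- rHits - fHits + 1
    if (len > maxLen) {
      res$status <- "too_long"
      return(res)
    }
    res$status <- "product"
    res$length <- len
    res$sequence <- as.character(subj[fHits:rHits])
    res
  })
  do.call(rbind, out)
}

#' Call the deletion genotype from diagnostic PCR products
#'
#' Classifies observed product lengths into the wildtype and deletion
#' size classes (predicted lengths +/- `tolerance`): both classes
#' observed gives "wt/del", only the deletion-size class "del/del", only
#' the wildtype class "wt/wt", and no product a no-call (NA).
#'
#' @param productLengths Numeric vector of observed product lengths for
#'   one sample (possibly empty).
#' @param wtLength,delLength Predicted product lengths of the two
#'   alleles.
#' @param tolerance Size-class half-width in bp (default 50).
#' @return "wt/wt", "wt/del", "del/del" or NA (no call).
#' @examples
#' genotypeFromProducts(c(1205), 8833, 1205)          # "del/del"
#' genotypeFromProducts(c(8833, 1205), 8833, 1205)    # "wt/del"
#' @export
genotypeFromProducts <- function(productLengths, wtLength, delLength,
                                 tolerance = 50) {
  if (!length(productLengths) || all(is.na(productLengths)))
    return(NA_character_)
  hasWt <- any(abs(productLengths - wtLength) <= tolerance, na.rm = TRUE)
  hasDel <- any(abs(productLengths - delLength) <= tolerance, na.rm = TRUE)
  if (hasWt && hasDel) "wt/del"
  else if (hasDel) "del/del"
  else if (hasWt) "wt/wt"
  else NA_character_
}

#' Concordance of genotypes with a recessive phenotype model
#'
#' Checks, sample by sample, the recessive model "affected phenotype if
#' and only if deletion homozygote": a case must be del/del and a
#' control must not be.
#'
#' @param genotypes Character vector ("wt/wt", "wt/del", "del/del" or
#'   NA) per sample.
#' @param phenotypes Character vector aligned with `genotypes`.
#' @param sampleIds Optional sample names for reporting violators.
#' @param caseLabel Phenotype value of affected samples (default "LY").
#' @return List with `n` (samples with a genotype call), `concordant`
#'   (count), `concordance` (fraction; NA when `n` is 0) and `violators`
#'   (character vector of sample ids).
#' @export
recessiveConcordance <- function(genotypes, phenotypes,
                                 sampleIds = NULL, caseLabel = "LY") {
  if (length(genotypes) != length(phenotypes))
    stop("'genotypes' and 'phenotypes' must be aligned")
  if (is.null(sampleIds))
    sampleIds <- sprintf("sample%03d", seq_along(genotypes))
  called <- !is.na(genotypes)
  ok <- (phenotypes == caseLabel) == (genotypes == "del/del")
  ok[!called] <- NA
  n <- sum(called)
  list(n = n,
       concordant = sum(ok, na.rm = TRUE),
       concordance = if (n > 0) sum(ok, na.rm = TRUE) / n else NA_real_,
       violators = sampleIds[called & !ok])
}

#' Predict plumage phenotype from a three-locus genotype
#'
#' Rule engine for the F1 plumage phenotypes segregating in the cross:
#' a male carrying at least one dominant-white allele (*I*, PMEL17) is
#' white regardless of the other loci; a female homozygous for the
#' SOX10 upstream deletion is light yellow (LY); a female with at least
#' one wildtype SOX10 allele and the observed F1 combination I/i with a
#' hemizygous wildtype (gold) Z allele is dark red (DR); any genotype
#' outside the enumerated combinations is labelled "other" rather than
#' guessed. Females are hemizygous at the Z-linked SLC45A2 locus
#' ("S/W" silver or "N/W" wildtype); males carry two Z alleles.
#'
#' @param sox10 "wt/wt", "wt/del" or "del/del".
#' @param pmel17 "I/I", "I/i" or "i/i".
#' @param slc45a2 Males: "S/S", "S/N" or "N/N"; females: "S/W" or "N/W".
#' @param sex "male" or "female".
#' @return One of "white", "LY", "DR", "other".
#' @examples
#' predictPlumage("del/del", "I/I", "N/W", "female")  # LY
#' predictPlumage("wt/del", "I/i", "N/W", "female")   # DR
#' predictPlumage("wt/wt", "I/i", "S/N", "male")      # white
#' @export
predictPlumage <- function(sox10, pmel17, slc45a2, sex) {
  sex <- match.arg(sex, c("male", "female"))
  if (!sox10 %in% c("wt/wt", "wt/del", "del/del"))
    stop("invalid SOX10 genotype: ", sox10)
  if (!pmel17 %in% c("I/I", "I/i", "i/i"))
    stop("invalid PMEL17 genotype: ", pmel17)
  maleZ <- c("S/S", "S/N", "N/N")
  femaleZ <- c("S/W", "N/W")
  if (sex == "male" && !slc45a2 %in% maleZ)
    stop("males carry two Z alleles (S/S, S/N or N/N), got: ", slc45a2)
  if (sex == "female" && !slc45a2 %in% femaleZ)
    stop("females are hemizygous at SLC45A2 (S/W or N/W), got: ", slc45a2)

  if (sex == "male") {
    if (pmel17 %in% c("I/I", "I/i")) return("white")
    return("other")
  }
  if (sox10 == "del/del") return("LY")
  if (pmel17 == "I/i" && slc45a2 == "N/W") return("DR")
  "other"
}

#' Genotype a cohort by in-silico diagnostic PCR
#'
#' Runs [predictAmplicons()] on each sample's two haplotypes (wildtype
#' or deletion sequence according to the sample sheet truth or supplied
#' sequences) and calls genotypes with [genotypeFromProducts()].
#'
#' @param cohort Sample sheet from [simulateCohort()].
#' @param wtSeq,delSeq Wildtype and deletion haplotype sequences
#'   (character).
#' @param primers A [PrimerPair-class].
#' @param maxLen,tolerance See [predictAmplicons()] and
#'   [genotypeFromProducts()].
#' @return data.frame with columns `sample_id`, `phenotype`,
#'   `true_genotype`, `pcr_genotype`, `products` (comma-separated
#'   lengths).
#' @export
pcrGenotypeCohort <- function(cohort, wtSeq, delSeq, primers,
                              maxLen = 20000, tolerance = 50) {
  preds <- predictAmplicons(c(wt = wtSeq, del = delSeq), primers, maxLen)
  lenFor <- setNames(preds$length, preds$allele)
  if (any(is.na(lenFor[c("wt", "del")])))
    stop("diagnostic primers fail to amplify a haplotype: check primer sites")
  hapAlleles <- list("wt/wt" = c("wt", "wt"), "wt/del" = c("wt", "del"),
                     "del/del" = c("del", "del"))
  calls <- vapply(cohort$del_genotype, function(g) {
    lens <- unique(lenFor[hapAlleles[[g]]])
    genotypeFromProducts(lens, lenFor[["wt"]], lenFor[["del"]], tolerance)
  }, "", USE.NAMES = FALSE)
  products <- vapply(cohort$del_genotype, function(g)
    paste(unique(lenFor[hapAlleles[[g]]]), collapse = ","), "",
    USE.NAMES = FALSE)
  data.frame(sample_id = cohort$sample_id, phenotype = cohort$phenotype,
             true_genotype = cohort$del_genotype, pcr_genotype = calls,
             products = products, stringsAsFactors = FALSE)
}
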