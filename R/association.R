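#' Tally the 2x2 allele table for one biallelic variant
#'
#' Rows are (case, control), columns (alt allele, ref allele). Each
#' non-missing diploid genotype contributes two alleles; missing
#' genotypes are excluded.
#'
#' @param gt Character vector of VCF-style genotypes, one per sample.
#' @param isCase Logical vector, TRUE for cases, aligned with `gt`.
#' @return 2x2 integer matrix with dimnames
#'   `list(c("case","control"), c("alt","ref"))`.
#' @examples
#' alleleTable(c("1/1", "1/1", "0/0", "0/0"), c(TRUE, TRUE, FALSE, FALSE))
#' @export
alleleTable <- function(gt, isCase) {
  if (length(gt) != length(isCase))
    stop("'gt' and 'isCase' must have the same length")
  altCount <- altDose(gt)
  ok <- !is.na(altCount)
  tab <- matrix(0L, 2, 2,
                dimnames = list(c("case", "control"), c("alt", "ref")))
  for (grp in 1:2) {
    sel <- ok & (isCase == (grp == 1))
    tab[grp, 1] <- sum(altCount[sel])
    tab[grp, 2] <- 2L * sum(sel) - sum(altCount[sel])
  }
  tab
}

## Alt-allele dosage (0/1/2) per genotype string; NA for missing. Errors on
## anything that is not a diploid biallelic call.
altDose <- function(gt) {
  dose <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
            "./." = NA_integer_, "." = NA_integer_)
  unknown <- !(gt %in% names(dose))
  if (any(unknown))
    stop("non-biallelic or malformed genotype: ", gt[which(unknown)[1]])
  unname(dose[gt])
}

#' Allelic 1-df Pearson chi-square test on a 2x2 allele table
#'
#' The basic allelic case/control association test: Pearson chi-square on
#' allele counts, 1 degree of freedom, no continuity correction, p-value
#' from the upper tail. A monomorphic site (a zero margin) is flagged and
#' assigned statistic 0, p = 1.
#'
#' @param tab 2x2 matrix as returned by [alleleTable()].
#' @return List with `chisq`, `p`, `negLog10P`, `monomorphic`.
#' @examples
#' allelicChiSquare(matrix(c(78, 0, 0, 80), 2, 2))  # complete separation
#' @export
allelicChiSquare <- function(tab) {
  if (sum(tab) == 0) stop("empty allele table")
  r <- rowSums(tab); cc <- colSums(tab); N <- sum(tab)
  if (any(r == 0) || any(cc == 0))
    return(list(chisq = 0, p = 1, negLog10P = 0, monomorphic = TRUE))
  chisq <- N * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    (r[1] * r[2] * cc[1] * cc[2])
  chisq <- unname(chisq)
  logP <- pchisq(chisq, df = 1, lower.tail = FALSE, log.p = TRUE)
  list(chisq = chisq, p = exp(logP), negLog10P = -logP / log(10),
       monomorphic = FALSE)
}

#' Bonferroni genome-wide significance threshold on the -log10 scale
#'
#' @param nVariants Number of tested variants (>= 1).
#' @param alpha Family-wise error rate (default 0.05).
#' @return `-log10(alpha / nVariants)`.
#' @examples
#' round(bonferroniThreshold(16745104), 2)  # 8.52
#' @export
bonferroniThreshold <- function(nVariants, alpha = 0.05) {
  if (nVariants < 1) stop("'nVariants' must be >= 1")
  -log10(alpha / nVariants)
}

#' Per-SNP case-control association scan
#'
#' Runs [allelicChiSquare()] at every variant and reports plink
#' `.assoc`-style columns, including the allele frequencies in cases
#' (`F_A`) and controls (`F_U`).
#'
#' @param variants A [VariantTable-class].
#' @param phenotypes Character vector aligned with the sample columns;
#'   values equal to `caseLabel` are cases.
#' @param caseLabel Phenotype value treated as "case" (default "LY").
#' @return data.frame with columns CHR, SNP, BP, A1, F_A, F_U, A2, CHISQ,
#'   P, NEG_LOG10_P, MONOMORPHIC, position-sorted.
#' @export
associationScan <- function(variants, phenotypes, caseLabel = "LY") {
  info <- variantInfo(variants)
  gt <- genotypes(variants)
  if (length(phenotypes) != ncol(gt))
    stop("one phenotype per sample column is required")
  isCase <- phenotypes == caseLabel
  res <- lapply(seq_len(nrow(info)), function(i) {
    tab <- alleleTable(gt[i, ], isCase)
    s <- allelicChiSquare(tab)
    fa <- if (sum(tab[1, ]) > 0) tab[1, 1] / sum(tab[1, ]) else NA_real_
    fu <- if (sum(tab[2, ]) > 0) tab[2, 1] / sum(tab[2, ]) else NA_real_
    c(fa, fu, s$chisq, s$p, s$negLog10P, s$monomorphic)
  })
  m <- do.call(rbind, res)
  out <- data.frame(CHR = info$chrom, SNP = info$id, BP = info$pos,
                    A1 = info$alt, F_A = m[, 1], F_U = m[, 2],
                    A2 = info$ref, CHISQ = m[, 3], P = m[, 4],
                    NEG_LOG10_P = m[, 5], MONOMORPHIC = m[, 6] == 1,
                    stringsAsFactors = FALSE)
  out[order(out$CHR, out$BP), , drop = FALSE]
}

#' Merge significant SNPs into regions
#'
#' Maximal runs of SNPs at or above the threshold, with runs separated by
#' at most `mergeGap` bp joined into one region.
#'
#' @param results data.frame from [associationScan()], position-sorted.
#' @param threshold Significance threshold on the -log10(p) scale.
#' @param mergeGap Maximum gap (bp) between merged significant SNPs.
#' @return A [GenomicRanges::GRanges] of significant regions with
#'   metadata columns `nSnps` and `peakNegLog10P` (empty when nothing is
#'   significant).
#' @export
significantRegions <- function(results, threshold, mergeGap = 10000) {
  hit <- results[results$NEG_LOG10_P >= threshold, , drop = FALSE]
  if (nrow(hit) == 0)
    return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(hit$CHR, IRanges::IRanges(hit$BP, hit$BP),
                               negLog10P = hit$NEG_LOG10_P)
  red <- GenomicRanges::reduce(gr, min.gapwidth = mergeGap + 1)
  ov <- GenomicRanges::findOverlaps(gr, red)
  S4Vectors::mcols(red)$nSnps <- as.integer(table(S4Vectors::subjectHits(ov)))
  S4Vectors::mcols(red)$peakNegLog10P <- vapply(
    split(hit$NEG_LOG10_P, S4Vectors::subjectHits(ov)), max, 0,
    USE.NAMES = FALSE)
  red
}
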