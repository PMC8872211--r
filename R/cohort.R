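#' Simulate a case-control cohort for a recessive deletion allele
#'
#' Cases (phenotype "LY") are homozygous for the deletion; controls
#' (phenotype "DR") are heterozygous carriers with probability
#' `hetFractionControls` and homozygous wildtype otherwise, mirroring a
#' fully penetrant recessive trait in an F1 intercross.
#'
#' @param nCases,nControls Cohort sizes (>= 1).
#' @param hetFractionControls Probability that a control is wt/del.
#' @param seed Integer seed.
#' @return A data.frame (sample sheet) with columns `sample_id`,
#'   `phenotype` ("LY" for cases, "DR" for controls) and `del_genotype`
#'   ("wt/wt", "wt/del" or "del/del").
#' @examples
#' simulateCohort(3, 4, 0.5, seed = 1)
#' @export
simulateCohort <- function(nCases, nControls, hetFractionControls = 0.5,
                           seed = 1) {
  if (nCases < 1 || nControls < 1)
    stop("'nCases' and 'nControls' must be >= 1")
  if (hetFractionControls < 0 || hetFractionControls > 1)
    stop("'hetFractionControls' must lie in [0, 1]")
  withSeed(seed, {
    ctrlHet <- runif(nControls) < hetFractionControls
  })
  data.frame(
    sample_id = c(sprintf("LY%02d", seq_len(nCases)),
                  sprintf("DR%02d", seq_len(nControls))),
    phenotype = c(rep("LY", nCases), rep("DR", nControls)),
    del_genotype = c(rep("del/del", nCases),
                     ifelse(ctrlHet, "wt/del", "wt/wt")),
    stringsAsFactors = FALSE)
}

## Per-sample haplotype deletion indicators (2 columns: haplotype A/B).
delHaplotypes <- function(cohort) {
  g <- cohort$del_genotype
  cbind(A = as.integer(g %in% c("del/del", "wt/del")),
        B = as.integer(g == "del/del"))
}
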