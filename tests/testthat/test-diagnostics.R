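studyPrimers <- function() {
  PrimerPair("TTTGCTCCCAACCCCTCATC", "AGCCATCGGAAAAGAAGCCA")
}

# Haplotypes with the diagnostic primer sites planted at their published
# coordinates around the 7638 bp deletion.
diagnosticStudy <- function(seed = 60) {
  cfg <- defaultConfig(seed)
  cfg$reads$coverage <- 0.1       # sequences only; reads are irrelevant here
  cfg$cohort <- list(nCases = 2L, nControls = 2L, hetFractionControls = 0.5)
  cfg$snps$n <- 2L
  cfg$depth$poolSize <- 2L
  simulateStudy(cfg)
}

test_that("amplicon lengths reproduce the diagnostic PCR arithmetic", {
  sim <- diagnosticStudy()
  amp <- predictAmplicons(c(wt = sim$wt$sequence, del = sim$del$sequence),
                          studyPrimers())
  expect_equal(amp$status, c("product", "product"))
  # wildtype: 51,043,419 - 51,034,587 + 1; deletion: 7638 bp out, 10 bp in
  expect_equal(amp$length[amp$allele == "wt"], 8833)
  expect_equal(amp$length[amp$allele == "del"], 8833 - 7638 + 10)
  # products begin/end with the primer and the reverse-complement site
  expect_true(startsWith(amp$sequence[1], "TTTGCTCCCAACCCCTCATC"))
  expect_true(endsWith(amp$sequence[1], as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(
      "AGCCATCGGAAAAGAAGCCA")))))
  # allele length difference equals deletion length minus insertion length
  expect_equal(amp$length[amp$allele == "wt"] -
                 amp$length[amp$allele == "del"], 7638 - 10)
})

test_that("primers absent or ambiguous give no-product results, not errors", {
  none <- predictAmplicons(c(x = strrep("ACGT", 100)), studyPrimers())
  expect_equal(none$status, "no_site")
  expect_true(is.na(none$length))

  dup <- paste0("TTTGCTCCCAACCCCTCATC", strrep("A", 30),
                "TTTGCTCCCAACCCCTCATC", strrep("C", 30),
                as.character(Biostrings::reverseComplement(
                  Biostrings::DNAString("AGCCATCGGAAAAGAAGCCA"))))
  expect_equal(predictAmplicons(c(x = dup), studyPrimers())$status,
               "multiple_sites")

  tooLong <- predictAmplicons(c(wt = diagnosticStudy()$wt$sequence),
                              studyPrimers(), maxLen = 5000)
  expect_equal(tooLong$status, "too_long")
})

test_that("genotypes follow the product size classes", {
  expect_equal(genotypeFromProducts(1205, 8833, 1205), "del/del")
  expect_equal(genotypeFromProducts(c(8833, 1205), 8833, 1205), "wt/del")
  expect_equal(genotypeFromProducts(8833, 8833, 1205), "wt/wt")
  expect_true(is.na(genotypeFromProducts(numeric(0), 8833, 1205)))
  # tolerance window
  expect_equal(genotypeFromProducts(1240, 8833, 1205), "del/del")
  expect_true(is.na(genotypeFromProducts(4000, 8833, 1205)))
})

test_that("in-silico PCR genotypes match the simulator's truth", {
  cfg <- defaultConfig(61)
  cfg$reads$coverage <- 0.1
  cfg$cohort <- list(nCases = 10L, nControls = 10L,
                     hetFractionControls = 0.5)
  cfg$snps$n <- 2L
  cfg$depth$poolSize <- 10L
  sim <- simulateStudy(cfg)
  tab <- pcrGenotypeCohort(sim$cohort, sim$wt$sequence, sim$del$sequence,
                           studyPrimers())
  expect_identical(tab$pcr_genotype, tab$true_genotype)
  conc <- recessiveConcordance(tab$pcr_genotype, tab$phenotype,
                               tab$sample_id)
  expect_equal(conc$concordance, 1.0)
  expect_length(conc$violators, 0)
})

test_that("recessive concordance flags violators and handles empty input", {
  g <- c("del/del", "wt/del", "del/del")
  p <- c("LY", "DR", "DR")                  # third sample violates
  r <- recessiveConcordance(g, p, c("a", "b", "c"))
  expect_equal(r$concordance, 2 / 3)
  expect_equal(r$violators, "c")
  empty <- recessiveConcordance(character(0), character(0))
  expect_equal(empty$n, 0)
  expect_true(is.na(empty$concordance))
})

test_that("plumage rule engine encodes the cross's allele combinations", {
  # males carrying dominant white are white regardless of SOX10
  expect_equal(predictPlumage("wt/wt", "I/i", "S/N", "male"), "white")
  expect_equal(predictPlumage("del/del", "I/I", "S/S", "male"), "white")
  expect_equal(predictPlumage("wt/del", "i/i", "N/N", "male"), "other")
  # females: deletion homozygotes are light yellow
  expect_equal(predictPlumage("del/del", "I/I", "N/W", "female"), "LY")
  expect_equal(predictPlumage("del/del", "I/i", "S/W", "female"), "LY")
  # the observed dark-red combination
  expect_equal(predictPlumage("wt/del", "I/i", "N/W", "female"), "DR")
  expect_equal(predictPlumage("wt/wt", "I/i", "N/W", "female"), "DR")
  # combinations outside the enumerated set are not guessed
  expect_equal(predictPlumage("wt/del", "I/I", "N/W", "female"), "other")
  expect_equal(predictPlumage("wt/del", "I/i", "S/W", "female"), "other")
  # sex/allele arity is enforced
  expect_error(predictPlumage("wt/wt", "I/i", "S/W", "male"), "two Z")
  expect_error(predictPlumage("wt/wt", "I/i", "S/N", "female"), "hemizygous")

  # total and deterministic over the enumerated genotype space
  for (sox in c("wt/wt", "wt/del", "del/del"))
    for (pm in c("I/I", "I/i", "i/i"))
      for (z in c("S/W", "N/W")) {
        out <- predictPlumage(sox, pm, z, "female")
        expect_true(out %in% c("white", "LY", "DR", "other"))
        expect_identical(out, predictPlumage(sox, pm, z, "female"))
      }
})
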