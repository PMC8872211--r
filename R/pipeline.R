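#' Default pipeline configuration
#'
#' The study conditions emulated by the synthetic pipeline: a 200 kb
#' reference anchored so the published breakpoint coordinates fall
#' inside, the 7638 bp deletion with the 10 bp GGTGCGGTGA junction
#' insertion, 39 deletion-homozygous cases and 40 controls
#' (heterozygous or wildtype at equal rates), linked SNPs, 5X 150 bp
#' paired-end reads with a 500/50 fragment model, the six hard-filter
#' thresholds, and the downstream scan parameters.
#'
#' @param seed Master seed; per-stage seeds derive from it via
#'   [deriveSeed()].
#' @return Nested configuration list.
#' @export
defaultConfig <- function(seed = 1) {
  list(
    seed = seed,
    region = list(name = "chr1", length = 200000L, offset = 50935000,
                  gc = 0.42),
    edit = list(delStart = 51035106, delEnd = 51042744,
                insertedSeq = "GGTGCGGTGA"),
    primers = list(forward = "TTTGCTCCCAACCCCTCATC",
                   reverse = "AGCCATCGGAAAAGAAGCCA",
                   forwardStart = 51034587, reverseEnd = 51043419),
    cohort = list(nCases = 39L, nControls = 40L,
                  hetFractionControls = 0.5),
    snps = list(n = 200L, r2AtZero = 1.0, decayBp = 20000,
                missingRate = 0.02, annotationFailRate = 0.05,
                annotationAbsentRate = 0.1),
    reads = list(coverage = 5, readLen = 150L, fragMean = 500,
                 fragSd = 50, errorRate = 0.001, minAnchor = 20L),
    filters = list(qual = 30.0, qd = 5.0, fs = 60.0, mq = 40.0,
                   mqRankSum = -12.5, readPosRankSum = -8.0,
                   clusterWindow = 10L, clusterCount = 3L,
                   callRate = 0.8),
    assoc = list(alpha = 0.05, mergeGap = 10000),
    depth = list(poolSize = 10L, pseudocount = 1, smoothWindow = 201L,
                 minLen = 500L, threshold = 1, normalize = TRUE),
    inserts = list(discordantZ = 5, margin = 0.05, minSupport = 3L),
    breakpoint = list(minClip = 20L, minSupport = 2L,
                      searchWindow = 20000, minAnchor = 20L),
    pcr = list(maxLen = 20000, tolerance = 50))
}

#' Validate a pipeline configuration
#'
#' @param config Configuration list (see [defaultConfig()]).
#' @return Character vector of violations; empty when the configuration
#'   is valid.
#' @export
validateConfig <- function(config) {
  v <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(is.numeric(config$seed) && length(config$seed) == 1,
      "seed must be a single number")
  chk(config$region$length >= 1000, "region length must be >= 1000 bp")
  chk(config$region$gc > 0 && config$region$gc < 1,
      "region gc must lie strictly in (0, 1)")
  chk(config$region$offset >= 1, "region offset must be >= 1")
  chk(config$edit$delEnd >= config$edit$delStart,
      "edit delEnd must be >= delStart")
  chk(config$edit$delStart >= config$region$offset &&
        config$edit$delEnd <= config$region$offset + config$region$length,
      "edit interval must lie inside the region")
  chk(!grepl("[^ACGT]", config$edit$insertedSeq) ||
        config$edit$insertedSeq == "",
      "insertedSeq must be ACGT only")
  chk(config$cohort$nCases >= 1, "nCases must be >= 1")
  chk(config$cohort$nControls >= 1, "nControls must be >= 1")
  chk(config$cohort$hetFractionControls >= 0 &&
        config$cohort$hetFractionControls <= 1,
      "hetFractionControls must lie in [0, 1]")
  chk(config$snps$n >= 1, "snps n must be >= 1")
  chk(config$reads$coverage > 0, "coverage must be positive")
  chk(config$reads$fragMean >= config$reads$readLen,
      "fragMean must be >= readLen")
  chk(config$depth$poolSize >= 1, "depth poolSize must be >= 1")
  chk(config$depth$poolSize <= min(config$cohort$nCases,
                                   config$cohort$nControls),
      "depth poolSize cannot exceed either cohort size")
  chk(config$assoc$alpha > 0 && config$assoc$alpha < 1,
      "alpha must lie in (0, 1)")
  v
}

#' Simulate the full synthetic study
#'
#' Builds the reference (with the diagnostic primer sites planted at
#' their published coordinates), the deletion haplotype, the cohort,
#' linked SNPs with calling annotations, and per-sample reads with
#' truth alignments.
#'
#' @param config Configuration list ([defaultConfig()]).
#' @return List with `ref`, `edit`, `wt`, `del` (haplotype lists),
#'   `cohort`, `variants`, `alignments`, `reads`.
#' @export
simulateStudy <- function(config) {
  violations <- validateConfig(config)
  if (length(violations))
    stop("invalid configuration:\n  ", paste(violations, collapse = "\n  "))
  cfg <- config
  ref <- buildReference(cfg$region$length, cfg$region$offset,
                        cfg$region$gc, deriveSeed(cfg$seed, "reference"),
                        cfg$region$name)
  if (!is.null(cfg$primers)) {
    revSite <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cfg$primers$reverse)))
    ref <- plantSequence(ref, cfg$primers$forwardStart, cfg$primers$forward)
    ref <- plantSequence(ref,
                         cfg$primers$reverseEnd - nchar(revSite) + 1,
                         revSite)
  }
  edit <- HaplotypeEdit(cfg$edit$delStart, cfg$edit$delEnd,
                        cfg$edit$insertedSeq)
  ref <- makeEditCanonical(ref, edit)
  wt <- applyEdit(ref, HaplotypeEdit(delStart(edit), delStart(edit), ""))
  del <- applyEdit(ref, edit)
  cohort <- simulateCohort(cfg$cohort$nCases, cfg$cohort$nControls,
                           cfg$cohort$hetFractionControls,
                           deriveSeed(cfg$seed, "cohort"))
  variants <- plantLinkedSnps(ref, edit, cohort, cfg$snps$n,
                              cfg$snps$r2AtZero, cfg$snps$decayBp,
                              deriveSeed(cfg$seed, "snps"),
                              cfg$snps$missingRate)
  variants <- simulateAnnotations(variants, cfg$snps$annotationFailRate,
                                  cfg$snps$annotationAbsentRate,
                                  deriveSeed(cfg$seed, "annotations"))
  sim <- simulateCohortReads(cohort, ref, edit,
                             seed = deriveSeed(cfg$seed, "reads"),
                             coverage = cfg$reads$coverage,
                             readLen = cfg$reads$readLen,
                             fragMean = cfg$reads$fragMean,
                             fragSd = cfg$reads$fragSd,
                             errorRate = cfg$reads$errorRate,
                             minAnchor = cfg$reads$minAnchor)
  list(ref = ref, edit = edit, wt = wt, del = del, cohort = cohort,
       variants = variants, alignments = sim$alignments,
       reads = sim$reads)
}

## On a random reference the planted edit may coincidentally admit a
## smaller-insertion equivalent representation (insertion boundary bases
## matching adjacent deleted bases). The generator breaks such ties by
## substituting the offending deleted boundary bases, so the planted
## coordinates are the canonical representation the resolver reports --
## as they are for the published edit on the real genome.
makeEditCanonical <- function(ref, edit) {
  ins <- insertedSeq(edit)
  s <- delStart(edit); e <- delEnd(edit)
  if (e <= s) return(ref)
  refChar <- as.character(refSequence(ref))
  off <- refOffset(ref)
  base <- function(g) substr(refChar, g - off + 1, g - off + 1)
  other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  if (nzchar(ins)) {
    first <- substr(ins, 1, 1)
    last <- substr(ins, nchar(ins), nchar(ins))
    if (base(s) == first) ref <- plantSequence(ref, s, other(first))
    if (e - 1 > s && base(e - 1) == last)
      ref <- plantSequence(ref, e - 1, other(last))
  } else if (s - 1 >= off && base(s - 1) == base(e - 1)) {
    ref <- plantSequence(ref, e - 1, other(base(e - 1)))
  }
  ref
}

#' Run the full analysis pipeline on synthetic data
#'
#' simulate -> filter -> association -> depth-ratio scan -> insert-size
#' SV typing -> breakpoint resolution -> PCR genotyping and recessive
#' concordance, as one reproducible run. Stage outputs are written
#' under `outDir` (FASTA/VCF/SAM/TSV/BED/bedGraph/JSON) when it is
#' given; the returned report collects the key numbers, each taken
#' directly from its stage's output.
#'
#' @param config Configuration list ([defaultConfig()]).
#' @param outDir Optional output directory (created if needed).
#' @param writeReads Also write per-sample FASTQ (large; default FALSE).
#' @return Report list: seed, variant counts, Bonferroni threshold,
#'   significant regions, candidate segment, SV call, breakpoint call,
#'   PCR genotypes and concordance.
#' @export
runPipeline <- function(config = defaultConfig(), outDir = NULL,
                        writeReads = FALSE) {
  violations <- validateConfig(config)
  if (length(violations))
    stop("invalid configuration:\n  ", paste(violations, collapse = "\n  "))
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  out <- function(f) if (is.null(outDir)) NULL else file.path(outDir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  sim <- stage("simulate", simulateStudy(config))
  if (!is.null(outDir)) {
    writeReferenceFasta(sim$ref, out("reference.fa"))
    writeSampleSheet(sim$cohort, out("samples.tsv"))
    writeVariantVcf(sim$variants, out("variants.vcf"))
    writeSam(sim$alignments, sim$ref, out("alignments.sam"))
    if (writeReads)
      for (s in names(sim$reads))
        writeReadsFastq(sim$reads[[s]], out(s))
  }

  fcfg <- config$filters
  filt <- stage("filter", filterVariants(
    sim$variants,
    thresholds = list(qual = fcfg$qual, qd = fcfg$qd, fs = fcfg$fs,
                      mq = fcfg$mq, mqRankSum = fcfg$mqRankSum,
                      readPosRankSum = fcfg$readPosRankSum),
    clusterWindow = fcfg$clusterWindow, clusterCount = fcfg$clusterCount,
    callRate = fcfg$callRate))
  if (!is.null(outDir))
    writeVariantVcf(filt$variants, out("variants.filtered.vcf"))

  assoc <- stage("association", {
    res <- associationScan(filt$variants, sim$cohort$phenotype)
    thr <- bonferroniThreshold(nVariants(filt$variants),
                               config$assoc$alpha)
    regions <- significantRegions(res, thr, config$assoc$mergeGap)
    list(results = res, threshold = thr, regions = regions)
  })
  if (!is.null(outDir)) {
    write.table(assoc$results, out("assoc.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeBed(assoc$regions, config$region$name, out("assoc.regions.bed"))
  }

  depth <- stage("depthscan", {
    casePool <- head(sim$cohort$sample_id[sim$cohort$phenotype == "DR"],
                     config$depth$poolSize)
    ctrlPool <- head(sim$cohort$sample_id[sim$cohort$phenotype == "LY"],
                     config$depth$poolSize)
    dA <- pooledDepth(sim$alignments, casePool, sim$ref)   # DR pool
    dB <- pooledDepth(sim$alignments, ctrlPool, sim$ref)   # LY pool
    ratio <- logDepthRatio(dA, dB, config$depth$pseudocount,
                           config$depth$normalize)
    segs <- callCandidateSegments(ratio, sim$ref, config$depth$threshold,
                                  config$depth$minLen,
                                  config$depth$smoothWindow)
    list(ratio = ratio, segments = segs, drPool = casePool,
         lyPool = ctrlPool)
  })
  if (!is.null(outDir)) {
    writeBedGraph(depth$ratio, sim$ref, out("depth.logratio.bedGraph"))
    writeBed(depth$segments, config$region$name, out("depth.segments.bed"))
  }
  candidate <- if (nrow(depth$segments))
    as.numeric(depth$segments[which.max(abs(depth$segments$meanRatio)),
                              c("start", "end")])
  else c(delStart(sim$edit), delEnd(sim$edit))

  sv <- stage("insertscan", {
    caseProf <- extractApparentInserts(sim$alignments, candidate, "LY",
                                       depth$lyPool)
    ctrlProf <- extractApparentInserts(sim$alignments, candidate, "DR",
                                       depth$drPool)
    call <- classifySV(caseProf, ctrlProf, config$reads$fragMean,
                       config$reads$fragSd, config$inserts$discordantZ,
                       config$inserts$margin, config$inserts$minSupport)
    list(caseProfile = caseProf, controlProfile = ctrlProf, call = call)
  })

  bp <- stage("breakpoint", {
    caseAln <- sim$alignments[
      sim$alignments$sample %in%
        sim$cohort$sample_id[sim$cohort$phenotype == "LY"], , drop = FALSE]
    resolveDeletion(caseAln, sim$ref,
                    minClip = config$breakpoint$minClip,
                    minSupport = config$breakpoint$minSupport,
                    searchWindow = config$breakpoint$searchWindow,
                    minAnchor = config$breakpoint$minAnchor)
  })
  if (!is.null(outDir) && bp@status == "resolved") {
    jsonlite::write_json(
      list(delStart = bp@delStart, delEnd = bp@delEnd,
           insertedSeq = bp@insertedSeq,
           deletionLength = bp@deletionLength, support = bp@support),
      out("breakpoint.json"), auto_unbox = TRUE, digits = NA)
    writeBreakpointVcf(bp, sim$ref, out("breakpoint.vcf"))
  }

  diag <- stage("diagnose", {
    if (is.null(config$primers))
      stop("diagnostic PCR stage requires primers in the configuration")
    primers <- PrimerPair(config$primers$forward, config$primers$reverse)
    gtTab <- pcrGenotypeCohort(sim$cohort, sim$wt$sequence,
                               sim$del$sequence, primers,
                               config$pcr$maxLen, config$pcr$tolerance)
    conc <- recessiveConcordance(gtTab$pcr_genotype, gtTab$phenotype,
                                 gtTab$sample_id)
    list(genotypes = gtTab, concordance = conc)
  })
  if (!is.null(outDir))
    write.table(diag$genotypes, out("pcr_genotypes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

  report <- list(
    seed = config$seed,
    nSamples = nrow(sim$cohort),
    variants = list(simulated = nVariants(sim$variants),
                    afterFilters = nVariants(filt$variants),
                    filterReport = filt$report),
    association = list(
      threshold = assoc$threshold,
      nSignificant = sum(assoc$results$NEG_LOG10_P >= assoc$threshold),
      regions = if (length(assoc$regions) == 0) NULL else data.frame(
        start = GenomicRanges::start(assoc$regions),
        end = GenomicRanges::end(assoc$regions),
        peak = S4Vectors::mcols(assoc$regions)$peakNegLog10P)),
    depth = list(candidateSegments = depth$segments),
    svCall = list(type = svType(sv$call), netSize = netSize(sv$call),
                  support = sv$call@support),
    breakpoint = list(status = bp@status, delStart = bp@delStart,
                      delEnd = bp@delEnd, insertedSeq = bp@insertedSeq,
                      deletionLength = bp@deletionLength,
                      support = bp@support),
    concordance = diag$concordance)
  if (!is.null(outDir))
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE, null = "null")
  report
}
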