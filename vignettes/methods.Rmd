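---
title: "Methods: mapping a recessive plumage deletion from short reads"
author: "PlumageSV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping a recessive plumage deletion from short reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The inference problem

A recessive plumage phenotype (light yellow, LY) segregates against dark
red (DR) in F1 intercross hens. The causal allele is a non-coding deletion
upstream of *SOX10*: roughly 7.6 kb of chromosome 1 absent from the LY
haplotype, with a 10 bp non-templated insertion (GGTGCGGTGA) at the
junction. Nothing in a SNP callset represents this allele directly, so the
package chains several independent read-level signals — association at
linked SNPs, pooled depth contrast, discordant insert sizes, soft-clipped
junction reads, and a diagnostic PCR — each implemented as a separately
testable stage over common data structures (`ReferenceRegion`,
`HaplotypeEdit`, `CoordinateMap`, alignment records, `VariantTable`,
`BreakpointCall`).

# Coordinate conventions

All coordinates are 1-based and inclusive, anchored by an `offset` so a
short synthetic sequence can carry published chromosome coordinates. The
one deliberate exception is the deletion-length convention: an edit removes
the bases `[delStart, delEnd - 1]` and its reported length is
`delEnd - delStart`. This convention is fixed by the published numbers
themselves: breakpoints 51,035,106 and 51,042,744 are reported with a
length of 7638 bp, which is their difference, not the inclusive count
(7639). The inclusive alternative is rejected for that reason and the
difference is worth a sentence because it is easy to re-introduce silently.

## Canonical edit representation

A deletion with a junction insertion is not a unique object: whenever the
first (last) inserted base equals the first (last) deleted base, one base
can migrate between deletion and insertion without changing the edited
sequence, and a pure deletion can slide across junction micro-homology.
The breakpoint resolver always reports the *minimal-insertion, leftmost*
representation — the same normalization an aligner-style caller would
apply. `canonicalEdit()` converts any planted edit to this form so tests
compare like with like, and the synthetic generator substitutes the
(deleted) boundary bases of the random reference when they would create a
spurious equivalent representation, so the planted printed coordinates
*are* the canonical answer, as they are for the real genome where the
published representation is the observed one.

# The synthetic generator

The generator defines the study conditions; every stage is exercised
against it.

* **Reference**: i.i.d. bases at a target GC of 0.42 (typical for this
  genome region), 200 kb anchored at 50,935,000 so the published
  coordinates fall inside. Diagnostic primer sites are planted verbatim at
  their published positions (51,034,587 for the forward primer; the
  reverse-complement site ending at 51,043,419), since random sequence
  cannot be expected to contain them.
* **Cohort**: 39 LY cases, all del/del, and 40 DR controls, wt/del or
  wt/wt with equal probability — full penetrance of a recessive allele in
  an intercross where every case is a deletion homozygote and no control
  is. The heterozygote fraction of 0.5 is the neutral choice for an F2-like
  segregating cross; it is configurable.
* **Linked SNPs**: each SNP receives a target `r²` with the deletion that
  decays exponentially with distance from the nearer breakpoint,
  `r²(d) = r²₀ · exp(−d / decay)`, default decay scale 20 kb — a typical
  within-cross LD range. Genotypes are drawn per haplotype: the SNP allele
  copies the haplotype's deletion indicator with a calibrated probability
  and is otherwise an independent draw at the deletion-allele frequency.
  The calibration matters: in a case-control cohort the two haplotypes of a
  sample are positively correlated (every case is del/del), which inflates
  genotype-level `r²` above the haplotype copy probability squared, so the
  copy probability is solved from
  `r² = q²(V₀ + C)/(V₀ + q²C)` with `V₀ = 2p(1−p)` and `C` twice the
  haplotype covariance. Genotypes are set missing at 2% so the call-rate
  filter has work to do.
* **Calling annotations** (QUAL, QD, FS, MQ, rank sums) are drawn from
  pass/fail mixtures with a configurable per-rule failure rate (default
  5%), and rank-sum fields are absent at 10% — these annotations are
  undefined at sites without heterozygous evidence in real callsets.
* **Reads**: fragments are normal(500, 50) bp, resampled below the 150 bp
  read length; 2×150 bp reads are cut from the fragment ends (FR
  orientation), substitution noise is uniform at 0.1%, and base qualities
  are constant Q30. The pair count is sized to the *haplotype* being
  sequenced, so realized depth over non-deleted sequence equals the nominal
  coverage (5X by default, matching the study's sequencing depth).
* **Truth alignments by projection**: no heuristic aligner is implemented
  or invoked. Each read's placement follows from the haplotype-to-reference
  `CoordinateMap`: reads inside a collinear block map ungapped; reads
  crossing the junction are soft-clipped there and anchored on the side
  with the longer mapped run (ties to the left), or flagged unmapped when
  neither side reaches the 20 bp minimum anchor. 20 bp keeps clip clusters
  unambiguous at these scales while still losing essentially no junction
  reads (a 150 bp read always has ≥ 20 bp on one side of a 10 bp
  insertion). Apparent insert size is the outer reference span of the pair
  (TLEN semantics), signed positive on the leftmost mate.

What the generator does **not** emulate: indel sequencing errors, quality
decay along reads, PCR and optical duplicates, GC-coverage bias, mapping
ambiguity in repeats, reference errors. Passing tests therefore show the
*inference chain* is correct given faithful alignments; they do not certify
robustness to real-world alignment pathology, which the study handled with
standard read QC and mapping tools upstream of the logic reimplemented
here.

# Stage-by-stage notes

## Variant filtering

The six hard thresholds are applied with strict inequalities exactly as
printed; a variant's verdict is the first failing rule in the fixed order
QUAL, QD, FS, MQ, MQRankSum, ReadPosRankSum, or MALFORMED when an
annotation is present but non-numeric. Absent rank-sum annotations do not
fail their rules — they are undefined rather than bad, and failing them
would discard most homozygous sites. The cluster rule's published wording
("more than 3 SNPs ... all 3 removed") is internally inconsistent; the
implementation removes every SNP in any 10 bp window containing ≥ 3 SNPs
(positions `p, q` cluster when `|p − q| ≤ 9`), the GATK-style convention
the wording echoes, with both count and window configurable. The call-rate
rule keeps sites with ≥ 0.8 of samples genotyped (63/79 fails, 64/79
passes). Hard filters and the call-rate rule commute and all filters are
idempotent; the pipeline order is hard filters → cluster rule → call rate.

## Association scan

The test is the basic allelic 1-df Pearson chi-square on the 2×2 allele
count table, no continuity correction, p from the upper tail — the default
case/control association of the standard GWAS toolchain, matching a
Manhattan plot of unadjusted p-values. The tool and options used by the
study are not recorded beyond that, so the default is assumed and noted
here as an open choice. Monomorphic sites get statistic 0, p 1, and a
flag rather than an error. The genome-wide threshold is
`−log₁₀(α/m)`; for the study's 16,745,104 variants at α = 0.05 this is
8.5249…, printed as 8.52 at two decimals. Significant SNPs are merged into
regions when separated by ≤ 10 kb (`mergeGap`), a scale chosen to bridge
gaps left by filtered SNPs without fusing distinct loci at cross-LD range.

## Depth-ratio scan

Per-base pooled depth counts mapped, non-clipped read bases (clipped bases
are unaligned sequence). Pools are normalized to a common mean before the
ratio — pool sizes are equal by design but sequencing yield need not be —
and the ratio is `log₂((a + ε)/(b + ε))` with pseudocount ε = 1, which
guards the log where the LY pool has literally zero depth inside the
deletion. Smoothing is a centered moving mean over 201 bp (windows shrink
at the track edges); candidate segments are maximal runs of smoothed
|ratio| ≥ 1 (2-fold) at least 500 bp long. None of these three constants
is dictated by the study, which reports only the observed contrast; they
are deliberately permissive so the segment caller's job is localization,
not detection significance, and all are configurable.

## Insert-size SV typing

Apparent inserts are collected once per pair (at the leftmost mate) for
pairs whose outer span intersects the candidate region — in the pipeline,
the depth scan's segment, mirroring the study's two-step logic of depth
first, insert sizes second. Pairs longer than `mean + 5·sd` of the
fragment model are discordant-long; a DELETION is called when the case
excess in discordant fraction is ≥ 0.05 with ≥ 3 supporting pairs, and the
net size estimate is `median(discordant) − fragment mean`. The 5-sd cut
(750 bp at the 500/50 default) sits comfortably between the fragment
distribution's tail and the observed > 7 kb junction pairs, reproducing the
"under 1 kb in controls, over 7 kb in cases" contrast. Note the estimator
targets the *net* size — deletion length minus junction insertion, 7628 bp
here, not 7638 — because the non-templated insertion gives part of the
deleted span back to the haplotype; conflating the two is a 10 bp error
that the breakpoint stage resolves exactly. Duplication-type (short/
everted) discordance is flagged directionally but not further typed.

## Breakpoint resolution

Soft-clipped reads with ≥ 20 clipped bases are clustered by clip-edge
position and side; clusters need ≥ 2 reads (suppressing chimeric
one-offs). The junction consensus is a per-column majority vote over the
clipped tails of the right-clipped cluster and the clipped heads of the
left-clipped cluster, each extended by its mapped anchors; outer columns
seen by fewer than two reads are trimmed (a single sequencing error in a
depth-1 column would otherwise poison exact anchoring), ties break to the
lexicographically smallest base (base qualities are constant in the
simulator, so a summed-quality tie-break degenerates to this), and the two
sides are merged at the best ungapped offset requiring ≥ 15 bp overlap at
≥ 90% identity, higher-depth columns winning disagreements. Breakpoints
come from exact-match anchoring of the consensus flanks to the reference:
a 20 bp seed (sliding inward by up to 20 bp to step over a ragged end) is
extended maximally; the unanchored middle is the insertion; overlapping
extensions (micro-homology) place the deletion leftmost; the right flank
must anchor uniquely within a 20 kb search window downstream of the left
anchor. Ambiguous or failed anchoring returns a diagnosed no-call rather
than a guess.

## Diagnostic PCR and inheritance

In-silico PCR uses exact primer matching (the bench diagnostic is clean;
mismatch tolerance would add failure modes the data do not show) and
requires a unique forward and unique reverse-complement site in order
within 20 kb; anything else is a per-haplotype no-product result. With the
published primer positions the wildtype product is
51,043,419 − 51,034,587 + 1 = 8833 bp and the deletion product
8833 − 7638 + 10 = 1205 bp. Observed product lengths are classified into
the two predicted size classes ± 50 bp — far tighter than the 7.6 kb
separation, loose enough for gel-scale error — giving wt/wt, wt/del or
del/del per sample, and concordance with the recessive model
(LY ⇔ del/del) is reported with named violators.

The plumage rule engine encodes the cross's three-locus combinations as
printed: males carrying dominant white (*I*) are white; females del/del at
*SOX10* are LY; females with a wildtype *SOX10* allele, *I/i*, and a
hemizygous gold Z allele (N/W) are DR. The published F1 allele
combinations contain apparent typos (an F1 from I/I × i/i parents listed
as I/I; F1 males listed as −/− though both parent lines carry Del), so the
engine deliberately routes every combination outside the enumerated set to
"other" instead of guessing an interpretation.

## Pipeline

`runPipeline()` derives one seed per stage from the master seed
(`deriveSeed()`, a fixed integer hash kept below 2³¹), so any stage can be
re-run in isolation; two runs with the same configuration are identical.
Stage outputs are written in standard formats (FASTA, VCF v4.2, SAM with
correct FLAG/CIGAR/TLEN, plink-style `.assoc` TSV, bedGraph/BED, JSON
report); every number in the report is taken from its stage's output, never
recomputed. Configuration violations (zero cases, fragment mean below read
length, pools larger than a cohort, ...) are reported before any stage
runs.

# Problem sizes in the test suite

Unit tests run on toy references (2–60 kb) and small cohorts; the
properties that the study design makes quantitative are checked at these
scales: filter-oracle equivalence on 10,000 simulated variants; chi-square
agreement with the textbook formula to 1e−10 on 500 random tables;
empirical type-I error of the allelic test within [0.04, 0.06] on 10,000
null sites in a 39/40 cohort; exact breakpoint recovery for 50 random
edits (deletions 200–2000 bp, insertions 0–20 bp) at 30X error-free and
for ≥ 95% of edits at 0.1% substitution error; depth-segment recovery at
Jaccard ≥ 0.8 in ≥ 18 of 20 seeded runs (5X, equal pools); and the net
insert-size estimator within 25 bp of 7628 averaged over 20 seeds. The
full-scale conditions (200 kb, 79 samples, 5X) run in the end-to-end
pipeline test and in `scripts/acceptance.R` at 30X for the breakpoint
target.

# Known limitations

* The resolver handles one deletion-with-insertion per segment; nested or
  multiple SVs in a window are out of scope, as is de-novo assembly.
* Depth segmentation is a smoothed threshold rule, not an HMM/CBS
  segmenter; it localizes a single strong event.
* The association stage fits no covariates or relatedness model —
  appropriate for an F1 intercross, not for structured populations.
* Exact primer matching means primer-site SNPs would produce allele
  dropout, as at the bench; mismatch-tolerant matching is configuration
  only.
* The generator's error model (uniform substitutions, constant Q30) is
  intentionally simple; see the generator section for what that implies
  about test coverage.
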