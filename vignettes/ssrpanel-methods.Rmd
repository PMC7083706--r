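---
title: "Methods: multiplex SSR-PCR panel development with ssrpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiplex SSR-PCR panel development with ssrpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrpanel)
```

## Overview

`ssrpanel` develops multiplex SSR-PCR (microsatellite) genotyping assays
from a reference genome and population genotype data. The pipeline runs in
seven stages: repeat cataloging, spanning-read genotyping, family-based
error profiling, saturation (rarefaction) analysis, polymorphic-locus
selection with variant-masked primer design, in-silico PCR specificity
screening, and multiplex grouping with fluorochrome-channel assignment.
This vignette explains the model behind each stage, the tunable parameters
and their defaults, the numerical conventions, and what the simulator does
and does not emulate.

## Repeat cataloging

A microsatellite motif is identified with its equivalence class under
cyclic rotation and reverse complementation: `TG`, `GT`, `CA` and `AC` all
name the same physical repeat, represented by the lexicographically
smallest member (`AC`). Only *primitive* motifs count (`ACAC` is not a
motif; it is two copies of `AC`). Exhaustive enumeration over all `4^k`
strings shows there are 2, 4, 10, 33, 102 and 350 classes for motif
lengths 1-6 — 501 in all:

```{r classes}
vapply(1:6, function(k) length(enumerate_pattern_classes(k)), integer(1))
```

`find_perfect_ssrs()` reports maximal perfect tandem runs meeting a
minimum repeat count per motif length (defaults 12, 8, 6, 5, 4 full units
for lengths 2-6). The detector is deliberately restricted to perfect
repeats: downstream stages use loci whose alleles differ by whole
tract-length steps, so alignment-based detection of interrupted repeats
would add loci the assay design cannot use, at the cost of exact
testability. Monomer runs are enumerable as classes but excluded from
detection, matching the genotyped range of 2-6 bp. Runs are trimmed to
whole units, reported once under their lowest-order primitive motif,
broken by `N`, and indifferent to soft-masking case. Coordinates are
0-based half-open throughout (BED convention).

## Spanning-read genotyping

The genotyper calls tract lengths from reads that span a locus entirely:
a read contributes one observation if it contains at least `min_border`
(default 5) exactly matching bases of the left reference flank, a tandem
run of the locus motif, and at least `min_border` bases of the right
flank. Both read orientations are scanned. The tract boundary is the
*largest* run length at which the right flank matches completely; this
matters when the flank's first bases happen to share the repeat's phase
(e.g. a `CCACC...` spacer after an `ACC` tract), where a naive first-match
rule would truncate or overshoot the allele.

Alleles are tract lengths in bp, matching capillary-platform semantics.
Observation values reaching a fraction `min_het_freq` (default 0.2) of
the informative reads are candidate alleles; the two most frequent
candidates form the genotype, a single candidate is a homozygote, no
observation is a missing call. Frequency ties prefer the longer allele —
a stated convention, since PCR favors shorter fragments slightly, making
an equally supported longer allele less likely to be an artifact. This
caller intentionally omits alignment, mapping filters and stutter-aware
probabilistic calling: its role is to provide calls with a controllable
error process for the statistics downstream, and pre-computed genotype
tables from any other caller are accepted in the same TSV schema.

## Family-based error profiling

In a full-sib family where both parents carry the same homozygous
genotype (a single parental allele length `R`), every offspring is
expected to be `R/R`; deviations measure genotyping error. Loci are
selected by strict filters: parent depth > 10, family-summed depth < 900
(a guard against collapsed paralogous repeats; the summed reading is the
documented interpretation — a per-individual bound of 900 would never
bind at realistic coverage), offspring missingness < 40%, parental-allele
frequency among offspring alleles > 0.80, and minor-allele frequency
< 0.20. The 0.80/0.20 thresholds come from Mendelian arithmetic: if one
of the four parental allele calls is itself erroneous (true cross
`R/R x R/X`), offspring show the parental allele at frequency 0.75; with
two erroneous parental alleles, 0.50 (`expected_offspring_parental_freq()`
enumerates the segregation). Frequencies are computed over offspring
*alleles* (two per genotype), not genotypes, because the expectations are
allele frequencies.

Each non-missing offspring call is scored by its length deviation in
motif units,

    S = (|A1 - R| + |A2 - R|) / M,

with `M` the motif length. `S > 0` is a genotype error; each allele
differing from `R` is one allelotype error, so the allelotype rate is at
most the genotype rate whenever single-allele errors dominate.
`error_profile()` tabulates counts and rates per motif-length category
and overall, including deviations above 10 and 20 bp — large deviations
matter because they can invade a neighbouring locus's size window on the
capillary. `score_correlations()` gives the Pearson matrix of score
against motif length, repeat count and depth.

## Saturation by rarefaction

How many individuals suffice to estimate a locus's allele-length range?
`rarefy_alleles()` draws `g = 1..N` individuals without replacement per
locus and records allele number, maximum/minimum allele length and range
over the `2g` drawn alleles. Draws are independent per group size — the
literal reading of drawing "from one to ten individuals" — with a nested
mode (one permutation per locus, prefixes of increasing length) available
for monotonicity testing, and an optional replicate average for smoother
curves (one draw is the default). Group sizes are compared with a
Friedman rank test over loci as blocks, using midranks and the tie
correction `T = (k-1) Σ(R_j - n(k+1)/2)² / (A - nk(k+1)²/4)`; without
ties this reduces to the classic statistic, and equals `n(k-1)` under
perfect agreement. Pairwise group differences use the Nemenyi post hoc
test on mean-rank differences referred to the studentized range with
infinite degrees of freedom; the test controls family-wise error by
construction, so no further p-value adjustment is applied. On simulated
populations of ten individuals the allele-length range flattens around
eight or nine individuals while the allele number is still rising — the
reason range-based assay windows can be fixed from modest samples while
polymorphism estimates cannot.

## Locus selection, masking and primer design

Polymorphic loci are selected by *allele number*, not heterozygosity:
allelotypes carry a lower error rate than genotypes, and allele counts
from few individuals respond faster to diversity. Defaults: motif length
≥ 3 (dimeric loci are excluded for their dominant share of stutter
error), genotyped in ≥ 5 individuals at depth ≥ 1, ≥ 5 distinct alleles.

Primer binding sites must avoid segregating variants, so every REF span
of a VCF record with Phred quality ≥ 20 is replaced by `N` in the
reference before design (`mask_variants()`); candidates may not cover any
`N`. The candidate generator enumerates windows of 18-27 bp (optimum 21)
in each flank with GC 30-70%, no homopolymer above 4, and a
nearest-neighbor melting temperature within ±3°C of the 60°C optimum
annealing temperature. Tm uses the unified nearest-neighbor
thermodynamic table with the entropic salt correction
`ΔS' = ΔS + 0.368 (N-1) ln[Na+]` at 50 mM Na+ and 250 nM oligo
(`CT/4` convention); an independent implementation of the same published
table agrees within 0.5°C on reference oligos. The product-size window is
the reference product adjusted by the locus's observed allele range plus
a safety margin of one motif unit per side (ranges estimated from ~10
individuals are near, not at, saturation); pairs must fit in
[80, 480] bp. Pairs are ranked by `|Tm - 60| + |len - 21|` summed over
both primers and the best pair per locus is kept. Full hairpin/dimer
thermodynamics are deliberately not reimplemented here; cross-pair
interactions are handled by the multiplex compatibility screen.

## In-silico PCR

Specificity is verified genome-wide: `insilico_pcr()` reports every
amplicon where one primer matches a strand and the other matches the
opposite strand downstream within the size bound (+100 bp slack over the
amplicon maximum, since slightly oversized off-target products still
amplify). Each primer tolerates up to 3 mismatches and up to 3 gap
positions (counted separately against a minimal-edit alignment; "indels"
are counted as gap positions), except that the two 3'-terminal bases must
match exactly — a 3' mismatch blocks polymerase extension. Overlapping
fuzzy-match windows around one physical site are collapsed so a binding
site is counted once. A pair is *specific* iff exactly one amplicon is
predicted. At zero tolerance the scan provably equals exact substring
search; note that at the generous default tolerance a large random
background can legitimately contain fuzzy off-target sites.

## Multiplex grouping and channel assignment

Cross-pair compatibility is screened with transparent, configurable
surrogates for duplex stability at "normal" stringency: the longest
perfect complementary run between any two primers (all cross combinations
plus self) must not exceed 7 bp, no complementary run anchored at a 3'
end may exceed 4 bp, and the Tm spread across all primers of a group must
stay within 3°C. The published preset name pins no numeric thresholds, so
these are exposed in `compatibility_params()` for tightening or loosening.

Grouping is greedy first-fit over pairs sorted by descending allele count
(ties by locus id, making packing deterministic up to input permutation):
a pair joins the first group under the target size (default 10) where it
is compatible with every member. Within a group, pairs are packed into
fluorochrome channels (default 4: FAM/HEX/TAMRA/ROX) first-fit by
ascending `product_min` such that consecutive windows in a channel are
separated by at least `min_space` = 20 bp; a gap exactly equal to 20
passes (inclusive boundary, stated to avoid off-by-one drift). Overflow
pairs re-enter as new groups. `audit_panel()` re-checks every emitted
panel exhaustively against both invariants.

## The simulator and what passing tests mean

`simulate_genome()` plants perfect repeats in non-repetitive random
spacers (rejection-sampled so no spacer contains a detectable SSR or
extends a planted run), records truth coordinates, and attaches a
population allele pool per locus (2-8 distinct tract lengths in
motif-unit steps, clipped so reads can span every allele).
`simulate_family()` draws Mendelian full-sib genotypes;
`inject_stutter()` perturbs each allele call independently with
probability ε by a signed geometric number of motif units (stutter, the
dominant SSR error mode, moves calls in whole-unit steps);
`simulate_reads()` produces error-free uniform-coverage single-end reads
from the two haplotype sequences. Test problem sizes are the study
conditions at desk scale: a 100-offspring family; 200 loci × 100
offspring × 2 alleles = 40,000 alleles for stutter-rate recovery at
ε = 0.05; ten individuals for rarefaction; family depths of 20 reads per
parent and 8 per offspring (parents sequenced deeper, SSR-informative
depth roughly half of genome coverage, and the family-summed depth must
sit under the 900 guard).

Stutter is injected *per allele call* rather than per read by default:
this makes the injected error rate exactly recoverable and separates
genotyper correctness (tested with error-free reads) from error-profile
correctness. Reads carry no substitution errors, no quality-score
structure, no GC bias and no duplicates; real data add mapping
ambiguity, depth heterogeneity and imperfect repeats. Passing tests
therefore demonstrate the correctness of the statistics and the design
logic under the stated error model, not the field error rate of any
platform.

## Numerical conventions and edge cases

* All filter inequalities are strict, following their stated wording
  (depth "greater than 10", frequency "greater than 0.80", etc.).
* Genotype tables encode missing alleles as `.`; all-missing inputs
  yield flagged `NA` statistics, not errors.
* Friedman blocks containing missing values are dropped with a warning;
  an all-constant matrix returns statistic 0 and p = 1.
* Correlation of a constant column is `NA` with a warning naming the
  column.
* `rarefy_alleles()` is bit-reproducible given its seed after sorting
  loci and individuals (input order normalization).
* Degenerate primer-design inputs (fully masked flanks, tract too long
  for the amplicon bound, no pair within bounds) drop the locus with a
  machine-readable reason code rather than failing the run.

## Known limitations

The repeat finder ignores interrupted and compound repeats; the
genotyper requires exact flank matches and will lose reads over
flank-adjacent variants (masking mitigates this at design time, not at
genotyping time); in-silico PCR's edit tolerance is a banded surrogate
for hybridization thermodynamics; and the compatibility screen's
run-length thresholds approximate, but do not compute, duplex free
energies. Assays emitted by the pipeline are candidates for wet-lab
validation, not validated markers.
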