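# ssrpanel

Development of multiplex SSR-PCR genotyping assays from population
resequencing data, in R.

Microsatellites (SSRs) remain the marker of choice for long-term genetic
monitoring, parentage assignment and diversity surveys: a handful of
highly polymorphic loci, co-amplified in one PCR and read on a capillary
sequencer, covers what would otherwise need thousands of SNPs. The hard
part is building the assay: finding repeat loci, knowing their error
behaviour, picking the polymorphic ones, and designing primers that
amplify specifically *and* coexist in one reaction without colliding on
the size axis of a shared dye channel. `ssrpanel` implements that whole
path for population geneticists and molecular ecologists working from a
draft genome plus per-individual genotype calls (or simulated reads).

## What it computes

* **Repeat catalog** — perfect tandem repeats of 2-6 bp motifs, with
  motifs canonicalized under cyclic rotation and reverse complementation
  (the scheme under which 1-6 bp motifs form 501 pattern classes:
  2/4/10/33/102/350 for lengths 1-6), minimum repeat counts 12/8/6/5/4.
* **Spanning-read genotyping** — tract-length calls anchored by exact
  flank matches, `min_het_freq = 0.2`, `min_border = 5`.
* **Family error profile** — in a full-sib family with identically
  homozygous parents (parental allele length R), each offspring call is
  scored by its length deviation in motif units,
  `S = (|A1 − R| + |A2 − R|) / M`; genotype and allelotype error rates
  are tabulated per motif-length category, with Mendelian expectations
  (0.75 / 0.50 parental-allele frequency under one / two erroneous
  parental alleles) motivating the 0.80 / 0.20 selection thresholds.
* **Saturation statistics** — rarefaction of allele number and allele
  length range over 1..N individuals, compared with a tie-corrected
  Friedman rank test and Nemenyi post hoc pairwise p values
  (studentized range, unadjusted).
* **Panel design** — allele-number-based locus selection (defaults:
  motif ≥ 3 bp, ≥ 5 individuals, ≥ 5 alleles, depth ≥ 1), VCF-driven
  reference masking (Phred ≥ 20 variants become `N`), nearest-neighbor
  Tm primer candidates at 60 ± 3 °C with amplicons in [80, 480] bp,
  genome-wide in-silico PCR specificity (≤ 3 mismatches and ≤ 3 indels
  per primer, exact 3' dinucleotide), and greedy multiplex grouping with
  fluorochrome channels separated by ≥ 20 bp size gaps.
* **Simulator** — planted-SSR genomes, Mendelian families with
  injectable per-allele stutter, and error-free spanning reads, so every
  stage is testable without external data.

## Worked example

```r
library(ssrpanel)

# a simulated study: planted-SSR genome, 10-individual population sample
cfg <- sim_config(seed = 5, n_loci = c(`3` = 8, `4` = 8),
                  allele_count_range = c(5, 8))
sim <- simulate_genome(cfg)
pop <- simulate_population(sim$loci, sprintf("I%02d", 1:10), seed = 6)
pop$depth <- 10L

loci <- find_perfect_ssrs(sim$genome)
nrow(loci)
#> [1] 16

sel <- select_polymorphic_loci(pop, loci, pipeline_params(min_alleles = 4))
masked  <- mask_variants(sim$genome, NULL)         # no VCF in this example
design  <- design_panel_primers(masked, sel)
primers <- screen_specificity(sim$genome, design$primers)
panel   <- build_panel(primers)
head(panel[, c("group_id", "channel", "locus_id", "product_min", "product_max")])
#>   group_id channel       locus_id product_min product_max
#> 1      G01     FAM chr1_1626_1659         309         351
#> 2      G01     FAM chr1_2613_2655         391         427
#> 3      G01     HEX chr1_4971_5019         366         418
#> 4      G01   TAMRA   chr1_300_330         368         416
#> 5      G02     FAM chr1_3971_4011         386         446
#> 6      G03     FAM chr1_5319_5355         336         396
```

Each panel row is one assay: its locus, its multiplex group (one PCR
tube), its dye channel, and the allele-size window it may occupy on the
capillary — windows in the same channel never come closer than 20 bp.
`audit_panel(panel)` re-verifies the separation and pairwise
compatibility invariants of any panel.

An end-to-end run from files (FASTA + genotype TSV or FASTQ, optional
VCF) is driven by a YAML config:

```r
res <- run_pipeline(read_run_config("run.yaml"))
```

or from the shell via the thin wrapper
`Rscript inst/scripts/ssrpanel-run.R --config run.yaml`.

## Package layout

* `R/` — motif catalog, detector, genotyper, family error profile,
  saturation statistics, primer/panel design, in-silico PCR, multiplex
  grouping, simulator, pipeline orchestration.
* `vignettes/ssrpanel-methods.Rmd` — the methods vignette: models,
  parameter choices, numerical conventions, limitations.
* `tests/testthat/` — unit, property and acceptance tests.
* `scripts/acceptance.R` — headline-quantity recomputation (above).
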