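test_that("polymorphic-locus selection applies the unit-length, coverage and allele filters", {
  loci <- data.frame(
    locus_id = c("Ldi", "Ltri5", "Ltri4"),
    chrom = "chr1", start = c(0L, 100L, 200L), end = c(24L, 130L, 230L),
    motif = c("AC", "AAC", "AAG"), unit = c("AC", "AAC", "AAG"),
    unit_len = c(2L, 3L, 3L), repeats = c(12L, 10L, 10L),
    tract_len = c(24L, 30L, 30L), stringsAsFactors = FALSE)
  ids <- sprintf("I%d", 1:5)
  mk <- function(locus, alleles) {
    do.call(rbind, lapply(seq_along(ids), function(i) {
      data.frame(locus_id = locus, individual_id = ids[i],
                 allele1 = alleles[[i]][1], allele2 = alleles[[i]][2],
                 depth = 10L, stringsAsFactors = FALSE)
    }))
  }
  five <- list(c(24, 26), c(28, 30), c(32, 24), c(26, 28), c(24, 30))
  five3 <- list(c(24, 27), c(30, 33), c(36, 24), c(27, 30), c(24, 36))
  four <- list(c(24, 27), c(30, 33), c(27, 30), c(24, 33), c(24, 27))
  calls <- rbind(mk("Ldi", five), mk("Ltri5", five3), mk("Ltri4", four))

  sel <- select_polymorphic_loci(calls, loci)
  expect_equal(sel$locus_id, "Ltri5")           # dimer and 4-allele loci out
  expect_equal(sel$n_alleles, 5L)
  expect_equal(sel$allele_min, min(unlist(five3)))
  expect_equal(sel$allele_max, max(unlist(five3)))

  # relaxing min_alleles admits the 4-allele trimer; tightening never adds
  sel4 <- select_polymorphic_loci(calls, loci,
                                  pipeline_params(min_alleles = 4L))
  expect_setequal(sel4$locus_id, c("Ltri5", "Ltri4"))
  expect_true(all(sel$locus_id %in% sel4$locus_id))
  sel_tight <- suppressWarnings(
    select_polymorphic_loci(calls, loci, pipeline_params(min_individuals = 6L)))
  expect_true(all(sel_tight$locus_id %in% sel$locus_id))
})

test_that("mask_variants replaces exactly the REF spans with N", {
  ref <- c(chr1 = "ACGTACGTACGTACGTACGT")
  vcf_lines <- function(records) {
    c("##fileformat=VCFv4.2", "##contig=<ID=chr1>",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", records)
  }
  path <- withr::local_tempfile(fileext = ".vcf")

  writeLines(vcf_lines("chr1\t5\t.\tA\tT\t50\tPASS\t."), path)
  m <- mask_variants(ref, path)
  expect_equal(unname(m[["chr1"]]), "ACGTNCGTACGTACGTACGT")
  expect_equal(nchar(m[["chr1"]]), nchar(ref[["chr1"]]))
  expect_equal(attr(m, "variant_count"), 1L)

  # deletion: the whole REF footprint is masked
  writeLines(vcf_lines("chr1\t10\t.\tACT\tA\t50\tPASS\t."), path)
  d <- mask_variants(ref, path)
  expect_equal(substr(d[["chr1"]], 10, 12), "NNN")
  expect_equal(substr(d[["chr1"]], 1, 9), substr(ref[["chr1"]], 1, 9))

  # empty VCF: output identical to input
  writeLines(vcf_lines(character(0)), path)
  e <- mask_variants(ref, path)
  expect_equal(unname(e[["chr1"]]), unname(ref[["chr1"]]))

  # quality filter: Phred < 20 dropped
  writeLines(vcf_lines(c("chr1\t3\t.\tG\tC\t19\tPASS\t.",
                         "chr1\t7\t.\tG\tC\t20\tPASS\t.")), path)
  q <- mask_variants(ref, path)
  expect_equal(substr(q[["chr1"]], 3, 3), "G")
  expect_equal(substr(q[["chr1"]], 7, 7), "N")

  # masking twice is idempotent
  writeLines(vcf_lines("chr1\t5\t.\tA\tT\t50\tPASS\t."), path)
  m2 <- mask_variants(mask_variants(ref, path), path)
  expect_equal(unname(m2[["chr1"]]), unname(m[["chr1"]]))

  writeLines(vcf_lines("chr2\t5\t.\tA\tT\t50\tPASS\t."), path)
  expect_error(mask_variants(ref, path), "contig error")
})

test_that("nearest-neighbor Tm matches an independent thermodynamic oracle", {
  # reference values computed by direct dH/dS summation over the unified
  # nearest-neighbor table at 250 nM oligo, 50 mM Na+
  oracle <- c(AGCTTGCCAAGGTTCACAGG = 57.1967,
              TGCAGGTCCAATGGCATCAAG = 57.4694,
              AAAGGGCCCTTTAGCAGATT = 53.3758,
              CGTTGGAACCTTCAGATCGCAAT = 57.8017,
              ACACACACACACACACACAC = 55.6040)
  for (s in names(oracle)) {
    expect_equal(nn_melting_temp(s), unname(oracle[s]), tolerance = 0.5 / 57)
  }
  # monotonicity: AT -> GC substitution at fixed length raises Tm
  expect_gt(nn_melting_temp("AGCTTGCCAAGGTTCACAGC"),
            nn_melting_temp("AGCTTGCCAAGGTTCACAGT") - 5)
  expect_gt(nn_melting_temp("GGCTTGCCAAGGTTCACAGG"),
            nn_melting_temp("AGCTTGCCAAGGTTCACAGG"))
  # duplex symmetry: reverse complement has the same Tm
  for (s in names(oracle)) {
    expect_equal(nn_melting_temp(dna_revcomp(s)), nn_melting_temp(s),
                 tolerance = 1e-10)
  }
  expect_error(nn_melting_temp("ACGTNACGTACG"), "invalid-sequence")
  expect_error(nn_melting_temp("ACGTACG"), "at least 8")
})

test_that("primer design finds a within-bounds pair on clean flanks and drops masked loci", {
  sel <- select_polymorphic_loci(
    std_pop, std_loci, pipeline_params(min_alleles = 4L))
  expect_gt(nrow(sel), 5L)
  masked <- mask_variants(std_sim$genome, NULL)
  locus <- sel[1, ]
  pair <- design_primer_pairs(masked, locus)
  expect_false(is.null(pair))
  expect_gte(pair$product_min, 80L)
  expect_lte(pair$product_max, 480L)
  expect_true(pair$product_min <= pair$product_max)
  expect_false(grepl("N", paste0(pair$fwd_seq, pair$rev_seq)))
  p <- pipeline_params()
  expect_lte(abs(pair$fwd_tm - p$opt_anneal_temp), p$tm_window)
  expect_lte(abs(pair$rev_tm - p$opt_anneal_temp), p$tm_window)
  # primers sit outside the repeat tract
  expect_lte(pair$fwd_start + nchar(pair$fwd_seq), locus$start)
  expect_gte(pair$rev_end - nchar(pair$rev_seq), locus$end)

  # fully masked flanks: locus dropped with a reason
  blind <- masked
  blind[["chr1"]] <- paste0(strrep("N", locus$start),
                            substr(masked[["chr1"]], locus$start + 1, locus$end),
                            strrep("N", nchar(masked[["chr1"]]) - locus$end))
  none <- design_primer_pairs(blind, locus)
  expect_equal(nrow(none), 0L)
  expect_equal(attr(none, "reason"), "no primer window")

  # allele range wider than the amplicon bound: rejected
  wide <- locus
  wide$allele_max <- wide$allele_min + 500L
  toowide <- design_primer_pairs(masked, wide)
  expect_equal(nrow(toowide), 0L)
  expect_equal(attr(toowide, "reason"), "no pair within amplicon bounds")
})

test_that("in-silico PCR equals the exact-search oracle at zero tolerance", {
  set.seed(1234)
  bg <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
              collapse = "")
  fwd <- "AGCTTGCCAAGGTTCACAGG"
  rev <- "TGCAGGTCCAATGGCATCAAG"
  insert <- strrep("TTAGGC", 20)
  genome <- c(chr1 = paste0(substr(bg, 1, 1000), fwd, insert,
                            dna_revcomp(rev), substr(bg, 1001, 3000)))
  p0 <- pipeline_params(max_mismatches_per_primer = 0L,
                        max_indels_per_primer = 0L)
  amps <- insilico_pcr(genome, fwd, rev, p0)
  expect_equal(nrow(amps), 1L)
  expect_true(attr(amps, "specific"))
  # exact-search oracle for the product coordinates
  s <- genome[["chr1"]]
  f_at <- as.integer(regexpr(fwd, s, fixed = TRUE))
  r_at <- as.integer(regexpr(dna_revcomp(rev), s, fixed = TRUE))
  expect_equal(amps$start, f_at - 1L)
  expect_equal(amps$end, r_at + nchar(rev) - 1L)
  expect_equal(amps$length, amps$end - amps$start)

  # default tolerance still reports the planted product (fuzzy background
  # sites may add off-target amplicons on top)
  amps3 <- insilico_pcr(genome, fwd, rev, pipeline_params())
  expect_true(any(amps3$start == f_at - 1L &
                    amps3$end == r_at + nchar(rev) - 1L))
})

test_that("in-silico PCR tolerance is three mismatches per primer", {
  set.seed(4321)
  bg <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE),
              collapse = "")
  fwd <- "AGCTTGCCAAGGTTCACAGG"
  rev <- "TGCAGGTCCAATGGCATCAAG"
  insert <- strrep("ATGGCC", 25)
  mutate <- function(p, n) {
    ch <- strsplit(p, "")[[1]]
    flip <- c(A = "C", C = "A", G = "T", T = "G")
    idx <- seq(2, by = 3, length.out = n)   # keep the 3' end intact
    ch[idx] <- flip[ch[idx]]
    paste(ch, collapse = "")
  }
  site <- function(f, r) paste0(f, insert, dna_revcomp(r))
  # second site with 3 mismatches in each primer: within tolerance
  g2 <- c(chr1 = paste0(substr(bg, 1, 1000), site(fwd, rev),
                        substr(bg, 1001, 2000),
                        site(mutate(fwd, 3), mutate(rev, 3)),
                        substr(bg, 2001, 4000)))
  a2 <- insilico_pcr(g2, fwd, rev)
  expect_equal(nrow(a2), 2L)
  expect_false(attr(a2, "specific"))

  # second site with 4 mismatches per primer: beyond tolerance
  g4 <- c(chr1 = paste0(substr(bg, 1, 1000), site(fwd, rev),
                        substr(bg, 1001, 2000),
                        site(mutate(fwd, 4), mutate(rev, 4)),
                        substr(bg, 2001, 4000)))
  a4 <- insilico_pcr(g4, fwd, rev)
  expect_equal(nrow(a4), 1L)
  expect_true(attr(a4, "specific"))

  # duplicated locus: two amplicons, pair not specific
  gd <- c(chr1 = paste0(substr(bg, 1, 800), site(fwd, rev),
                        substr(bg, 801, 1600), site(fwd, rev),
                        substr(bg, 1601, 2400)))
  ad <- insilico_pcr(gd, fwd, rev)
  expect_equal(nrow(ad), 2L)

  # a mismatch at the 3'-terminal bases blocks the site
  fwd_3p <- paste0(substr(fwd, 1, 18), "TT")   # last two bases changed
  g3p <- c(chr1 = paste0(substr(bg, 1, 1000), site(fwd_3p, rev),
                         substr(bg, 1001, 2000)))
  a3p <- insilico_pcr(g3p, fwd, rev)
  expect_equal(nrow(a3p), 0L)
})

test_that("every designed panel pair passes its own specificity screen", {
  sel <- select_polymorphic_loci(std_pop, std_loci,
                                 pipeline_params(min_alleles = 4L))
  masked <- mask_variants(std_sim$genome, NULL)
  des <- design_panel_primers(masked, sel)
  expect_gt(nrow(des$primers), 3L)
  pr <- screen_specificity(std_sim$genome, des$primers)
  for (i in which(pr$specific)) {
    amps <- insilico_pcr(std_sim$genome, pr$fwd_seq[i], pr$rev_seq[i])
    expect_true(attr(amps, "specific"))
  }
})
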