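#' Assay-design pipeline parameters
#'
#' Defaults follow the standard parameter set for panel development:
#' optimum annealing temperature 60 degrees C, minimum repeat-unit length
#' 3 bp (dimeric loci are excluded for their high stutter error), minimum
#' of 5 genotyped individuals, minimum of 5 distinct alleles, minimum
#' genotype depth 1, amplicon length 80-480 bp, and a 20 bp minimum space
#' between allele-size windows sharing a fluorochrome.
#'
#' @param opt_anneal_temp optimum annealing temperature, degrees C.
#' @param min_unit_len minimum motif length retained (bp).
#' @param min_individuals minimum genotyped individuals per locus.
#' @param min_alleles minimum distinct allele lengths per locus.
#' @param min_depth minimum depth for a genotype to count.
#' @param min_amplicon,max_amplicon amplicon size bounds (bp).
#' @param min_space minimum gap between size windows in a dye channel (bp).
#' @param opt_primer_len optimum primer length (bp).
#' @param max_mismatches_per_primer,max_indels_per_primer in-silico PCR
#'   tolerance per primer (both default 3).
#' @param tm_window allowed deviation of primer Tm from
#'   `opt_anneal_temp`, degrees C.
#' @param range_margin_units extra safety margin on the product-size
#'   window, in motif units each side (default 1); allele ranges estimated
#'   from few individuals can still widen slightly.
#' @return A `pipeline_params` list.
#' @export
pipeline_params <- function(opt_anneal_temp = 60,
                            min_unit_len = 3L,
                            min_individuals = 5L,
                            min_alleles = 5L,
                            min_depth = 1L,
                            min_amplicon = 80L,
                            max_amplicon = 480L,
                            min_space = 20L,
                            opt_primer_len = 21L,
                            max_mismatches_per_primer = 3L,
                            max_indels_per_primer = 3L,
                            tm_window = 3,
                            range_margin_units = 1L) {
  stopifnot(min_amplicon < max_amplicon, min_unit_len >= 2,
            min_individuals >= 1, min_alleles >= 1, min_depth >= 1,
            min_space >= 0, tm_window > 0)
  structure(list(opt_anneal_temp = opt_anneal_temp,
                 min_unit_len = as.integer(min_unit_len),
                 min_individuals = as.integer(min_individuals),
                 min_alleles = as.integer(min_alleles),
                 min_depth = as.integer(min_depth),
                 min_amplicon = as.integer(min_amplicon),
                 max_amplicon = as.integer(max_amplicon),
                 min_space = as.integer(min_space),
                 opt_primer_len = as.integer(opt_primer_len),
                 max_mismatches_per_primer = as.integer(max_mismatches_per_primer),
                 max_indels_per_primer = as.integer(max_indels_per_primer),
                 tm_window = tm_window,
                 range_margin_units = as.integer(range_margin_units)),
            class = "pipeline_params")
}

#' Select highly polymorphic loci for assay design
#'
#' Allele number, not heterozygosity, is the polymorphism criterion:
#' allelotypes carry a lower error rate than genotypes and allele counts
#' from few individuals are more sensitive to diversity. A locus is kept
#' when its motif length is at least `min_unit_len`, it is genotyped at
#' depth `>= min_depth` in at least `min_individuals` individuals, and it
#' shows at least `min_alleles` distinct allele lengths.
#'
#' @param calls genotype table.
#' @param loci locus data frame from [find_perfect_ssrs()].
#' @param params a [pipeline_params()].
#' @return Locus data frame restricted to the kept loci, with added
#'   `n_typed`, `n_alleles`, `allele_min`, `allele_max` columns.
#' @export
select_polymorphic_loci <- function(calls, loci, params = pipeline_params()) {
  d <- calls[!is.na(calls$allele1) & calls$depth >= params$min_depth, , drop = FALSE]
  per_locus <- lapply(split(d, d$locus_id), function(x) {
    alleles <- c(x$allele1, x$allele2)
    data.frame(locus_id = x$locus_id[1],
               n_typed = length(unique(x$individual_id)),
               n_alleles = length(unique(alleles)),
               allele_min = min(alleles), allele_max = max(alleles),
               stringsAsFactors = FALSE)
  })
  stats <- do.call(rbind, per_locus)
  out <- merge(loci, stats, by = "locus_id")
  out <- out[out$unit_len >= params$min_unit_len &
               out$n_typed >= params$min_individuals &
               out$n_alleles >= params$min_alleles, , drop = FALSE]
  if (nrow(out) == 0L) warning("no loci pass the polymorphism filters")
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mask population variants in a reference with N
#'
#' Every reference base covered by a retained VCF record (the full REF
#' span, so deletions mask their whole footprint) becomes `N`; sequence
#' length is unchanged. Records with Phred quality below `min_qual` are
#' dropped; records with missing QUAL are kept. Primer candidates are
#' later forbidden to cover any `N`, which keeps binding sites clear of
#' segregating mutations.
#'
#' @param reference named character vector of sequences, or FASTA path.
#' @param vcf path to a VCF (plain or gzipped), or NULL to skip masking.
#' @param min_qual minimum QUAL retained (default 20).
#' @return Named character vector of masked sequences with attributes
#'   `variant_count` (records applied) and `source_vcf`.
#' @export
mask_variants <- function(reference, vcf, min_qual = 20) {
  if (is.character(reference) && length(reference) == 1L &&
      is.null(names(reference)) && file.exists(reference)) {
    reference <- read_fasta_chr(reference)
  }
  if (is.null(vcf)) {
    attr(reference, "variant_count") <- 0L
    attr(reference, "source_vcf") <- NA_character_
    return(reference)
  }
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)   # single record comes back as a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix)) {
    qual <- suppressWarnings(as.numeric(fix$QUAL))
    fix <- fix[is.na(qual) | qual >= min_qual, , drop = FALSE]
  }
  applied <- 0L
  for (i in seq_len(nrow(fix))) {
    chrom <- fix$CHROM[i]
    if (!chrom %in% names(reference)) {
      stop("contig error: VCF contig '", chrom, "' absent from reference")
    }
    pos <- as.integer(fix$POS[i])
    span <- nchar(fix$REF[i])
    if (pos < 1L || pos + span - 1L > nchar(reference[[chrom]])) {
      stop("contig error: VCF record outside reference bounds at ",
           chrom, ":", pos)
    }
    substr(reference[[chrom]], pos, pos + span - 1L) <- strrep("N", span)
    applied <- applied + 1L
  }
  attr(reference, "variant_count") <- applied
  attr(reference, "source_vcf") <- vcf
  reference
}

# enumerate primer candidates on one side of a locus.
# side "left": windows end at or before `boundary` (1-based index of the
# last base allowed); side "right": windows start at or after `boundary`.
primer_candidates <- function(seq, boundary, side, params,
                              reach, lengths = 18:27) {
  n <- nchar(seq)
  cands <- list()
  offsets <- 0:(reach - min(lengths))
  for (off in offsets) {
    for (len in lengths) {
      if (side == "left") {
        e <- boundary - off
        s <- e - len + 1L
      } else {
        s <- boundary + off
        e <- s + len - 1L
      }
      if (s < 1L || e > n) next
      p <- substr(seq, s, e)
      if (grepl("N", p, fixed = TRUE)) next
      gc <- gc_fraction(p)
      if (gc < 0.3 || gc > 0.7) next
      if (max_homopolymer(p) > 4L) next
      seq5to3 <- if (side == "left") p else dna_revcomp(p)
      tm <- nn_melting_temp(seq5to3)
      if (abs(tm - params$opt_anneal_temp) > params$tm_window) next
      cands[[length(cands) + 1L]] <- data.frame(
        start = s, end = e, seq = seq5to3, tm = tm, len = len,
        penalty = abs(tm - params$opt_anneal_temp) +
          abs(len - params$opt_primer_len),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(cands)) return(NULL)
  out <- do.call(rbind, cands)
  out[order(out$penalty), , drop = FALSE]
}

#' Design the best primer pair for one SSR locus
#'
#' Enumerates candidate primers in the masked flanks (length 18-27 bp,
#' optimum 21; GC 30-70%; no homopolymer run over 4; no masked base; Tm
#' within `tm_window` of the optimum annealing temperature), then retains
#' the lowest-penalty pair whose product-size window, after adjusting the
#' reference product by the locus allele-length range plus the safety
#' margin, fits inside `[min_amplicon, max_amplicon]`. Penalty is the sum
#' over both primers of `|Tm - T_opt| + |len - 21|`.
#'
#' @param masked masked reference (named character vector).
#' @param locus one-row data frame from [select_polymorphic_loci()]
#'   (needs `chrom`, `start`, `end`, `unit_len`, `tract_len`,
#'   `allele_min`, `allele_max`).
#' @param params a [pipeline_params()].
#' @param max_candidates_per_side candidate pool kept per side after
#'   penalty ranking (caps the pairwise search).
#' @return One-row data frame (`locus_id`, `fwd_seq`, `rev_seq`,
#'   `fwd_start`, `rev_end` 0-based, `fwd_tm`, `rev_tm`, `product_min`,
#'   `product_max`, `penalty`); on failure a zero-row data frame whose
#'   `reason` attribute carries the drop reason.
#' @export
design_primer_pairs <- function(masked, locus, params = pipeline_params(),
                                max_candidates_per_side = 25L) {
  failed <- function(reason) {
    out <- data.frame()
    attr(out, "reason") <- reason
    out
  }
  s <- masked[[locus$chrom]]
  reach <- params$max_amplicon - locus$tract_len
  if (reach < 2L * 18L) {
    return(failed("tract too long for amplicon bound"))
  }
  fwd <- primer_candidates(s, boundary = locus$start, side = "left",
                           params = params, reach = reach)
  rev <- primer_candidates(s, boundary = locus$end + 1L, side = "right",
                           params = params, reach = reach)
  if (is.null(fwd) || is.null(rev)) {
    return(failed("no primer window"))
  }
  fwd <- head(fwd, max_candidates_per_side)
  rev <- head(rev, max_candidates_per_side)
  margin <- params$range_margin_units * locus$unit_len
  best <- NULL
  for (i in seq_len(nrow(fwd))) {
    for (j in seq_len(nrow(rev))) {
      product_ref <- rev$end[j] - fwd$start[i] + 1L
      pmin <- product_ref + (locus$allele_min - locus$tract_len) - margin
      pmax <- product_ref + (locus$allele_max - locus$tract_len) + margin
      if (pmin < params$min_amplicon || pmax > params$max_amplicon) next
      pen <- fwd$penalty[i] + rev$penalty[j]
      if (is.null(best) || pen < best$penalty) {
        best <- data.frame(
          locus_id = locus$locus_id,
          fwd_seq = fwd$seq[i], rev_seq = rev$seq[j],
          fwd_start = fwd$start[i] - 1L, rev_end = rev$end[j],
          fwd_tm = fwd$tm[i], rev_tm = rev$tm[j],
          product_min = pmin, product_max = pmax,
          penalty = pen, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (is.null(best)) {
    return(failed("no pair within amplicon bounds"))
  }
  best
}

#' Design primer pairs for a set of polymorphic loci
#'
#' @param masked masked reference.
#' @param loci data frame from [select_polymorphic_loci()].
#' @param params a [pipeline_params()].
#' @return List with `primers` (data frame, one row per designed pair,
#'   carrying `chrom` and `n_alleles` for downstream grouping) and
#'   `dropped` (data frame `locus_id`, `reason`).
#' @export
design_panel_primers <- function(masked, loci, params = pipeline_params()) {
  primers <- list(); dropped <- list()
  for (i in seq_len(nrow(loci))) {
    locus <- loci[i, ]
    pair <- design_primer_pairs(masked, locus, params)
    if (nrow(pair) == 0L) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        locus_id = locus$locus_id, reason = attr(pair, "reason"),
        stringsAsFactors = FALSE)
    } else {
      pair$chrom <- locus$chrom
      pair$n_alleles <- locus$n_alleles
      primers[[length(primers) + 1L]] <- pair
    }
  }
  list(
    primers = if (length(primers)) do.call(rbind, primers) else NULL,
    dropped = if (length(dropped)) do.call(rbind, dropped) else
      data.frame(locus_id = character(), reason = character())
  )
}
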