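#' Simulation configuration
#'
#' Defines the planted-SSR genome, the population allele pool, the
#' full-sib family, the per-allele stutter error process and the read
#' simulator. Allele tract lengths are always multiples of the motif
#' length; planted loci are separated by non-repetitive spacers of at
#' least `2 * read_len` so spanning reads never bridge two loci.
#'
#' @param seed integer master seed.
#' @param n_loci named integer vector: loci per motif length
#'   (names `"2"`..`"6"`).
#' @param repeats_range range of planted repeat counts *above* the
#'   detection minimum (units added on top of the policy floor).
#' @param allele_count_range distinct tract lengths segregating per locus
#'   in the population pool (uniform draw, motif-unit steps).
#' @param n_offspring offspring in the full-sib family (default 100).
#' @param stutter_rate per-allele-call stutter probability.
#' @param stutter_geom_p geometric parameter of the stutter step size in
#'   motif units (step `k >= 1`, signed; default 0.7).
#' @param read_len simulated read length (default 150).
#' @param coverage per-individual sequencing coverage (default 30).
#' @param spacer_len spacer between planted loci (default `2 * read_len`).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_loci = c(`2` = 4L, `3` = 4L, `4` = 4L, `5` = 4L, `6` = 4L),
                       repeats_range = c(0L, 6L),
                       allele_count_range = c(2L, 8L),
                       n_offspring = 100L,
                       stutter_rate = 0.05,
                       stutter_geom_p = 0.7,
                       read_len = 150L,
                       coverage = 30,
                       spacer_len = NULL) {
  stopifnot(stutter_rate >= 0, stutter_rate <= 1,
            stutter_geom_p > 0, stutter_geom_p <= 1,
            all(names(n_loci) %in% as.character(2:6)))
  if (is.null(spacer_len)) spacer_len <- 2L * as.integer(read_len)
  structure(list(seed = as.integer(seed), n_loci = n_loci,
                 repeats_range = as.integer(repeats_range),
                 allele_count_range = as.integer(allele_count_range),
                 n_offspring = as.integer(n_offspring),
                 stutter_rate = stutter_rate,
                 stutter_geom_p = stutter_geom_p,
                 read_len = as.integer(read_len),
                 coverage = coverage,
                 spacer_len = as.integer(spacer_len)),
            class = "sim_config")
}

# random background sequence that neither contains a detectable SSR nor
# extends the repeat units flanking it
random_spacer <- function(len, left_unit = NULL, right_unit = NULL,
                          policy = min_repeat_policy()) {
  repeat {
    s <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
    if (!is.null(left_unit) &&
        substr(s, 1L, 1L) == substr(left_unit, 1L, 1L)) next
    if (!is.null(right_unit) &&
        substr(s, len, len) == substr(right_unit, nchar(right_unit),
                                      nchar(right_unit))) next
    if (nrow(find_perfect_ssrs(c(x = s), policy)) > 0L) next
    return(s)
  }
}

#' Simulate a genome with planted perfect SSR loci
#'
#' Builds one contig per batch of loci: non-repetitive random spacers
#' alternating with planted perfect repeats whose coordinates, motifs and
#' repeat counts are recorded as ground truth. Deterministic for a fixed
#' seed.
#'
#' @param cfg a [sim_config()].
#' @param policy a [min_repeat_policy()] (planted repeat counts sit at or
#'   above its thresholds).
#' @return List `genome` (named character vector, single contig `chr1`)
#'   and `loci` (truth data frame in the [find_perfect_ssrs()] layout,
#'   plus `allele_pool` list column of population tract lengths).
#' @export
simulate_genome <- function(cfg = sim_config(), policy = min_repeat_policy()) {
  set.seed(cfg$seed)
  parts <- character(0)
  truth <- list()
  pos <- 0L
  prev_unit <- NULL
  for (k in as.integer(names(cfg$n_loci))) {
    classes <- enumerate_pattern_classes(k)
    for (i in seq_len(cfg$n_loci[[as.character(k)]])) {
      unit <- sample(classes, 1L)
      min_rep <- unclass(policy)[[as.character(k)]]
      reps <- min_rep + sample(seq(cfg$repeats_range[1], cfg$repeats_range[2]), 1L)
      spacer <- random_spacer(cfg$spacer_len, prev_unit, unit, policy)
      parts <- c(parts, spacer, strrep(unit, reps))
      start <- pos + nchar(spacer)
      end <- start + reps * k
      pos <- end
      # population allele pool: distinct tract lengths in motif-unit steps,
      # centred on the planted repeat count and short enough to span
      n_alleles <- sample(seq(cfg$allele_count_range[1],
                              cfg$allele_count_range[2]), 1L)
      max_reps <- (cfg$read_len - 20L) %/% k
      offs <- sample(seq(-3L, n_alleles + 3L), n_alleles)
      pool_reps <- pmin(pmax(reps + offs, 2L), max_reps)
      pool_reps <- unique(pool_reps)
      while (length(pool_reps) < n_alleles) {
        pool_reps <- unique(c(pool_reps, min(pool_reps) - 1L))
        pool_reps <- pool_reps[pool_reps >= 2L]
        if (min(pool_reps) <= 2L && length(pool_reps) < n_alleles) {
          pool_reps <- unique(c(pool_reps, max(pool_reps) + 1L))
        }
      }
      pool <- sort(pool_reps * k)
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = "chr1", start = start, end = end,
        motif = canonical_motif(unit)$canonical, unit = unit,
        unit_len = k, repeats = reps, tract_len = reps * k,
        stringsAsFactors = FALSE)
      truth[[length(truth)]]$allele_pool <- list(pool)
      prev_unit <- unit
    }
  }
  tail_spacer <- random_spacer(cfg$spacer_len, prev_unit, NULL, policy)
  genome <- c(chr1 = paste(c(parts, tail_spacer), collapse = ""))
  loci <- do.call(rbind, truth)
  loci <- cbind(locus_id = sprintf("%s_%d_%d", loci$chrom, loci$start, loci$end),
                loci, stringsAsFactors = FALSE)
  rownames(loci) <- NULL
  list(genome = genome, loci = loci)
}

#' Simulate true genotypes for a population sample
#'
#' Each individual receives two alleles per locus drawn uniformly (with
#' replacement) from the locus allele pool.
#'
#' @param loci truth loci from [simulate_genome()] (with `allele_pool`).
#' @param individual_ids character vector.
#' @param seed integer seed.
#' @return Genotype table (`allele1 <= allele2`, `depth` NA).
#' @export
simulate_population <- function(loci, individual_ids, seed = 1L) {
  set.seed(as.integer(seed))
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    pool <- loci$allele_pool[[i]]
    for (id in individual_ids) {
      a <- sort(sample(pool, 2L, replace = TRUE))
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = loci$locus_id[i], individual_id = id,
        allele1 = a[1], allele2 = a[2], depth = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a Mendelian full-sib family
#'
#' Parent genotypes are drawn from each locus's allele pool (or forced
#' homozygous identical when `parents_homozygous = TRUE`, the layout used
#' for error profiling); each offspring receives one allele from each
#' parent uniformly at random.
#'
#' @param loci truth loci from [simulate_genome()].
#' @param cfg a [sim_config()].
#' @param parent_ids two IDs (default `P1`, `P2`).
#' @param parents_homozygous force both parents homozygous for the same
#'   allele at every locus (default TRUE).
#' @param seed integer seed (defaults to `cfg$seed + 1`).
#' @return List `family` (a [family_design()]), `truth` (genotype table
#'   for parents + offspring, depth NA).
#' @export
simulate_family <- function(loci, cfg = sim_config(),
                            parent_ids = c("P1", "P2"),
                            parents_homozygous = TRUE,
                            seed = NULL) {
  if (is.null(seed)) seed <- cfg$seed + 1L
  set.seed(as.integer(seed))
  offspring_ids <- sprintf("O%03d", seq_len(cfg$n_offspring))
  fam <- family_design(parent_ids, offspring_ids)
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    pool <- loci$allele_pool[[i]]
    if (parents_homozygous) {
      R <- sample(pool, 1L)
      p1 <- c(R, R); p2 <- c(R, R)
    } else {
      p1 <- sort(sample(pool, 2L, replace = TRUE))
      p2 <- sort(sample(pool, 2L, replace = TRUE))
    }
    add <- function(id, a) data.frame(
      locus_id = loci$locus_id[i], individual_id = id,
      allele1 = min(a), allele2 = max(a), depth = NA_integer_,
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- add(parent_ids[1], p1)
    rows[[length(rows) + 1L]] <- add(parent_ids[2], p2)
    for (o in offspring_ids) {
      a <- c(sample(p1, 1L), sample(p2, 1L))
      rows[[length(rows) + 1L]] <- add(o, a)
    }
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  list(family = fam, truth = truth)
}

#' Inject stutter error into true genotype calls
#'
#' Each allele is independently perturbed with probability `epsilon` by a
#' signed step of `k >= 1` motif units, `k - 1` geometric with parameter
#' `step_geom_p`. Flags record exactly which alleles were perturbed, so
#' downstream error-rate estimates can be checked against truth.
#'
#' @param truth genotype table of true calls.
#' @param loci locus data frame (for `unit_len`).
#' @param epsilon per-allele error probability.
#' @param step_geom_p geometric parameter of the step magnitude.
#' @param seed integer seed.
#' @return List `calls` (perturbed table, alleles re-sorted) and `flags`
#'   (logical matrix columns `allele1_err`, `allele2_err` aligned to the
#'   *input* rows before re-sorting).
#' @export
inject_stutter <- function(truth, loci, epsilon, step_geom_p = 0.7, seed = 1L) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  set.seed(as.integer(seed))
  unit_len <- loci$unit_len[match(truth$locus_id, loci$locus_id)]
  n <- nrow(truth)
  perturb <- function(a) {
    hit <- runif(n) < epsilon & !is.na(a)
    step <- (rgeom(n, step_geom_p) + 1L) * sample(c(-1L, 1L), n, replace = TRUE)
    new <- a
    new[hit] <- pmax(unit_len[hit], a[hit] + step[hit] * unit_len[hit])
    list(a = new, hit = hit & new != a)
  }
  r1 <- perturb(truth$allele1)
  r2 <- perturb(truth$allele2)
  calls <- truth
  calls$allele1 <- pmin(r1$a, r2$a)
  calls$allele2 <- pmax(r1$a, r2$a)
  list(calls = calls,
       flags = cbind(allele1_err = r1$hit, allele2_err = r2$hit))
}

#' Simulate error-free spanning reads for one individual
#'
#' Substitutes the individual's two allele tract lengths into the
#' reference to build two haplotype sequences, then draws uniform-coverage
#' error-free single-end reads from each (coverage split evenly).
#'
#' @param genome named character vector (the simulated reference).
#' @param loci truth loci.
#' @param genotypes genotype table rows for this individual (true calls).
#' @param cfg a [sim_config()] (read length and coverage).
#' @param seed integer seed.
#' @return Character vector of read sequences.
#' @export
simulate_reads <- function(genome, loci, genotypes, cfg = sim_config(),
                           seed = 1L) {
  set.seed(as.integer(seed))
  loci <- loci[order(-loci$start), , drop = FALSE]  # edit right-to-left
  hap_seq <- function(which_allele) {
    s <- genome[["chr1"]]
    for (i in seq_len(nrow(loci))) {
      g <- genotypes[genotypes$locus_id == loci$locus_id[i], , drop = FALSE]
      if (nrow(g) == 0L || is.na(g$allele1[1])) next
      tract <- if (which_allele == 1L) g$allele1[1] else g$allele2[1]
      unit <- loci$unit[i]
      tract_seq <- substr(strrep(unit, tract %/% nchar(unit) + 1L), 1L, tract)
      s <- paste0(substr(s, 1L, loci$start[i]), tract_seq,
                  substr(s, loci$end[i] + 1L, nchar(s)))
    }
    s
  }
  too_long <- loci$tract_len + 2L > cfg$read_len
  if (any(too_long)) {
    warning("unspannable loci at read length ", cfg$read_len, ": ",
            paste(loci$locus_id[too_long], collapse = ", "))
  }
  reads <- character(0)
  for (hap in 1:2) {
    s <- hap_seq(hap)
    n_reads <- ceiling(nchar(s) * cfg$coverage / 2 / cfg$read_len)
    if (n_reads < 1L) next
    starts <- sample.int(max(1L, nchar(s) - cfg$read_len + 1L), n_reads,
                         replace = TRUE)
    reads <- c(reads, substring(s, starts, starts + cfg$read_len - 1L))
  }
  reads
}

#' Serialize a simulation truth set as JSON
#'
#' Records the planted loci (without sequence pools), the per-individual
#' true genotypes, and any injected-error flags, so downstream error-rate
#' estimates can always be audited against ground truth.
#'
#' @param loci truth loci from [simulate_genome()].
#' @param truth genotype table of true calls.
#' @param path output JSON file.
#' @param flags optional error-flag matrix from [inject_stutter()].
#' @export
write_truth_json <- function(loci, truth, path, flags = NULL) {
  obj <- list(
    loci = loci[, setdiff(names(loci), "allele_pool")],
    allele_pools = setNames(loci$allele_pool, loci$locus_id),
    genotypes = truth
  )
  if (!is.null(flags)) obj$error_flags <- as.data.frame(flags)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write reads as FASTQ
#' @param reads character vector of read sequences.
#' @param path output file (`.gz` accepted).
#' @param id_prefix read-name prefix.
#' @export
write_fastq <- function(reads, path, id_prefix = "read") {
  qual <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
  dss <- Biostrings::DNAStringSet(reads)
  names(dss) <- sprintf("%s_%06d", id_prefix, seq_along(reads))
  Biostrings::writeXStringSet(dss, filepath = path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}
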