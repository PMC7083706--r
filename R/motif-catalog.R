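#' Canonicalize a repeat motif
#'
#' Reduces a repeat unit to the representative of its equivalence class
#' under cyclic rotation and reverse complementation: the lexicographically
#' smallest string among all rotations of the unit and all rotations of its
#' reverse complement. This is the standard scheme under which 1-6 bp
#' microsatellite motifs fall into 501 pattern classes.
#'
#' The unit must be primitive (not a whole-number repetition of a shorter
#' unit): `"ACAC"` is rejected with a message naming the reduced unit
#' `"AC"`.
#'
#' @param unit DNA string of length 1-6 over `A/C/G/T` (case-insensitive).
#' @return An object of class `ssr_motif`: a list with elements `unit`
#'   (uppercased input) and `canonical` (class representative).
#' @examples
#' canonical_motif("TG")$canonical   # "AC"
#' canonical_motif("gaa")$canonical  # "AAG"
#' @seealso [enumerate_pattern_classes()], [find_perfect_ssrs()]
#' @export
canonical_motif <- function(unit) {
  if (length(unit) != 1L || !is.character(unit) || is.na(unit) || !nzchar(unit)) {
    stop("unit must be a single non-empty string")
  }
  unit <- toupper(unit)
  if (nchar(unit) > 6L) {
    stop("unit length must be between 1 and 6")
  }
  if (grepl("[^ACGT]", unit)) {
    stop("invalid-alphabet: unit contains characters outside {A,C,G,T}")
  }
  red <- primitive_root(unit)
  if (nchar(red) < nchar(unit)) {
    stop(sprintf("non-primitive: unit '%s' is a repetition of '%s'", unit, red))
  }
  canon <- min(c(cyclic_rotations(unit), cyclic_rotations(dna_revcomp(unit))))
  structure(list(unit = unit, canonical = canon), class = "ssr_motif")
}

# smallest string whose whole-number repetition equals u
primitive_root <- function(u) {
  n <- nchar(u)
  for (d in seq_len(n - 1L)) {
    if (n %% d == 0L) {
      base <- substr(u, 1L, d)
      if (strrep(base, n %/% d) == u) return(base)
    }
  }
  u
}

#' @export
print.ssr_motif <- function(x, ...) {
  cat(sprintf("<ssr_motif> unit %s, canonical class %s\n", x$unit, x$canonical))
  invisible(x)
}

#' Enumerate motif pattern classes of one length
#'
#' Exhaustively enumerates all `4^k` DNA strings of length `k`, discards
#' non-primitive strings, and groups the remainder under cyclic-rotation and
#' reverse-complement equivalence. The class counts for k = 1..6 are
#' 2, 4, 10, 33, 102 and 350 (501 in total).
#'
#' @param k motif length, 1 to 6.
#' @return Sorted character vector of canonical class representatives.
#' @examples
#' enumerate_pattern_classes(2)  # "AC" "AG" "AT" "CG"
#' length(enumerate_pattern_classes(4))  # 33
#' @export
enumerate_pattern_classes <- function(k) {
  if (length(k) != 1L || is.na(k) || k < 1 || k > 6 || k != as.integer(k)) {
    stop("k must be an integer between 1 and 6")
  }
  k <- as.integer(k)
  grid <- do.call(expand.grid,
                  c(rep(list(DNA_BASES), k), stringsAsFactors = FALSE))
  mers <- do.call(paste0, grid)
  prim <- mers[vapply(mers, function(u) nchar(primitive_root(u)) == k, logical(1))]
  canon <- vapply(prim, function(u) {
    min(c(cyclic_rotations(u), cyclic_rotations(dna_revcomp(u))))
  }, character(1), USE.NAMES = FALSE)
  sort(unique(canon))
}

#' Minimum repeat-count policy for SSR detection
#'
#' Detection thresholds by motif length: a tandem run is reported only if it
#' contains at least this many full units. Defaults are 12, 8, 6, 5 and 4
#' full units for motif lengths 2-6; monomer runs are not detected.
#'
#' @param by_motif_len named integer vector with names `"2"`..`"6"`.
#' @return A validated `min_repeat_policy` object (named integer vector).
#' @export
min_repeat_policy <- function(by_motif_len = c(`2` = 12L, `3` = 8L, `4` = 6L,
                                               `5` = 5L, `6` = 4L)) {
  if (!all(as.character(2:6) %in% names(by_motif_len))) {
    stop("policy must cover motif lengths 2 to 6")
  }
  v <- as.integer(by_motif_len[as.character(2:6)])
  if (any(is.na(v)) || any(v < 1L)) stop("minimum repeat counts must be positive integers")
  structure(setNames(v, as.character(2:6)), class = "min_repeat_policy")
}

#' Detect perfect SSR loci in a sequence set
#'
#' Scans each sequence for maximal perfect tandem runs of primitive motifs
#' of the requested lengths and reports those meeting the minimum
#' repeat-count policy. Runs are trimmed to whole units; each physical run
#' is reported once, under its primitive motif of lowest order (a dimer run
#' is never re-reported as a tetramer or hexamer repetition). Lowercase
#' (soft-masked) bases are treated as normal bases; `N` breaks runs.
#'
#' @param sequences named character vector of DNA sequences, a
#'   `DNAStringSet`, or a path to a (possibly gzipped) FASTA file.
#' @param policy a [min_repeat_policy()].
#' @param motif_lens integer vector of motif lengths to scan, subset of 2:6.
#' @return Data frame with one row per locus: `locus_id`, `chrom`, `start`
#'   (0-based inclusive), `end` (0-based exclusive), `motif` (canonical
#'   class), `unit` (unit as it occurs at the locus), `unit_len`, `repeats`,
#'   `tract_len`. `tract_len == repeats * unit_len` always holds.
#' @examples
#' find_perfect_ssrs(c(chr1 = paste0("GGTCA", strrep("AC", 12), "TTGCA")))
#' @export
find_perfect_ssrs <- function(sequences,
                              policy = min_repeat_policy(),
                              motif_lens = 2:6) {
  if (is.character(sequences) && length(sequences) == 1L &&
      is.null(names(sequences)) && file.exists(sequences)) {
    sequences <- read_fasta_chr(sequences)
  }
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("sequences must be named (chromosome/scaffold names)")
  }
  if (!all(motif_lens %in% 2:6)) stop("motif_lens must be a subset of 2:6")
  policy <- if (inherits(policy, "min_repeat_policy")) policy else min_repeat_policy(policy)

  rows <- list()
  for (chrom in names(sequences)) {
    s <- toupper(sequences[[chrom]])
    L <- nchar(s)
    if (L == 0L) next
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ok <- ch %in% DNA_BASES
    for (k in sort(as.integer(motif_lens))) {
      min_rep <- unclass(policy)[[as.character(k)]]
      if (L < k * min_rep) next
      idx <- seq_len(L - k)
      eq <- ch[idx] == ch[idx + k] & ok[idx] & ok[idx + k]
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      hit <- which(r$values & r$lengths >= (min_rep - 1L) * k)
      for (h in hit) {
        i <- starts[h]                      # 1-based start of the run
        run_bp <- r$lengths[h] + k          # total periodic tract incl. partial unit
        reps <- run_bp %/% k
        if (reps < min_rep) next
        unit <- substr(s, i, i + k - 1L)
        if (nchar(primitive_root(unit)) < k) next  # reported at its lower order
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom,
          start = i - 1L,
          end = i - 1L + reps * k,
          motif = min(c(cyclic_rotations(unit),
                        cyclic_rotations(dna_revcomp(unit)))),
          unit = unit,
          unit_len = k,
          repeats = reps,
          tract_len = reps * k,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      motif = character(), unit = character(),
                      unit_len = integer(), repeats = integer(),
                      tract_len = integer(), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    out <- out[order(out$chrom, out$start, out$unit_len), , drop = FALSE]
  }
  out <- cbind(locus_id = sprintf("%s_%d_%d", out$chrom, out$start, out$end),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarise an SSR catalog
#'
#' Counts loci per canonical motif class and bins them by repeat count and
#' by tract length, reporting the fraction of loci shorter than 100 bp
#' (loci short enough to be spanned by a typical sequencing read).
#'
#' @param loci data frame from [find_perfect_ssrs()].
#' @param len_breaks tract-length bin edges in bp.
#' @return List with `by_motif` (counts per canonical class), `by_repeats`,
#'   `by_length` (binned counts), `total`, and `frac_under_100bp`.
#' @export
pattern_summary <- function(loci, len_breaks = c(0, 20, 40, 60, 80, 100, Inf)) {
  total <- nrow(loci)
  by_motif <- if (total) sort(table(loci$motif), decreasing = TRUE) else table(character())
  by_repeats <- if (total) table(loci$repeats) else table(integer())
  by_length <- if (total) {
    table(cut(loci$tract_len, breaks = len_breaks, right = FALSE))
  } else {
    table(cut(numeric(), breaks = len_breaks, right = FALSE))
  }
  list(
    by_motif = by_motif,
    by_repeats = by_repeats,
    by_length = by_length,
    total = total,
    frac_under_100bp = if (total) mean(loci$tract_len < 100) else NA_real_
  )
}

#' Write an SSR catalog as BED6+3
#'
#' Columns: chrom, start, end, name (canonical motif), score (repeat
#' count), strand (`+`), unit_len, tract_len, unit_seq. Coordinates are
#' 0-based half-open as in BED.
#'
#' @param loci data frame from [find_perfect_ssrs()].
#' @param path output file.
#' @export
write_loci_bed <- function(loci, path) {
  bed <- data.frame(chrom = loci$chrom, start = loci$start, end = loci$end,
                    name = loci$motif, score = loci$repeats, strand = "+",
                    unit_len = loci$unit_len, tract_len = loci$tract_len,
                    unit_seq = loci$unit, stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an SSR catalog written by [write_loci_bed()]
#' @param path BED6+3 file.
#' @return Data frame in the [find_perfect_ssrs()] layout.
#' @export
read_loci_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 9L) stop("expected BED6+3 with 9 columns")
  names(bed) <- c("chrom", "start", "end", "motif", "repeats", "strand",
                  "unit_len", "tract_len", "unit")
  out <- data.frame(
    locus_id = sprintf("%s_%d_%d", bed$chrom, bed$start, bed$end),
    chrom = bed$chrom, start = as.integer(bed$start), end = as.integer(bed$end),
    motif = bed$motif, unit = bed$unit, unit_len = as.integer(bed$unit_len),
    repeats = as.integer(bed$repeats), tract_len = as.integer(bed$tract_len),
    stringsAsFactors = FALSE
  )
  out
}
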