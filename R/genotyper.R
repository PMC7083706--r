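#' Genotyper parameters
#'
#' @param min_het_freq minimum fraction of informative reads an allele must
#'   reach to be called (default 0.2; an allele seen in fewer reads is
#'   treated as stutter noise).
#' @param min_border exact flank match required on each side of the repeat
#'   tract, in bp (default 5).
#' @param min_depth_call minimum informative reads for a call (default 1).
#' @return A `genotyper_params` list.
#' @export
genotyper_params <- function(min_het_freq = 0.2, min_border = 5L,
                             min_depth_call = 1L) {
  stopifnot(min_het_freq > 0, min_het_freq <= 0.5, min_border >= 1,
            min_depth_call >= 1)
  structure(list(min_het_freq = min_het_freq,
                 min_border = as.integer(min_border),
                 min_depth_call = as.integer(min_depth_call)),
            class = "genotyper_params")
}

# does `segment` consist of tandem copies (possibly truncated) of `unit`,
# starting in phase with `unit`?
is_tandem_of <- function(segment, unit) {
  n <- nchar(segment)
  if (n == 0L) return(FALSE)
  k <- nchar(unit)
  segment == substr(strrep(unit, n %/% k + 1L), 1L, n)
}

#' Extract tract-length observations from spanning reads
#'
#' A read contributes one observation iff it contains, in order: at least
#' `min_border` exactly matching bases of the left reference flank, a
#' tandem run of the locus motif, and at least `min_border` exactly
#' matching bases of the right flank. The tract length is the number of
#' bases between the two flank matches. Both read orientations are
#' scanned, so calls are strand-invariant.
#'
#' @param reads character vector of read sequences.
#' @param locus one-row locus data frame (needs `unit`).
#' @param flank_left,flank_right reference sequence immediately left/right
#'   of the tract, each at least `min_border` bp.
#' @param params a [genotyper_params()].
#' @return Integer vector of observed tract lengths (bp), one per
#'   informative read.
#' @export
informative_reads <- function(reads, locus, flank_left, flank_right,
                              params = genotyper_params()) {
  b <- params$min_border
  if (nchar(flank_left) < b || nchar(flank_right) < b) {
    stop("configuration error: flanks shorter than min_border")
  }
  lf <- toupper(substr(flank_left, nchar(flank_left) - b + 1L, nchar(flank_left)))
  rf <- toupper(substr(flank_right, 1L, b))
  unit <- toupper(locus$unit)
  u <- strsplit(unit, "", fixed = TRUE)[[1]]

  obs_one <- function(read) {
    starts <- gregexpr(lf, read, fixed = TRUE)[[1]]
    if (starts[1] == -1L) return(NA_integer_)
    n <- nchar(read)
    for (st in starts) {
      tract_from <- st + b
      if (tract_from > n) next
      # maximal tandem run of the locus unit starting right after the flank
      x <- strsplit(substr(read, tract_from, n), "", fixed = TRUE)[[1]]
      mism <- which(x != rep(u, length.out = length(x)))
      L_max <- if (length(mism)) mism[1] - 1L else length(x)
      if (L_max < 1L) next
      # the right flank must follow the tract completely; when the flank
      # shares the repeat's phase the run overshoots, so search backwards
      # from the maximal run for the largest consistent boundary
      for (L in seq(L_max, 1L)) {
        if (tract_from + L + b - 1L > n) next
        if (substr(read, tract_from + L, tract_from + L + b - 1L) == rf) {
          return(L)
        }
      }
    }
    NA_integer_
  }

  out <- integer(0)
  for (read in toupper(reads)) {
    v <- obs_one(read)
    if (is.na(v)) v <- obs_one(dna_revcomp(read))
    if (!is.na(v)) out <- c(out, v)
  }
  out
}

#' Call a genotype from tract-length observations
#'
#' Observation values reaching frequency `min_het_freq` among all
#' observations are candidate alleles. The two most frequent candidates
#' form the genotype (frequency ties broken in favour of the longer
#' allele); a single candidate yields a homozygote; no observations (or
#' depth below `min_depth_call`) yields a missing call.
#'
#' @param observations integer vector from [informative_reads()].
#' @param params a [genotyper_params()].
#' @return List with `allele1 <= allele2` (NA when missing), `depth`, and
#'   `missing`.
#' @examples
#' call_genotype(c(rep(30, 6), rep(34, 4)))  # heterozygote 30/34
#' call_genotype(c(rep(30, 9), 34))          # homozygote 30/30
#' @export
call_genotype <- function(observations, params = genotyper_params()) {
  depth <- length(observations)
  if (depth == 0L || depth < params$min_depth_call) {
    return(list(allele1 = NA_integer_, allele2 = NA_integer_,
                depth = depth, missing = TRUE))
  }
  tab <- table(observations)
  vals <- as.integer(names(tab))
  cnt <- as.integer(tab)
  keep <- cnt / depth >= params$min_het_freq
  if (!any(keep)) {
    return(list(allele1 = NA_integer_, allele2 = NA_integer_,
                depth = depth, missing = TRUE))
  }
  vals <- vals[keep]; cnt <- cnt[keep]
  ord <- order(-cnt, -vals)
  top <- vals[ord][seq_len(min(2L, length(vals)))]
  a <- if (length(top) == 1L) c(top, top) else sort(top)
  list(allele1 = a[1], allele2 = a[2], depth = depth, missing = FALSE)
}

#' Genotype one individual's reads over an SSR catalog
#'
#' Runs [informative_reads()] and [call_genotype()] at every locus. Flanks
#' are taken from the reference; this spanning-read caller needs no
#' alignment step.
#'
#' @param reads character vector of read sequences, or a FASTQ path
#'   (optionally gzipped).
#' @param loci locus data frame from [find_perfect_ssrs()].
#' @param reference named character vector of reference sequences, or FASTA
#'   path.
#' @param individual_id label for the output table.
#' @param params a [genotyper_params()].
#' @param flank_len bp of reference flank passed to the matcher (must be
#'   `>= min_border`).
#' @return Genotype table: `locus_id`, `individual_id`, `allele1`,
#'   `allele2`, `depth` (missing calls have NA alleles).
#' @export
genotype_individual <- function(reads, loci, reference, individual_id,
                                params = genotyper_params(), flank_len = 20L) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = "fastq"))
  }
  if (is.character(reference) && length(reference) == 1L &&
      is.null(names(reference)) && file.exists(reference)) {
    reference <- read_fasta_chr(reference)
  }
  flank_len <- max(flank_len, params$min_border)
  calls <- lapply(seq_len(nrow(loci)), function(i) {
    loc <- loci[i, ]
    s <- reference[[loc$chrom]]
    fl <- substr(s, max(1L, loc$start - flank_len + 1L), loc$start)
    fr <- substr(s, loc$end + 1L, min(nchar(s), loc$end + flank_len))
    obs <- informative_reads(reads, loc, fl, fr, params)
    g <- call_genotype(obs, params)
    data.frame(locus_id = loc$locus_id, individual_id = individual_id,
               allele1 = g$allele1, allele2 = g$allele2, depth = g$depth,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Read a genotype table
#'
#' Tab-separated with header `locus_id, individual_id, allele1, allele2,
#' depth`; missing alleles encoded as `"."`.
#'
#' @param path TSV file.
#' @return Genotype data frame with integer alleles (NA for missing).
#' @export
read_genotypes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(allele1 = "character", allele2 = "character"))
  need <- c("locus_id", "individual_id", "allele1", "allele2", "depth")
  if (!all(need %in% names(df))) {
    stop("genotype table must have columns: ", paste(need, collapse = ", "))
  }
  df$allele1 <- suppressWarnings(as.integer(ifelse(df$allele1 == ".", NA, df$allele1)))
  df$allele2 <- suppressWarnings(as.integer(ifelse(df$allele2 == ".", NA, df$allele2)))
  df$depth <- as.integer(df$depth)
  df
}

#' Write a genotype table
#' @param calls genotype data frame.
#' @param path output TSV.
#' @export
write_genotypes <- function(calls, path) {
  out <- calls
  out$allele1 <- ifelse(is.na(out$allele1), ".", as.character(out$allele1))
  out$allele2 <- ifelse(is.na(out$allele2), ".", as.character(out$allele2))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
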