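# find binding sites of `primer` (given 5'->3') whose sequence matches the
# plus strand of `subject` within the mismatch/indel tolerance. The caller
# passes the primer itself (rightward-extending site) or its reverse
# complement (leftward-extending site).
# Returns a data.frame(start, end) of 1-based plus-strand ranges.
primer_sites <- function(subject_dss, pattern, max_mm, max_indel,
                         anchor_3prime = 2L, anchored_end = c("right", "left")) {
  anchored_end <- match.arg(anchored_end)
  tol <- max_mm + max_indel
  hits <- Biostrings::matchPattern(pattern, subject_dss,
                                   max.mismatch = tol,
                                   with.indels = tol > 0)
  if (length(hits) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  rng <- as.data.frame(IRanges::ranges(hits))
  keep <- logical(nrow(rng))
  plen <- nchar(pattern)
  subj_chr <- as.character(subject_dss)
  for (i in seq_len(nrow(rng))) {
    window <- substr(subj_chr, rng$start[i], rng$end[i])
    if (tol == 0L) {
      ops <- c(mm = 0L, indel = 0L)
    } else {
      ops <- count_edit_ops(pattern, window)
    }
    if (ops[["mm"]] > max_mm || ops[["indel"]] > max_indel) next
    # the 2 bases at the primer's 3' end must match the template exactly
    if (anchor_3prime > 0L) {
      if (anchored_end == "right") {
        site <- substr(subj_chr, rng$end[i] - anchor_3prime + 1L, rng$end[i])
        pend <- substr(pattern, plen - anchor_3prime + 1L, plen)
      } else {
        site <- substr(subj_chr, rng$start[i], rng$start[i] + anchor_3prime - 1L)
        pend <- substr(pattern, 1L, anchor_3prime)
      }
      if (site != pend) next
    }
    keep[i] <- TRUE
  }
  sites <- unique(rng[keep, c("start", "end"), drop = FALSE])
  if (nrow(sites) > 1L) {
    # fuzzy matching reports shifted windows around one physical binding
    # site; collapse overlapping windows to a single representative
    ir <- IRanges::reduce(IRanges::IRanges(sites$start, sites$end))
    sites <- data.frame(start = IRanges::start(ir), end = IRanges::end(ir))
  }
  rownames(sites) <- NULL
  sites
}

# minimal-edit alignment of two short strings: returns counts of
# substitutions and gap positions (indel bp)
count_edit_ops <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 1)
  ind <- Biostrings::nindel(aln)
  c(mm = Biostrings::nmismatch(aln),
    indel = sum(Biostrings::insertion(ind)[, "WidthSum"]) +
      sum(Biostrings::deletion(ind)[, "WidthSum"]))
}

#' In-silico PCR: predict amplicons of a primer pair genome-wide
#'
#' Scans every contig for binding-site pairs: a rightward-extending site
#' of one primer followed, within the product-size bound, by a
#' leftward-extending site of the other. Each primer may bind with up to
#' `max_mismatches_per_primer` substitutions and `max_indels_per_primer`
#' gap positions (counted separately per primer), except that the two
#' bases at the primer's 3' end must match exactly (a 3'-terminal
#' mismatch blocks polymerase extension). Both amplicon orientations are
#' searched. A pair is *specific* iff exactly one amplicon is predicted
#' genome-wide.
#'
#' @param genome named character vector of sequences, or FASTA path.
#' @param fwd_seq,rev_seq primer sequences, 5' to 3'.
#' @param params a [pipeline_params()]; tolerance and amplicon bounds are
#'   taken from it.
#' @param size_slack extra bp allowed above `max_amplicon` when scanning
#'   (default 100; off-target products slightly above the bound would
#'   still amplify).
#' @return Data frame `chrom`, `start` (0-based), `end` (exclusive),
#'   `strand`, `length`; attribute `specific` (logical).
#' @export
insilico_pcr <- function(genome, fwd_seq, rev_seq,
                         params = pipeline_params(), size_slack = 100L) {
  if (is.character(genome) && length(genome) == 1L &&
      is.null(names(genome)) && file.exists(genome)) {
    genome <- read_fasta_chr(genome)
  }
  max_len <- params$max_amplicon + size_slack
  mm <- params$max_mismatches_per_primer
  ind <- params$max_indels_per_primer
  out <- list()
  for (chrom in names(genome)) {
    subj <- Biostrings::DNAString(genome[[chrom]])
    for (orient in c("+", "-")) {
      left_p <- if (orient == "+") fwd_seq else rev_seq
      right_p <- if (orient == "+") rev_seq else fwd_seq
      lsites <- primer_sites(subj, left_p, mm, ind, anchored_end = "right")
      if (nrow(lsites) == 0L) next
      rsites <- primer_sites(subj, dna_revcomp(right_p), mm, ind,
                             anchored_end = "left")
      if (nrow(rsites) == 0L) next
      for (i in seq_len(nrow(lsites))) {
        len <- rsites$end - lsites$start[i] + 1L
        ok <- rsites$start > lsites$start[i] &
          rsites$end > lsites$end[i] & len <= max_len
        for (j in which(ok)) {
          out[[length(out) + 1L]] <- data.frame(
            chrom = chrom, start = lsites$start[i] - 1L, end = rsites$end[j],
            strand = orient, length = len[j], stringsAsFactors = FALSE)
        }
      }
    }
  }
  amps <- if (length(out)) unique(do.call(rbind, out)) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), length = integer())
  # a site pair found in both orientations is the same physical product
  amps <- amps[!duplicated(amps[, c("chrom", "start", "end")]), , drop = FALSE]
  rownames(amps) <- NULL
  attr(amps, "specific") <- nrow(amps) == 1L
  amps
}

#' Specificity screen of a primer table
#'
#' Runs [insilico_pcr()] for every pair and appends `specific` and
#' `n_amplicons` columns.
#'
#' @param genome unmasked reference (named character vector or FASTA path).
#' @param primers primer table from [design_panel_primers()].
#' @param params a [pipeline_params()].
#' @return The primer table with `specific` and `n_amplicons` added.
#' @export
screen_specificity <- function(genome, primers, params = pipeline_params()) {
  if (is.character(genome) && length(genome) == 1L &&
      is.null(names(genome)) && file.exists(genome)) {
    genome <- read_fasta_chr(genome)
  }
  res <- lapply(seq_len(nrow(primers)), function(i) {
    amps <- insilico_pcr(genome, primers$fwd_seq[i], primers$rev_seq[i], params)
    data.frame(specific = attr(amps, "specific"), n_amplicons = nrow(amps))
  })
  cbind(primers, do.call(rbind, res))
}
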