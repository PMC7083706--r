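#' @importFrom stats cor median na.omit p.adjust pchisq ptukey quantile rbinom
#'   rgeom runif sd setNames
#' @importFrom utils read.delim write.table head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorized reverse complement over plain character vectors. Only
#' `A/C/G/T/N` (upper- or lowercase) are accepted; output is uppercase.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @examples
#' dna_revcomp(c("ACGT", "TTAA"))
#' @export
dna_revcomp <- function(x) {
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("invalid-alphabet: sequence contains characters outside {A,C,G,T,N}")
  }
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

#' GC fraction of a DNA string
#' @param x single DNA string.
#' @return numeric in \[0, 1\].
#' @export
gc_fraction <- function(x) {
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  mean(ch %in% c("G", "C"))
}

#' Longest single-base run in a DNA string
#' @param x single DNA string.
#' @return integer length of the longest homopolymer run.
#' @export
max_homopolymer <- function(x) {
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  if (length(ch) == 0L) return(0L)
  max(rle(ch)$lengths)
}

# all cyclic rotations of a string
cyclic_rotations <- function(u) {
  n <- nchar(u)
  if (n == 1L) return(u)
  doubled <- paste0(u, u)
  vapply(seq_len(n), function(i) substr(doubled, i, i + n - 1L), character(1))
}

# read a (possibly gzipped) FASTA into a named uppercase character vector
read_fasta_chr <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(dss))
  names(out) <- sub("\\s.*$", "", names(dss))
  out
}

write_fasta_chr <- function(seqs, path, width = 70L) {
  dss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dss, filepath = path, width = width)
  invisible(path)
}
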