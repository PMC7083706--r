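# Unified nearest-neighbor thermodynamic parameters for DNA/DNA duplexes
# (Allawi & SantaLucia 1997 / SantaLucia 1998 unified set).
# dH in kcal/mol, dS in cal/(mol K).
NN_DH <- c("AA" = -7.9, "AT" = -7.2, "TA" = -7.2, "CA" = -8.5, "GT" = -8.4,
           "CT" = -7.8, "GA" = -8.2, "CG" = -10.6, "GC" = -9.8, "GG" = -8.0,
           "TT" = -7.9, "TG" = -8.5, "AC" = -8.4, "AG" = -7.8, "TC" = -8.2,
           "CC" = -8.0)
NN_DS <- c("AA" = -22.2, "AT" = -20.4, "TA" = -21.3, "CA" = -22.7, "GT" = -22.4,
           "CT" = -21.0, "GA" = -22.2, "CG" = -27.2, "GC" = -24.4, "GG" = -19.9,
           "TT" = -22.2, "TG" = -22.7, "AC" = -22.4, "AG" = -21.0, "TC" = -22.2,
           "CC" = -19.9)
# duplex initiation per terminal base pair
NN_INIT_DH <- c(A = 2.3, T = 2.3, G = 0.1, C = 0.1)
NN_INIT_DS <- c(A = 4.1, T = 4.1, G = -2.8, C = -2.8)

#' Nearest-neighbor melting temperature of an oligonucleotide
#'
#' Duplex melting temperature from the unified nearest-neighbor
#' thermodynamic table (dH/dS per dinucleotide stack plus terminal
#' initiation terms), with the entropic salt correction
#' `dS' = dS + 0.368 (N-1) ln[Na+]` and
#' `Tm = 1000 dH / (dS' + R ln(CT/4)) - 273.15` for a non-self-complementary
#' oligo at total strand concentration CT (the usual excess-primer
#' approximation). Self-complementary sequences get the symmetry entropy
#' term and use `ln(CT)`.
#'
#' @param primer DNA string, N-free, length >= 8.
#' @param conc_nM total oligo concentration in nM (default 250, a typical
#'   per-primer PCR concentration).
#' @param na_mM monovalent cation concentration in mM (default 50).
#' @return Melting temperature in degrees Celsius.
#' @examples
#' nn_melting_temp("AGCTTGCCAAGGTTCACAGG")
#' @export
nn_melting_temp <- function(primer, conc_nM = 250, na_mM = 50) {
  primer <- toupper(primer)
  if (grepl("[^ACGT]", primer)) {
    stop("invalid-sequence: primer contains non-ACGT characters")
  }
  n <- nchar(primer)
  if (n < 8L) stop("primer must be at least 8 bases")
  ch <- strsplit(primer, "", fixed = TRUE)[[1]]
  stacks <- paste0(ch[-n], ch[-1])
  dH <- sum(NN_DH[stacks]) + NN_INIT_DH[[ch[1]]] + NN_INIT_DH[[ch[n]]]
  dS <- sum(NN_DS[stacks]) + NN_INIT_DS[[ch[1]]] + NN_INIT_DS[[ch[n]]]
  selfcomp <- primer == dna_revcomp(primer)
  ct <- conc_nM * 1e-9
  if (selfcomp) {
    dS <- dS - 1.4
    k <- ct
  } else {
    k <- ct / 4
  }
  dS <- dS + 0.368 * (n - 1) * log(na_mM / 1000)
  1000 * dH / (dS + 1.987 * log(k)) - 273.15
}
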