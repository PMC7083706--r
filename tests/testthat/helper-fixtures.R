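# Shared small fixtures, built once per test run.

# brute-force canonicalization used as the independent oracle for motifs
oracle_canonical <- function(u) {
  rc <- dna_revcomp(u)
  rots <- function(s) {
    n <- nchar(s)
    vapply(seq_len(n), function(i) {
      paste0(substr(s, i, n), substr(s, 1, i - 1))
    }, character(1))
  }
  min(c(rots(u), rots(rc)))
}

# a tiny genotype table builder: one locus, explicit per-individual calls
make_calls <- function(locus_id, genotypes, depths = NULL) {
  ids <- names(genotypes)
  if (is.null(depths)) depths <- rep(20L, length(ids))
  do.call(rbind, lapply(seq_along(ids), function(i) {
    g <- genotypes[[i]]
    data.frame(locus_id = locus_id, individual_id = ids[i],
               allele1 = g[1], allele2 = g[2],
               depth = depths[i], stringsAsFactors = FALSE)
  }))
}

# family with 2 parents and n offspring all sharing one genotype, plus
# optional overrides: list(offspring_index = c(a1, a2))
make_family_calls <- function(locus_id, R = 30L, n_off = 10L,
                              parent_depth = 20L, off_depth = 8L,
                              overrides = list()) {
  ids <- c("P1", "P2", sprintf("O%02d", seq_len(n_off)))
  g <- rep(list(c(R, R)), length(ids))
  names(g) <- ids
  for (nm in names(overrides)) g[[nm]] <- overrides[[nm]]
  make_calls(locus_id, g,
             depths = c(parent_depth, parent_depth, rep(off_depth, n_off)))
}

std_family <- family_design(c("P1", "P2"), sprintf("O%02d", 1:10))

# small planted-SSR world reused by several files (cheap to build)
std_sim_cfg <- sim_config(seed = 5, n_loci = c(`3` = 8L, `4` = 8L),
                          allele_count_range = c(5L, 8L))
std_sim <- simulate_genome(std_sim_cfg)
std_loci <- std_sim$loci[, setdiff(names(std_sim$loci), "allele_pool")]
std_pop_ids <- sprintf("I%02d", 1:10)
std_pop <- local({
  p <- simulate_population(std_sim$loci, std_pop_ids, seed = 6)
  p$depth <- 10L
  p
})
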