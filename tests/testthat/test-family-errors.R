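test_that("family_design validates membership", {
  expect_error(family_design("P1", "O1"), "two distinct parent")
  expect_error(family_design(c("P1", "P1"), "O1"), "two distinct parent")
  expect_error(family_design(c("P1", "P2"), c("P1", "O1")), "overlap")
  fam <- family_design(c("P1", "P2"), c("O1", "O2"))
  expect_s3_class(fam, "family_design")
})

test_that("select_error_loci keeps identically homozygous parents only", {
  clean <- make_family_calls("L1", R = 30L)
  sel <- select_error_loci(clean, std_family)
  expect_equal(sel, data.frame(locus_id = "L1", R = 30L,
                               stringsAsFactors = FALSE))

  # parents differ: excluded
  het_parent <- make_family_calls("L1", R = 30L,
                                  overrides = list(P2 = c(30L, 34L)))
  expect_equal(nrow(select_error_loci(het_parent, std_family)), 0L)

  # both parents heterozygous (even identically) admit no single R
  both_het <- make_family_calls("L1", R = 30L,
                                overrides = list(P1 = c(30L, 34L),
                                                 P2 = c(30L, 34L)))
  expect_equal(nrow(select_error_loci(both_het, std_family)), 0L)

  expect_error(select_error_loci(clean, family_design(c("P1", "PX"), "O01")),
               "missing-individual")
})

test_that("select_error_loci applies the depth, missingness and frequency filters", {
  # parent depth must be strictly greater than 10
  expect_equal(nrow(select_error_loci(
    make_family_calls("L1", parent_depth = 10L), std_family)), 0L)
  expect_equal(nrow(select_error_loci(
    make_family_calls("L1", parent_depth = 11L), std_family)), 1L)

  # summed family depth must stay under 900
  deep <- make_family_calls("L1", parent_depth = 50L, off_depth = 80L)
  expect_equal(nrow(select_error_loci(deep, std_family)), 0L)

  # offspring missing fraction must stay under 0.40
  miss4 <- make_family_calls("L1", overrides = list(
    O01 = c(NA, NA), O02 = c(NA, NA), O03 = c(NA, NA), O04 = c(NA, NA)))
  expect_equal(nrow(select_error_loci(miss4, std_family)), 0L)
  miss3 <- make_family_calls("L1", overrides = list(
    O01 = c(NA, NA), O02 = c(NA, NA), O03 = c(NA, NA)))
  expect_equal(nrow(select_error_loci(miss3, std_family)), 1L)

  # parental allele frequency among offspring alleles: 15/20 = 0.75 fails
  freq75 <- make_family_calls("L1", overrides = list(
    O01 = c(34L, 34L), O02 = c(34L, 34L), O03 = c(30L, 34L)))
  expect_equal(nrow(select_error_loci(freq75, std_family)), 0L)
  # 17/20 = 0.85 passes (minor allele at 0.15)
  freq85 <- make_family_calls("L1", overrides = list(
    O01 = c(34L, 34L), O02 = c(30L, 34L)))
  expect_equal(nrow(select_error_loci(freq85, std_family)), 1L)
})

test_that("tightening any error filter never adds loci", {
  set.seed(91)
  tables <- lapply(1:12, function(i) {
    n_err <- sample(0:4, 1)
    ov <- lapply(seq_len(n_err), function(j) c(30L, sample(c(34L, 38L), 1)))
    names(ov) <- sprintf("O%02d", sample(1:10, n_err))
    make_family_calls("L1", overrides = ov,
                      parent_depth = sample(c(9L, 12L, 30L), 1),
                      off_depth = sample(c(5L, 8L, 95L), 1))
  })
  loose <- error_filter_params()
  tight_list <- list(
    error_filter_params(min_parent_depth = 25L),
    error_filter_params(max_total_depth = 300L),
    error_filter_params(max_missing_frac = 0.1),
    error_filter_params(min_parental_allele_freq = 0.95),
    error_filter_params(max_minor_allele_freq = 0.05))
  for (tab in tables) {
    base <- select_error_loci(tab, std_family, loose)$locus_id
    for (tp in tight_list) {
      expect_true(all(select_error_loci(tab, std_family, tp)$locus_id %in% base))
    }
  }
})

test_that("Mendelian expectations for erroneous parental alleles", {
  expect_equal(expected_offspring_parental_freq(0), 1.0)
  expect_equal(expected_offspring_parental_freq(1), 0.75)
  expect_equal(expected_offspring_parental_freq(2), 0.50)
  expect_error(expected_offspring_parental_freq(3), "0, 1 or 2")
})

test_that("genotype score follows the length-deviation formula", {
  s0 <- genotype_score(20, 20, R = 20, M = 4)
  expect_equal(s0$S, 0)
  expect_equal(s0$allele_errors, 0L)
  expect_false(s0$is_genotype_error)

  s1 <- genotype_score(20, 24, R = 20, M = 4)
  expect_equal(s1$S, 1.0)
  expect_equal(s1$allele_errors, 1L)
  expect_true(s1$is_genotype_error)

  s2 <- genotype_score(18, 22, R = 20, M = 2)
  expect_equal(s2$S, 2.0)
  expect_equal(s2$allele_errors, 2L)

  expect_error(genotype_score(20, 20, R = 20, M = 0), "positive")

  # symmetric in the two alleles, invariant to translating all lengths
  set.seed(17)
  for (i in 1:20) {
    a <- sample(seq(12, 60, 3), 2); R <- sample(seq(12, 60, 3), 1)
    c0 <- sample(3:30, 1)
    expect_equal(genotype_score(a[1], a[2], R, 3)$S,
                 genotype_score(a[2], a[1], R, 3)$S)
    expect_equal(genotype_score(a[1] + c0, a[2] + c0, R + c0, 3)$S,
                 genotype_score(a[1], a[2], R, 3)$S)
  }
})

test_that("error_profile tabulates counts with consistent totals", {
  loci <- data.frame(locus_id = c("L1", "L2"), unit_len = c(3L, 4L),
                     stringsAsFactors = FALSE)
  calls <- rbind(
    make_family_calls("L1", R = 30L, overrides = list(O01 = c(30L, 33L))),
    make_family_calls("L2", R = 40L, overrides = list(O01 = c(28L, 28L))))
  sel <- select_error_loci(calls, std_family)
  expect_equal(nrow(sel), 2L)
  prof <- error_profile(calls, sel, loci, std_family)
  ov <- prof[prof$category == "overall", ]
  cats <- prof[prof$category != "overall", ]
  expect_equal(sum(cats$genotype_n), ov$genotype_n)
  expect_equal(sum(cats$allele_err_n), ov$allele_err_n)
  expect_equal(ov$allele_n, 2L * ov$genotype_n)
  expect_equal(ov$genotype_err_n, 2L)       # one errored offspring per locus
  expect_equal(ov$allele_err_n, 3L)         # one single + one double deviation
  expect_equal(ov$allele_err_gt10_n, 2L)    # |28-40| = 12 on both alleles
  expect_equal(ov$allele_err_gt20_n, 0L)

  # single-category input: overall equals the category row
  prof1 <- error_profile(calls[calls$locus_id == "L1", ],
                         sel[sel$locus_id == "L1", ], loci, std_family)
  expect_equal(unlist(prof1[1, -1]), unlist(prof1[2, -1]))

  # no discordant calls: all rates zero
  clean <- make_family_calls("L1", R = 30L)
  prof0 <- error_profile(clean, select_error_loci(clean, std_family),
                         loci, std_family)
  expect_true(all(prof0$genotype_err_rate == 0))
  expect_true(all(prof0$allele_err_rate == 0))
})

test_that("score_correlations matches the textbook Pearson oracle", {
  x <- 1:20
  exact <- data.frame(a = x, b = 2 * x, c = -x + 40)
  m <- score_correlations(exact)
  expect_equal(m["a", "b"], 1.0)
  expect_equal(m["a", "c"], -1.0)
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))

  set.seed(33)
  rnd <- data.frame(u = rnorm(50), v = rnorm(50), w = runif(50))
  m2 <- score_correlations(rnd)
  pearson_oracle <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  for (i in names(rnd)) {
    for (j in names(rnd)) {
      expect_equal(m2[i, j], pearson_oracle(rnd[[i]], rnd[[j]]),
                   tolerance = 1e-12)
    }
  }
  expect_true(isSymmetric(m2))
  expect_true(all(m2 >= -1 & m2 <= 1))

  const <- data.frame(a = rnorm(10), b = rep(1, 10))
  expect_warning(score_correlations(const), "constant")
  expect_error(score_correlations(rnd[1:2, ]), "at least 3")
})

test_that("heterozygosity matches hand-enumerated frequencies", {
  mono <- make_calls("L1", list(a = c(30L, 30L), b = c(30L, 30L)))
  h <- heterozygosity(mono)
  expect_equal(h$Ho, 0)
  expect_equal(h$He, 0)

  het <- make_calls("L1", list(a = c(30L, 34L), b = c(30L, 34L),
                               c = c(30L, 34L)))
  h2 <- heterozygosity(het)
  expect_equal(h2$Ho, 1)
  expect_equal(h2$He, 0.5)

  # 3-allele table: alleles 30 x3, 34 x2, 38 x1 over 3 individuals
  tri <- make_calls("L1", list(a = c(30L, 30L), b = c(30L, 34L),
                               c = c(34L, 38L)))
  h3 <- heterozygosity(tri)
  expect_equal(h3$Ho, 2 / 3)
  expect_equal(h3$He, 1 - ((3 / 6)^2 + (2 / 6)^2 + (1 / 6)^2))
  expect_equal(h3$n_alleles, 3L)

  allmiss <- make_calls("L1", list(a = c(NA, NA)))
  expect_warning(hm <- heterozygosity(allmiss), "missing")
  expect_true(is.na(hm$Ho))
})

test_that("allelotype error rate stays below genotype error rate under stutter", {
  cfg <- sim_config(seed = 3, n_loci = c(`3` = 20L, `4` = 20L),
                    n_offspring = 60L)
  sim <- simulate_genome(cfg)
  fam <- simulate_family(sim$loci, cfg)
  truth <- fam$truth
  truth$depth <- ifelse(truth$individual_id %in% fam$family$parent_ids, 20L, 8L)
  st <- inject_stutter(truth, sim$loci, epsilon = 0.08, seed = 4)
  calls <- st$calls
  pmask <- calls$individual_id %in% fam$family$parent_ids
  calls[pmask, c("allele1", "allele2")] <- truth[pmask, c("allele1", "allele2")]
  sel <- select_error_loci(calls, fam$family)
  expect_gt(nrow(sel), 10L)
  prof <- error_profile(calls, sel,
                        sim$loci[, setdiff(names(sim$loci), "allele_pool")],
                        fam$family)
  ov <- prof[prof$category == "overall", ]
  expect_lt(ov$allele_err_rate, ov$genotype_err_rate)
  expect_equal(ov$allele_n, 2L * ov$genotype_n)
})
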