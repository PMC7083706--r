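#' Loci eligible for rarefaction
#'
#' Keeps loci typed (non-missing) in every one of the `individuals` and
#' showing at least `min_alleles` distinct allele lengths across them.
#'
#' @param calls genotype table.
#' @param individuals character vector of individual IDs (all must be
#'   covered).
#' @param min_alleles minimum distinct allele count (default 6).
#' @return Character vector of locus IDs.
#' @export
eligible_loci <- function(calls, individuals, min_alleles = 6L) {
  if (length(individuals) == 0L) stop("at least one individual required")
  d <- calls[calls$individual_id %in% individuals, , drop = FALSE]
  ok <- vapply(split(d, d$locus_id), function(x) {
    x <- x[!is.na(x$allele1), , drop = FALSE]
    length(unique(x$individual_id)) == length(individuals) &&
      length(unique(c(x$allele1, x$allele2))) >= min_alleles
  }, logical(1))
  sort(names(ok)[ok])
}

#' Rarefaction of allele statistics over individuals
#'
#' For each locus and each group size `g`, draws `g` individuals uniformly
#' without replacement and records, over the `2g` drawn alleles: the number
#' of distinct alleles, the maximum and minimum allele length, and the
#' allele length range (max - min). By default each group size is drawn
#' independently; `nested = TRUE` draws one permutation per locus and
#' takes its first `g` individuals, which makes all four statistics
#' monotone in `g`.
#'
#' @param calls genotype table.
#' @param loci character vector of locus IDs (see [eligible_loci()]).
#' @param individuals individual IDs to draw from.
#' @param sizes group sizes (default `1:length(individuals)`).
#' @param seed integer seed; draws are reproducible given the seed.
#' @param nested logical; nested draws (see above).
#' @param replicates independent draws per locus and size, averaged
#'   (default 1, a single draw).
#' @return Data frame `locus_id`, `g`, `replicate`, `allele_number`,
#'   `max_len`, `min_len`, `range`.
#' @export
rarefy_alleles <- function(calls, loci, individuals,
                           sizes = seq_along(individuals),
                           seed = 1L, nested = FALSE, replicates = 1L) {
  if (any(sizes > length(individuals))) {
    stop("group size exceeds the number of individuals")
  }
  individuals <- sort(individuals)
  loci <- sort(loci)
  d <- calls[calls$locus_id %in% loci &
               calls$individual_id %in% individuals &
               !is.na(calls$allele1), , drop = FALSE]
  set.seed(as.integer(seed))
  rows <- list()
  for (locus in loci) {
    dl <- d[d$locus_id == locus, , drop = FALSE]
    dl <- dl[order(dl$individual_id), , drop = FALSE]
    for (rep_i in seq_len(replicates)) {
      perm <- sample(individuals)
      for (g in sort(sizes)) {
        drawn <- if (nested) perm[seq_len(g)] else sample(individuals, g)
        a <- dl[dl$individual_id %in% drawn, , drop = FALSE]
        alleles <- c(a$allele1, a$allele2)
        rows[[length(rows) + 1L]] <- data.frame(
          locus_id = locus, g = g, replicate = rep_i,
          allele_number = length(unique(alleles)),
          max_len = max(alleles), min_len = min(alleles),
          range = max(alleles) - min(alleles),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# loci x group-size matrix for one rarefaction statistic
rarefaction_matrix <- function(rar, statistic = c("allele_number", "max_len",
                                                  "min_len", "range")) {
  statistic <- match.arg(statistic)
  agg <- stats::aggregate(rar[[statistic]],
                          by = list(locus_id = rar$locus_id, g = rar$g), FUN = mean)
  m <- tapply(agg$x, list(agg$locus_id, agg$g), identity)
  m[order(rownames(m)), order(as.integer(colnames(m))), drop = FALSE]
}

#' Friedman rank test over a loci-by-group-size matrix
#'
#' Blocks are rows (loci), treatments are columns (group sizes). Within
#' each block values are midranked; the tie-corrected statistic
#' `T = (k-1) * sum((Rj - n(k+1)/2)^2) / (A - n k (k+1)^2 / 4)` (with `A`
#' the sum of squared ranks) is referred to a chi-square distribution with
#' `k - 1` degrees of freedom. Without ties this reduces to the classic
#' `12/(n k (k+1)) * sum(Rj^2) - 3 n (k+1)`, which equals `n (k-1)` when
#' every block orders the treatments identically.
#'
#' @param mat numeric matrix, rows = blocks, columns = groups. Rows with
#'   any missing value are dropped with a warning.
#' @return List `statistic`, `df`, `p_value`, `n` (blocks used), `k`,
#'   `mean_ranks`; class `friedman_result`.
#' @export
friedman_rank_test <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need at least 2 groups")
  drop <- apply(mat, 1, anyNA)
  if (any(drop)) {
    warning(sum(drop), " block(s) with missing values dropped")
    mat <- mat[!drop, , drop = FALSE]
  }
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2L) stop("need at least 2 complete blocks")
  ranks <- t(apply(mat, 1, rank))     # midranks for ties
  Rj <- colSums(ranks)
  A <- sum(ranks^2)
  C <- n * k * (k + 1)^2 / 4
  denom <- A - C
  if (denom <= 0) {                    # all blocks constant: no evidence
    stat <- 0
  } else {
    stat <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / denom
  }
  structure(list(statistic = stat, df = k - 1L,
                 p_value = pchisq(stat, df = k - 1L, lower.tail = FALSE),
                 n = n, k = k, mean_ranks = Rj / n),
            class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("Friedman rank test: chi-squared = %.4g, df = %d, p = %.4g (n = %d blocks, k = %d groups)\n",
              x$statistic, x$df, x$p_value, x$n, x$k))
  invisible(x)
}

#' Nemenyi post hoc test for all pairwise group comparisons
#'
#' Mean-rank differences are referred to the studentized range
#' distribution with infinite degrees of freedom:
#' `q_ij = |Rbar_i - Rbar_j| / sqrt(k (k+1) / (12 n))`, with
#' `p = P(Q_{k,Inf} > q_ij)`. The test controls the family-wise error by
#' construction, so the pairwise p values receive no further adjustment.
#'
#' @param mat numeric matrix, rows = blocks, columns = groups (same input
#'   as [friedman_rank_test()]).
#' @return Symmetric matrix of pairwise p values with unit diagonal.
#' @export
nemenyi_posthoc <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need at least 2 groups")
  drop <- apply(mat, 1, anyNA)
  mat <- mat[!drop, , drop = FALSE]
  n <- nrow(mat); k <- ncol(mat)
  ranks <- t(apply(mat, 1, rank))
  rbar <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (12 * n))
  q <- abs(outer(rbar, rbar, `-`)) / se
  p <- ptukey(q, nmeans = k, df = Inf, lower.tail = FALSE)
  diag(p) <- 1
  dimnames(p) <- list(colnames(mat), colnames(mat))
  p
}

#' Saturation analysis of a population genotype table
#'
#' Convenience wrapper: selects eligible loci, rarefies over 1..N
#' individuals, and runs the Friedman and Nemenyi tests on each of the
#' four rarefaction statistics.
#'
#' @param calls genotype table.
#' @param individuals individual IDs (the population sample).
#' @param min_alleles eligibility threshold (default 6).
#' @param seed draw seed.
#' @param nested logical, passed to [rarefy_alleles()].
#' @return List `loci`, `rarefaction` (long table), and per-statistic
#'   `tests` (each with `friedman` and `nemenyi`).
#' @export
saturation_analysis <- function(calls, individuals, min_alleles = 6L,
                                seed = 1L, nested = FALSE) {
  loci <- eligible_loci(calls, individuals, min_alleles)
  if (length(loci) < 2L) stop("fewer than 2 eligible loci")
  rar <- rarefy_alleles(calls, loci, individuals, seed = seed, nested = nested)
  stats_names <- c("allele_number", "max_len", "min_len", "range")
  tests <- lapply(setNames(stats_names, stats_names), function(s) {
    m <- rarefaction_matrix(rar, s)
    list(friedman = friedman_rank_test(m), nemenyi = nemenyi_posthoc(m))
  })
  list(loci = loci, rarefaction = rar, tests = tests)
}
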