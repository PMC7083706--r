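#' Full-sib family design
#'
#' @param parent_ids exactly two distinct individual IDs.
#' @param offspring_ids one or more offspring IDs, disjoint from the
#'   parents.
#' @return A `family_design` list.
#' @export
family_design <- function(parent_ids, offspring_ids) {
  parent_ids <- as.character(parent_ids)
  offspring_ids <- as.character(offspring_ids)
  if (length(parent_ids) != 2L || anyDuplicated(parent_ids)) {
    stop("exactly two distinct parent IDs required")
  }
  if (length(offspring_ids) < 1L) stop("at least one offspring ID required")
  if (any(offspring_ids %in% parent_ids)) {
    stop("offspring IDs must not overlap parent IDs")
  }
  structure(list(parent_ids = parent_ids, offspring_ids = offspring_ids),
            class = "family_design")
}

#' Read a family design TSV (columns `role`, `individual_id`;
#' role is `parent` or `offspring`)
#' @param path TSV file.
#' @return A [family_design()] object.
#' @export
read_family <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("role", "individual_id") %in% names(df))) {
    stop("family table must have columns role, individual_id")
  }
  family_design(df$individual_id[df$role == "parent"],
                df$individual_id[df$role == "offspring"])
}

#' Error-assessment locus filters
#'
#' All comparisons are strict, following the filtering rules: parent depth
#' greater than `min_parent_depth`; total depth summed over all family
#' members less than `max_total_depth`; offspring missing fraction less
#' than `max_missing_frac`; parental-allele frequency among non-missing
#' offspring alleles greater than `min_parental_allele_freq`; minor
#' (non-parental) allele frequency less than `max_minor_allele_freq`.
#'
#' @param min_parent_depth default 10 reads (exclusive).
#' @param max_total_depth default 900 reads summed over the family
#'   (exclusive); guards against collapsed paralogous repeats.
#' @param max_missing_frac default 0.40 (exclusive).
#' @param min_parental_allele_freq default 0.80 (exclusive).
#' @param max_minor_allele_freq default 0.20 (exclusive).
#' @return An `error_filter_params` list.
#' @export
error_filter_params <- function(min_parent_depth = 10L,
                                max_total_depth = 900L,
                                max_missing_frac = 0.40,
                                min_parental_allele_freq = 0.80,
                                max_minor_allele_freq = 0.20) {
  stopifnot(min_parent_depth > 0, max_total_depth > 0,
            max_missing_frac > 0, max_missing_frac < 1,
            min_parental_allele_freq > 0, min_parental_allele_freq < 1,
            max_minor_allele_freq > 0, max_minor_allele_freq < 1)
  structure(list(min_parent_depth = as.integer(min_parent_depth),
                 max_total_depth = as.integer(max_total_depth),
                 max_missing_frac = max_missing_frac,
                 min_parental_allele_freq = min_parental_allele_freq,
                 max_minor_allele_freq = max_minor_allele_freq),
            class = "error_filter_params")
}

#' Select error-assessment loci in a full-sib family
#'
#' Retains loci where both parents carry the same homozygous genotype (so
#' a single parental allele length R exists) and the family-level depth,
#' missingness and offspring allele-frequency filters of
#' [error_filter_params()] all pass. At such loci every offspring is
#' expected to be homozygous R/R, so any deviation measures genotyping
#' error.
#'
#' @param calls genotype table covering parents and offspring.
#' @param family a [family_design()].
#' @param params an [error_filter_params()].
#' @return Data frame `locus_id`, `R` (parental allele length, bp).
#' @export
select_error_loci <- function(calls, family, params = error_filter_params()) {
  ids <- c(family$parent_ids, family$offspring_ids)
  absent <- setdiff(ids, unique(calls$individual_id))
  if (length(absent)) {
    stop("missing-individual: no calls for ", paste(absent, collapse = ", "))
  }
  fam_calls <- calls[calls$individual_id %in% ids, , drop = FALSE]
  n_off <- length(family$offspring_ids)
  keep <- lapply(split(fam_calls, fam_calls$locus_id), function(d) {
    p <- d[match(family$parent_ids, d$individual_id), , drop = FALSE]
    if (any(is.na(p$allele1)) || any(is.na(p$allele2))) return(NULL)
    if (p$allele1[1] != p$allele2[1] || p$allele1[2] != p$allele2[2]) return(NULL)
    if (p$allele1[1] != p$allele1[2]) return(NULL)
    R <- p$allele1[1]
    if (!all(p$depth > params$min_parent_depth)) return(NULL)
    if (sum(d$depth, na.rm = TRUE) >= params$max_total_depth) return(NULL)
    o <- d[d$individual_id %in% family$offspring_ids, , drop = FALSE]
    n_nonmiss <- sum(!is.na(o$allele1))
    miss_frac <- 1 - n_nonmiss / n_off
    if (miss_frac >= params$max_missing_frac) return(NULL)
    if (n_nonmiss == 0L) return(NULL)
    alleles <- c(o$allele1[!is.na(o$allele1)], o$allele2[!is.na(o$allele2)])
    pf <- mean(alleles == R)
    if (pf <= params$min_parental_allele_freq) return(NULL)
    other <- alleles[alleles != R]
    maf <- if (length(other)) max(table(other)) / length(alleles) else 0
    if (maf >= params$max_minor_allele_freq) return(NULL)
    data.frame(locus_id = d$locus_id[1], R = R, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, keep)
  if (is.null(out)) {
    out <- data.frame(locus_id = character(), R = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out[order(out$locus_id), , drop = FALSE]
}

#' Expected offspring parental-allele frequency under Mendelian segregation
#'
#' When both parents are called identically homozygous for allele R but
#' some of the four parental allele calls are themselves erroneous, the
#' offspring allele pool deviates predictably: with no erroneous parental
#' allele the expected frequency of R among offspring alleles is 1.0; with
#' one (true cross R/R x R/X) it is 0.75; with two (R/X x R/X) it is 0.50.
#' These expectations motivate the 0.80 / 0.20 offspring allele-frequency
#' thresholds.
#'
#' @param n_error_alleles_in_parents 0, 1 or 2.
#' @return Expected frequency of R among offspring alleles.
#' @examples
#' expected_offspring_parental_freq(1)  # 0.75
#' @export
expected_offspring_parental_freq <- function(n_error_alleles_in_parents) {
  n <- n_error_alleles_in_parents
  if (length(n) != 1L || is.na(n) || !n %in% 0:2) {
    stop("n_error_alleles_in_parents must be 0, 1 or 2")
  }
  # enumerate gamete draws: each parent transmits one of its two true alleles
  p1 <- c(1, 1) ; p2 <- c(1, 1)           # 1 = R, 0 = other
  if (n >= 1) p2 <- c(1, 0)
  if (n == 2) p1 <- c(1, 0)
  mean(outer(p1, p2, `+`)) / 2
}

#' Genotype deviation score
#'
#' `S = (|A1 - R| + |A2 - R|) / M`: total absolute deviation of the two
#' called allele lengths from the parental allele length, in motif units.
#' `S == 0` iff the call equals the expected homozygote R/R; each allele
#' differing from R is one allelotype error.
#'
#' @param allele1,allele2 called allele lengths (bp).
#' @param R parental allele length (bp).
#' @param M motif length (bp), 2-6.
#' @return List `S`, `allele_errors` (0, 1 or 2), `is_genotype_error`.
#' @examples
#' genotype_score(20, 24, R = 20, M = 4)  # S = 1, one allelotype error
#' @export
genotype_score <- function(allele1, allele2, R, M) {
  if (M <= 0) stop("motif length M must be positive")
  if (any(is.na(c(allele1, allele2)))) stop("call is missing; score undefined")
  S <- (abs(allele1 - R) + abs(allele2 - R)) / M
  list(S = S,
       allele_errors = sum(allele1 != R, allele2 != R),
       is_genotype_error = S > 0)
}

#' Genotype and allelotype error profile of a full-sib family
#'
#' At each selected locus every non-missing offspring genotype is compared
#' with the expected homozygote R/R. A genotype differing from (R, R) is a
#' genotype error; each allele differing from R is an allelotype error.
#' Counts and rates are tabulated per motif-length category (2-6 bp) and
#' overall, including errors whose allele-length deviation exceeds 10 bp
#' and 20 bp (large deviations matter because they can collide with a
#' neighbouring locus's size window on the capillary).
#'
#' @param calls genotype table.
#' @param selected data frame from [select_error_loci()].
#' @param loci locus data frame (for `unit_len`).
#' @param family a [family_design()].
#' @return Data frame, one row per motif-length category plus `overall`:
#'   `genotype_n`, `genotype_err_n`, `genotype_err_rate`, `allele_n`,
#'   `allele_err_n`, `allele_err_rate`, `allele_err_gt10_n/rate`,
#'   `allele_err_gt20_n/rate`. Class `ssr_error_profile`.
#' @export
error_profile <- function(calls, selected, loci, family) {
  m <- merge(selected, loci[, c("locus_id", "unit_len")], by = "locus_id")
  o <- calls[calls$individual_id %in% family$offspring_ids &
               calls$locus_id %in% m$locus_id &
               !is.na(calls$allele1), , drop = FALSE]
  o <- merge(o, m, by = "locus_id")
  cat_row <- function(d) {
    dev1 <- abs(d$allele1 - d$R); dev2 <- abs(d$allele2 - d$R)
    data.frame(
      genotype_n = nrow(d),
      genotype_err_n = sum(dev1 > 0 | dev2 > 0),
      allele_n = 2L * nrow(d),
      allele_err_n = sum(dev1 > 0) + sum(dev2 > 0),
      allele_err_gt10_n = sum(dev1 > 10) + sum(dev2 > 10),
      allele_err_gt20_n = sum(dev1 > 20) + sum(dev2 > 20)
    )
  }
  cats <- sort(unique(o$unit_len))
  rows <- lapply(cats, function(k) cat_row(o[o$unit_len == k, , drop = FALSE]))
  rows <- do.call(rbind, c(rows, list(cat_row(o))))
  rows <- cbind(category = c(as.character(cats), "overall"), rows,
                stringsAsFactors = FALSE)
  rows$genotype_err_rate <- ifelse(rows$genotype_n > 0,
                                   rows$genotype_err_n / rows$genotype_n, NA)
  rows$allele_err_rate <- ifelse(rows$allele_n > 0,
                                 rows$allele_err_n / rows$allele_n, NA)
  rows$allele_err_gt10_rate <- ifelse(rows$allele_n > 0,
                                      rows$allele_err_gt10_n / rows$allele_n, NA)
  rows$allele_err_gt20_rate <- ifelse(rows$allele_n > 0,
                                      rows$allele_err_gt20_n / rows$allele_n, NA)
  rownames(rows) <- NULL
  class(rows) <- c("ssr_error_profile", "data.frame")
  rows
}

#' Per-genotype score records for correlation analysis
#'
#' @param calls genotype table.
#' @param selected data frame from [select_error_loci()].
#' @param loci locus data frame.
#' @param family a [family_design()].
#' @return Data frame `motif_len`, `repeats`, `depth`, `score`, one row per
#'   non-missing offspring genotype at a selected locus.
#' @export
score_records <- function(calls, selected, loci, family) {
  m <- merge(selected, loci[, c("locus_id", "unit_len", "repeats")],
             by = "locus_id")
  o <- calls[calls$individual_id %in% family$offspring_ids &
               calls$locus_id %in% m$locus_id &
               !is.na(calls$allele1), , drop = FALSE]
  o <- merge(o, m, by = "locus_id")
  data.frame(
    motif_len = o$unit_len,
    repeats = o$repeats,
    depth = o$depth,
    score = (abs(o$allele1 - o$R) + abs(o$allele2 - o$R)) / o$unit_len
  )
}

#' Pearson correlation matrix of score predictors
#'
#' @param records data frame from [score_records()] (or any numeric data
#'   frame with at least 3 rows).
#' @return Symmetric correlation matrix with unit diagonal. Pairs involving
#'   a constant column are NA and flagged with a warning.
#' @export
score_correlations <- function(records) {
  x <- as.matrix(records)
  if (nrow(x) < 3L) stop("need at least 3 records")
  const <- apply(x, 2, function(v) sd(v) == 0 || is.na(sd(v)))
  if (any(const)) {
    warning("undefined correlation for constant column(s): ",
            paste(colnames(x)[const], collapse = ", "))
  }
  suppressWarnings(cor(x, method = "pearson"))
}

#' Observed and expected heterozygosity at one locus
#'
#' `Ho` is the fraction of heterozygous genotypes among non-missing calls;
#' `He = 1 - sum(p_i^2)` over allele frequencies pooled across the two
#' alleles of each call.
#'
#' @param calls genotype table restricted to one locus (or with a
#'   `locus_id` column covering exactly one locus).
#' @return List `Ho`, `He`, `n` (non-missing genotypes), `n_alleles`
#'   (distinct alleles). All-missing input yields NA with a warning.
#' @export
heterozygosity <- function(calls) {
  d <- calls[!is.na(calls$allele1) & !is.na(calls$allele2), , drop = FALSE]
  if (nrow(d) == 0L) {
    warning("all genotypes missing; heterozygosity undefined")
    return(list(Ho = NA_real_, He = NA_real_, n = 0L, n_alleles = 0L))
  }
  Ho <- mean(d$allele1 != d$allele2)
  alleles <- c(d$allele1, d$allele2)
  p <- table(alleles) / length(alleles)
  list(Ho = Ho, He = 1 - sum(p^2), n = nrow(d),
       n_alleles = length(unique(alleles)))
}

#' Per-locus heterozygosity summary across a genotype table
#' @param calls genotype table (any number of loci).
#' @return Data frame `locus_id`, `Ho`, `He`, `n`, `n_alleles`.
#' @export
heterozygosity_summary <- function(calls) {
  rows <- lapply(split(calls, calls$locus_id), function(d) {
    h <- suppressWarnings(heterozygosity(d))
    data.frame(locus_id = d$locus_id[1], Ho = h$Ho, He = h$He,
               n = h$n, n_alleles = h$n_alleles, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
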