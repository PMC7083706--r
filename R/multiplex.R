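#' Primer-compatibility screening thresholds
#'
#' Cross-dimer screening operationalized as perfect-complementarity run
#' lengths plus a Tm-spread bound; the `"normal"` preset reflects common
#' multiplex practice (any-position complementary run up to 7 bp,
#' 3'-anchored run up to 4 bp, Tm spread up to 3 degrees C).
#'
#' @param max_any_complementarity_run longest tolerated perfect
#'   complementary run anywhere between two primers (bp).
#' @param max_3prime_complementarity_run longest tolerated complementary
#'   run anchored at a primer's 3' end (bp).
#' @param max_tm_spread maximum Tm spread across all primers of a group
#'   (degrees C).
#' @param stringency preset label.
#' @return A `compatibility_params` list.
#' @export
compatibility_params <- function(max_any_complementarity_run = 7L,
                                 max_3prime_complementarity_run = 4L,
                                 max_tm_spread = 3,
                                 stringency = "normal") {
  stopifnot(max_any_complementarity_run > 0,
            max_3prime_complementarity_run > 0, max_tm_spread > 0)
  structure(list(max_any_complementarity_run = as.integer(max_any_complementarity_run),
                 max_3prime_complementarity_run = as.integer(max_3prime_complementarity_run),
                 max_tm_spread = max_tm_spread,
                 stringency = stringency),
            class = "compatibility_params")
}

# longest common substring length of two short strings (O(nm) DP)
longest_common_substring <- function(x, y) {
  a <- strsplit(x, "", fixed = TRUE)[[1]]
  b <- strsplit(y, "", fixed = TRUE)[[1]]
  if (!length(a) || !length(b)) return(0L)
  best <- 0L
  prev <- integer(length(b))
  for (i in seq_along(a)) {
    cur <- integer(length(b))
    eq <- a[i] == b
    cur[eq] <- c(0L, prev[-length(prev)])[eq] + 1L
    best <- max(best, cur)
    prev <- cur
  }
  best
}

# longest complementary (antiparallel) run between primers x and y:
# a run of x pairing with a run of y equals a common substring of x and
# the reverse complement of y
complementarity_run <- function(x, y) {
  longest_common_substring(toupper(x), dna_revcomp(y))
}

# longest complementary run anchored at the 3' end of x against any
# window of y: longest suffix of x that occurs in revcomp(y)
three_prime_run <- function(x, y) {
  x <- toupper(x); rcy <- dna_revcomp(y)
  n <- nchar(x)
  for (L in seq(n, 1L)) {
    if (grepl(substr(x, n - L + 1L, n), rcy, fixed = TRUE)) return(L)
  }
  0L
}

#' Pairwise compatibility of two primer pairs
#'
#' Fails when any of the primer-vs-primer combinations (all four cross
#' combinations plus each primer against itself) shows a perfect
#' complementary run longer than `max_any_complementarity_run`, or a run
#' anchored at either 3' end longer than `max_3prime_complementarity_run`,
#' or when the Tm spread across all four primers exceeds `max_tm_spread`.
#'
#' @param a,b one-row primer-table entries (need `fwd_seq`, `rev_seq`,
#'   `fwd_tm`, `rev_tm`). Pass the same row twice to self-screen a pair.
#' @param params a [compatibility_params()].
#' @return List `pass` (logical) and `reason` (`NA` when passing).
#' @export
pair_compatibility <- function(a, b, params = compatibility_params()) {
  pa <- c(a$fwd_seq, a$rev_seq)
  pb <- c(b$fwd_seq, b$rev_seq)
  all_primers <- unique(c(pa, pb))
  combos <- expand.grid(x = all_primers, y = all_primers,
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    if (complementarity_run(combos$x[i], combos$y[i]) >
        params$max_any_complementarity_run) {
      return(list(pass = FALSE, reason = "cross dimer"))
    }
  }
  for (x in all_primers) {
    for (y in all_primers) {
      if (three_prime_run(x, y) > params$max_3prime_complementarity_run) {
        return(list(pass = FALSE, reason = "3' dimer"))
      }
    }
  }
  tms <- c(a$fwd_tm, a$rev_tm, b$fwd_tm, b$rev_tm)
  if (diff(range(tms)) > params$max_tm_spread) {
    return(list(pass = FALSE, reason = "Tm spread"))
  }
  list(pass = TRUE, reason = NA_character_)
}

#' Greedy grouping of primer pairs into compatible multiplex reactions
#'
#' Pairs are sorted by descending allele count (ties by locus id) and
#' placed first-fit: each pair joins the first group below
#' `target_group_size` where it is pairwise compatible with every member;
#' otherwise it opens a new group. Every pair must first pass the screen
#' against itself.
#'
#' @param primers primer table (rows with `specific == FALSE` are dropped
#'   if the column is present).
#' @param params a [compatibility_params()].
#' @param target_group_size maximum pairs per reaction (default 10).
#' @return List of groups, each a data frame of member rows with a
#'   `group_id` column.
#' @export
group_primers <- function(primers, params = compatibility_params(),
                          target_group_size = 10L) {
  if ("specific" %in% names(primers)) {
    primers <- primers[primers$specific, , drop = FALSE]
  }
  if (!"n_alleles" %in% names(primers)) primers$n_alleles <- 0L
  primers <- primers[order(-primers$n_alleles, primers$locus_id), , drop = FALSE]
  groups <- list()
  for (i in seq_len(nrow(primers))) {
    row <- primers[i, , drop = FALSE]
    self <- pair_compatibility(row, row, params)
    placed <- FALSE
    if (self$pass) {
      for (gi in seq_along(groups)) {
        g <- groups[[gi]]
        if (nrow(g) >= target_group_size) next
        ok <- all(vapply(seq_len(nrow(g)), function(j) {
          pair_compatibility(row, g[j, , drop = FALSE], params)$pass
        }, logical(1)))
        if (ok) {
          groups[[gi]] <- rbind(g, row)
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- row
  }
  for (gi in seq_along(groups)) {
    groups[[gi]]$group_id <- sprintf("G%02d", gi)
    rownames(groups[[gi]]) <- NULL
  }
  groups
}

#' Assign fluorochrome channels within a multiplex group
#'
#' Pairs are sorted by `product_min` and packed first-fit into channels so
#' that consecutive allele-size windows in a channel are separated by at
#' least `min_space` bp (gap between one window's `product_max` and the
#' next window's `product_min`; a gap exactly equal to `min_space`
#' passes). Pairs overflowing `n_channels` are returned separately so the
#' caller can open a new group.
#'
#' @param group data frame of primer rows (needs `product_min`,
#'   `product_max`).
#' @param min_space minimum inter-window gap (bp, default 20).
#' @param n_channels dye channels available (default 4).
#' @param channel_labels dye names, longest-wavelength last.
#' @return List `assigned` (group with `channel` column) and `overflow`
#'   (rows that did not fit, possibly empty).
#' @export
assign_channels <- function(group, min_space = 20L, n_channels = 4L,
                            channel_labels = c("FAM", "HEX", "TAMRA", "ROX")) {
  channel_labels <- rep_len(channel_labels, n_channels)
  group <- group[order(group$product_min, group$product_max), , drop = FALSE]
  last_max <- rep(-Inf, n_channels)
  channel <- rep(NA_character_, nrow(group))
  overflow <- logical(nrow(group))
  for (i in seq_len(nrow(group))) {
    placed <- FALSE
    for (ch in seq_len(n_channels)) {
      if (group$product_min[i] - last_max[ch] >= min_space) {
        channel[i] <- channel_labels[ch]
        last_max[ch] <- group$product_max[i]
        placed <- TRUE
        break
      }
    }
    if (!placed) overflow[i] <- TRUE
  }
  assigned <- group[!overflow, , drop = FALSE]
  assigned$channel <- channel[!overflow]
  list(assigned = assigned, overflow = group[overflow, , drop = FALSE])
}

#' Build a complete multiplex panel
#'
#' Groups specific primer pairs by compatibility, then assigns dye
#' channels; overflow pairs re-enter as new groups until all pairs are
#' placed.
#'
#' @param primers primer table with `specific` column.
#' @param comp_params a [compatibility_params()].
#' @param min_space minimum inter-window gap per channel (bp).
#' @param n_channels dye channels per group.
#' @param target_group_size maximum pairs per group.
#' @return Panel data frame: `group_id`, `channel`, `locus_id`, `fwd_seq`,
#'   `rev_seq`, `fwd_tm`, `rev_tm`, `product_min`, `product_max`.
#' @export
build_panel <- function(primers, comp_params = compatibility_params(),
                        min_space = 20L, n_channels = 4L,
                        target_group_size = 10L) {
  groups <- group_primers(primers, comp_params, target_group_size)
  panel <- list()
  queue <- groups
  next_id <- length(groups) + 1L
  guard <- 0L
  while (length(queue)) {
    g <- queue[[1]]; queue <- queue[-1]
    res <- assign_channels(g, min_space, n_channels)
    if (nrow(res$assigned)) panel[[length(panel) + 1L]] <- res$assigned
    if (nrow(res$overflow)) {
      ov <- res$overflow
      ov$group_id <- sprintf("G%02d", next_id)
      next_id <- next_id + 1L
      queue[[length(queue) + 1L]] <- ov
    }
    guard <- guard + 1L
    if (guard > 10000L) stop("channel assignment did not converge")
  }
  out <- do.call(rbind, panel)
  keep <- c("group_id", "channel", "locus_id", "fwd_seq", "rev_seq",
            "fwd_tm", "rev_tm", "product_min", "product_max")
  out <- out[order(out$group_id, out$channel, out$product_min),
             intersect(c(keep, names(out)), names(out)), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Audit a panel against the separation and compatibility invariants
#'
#' Checks that every channel of every group keeps consecutive windows
#' separated by at least `min_space` and that all within-group pairs pass
#' [pair_compatibility()].
#'
#' @param panel panel data frame from [build_panel()].
#' @param primers the full primer table (for sequences/Tms if the panel
#'   was subset; defaults to the panel itself).
#' @param comp_params a [compatibility_params()].
#' @param min_space the gap the panel was built with.
#' @return TRUE invisibly; stops with a message on the first violation.
#' @export
audit_panel <- function(panel, primers = panel,
                        comp_params = compatibility_params(),
                        min_space = 20L) {
  for (gid in unique(panel$group_id)) {
    g <- panel[panel$group_id == gid, , drop = FALSE]
    for (ch in unique(g$channel)) {
      w <- g[g$channel == ch, , drop = FALSE]
      w <- w[order(w$product_min), , drop = FALSE]
      if (nrow(w) > 1L) {
        gaps <- w$product_min[-1] - w$product_max[-nrow(w)]
        if (any(gaps < min_space)) {
          stop("audit: window gap below min_space in ", gid, "/", ch)
        }
      }
    }
    if (nrow(g) > 1L) {
      for (i in seq_len(nrow(g) - 1L)) {
        for (j in seq(i + 1L, nrow(g))) {
          if (!pair_compatibility(g[i, ], g[j, ], comp_params)$pass) {
            stop("audit: incompatible pair in ", gid, ": ",
                 g$locus_id[i], " vs ", g$locus_id[j])
          }
        }
      }
    }
  }
  invisible(TRUE)
}
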