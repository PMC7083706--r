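#' Read a pipeline run configuration
#'
#' YAML with keys: `fasta`, and exactly one of `fastq` (named list
#' individual -> file) or `calls` (genotype TSV); optional `vcf`,
#' `family`, `out_dir`, `seed`, and parameter blocks `pipeline`
#' and `compatibility` overriding [pipeline_params()] /
#' [compatibility_params()] defaults.
#'
#' @param path YAML file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  absolutize <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^/", p), p, file.path(base, p))
  }
  cfg$fasta <- absolutize(cfg$fasta)
  cfg$vcf <- absolutize(cfg$vcf)
  cfg$calls <- absolutize(cfg$calls)
  cfg$family <- absolutize(cfg$family)
  if (!is.null(cfg$fastq)) cfg$fastq <- lapply(cfg$fastq, absolutize)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$fasta)) stop("config requires 'fasta'")
  has_fastq <- !is.null(cfg$fastq) && length(cfg$fastq) > 0
  has_calls <- !is.null(cfg$calls)
  if (has_fastq == has_calls) {
    stop("config requires exactly one of 'fastq' or 'calls'")
  }
  for (f in c(cfg$fasta, cfg$vcf, cfg$calls, unlist(cfg$fastq))) {
    if (!file.exists(f)) stop("file not found: ", f)
  }
  pp <- do.call(pipeline_params, as.list(cfg$pipeline %||% list()))
  cp <- do.call(compatibility_params, as.list(cfg$compatibility %||% list()))
  structure(list(fasta = cfg$fasta, vcf = cfg$vcf, fastq = cfg$fastq,
                 calls = cfg$calls, family = cfg$family,
                 out_dir = cfg$out_dir %||% ".",
                 seed = as.integer(cfg$seed %||% 1L),
                 pipeline = pp, compatibility = cp,
                 target_group_size = as.integer(cfg$target_group_size %||% 10L),
                 n_channels = as.integer(cfg$n_channels %||% 4L)),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the complete assay-development pipeline
#'
#' Stages: repeat cataloging, genotyping (or the skip model when a
#' pre-computed genotype table is supplied), polymorphic-locus selection,
#' variant masking, primer design, in-silico PCR specificity screening,
#' and multiplex grouping with dye-channel assignment. Every stage writes
#' its artifact under `out_dir` and appends a row-count audit line;
#' identical configuration and seed reproduce identical outputs.
#'
#' @param cfg a `run_config` from [read_run_config()], or a list with the
#'   same fields.
#' @return List `panel` (final panel data frame), `audit` (stage
#'   accounting), and intermediate tables (`loci`, `calls`, `selected`,
#'   `primers`).
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- validate_run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  audit <- list()
  log_stage <- function(stage, n_in, n_out) {
    audit[[length(audit) + 1L]] <<- data.frame(
      stage = stage, n_in = n_in, n_out = n_out, stringsAsFactors = FALSE)
    message(sprintf("[%s] %d -> %d", stage, n_in, n_out))
  }

  reference <- read_fasta_chr(cfg$fasta)

  loci <- find_perfect_ssrs(reference)
  write_loci_bed(loci, file.path(cfg$out_dir, "loci.bed"))
  log_stage("catalog", length(reference), nrow(loci))

  if (!is.null(cfg$calls)) {
    calls <- read_genotypes(cfg$calls)
    log_stage("genotype (skip model)", nrow(calls), nrow(calls))
  } else {
    calls <- do.call(rbind, lapply(names(cfg$fastq), function(id) {
      genotype_individual(cfg$fastq[[id]], loci, reference, id)
    }))
    log_stage("genotype", length(cfg$fastq), nrow(calls))
  }
  write_genotypes(calls, file.path(cfg$out_dir, "calls.tsv"))

  selected <- select_polymorphic_loci(calls, loci, cfg$pipeline)
  log_stage("select", nrow(loci), nrow(selected))

  if (is.null(cfg$vcf)) {
    warning("no VCF supplied; variant masking skipped")
    masked <- mask_variants(reference, NULL)
  } else {
    masked <- mask_variants(reference, cfg$vcf)
  }
  write_fasta_chr(masked, file.path(cfg$out_dir, "masked.fa"))
  log_stage("mask", length(reference), attr(masked, "variant_count"))

  design <- design_panel_primers(masked, selected, cfg$pipeline)
  n_designed <- if (is.null(design$primers)) 0L else nrow(design$primers)
  log_stage("design", nrow(selected), n_designed)
  if (n_designed == 0L) stop("stage design failed: no primer pairs designed")

  primers <- screen_specificity(reference, design$primers, cfg$pipeline)
  write.table(primers, file.path(cfg$out_dir, "primers.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("specificity", n_designed, sum(primers$specific))
  if (!any(primers$specific)) stop("stage specificity failed: no specific pair")

  panel <- build_panel(primers, cfg$compatibility,
                       min_space = cfg$pipeline$min_space,
                       n_channels = cfg$n_channels,
                       target_group_size = cfg$target_group_size)
  audit_panel(panel, comp_params = cfg$compatibility,
              min_space = cfg$pipeline$min_space)
  write.table(panel, file.path(cfg$out_dir, "panel.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("multiplex", sum(primers$specific), nrow(panel))

  audit_df <- do.call(rbind, audit)
  write.table(audit_df, file.path(cfg$out_dir, "audit.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  list(panel = panel, audit = audit_df, loci = loci, calls = calls,
       selected = selected, primers = primers)
}
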