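#' Analysis configuration
#'
#' Bundles every threshold used across the pipeline. Defaults follow the
#' published study design where a value is stated there (MAF, length window,
#' tag count, flanks, mismatch/indel allowance, pair window, fold/p cutoffs)
#' and conventional practice otherwise (depth and homozygosity guards,
#' duplex pairing fraction).
#'
#' @param maf_min minimum minor-allele frequency for a heterozygous (AB) call.
#' @param min_depth minimum read depth for any genotype call; shallower
#'   covered sites are called `NA`.
#' @param hom_err_max maximum minor-allele frequency still compatible with a
#'   homozygous (AA) call; frequencies between `hom_err_max` and `maf_min`
#'   are ambiguous and called `NA`.
#' @param sr_len_min,sr_len_max retained small RNA tag lengths (nt).
#' @param min_tag_count minimum read count in any one sample for a tag to be
#'   retained.
#' @param flank genic flank (bp) added on each side of a gene span.
#' @param sr_max_mm maximum substitutions in a small RNA placement.
#' @param sr_indel_max maximum length (nt) of the single tolerated microindel.
#' @param pair_window maximum distance (bp, 5'-start to 5'-start, inclusive)
#'   between the two arms of a candidate miRNA/miRNA* pair.
#' @param duplex_min_paired minimum fraction of miR bases paired (Watson-Crick
#'   or G:U) against the star arm for hairpin acceptance.
#' @param min_loop minimum loop (nt) between the two arms.
#' @param fc_min minimum fold change for mRNA differential calls.
#' @param de_alpha BH-adjusted p-value cutoff for mRNA differential calls.
#' @param go_alpha enrichment p-value cutoff.
#' @param qpcr_fc_min fold-change cutoff (strict) for qPCR calls.
#' @param qpcr_alpha t-test p cutoff (strict) for qPCR calls.
#' @param mrna_mm_frac maximum mismatch fraction of read length for mRNA
#'   read alignment (carried for completeness; used by the SAM reader only
#'   as a sanity bound).
#' @param seed default seed for stochastic helpers.
#' @return A list of class `apo_config`.
#' @export
apo_config <- function(maf_min = 0.25, min_depth = 8L, hom_err_max = 0.05,
                       sr_len_min = 18L, sr_len_max = 25L, min_tag_count = 5L,
                       flank = 500L, sr_max_mm = 2L, sr_indel_max = 2L,
                       pair_window = 400L, duplex_min_paired = 0.6,
                       min_loop = 3L, fc_min = 2, de_alpha = 0.01,
                       go_alpha = 1e-5, qpcr_fc_min = 1.5, qpcr_alpha = 0.05,
                       mrna_mm_frac = 0.10, seed = 1L) {
  cfg <- list(maf_min = maf_min, min_depth = as.integer(min_depth),
              hom_err_max = hom_err_max, sr_len_min = as.integer(sr_len_min),
              sr_len_max = as.integer(sr_len_max),
              min_tag_count = as.integer(min_tag_count),
              flank = as.integer(flank), sr_max_mm = as.integer(sr_max_mm),
              sr_indel_max = as.integer(sr_indel_max),
              pair_window = as.integer(pair_window),
              duplex_min_paired = duplex_min_paired,
              min_loop = as.integer(min_loop),
              fc_min = fc_min, de_alpha = de_alpha, go_alpha = go_alpha,
              qpcr_fc_min = qpcr_fc_min, qpcr_alpha = qpcr_alpha,
              mrna_mm_frac = mrna_mm_frac, seed = as.integer(seed))
  fracs <- c("maf_min", "hom_err_max", "duplex_min_paired", "go_alpha",
             "de_alpha", "qpcr_alpha", "mrna_mm_frac")
  for (f in fracs)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("config field '", f, "' must lie in [0, 1]")
  pos <- c("min_depth", "sr_len_min", "sr_len_max", "min_tag_count", "flank",
           "pair_window", "fc_min", "qpcr_fc_min")
  for (f in pos)
    if (cfg[[f]] <= 0) stop("config field '", f, "' must be positive")
  structure(cfg, class = "apo_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Unknown keys are rejected so typos surface early.
#'
#' @param path YAML file with a flat mapping of `apo_config()` fields.
#' @return An `apo_config` object.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(apo_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(apo_config, vals)
}

#' @export
print.apo_config <- function(x, ...) {
  cat("aposeq analysis configuration\n")
  for (f in names(x)) cat(sprintf("  %-18s %s\n", f, format(x[[f]])))
  invisible(x)
}

as_config <- function(config) {
  if (is.null(config)) return(apo_config())
  if (!inherits(config, "apo_config")) stop("'config' must be an apo_config")
  config
}
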