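## Deletion-marker discovery from transcriptome SNP genotype patterns.
##
## A parent genotype is compared against deletion mutants at per-site allele
## counts. Two loss patterns are recognised:
##   scenario 1 -- the parent is heterozygous (AB) at a site (two homeologous
##     or paralogous copies) and every mutant is homozygous (AA) for the same
##     retained allele: one copy lost.
##   scenario 2 -- the parent is monomorphic with coverage (A-) and every
##     mutant shows an absence of reads (--): a hemizygous gene fully lost.

#' Call per-sample SNP genotypes from allele-count pileups
#'
#' Site alleles (major/minor) are defined from counts pooled over all
#' samples. Per sample: depth 0 gives `--`; depth below `min_depth` gives
#' `NA`; minor-allele frequency at least `maf_min` gives `AB`; at most
#' `hom_err_max` gives `AA` (reported as `A-` for the parent when no second
#' allele is seen in any sample); frequencies in between are ambiguous and
#' give `NA`. A site is a SNP locus only if some sample is `AB`.
#'
#' @param pileup pileup data.frame from [load_pileup()] or the simulator.
#' @param config an [apo_config()].
#' @param parent optional parent sample id, enabling `A-` calls at
#'   monomorphic covered sites.
#' @return data.frame with one row per (site, sample): `contig`, `pos`,
#'   `sample`, `depth`, `genotype`, `major`, `minor`, `maf`, `top_base`,
#'   `snp_site`.
#' @export
call_genotypes <- function(pileup, config = NULL, parent = NULL) {
  config <- as_config(config)
  if (!is.null(parent) && !parent %in% pileup$sample)
    stop("parent sample '", parent, "' absent from pileup; samples: ",
         paste(unique(pileup$sample), collapse = ", "))
  bases <- c("A", "C", "G", "T")
  site_key <- paste(pileup$contig, pileup$pos)
  pooled <- rowsum(as.matrix(pileup[, bases]), site_key)
  ord <- t(apply(pooled, 1, order, decreasing = TRUE))
  site_major <- bases[ord[, 1]]
  minor_count <- pooled[cbind(seq_len(nrow(pooled)), ord[, 2])]
  site_minor <- ifelse(minor_count > 0, bases[ord[, 2]], NA_character_)
  names(site_major) <- names(site_minor) <- rownames(pooled)

  cm <- as.matrix(pileup[, bases])
  depth <- rowSums(cm)
  major <- site_major[site_key]
  minor <- site_minor[site_key]
  minor_n <- ifelse(is.na(minor), 0L,
                    cm[cbind(seq_len(nrow(cm)), match(minor, bases))])
  maf <- ifelse(depth > 0, minor_n / depth, NA_real_)
  top_base <- bases[max.col(cm, ties.method = "first")]
  top_base[depth == 0] <- NA_character_

  gt <- rep(NA_character_, nrow(pileup))
  gt[depth == 0] <- "--"
  ok <- depth >= config$min_depth
  gt[ok & maf >= config$maf_min] <- "AB"
  hom <- ok & maf <= config$hom_err_max & maf < config$maf_min
  gt[hom] <- "AA"
  if (!is.null(parent))
    gt[hom & pileup$sample == parent & is.na(minor)] <- "A-"

  out <- data.frame(contig = pileup$contig, pos = pileup$pos,
                    sample = pileup$sample, depth = depth, genotype = gt,
                    major = major, minor = minor, maf = maf,
                    top_base = top_base, stringsAsFactors = FALSE)
  snp_sites <- unique(site_key[gt == "AB" & !is.na(gt)])
  out$snp_site <- site_key %in% snp_sites
  out
}

#' Classify deletion scenarios across a parent and mutants
#'
#' Scenario 1: parent `AB` and every mutant `AA` for the same retained
#' allele (one of the parent's two alleles), at a SNP locus. Scenario 2:
#' parent `A-` and every mutant `--`. Sites where any mutant is `NA`
#' are excluded. When a `gene_map` is supplied, scenario-2 support is
#' required to be consistent across each gene: a gene is disqualified if
#' any mutant shows more than `max_stray_reads` total reads over the gene's
#' covered sites.
#'
#' @param calls output of [call_genotypes()].
#' @param parent_id parent sample id.
#' @param mutant_ids character vector of one or more mutant sample ids.
#' @param config an [apo_config()].
#' @param gene_map optional data.frame `contig`, `pos`, `gene_id` assigning
#'   sites to genes.
#' @param max_stray_reads tolerated mutant reads per gene for scenario 2
#'   (default 0, the strict absence-of-reads rule).
#' @return data.frame of supporting sites: `contig`, `pos`, `gene_id`,
#'   `scenario`, `retained`.
#' @export
classify_scenarios <- function(calls, parent_id, mutant_ids, config = NULL,
                               gene_map = NULL, max_stray_reads = 0L) {
  config <- as_config(config)
  if (length(parent_id) != 1L || length(mutant_ids) < 1L)
    stop("need exactly one parent and at least one mutant")
  key <- paste(calls$contig, calls$pos)
  par <- calls[calls$sample == parent_id, , drop = FALSE]
  rownames(par) <- paste(par$contig, par$pos)
  muts <- lapply(mutant_ids, function(m) {
    d <- calls[calls$sample == m, , drop = FALSE]
    rownames(d) <- paste(d$contig, d$pos)
    d <- d[rownames(par), , drop = FALSE]
    miss <- is.na(d$depth)  # site absent from the mutant's pileup: no reads
    d$depth[miss] <- 0
    d$genotype[miss] <- "--"
    d
  })

  mut_gt <- vapply(muts, function(d) d$genotype, character(nrow(par)))
  mut_top <- vapply(muts, function(d) d$top_base, character(nrow(par)))
  mut_depth <- vapply(muts, function(d) d$depth, numeric(nrow(par)))
  if (length(mutant_ids) == 1L) {
    mut_gt <- matrix(mut_gt, ncol = 1); mut_top <- matrix(mut_top, ncol = 1)
    mut_depth <- matrix(mut_depth, ncol = 1)
  }
  any_na <- apply(mut_gt, 1, function(g) any(is.na(g)))

  same_allele <- apply(mut_top, 1, function(b)
    !any(is.na(b)) && length(unique(b)) == 1L)
  retained <- mut_top[, 1]
  allele_ok <- same_allele & !is.na(par$major) &
    (retained == par$major |
       (!is.na(par$minor) & retained == par$minor))
  s1 <- !any_na & !is.na(par$genotype) & par$genotype == "AB" &
    apply(mut_gt, 1, function(g) all(g == "AA")) & allele_ok
  s2 <- !is.na(par$genotype) & par$genotype == "A-" &
    apply(mut_gt, 1, function(g) all(!is.na(g) & g == "--"))

  out <- data.frame(contig = par$contig, pos = par$pos,
                    gene_id = NA_character_,
                    scenario = ifelse(s1, 1L, ifelse(s2, 2L, NA_integer_)),
                    retained = ifelse(s1, retained, NA_character_),
                    stringsAsFactors = FALSE)
  if (!is.null(gene_map)) {
    gkey <- paste(gene_map$contig, gene_map$pos)
    out$gene_id <- gene_map$gene_id[match(paste(out$contig, out$pos), gkey)]
    # scenario-2 cross-site consistency within each gene
    s2_genes <- unique(out$gene_id[!is.na(out$scenario) &
                                     out$scenario == 2L & !is.na(out$gene_id)])
    for (g in s2_genes) {
      sites <- rownames(par)[!is.na(out$gene_id) & out$gene_id == g]
      stray <- colSums(mut_depth[rownames(par) %in% sites, , drop = FALSE])
      if (any(stray > max_stray_reads))
        out$scenario[out$gene_id == g & !is.na(out$scenario) &
                       out$scenario == 2L] <- NA_integer_
    }
  }
  out <- out[!is.na(out$scenario), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarise deletion candidates per gene or contig
#'
#' @param candidates output of [classify_scenarios()].
#' @param group_by `"gene"` (requires gene ids) or `"contig"`.
#' @param min_support minimum number of supporting sites (default 1).
#' @return data.frame ranked by `n_support` (descending, ties by id):
#'   `id`, `n_support`, `n_scenario1`, `n_scenario2`, `sites`.
#' @export
summarize_candidates <- function(candidates, group_by = c("gene", "contig"),
                                 min_support = 1L) {
  group_by <- match.arg(group_by)
  id <- if (group_by == "gene") candidates$gene_id else candidates$contig
  keep <- !is.na(id)
  candidates <- candidates[keep, , drop = FALSE]
  id <- id[keep]
  if (!nrow(candidates))
    return(data.frame(id = character(), n_support = integer(),
                      n_scenario1 = integer(), n_scenario2 = integer(),
                      sites = character(), stringsAsFactors = FALSE))
  sp <- split(candidates, id)
  out <- data.frame(
    id = names(sp),
    n_support = vapply(sp, nrow, integer(1)),
    n_scenario1 = vapply(sp, function(d) sum(d$scenario == 1L), integer(1)),
    n_scenario2 = vapply(sp, function(d) sum(d$scenario == 2L), integer(1)),
    sites = vapply(sp, function(d)
      paste(paste0(d$contig, ":", d$pos), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  out <- out[out$n_support >= min_support, , drop = FALSE]
  out <- out[order(-out$n_support, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
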