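## GO term enrichment with one-to-many orthology count weighting.
##
## Gene models map many-to-one onto reference-species orthologs carrying GO
## terms. Where m distinct gene models match one ortholog, each matched gene
## contributes m (the ortholog's multiplicity) to every one of its terms,
## mirroring the study's count multiplication; an unweighted mode is kept
## for comparison.

#' Multiplicity-weighted GO term counts for a gene list
#'
#' @param gene_list character vector of gene model ids.
#' @param annotation_map data.frame from [load_annotation_map()].
#' @param universe gene ids defining the universe within which ortholog
#'   multiplicities are computed (default: all genes in the map).
#' @param weighted multiply contributions by ortholog multiplicity
#'   (default TRUE).
#' @return list: `term_counts` (named numeric), `total` (weighted number of
#'   annotated units contributed by the list), `n_unannotated`.
#' @export
expand_counts <- function(gene_list, annotation_map, universe = NULL,
                          weighted = TRUE) {
  if (is.null(universe)) universe <- annotation_map$gene
  map <- annotation_map[annotation_map$gene %in% universe, , drop = FALSE]
  mult <- table(map$ortholog)
  idx <- match(gene_list, map$gene)
  miss <- is.na(idx)
  if (any(miss))
    message(sum(miss), " gene(s) without annotation contribute 0")
  idx <- idx[!miss]
  term_counts <- numeric(0)
  total <- 0
  for (i in idx) {
    m <- if (weighted) as.numeric(mult[map$ortholog[i]]) else 1
    terms <- map$go_terms[[i]]
    total <- total + m
    for (tm in terms)
      term_counts[tm] <- (if (tm %in% names(term_counts))
        term_counts[tm] else 0) + m
  }
  list(term_counts = term_counts, total = total,
       n_unannotated = sum(miss))
}

#' Hypergeometric GO enrichment of a foreground list against a background
#'
#' Counts are the multiplicity-weighted "annotated units" of
#' [expand_counts()]. Per term, the upper-tail hypergeometric p is the
#' probability of drawing at least the observed foreground count in
#' `fg_total` draws from a universe of `bg_total` units containing
#' `bg_count` annotated ones. Enriched iff p is at most `go_alpha`
#' (inclusive).
#'
#' @param fg_genes foreground gene ids (subset of `bg_genes`).
#' @param bg_genes background (universe) gene ids.
#' @param annotation_map data.frame from [load_annotation_map()].
#' @param config an [apo_config()].
#' @param weighted use multiplicity weighting (default TRUE).
#' @return data.frame sorted by p: `term`, `fg_count`, `bg_count`,
#'   `fg_total`, `bg_total`, `p`, `enriched`.
#' @export
enrich <- function(fg_genes, bg_genes, annotation_map, config = NULL,
                   weighted = TRUE) {
  config <- as_config(config)
  if (!all(fg_genes %in% bg_genes))
    stop("foreground genes must be a subset of the background universe")
  fg <- expand_counts(fg_genes, annotation_map, universe = bg_genes,
                      weighted = weighted)
  bg <- expand_counts(bg_genes, annotation_map, universe = bg_genes,
                      weighted = weighted)
  terms <- names(bg$term_counts)
  fg_count <- ifelse(terms %in% names(fg$term_counts),
                     fg$term_counts[terms], 0)
  bg_count <- bg$term_counts[terms]
  if (any(fg_count > bg_count))
    stop("foreground term count exceeds background count")
  fg_total <- round(fg$total); bg_total <- round(bg$total)
  p <- phyper(round(fg_count) - 1, round(bg_count),
              bg_total - round(bg_count), fg_total, lower.tail = FALSE)
  out <- data.frame(term = terms, fg_count = round(fg_count),
                    bg_count = round(bg_count), fg_total = fg_total,
                    bg_total = bg_total, p = p,
                    enriched = p <= config$go_alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
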