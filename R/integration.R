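## Cross-list integration: directional overlaps between mutant comparisons
## and complementary sRNA/mRNA target identification.
##
## Sign convention throughout: log2fc = log2(reference / comparison), so a
## gene lower in the mutant of a parent:mutant comparison has positive
## log2fc.

#' Directional overlap of two differential lists
#'
#' Genes differential in both lists are partitioned by sign agreement into
#' up_in_both / down_in_both / upA_downB / downA_upB ("up" = positive
#' log2fc); genes in only one list are reported as exclusive.
#'
#' @param deA,deB data.frames with `feature_id` and `log2fc`, restricted or
#'   restrictable via `is_differential` to the differential genes.
#' @return list of class `directional_overlap`: the four category gene-id
#'   vectors, `exclusiveA`, `exclusiveB`, `unclassifiable` (log2fc 0) and a
#'   `counts` summary vector.
#' @export
overlap_directional <- function(deA, deB) {
  a <- de_to_signed(deA); b <- de_to_signed(deB)
  common <- intersect(names(a), names(b))
  zero <- common[a[common] == 0 | b[common] == 0]
  if (length(zero))
    warning("gene(s) with log2fc 0 are unclassifiable: ",
            paste(zero, collapse = ", "))
  common <- setdiff(common, zero)
  res <- list(
    up_in_both = common[a[common] > 0 & b[common] > 0],
    down_in_both = common[a[common] < 0 & b[common] < 0],
    upA_downB = common[a[common] > 0 & b[common] < 0],
    downA_upB = common[a[common] < 0 & b[common] > 0],
    exclusiveA = setdiff(names(a), names(b)),
    exclusiveB = setdiff(names(b), names(a)),
    unclassifiable = zero)
  res$counts <- vapply(res, length, integer(1))
  class(res) <- "directional_overlap"
  res
}

de_to_signed <- function(de) {
  if ("is_differential" %in% names(de))
    de <- de[de$is_differential, , drop = FALSE]
  setNames(sign(de$log2fc), de$feature_id)
}

#' @export
print.directional_overlap <- function(x, ...) {
  cat("directional overlap:\n")
  print(x$counts)
  invisible(x)
}

#' Genes with complementary sRNA and mRNA fold-change directions
#'
#' Genes differential in both a small RNA and an mRNA comparison with
#' opposite log2fc signs (e.g. more small RNAs and less transcript in the
#' mutant).
#'
#' @param mrna_de,srna_de data.frames with `feature_id`, `log2fc` and
#'   optionally `is_differential`.
#' @return data.frame `gene_id`, `mrna_log2fc`, `srna_log2fc`.
#' @export
complementary_targets <- function(mrna_de, srna_de) {
  m <- de_to_lfc(mrna_de); s <- de_to_lfc(srna_de)
  common <- intersect(names(m), names(s))
  hit <- common[sign(m[common]) * sign(s[common]) == -1]
  out <- data.frame(gene_id = hit, mrna_log2fc = unname(m[hit]),
                    srna_log2fc = unname(s[hit]), stringsAsFactors = FALSE)
  out[order(out$gene_id), , drop = FALSE]
}

de_to_lfc <- function(de) {
  if ("is_differential" %in% names(de))
    de <- de[de$is_differential, , drop = FALSE]
  setNames(de$log2fc, de$feature_id)
}

#' Cross-reference target lists by membership count
#'
#' @param target_lists list (length >= 2) of character vectors of gene ids
#'   (or data.frames with a `gene_id` column), e.g. per stage x mutant.
#' @param k minimum number of lists a gene must appear in (default 2).
#' @return data.frame `gene_id`, `n_lists`, `lists` (comma-joined names),
#'   sorted by `n_lists` descending then gene id.
#' @export
cross_reference <- function(target_lists, k = 2L) {
  if (length(target_lists) < 2L) stop("need at least two lists")
  ids <- lapply(target_lists, function(x)
    unique(if (is.data.frame(x)) x$gene_id else x))
  if (is.null(names(ids)))
    names(ids) <- paste0("list", seq_along(ids))
  all_genes <- sort(unique(unlist(ids)))
  member <- vapply(ids, function(v) all_genes %in% v,
                   logical(length(all_genes)))
  if (length(all_genes) == 1L) member <- matrix(member, nrow = 1)
  n <- rowSums(member)
  lists <- apply(member, 1, function(r)
    paste(names(ids)[r], collapse = ","))
  out <- data.frame(gene_id = all_genes, n_lists = as.integer(n),
                    lists = lists, stringsAsFactors = FALSE)
  out <- out[out$n_lists >= k, , drop = FALSE]
  out <- out[order(-out$n_lists, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percentage of one set shared with another
#'
#' `100 * |A intersect B| / |A|`, rounded half-up to one decimal, matching
#' the printed style of shared-fraction summaries.
#'
#' @param setA,setB character vectors (or scalar counts via
#'   `shared_fraction_counts`).
#' @return percentage with one decimal.
#' @export
shared_fraction <- function(setA, setB) {
  if (!length(setA)) stop("set A must be non-empty")
  shared_fraction_counts(length(intersect(setA, setB)),
                         length(unique(setA)))
}

#' @rdname shared_fraction
#' @param n_shared,n_total counts of shared and total items.
#' @export
shared_fraction_counts <- function(n_shared, n_total) {
  if (n_total <= 0) stop("total must be positive")
  round_half_up(100 * n_shared / n_total, 1)
}
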