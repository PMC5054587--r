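## Small RNA tag filtering, genome placement and genic annotation.

#' Filter small RNA tags by length and abundance
#'
#' Keeps tags whose length lies in `[sr_len_min, sr_len_max]` and whose read
#' count reaches `min_tag_count` in at least one sample. Idempotent.
#'
#' @param tags an `srna_tags` object.
#' @param config an [apo_config()].
#' @return filtered `srna_tags`.
#' @export
filter_tags <- function(tags, config = NULL) {
  config <- as_config(config)
  len <- nchar(tags$sequence)
  keep <- len >= config$sr_len_min & len <= config$sr_len_max &
    apply(tags$counts, 1, max) >= config$min_tag_count
  srna_tags(tags$sequence[keep], tags$counts[keep, , drop = FALSE])
}

#' Place small RNA tags on the genome
#'
#' Reports every placement of every tag, on both strands, with at most
#' `sr_max_mm` substitutions and at most one microindel of up to
#' `sr_indel_max` nt. Placements are keyed by genome start; when a start
#' admits both a substitution-only and an indel alignment the
#' substitution-only one is recorded, otherwise the alignment with fewest
#' substitutions (ties to the shorter indel). `N` bases never match.
#'
#' @param tags an `srna_tags` object (tags must be at least 16 nt).
#' @param genome named character vector of contigs.
#' @param config an [apo_config()].
#' @return data.frame of class `srna_alignments`: `tag` (row index into
#'   `tags`), `sequence`, `contig`, `strand`, `start`, `end` (0-based
#'   half-open genome span), `mm`, `indel_len`.
#' @export
align_tags <- function(tags, genome, config = NULL) {
  config <- as_config(config)
  hits <- cpp_align_tags(unname(genome), tags$sequence,
                         config$sr_max_mm, config$sr_indel_max)
  out <- data.frame(tag = hits$tag,
                    sequence = tags$sequence[hits$tag],
                    contig = names(genome)[hits$contig],
                    strand = hits$strand, start = hits$start,
                    end = hits$end, mm = hits$mm,
                    indel_len = hits$indel_len, stringsAsFactors = FALSE)
  out <- out[order(out$tag, out$contig, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("srna_alignments", "data.frame")
  out
}

#' Annotate small RNA placements against extended gene models
#'
#' Each placement is assigned by its 5'-most base (start on `+`, `end - 1`
#' on `-`) to one feature class per overlapped gene, with precedence
#' `gene_body` (CDS blocks and the introns between them) over `utr5`/`utr3`
#' over `upstream`/`downstream` (strand-relative to the gene). A placement
#' whose 5' base falls in no extended region is `intergenic`. Placements
#' overlapping several genes' regions are assigned to each gene and flagged
#' ambiguous (dropped when `unique_gene = TRUE`).
#'
#' @param alignments an `srna_alignments` data.frame.
#' @param gm a `gene_models` data.frame.
#' @param contig_lengths named integer vector of contig lengths.
#' @param tags the `srna_tags` the alignments came from (for read weights).
#' @param config an [apo_config()].
#' @param unique_gene drop multi-gene placements instead of double-counting.
#' @return list with `assignments` (one row per placement x gene:
#'   `alignment`, `gene_id`, `class`, `ambiguous`) and `counts`
#'   (read-weighted per `gene_id` x `class` x sample, wide by sample).
#' @export
annotate_alignments <- function(alignments, gm, contig_lengths, tags,
                                config = NULL, unique_gene = FALSE) {
  config <- as_config(config)
  pos5 <- ifelse(alignments$strand == "+", alignments$start,
                 alignments$end - 1L)
  regions <- extended_regions(gm, contig_lengths, config$flank)
  spans <- gene_spans(gm)
  cds <- gm[gm$type == "cds", , drop = FALSE]
  cds_span <- do.call(rbind, lapply(split(cds, cds$gene_id), function(d)
    data.frame(gene_id = d$gene_id[1], start = min(d$start),
               end = max(d$end), stringsAsFactors = FALSE)))

  res <- vector("list", length(unique(regions$contig_id)))
  names(res) <- unique(regions$contig_id)
  rows <- list()
  for (ct in unique(alignments$contig)) {
    ai <- which(alignments$contig == ct)
    ri <- which(regions$contig_id == ct)
    if (!length(ai)) next
    q <- IRanges::IRanges(start = pos5[ai] + 1L, width = 1L)
    s <- IRanges::IRanges(start = regions$start[ri] + 1L,
                          end = regions$end[ri])
    ov <- IRanges::findOverlaps(q, s)
    if (length(ov)) {
      rows[[ct]] <- data.frame(
        alignment = ai[S4Vectors::queryHits(ov)],
        gene_id = regions$gene_id[ri[S4Vectors::subjectHits(ov)]],
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(alignment = integer(), gene_id = character(),
               stringsAsFactors = FALSE)

  # classify each (placement, gene) by the 5' base position
  cls <- character(nrow(hits))
  if (nrow(hits)) {
    p <- pos5[hits$alignment]
    gsp <- spans[match(hits$gene_id, spans$gene_id), ]
    csp <- cds_span[match(hits$gene_id, cds_span$gene_id), ]
    in_body <- !is.na(csp$start) & p >= csp$start & p < csp$end
    in_utr5 <- in_interval_set(p, hits$gene_id,
                               gm[gm$type == "utr5", , drop = FALSE])
    in_utr3 <- in_interval_set(p, hits$gene_id,
                               gm[gm$type == "utr3", , drop = FALSE])
    before <- p < gsp$start  # left of span
    five_side <- ifelse(gsp$strand == "+", before, !before & p >= gsp$end)
    cls <- ifelse(in_body, "gene_body",
           ifelse(in_utr5, "utr5",
           ifelse(in_utr3, "utr3",
           ifelse(p < gsp$start | p >= gsp$end,
                  ifelse(five_side, "upstream", "downstream"),
                  "gene_body"))))  # inside span but between blocks: genic
    cls[is.na(cls)] <- "gene_body"
  }
  hits$class <- cls
  n_genes <- table(hits$alignment)
  hits$ambiguous <- as.integer(n_genes[as.character(hits$alignment)]) > 1L
  if (unique_gene) hits <- hits[!hits$ambiguous, , drop = FALSE]

  inter <- setdiff(seq_len(nrow(alignments)), unique(hits$alignment))
  assignments <- rbind(hits,
    if (length(inter)) data.frame(alignment = inter,
                                  gene_id = NA_character_,
                                  class = "intergenic", ambiguous = FALSE,
                                  stringsAsFactors = FALSE))
  assignments <- assignments[order(assignments$alignment,
                                   assignments$gene_id), , drop = FALSE]
  rownames(assignments) <- NULL

  # read-weighted per-gene per-class counts
  w <- tags$counts[alignments$tag[assignments$alignment], , drop = FALSE]
  key <- paste(ifelse(is.na(assignments$gene_id), ".", assignments$gene_id),
               assignments$class, sep = "\r")
  agg <- rowsum(w, key)
  parts <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
  counts <- data.frame(gene_id = ifelse(parts[, 1] == ".", NA_character_,
                                        parts[, 1]),
                       class = parts[, 2], agg, check.names = FALSE,
                       stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  list(assignments = assignments, counts = counts)
}

in_interval_set <- function(pos, gene_id, iv) {
  if (!nrow(iv)) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  key <- split(seq_along(pos), gene_id)
  for (g in names(key)) {
    sub <- iv[iv$gene_id == g, , drop = FALSE]
    if (!nrow(sub)) next
    idx <- key[[g]]
    for (r in seq_len(nrow(sub)))
      out[idx] <- out[idx] | (pos[idx] >= sub$start[r] &
                                pos[idx] < sub$end[r])
  }
  out
}

#' Per-gene total small RNA counts
#'
#' Collapses an annotation to a gene x sample read-count matrix over the
#' extended regions (all classes except `intergenic`).
#'
#' @param annotation result of [annotate_alignments()].
#' @return integer matrix gene x sample.
#' @export
srna_gene_counts <- function(annotation) {
  cn <- annotation$counts
  cn <- cn[!is.na(cn$gene_id), , drop = FALSE]
  samples <- setdiff(names(cn), c("gene_id", "class"))
  m <- rowsum(as.matrix(cn[, samples, drop = FALSE]), cn$gene_id)
  storage.mode(m) <- "integer"
  m
}

#' Read-weighted tag length distribution per sample
#'
#' @param tags an `srna_tags` object.
#' @param range length range to tabulate (default 18-25).
#' @return integer matrix length x sample; bins sum to total read counts
#'   within range.
#' @export
length_distribution <- function(tags, range = c(18L, 25L)) {
  lens <- range[1]:range[2]
  len <- nchar(tags$sequence)
  m <- matrix(0L, length(lens), ncol(tags$counts),
              dimnames = list(lens, colnames(tags$counts)))
  keep <- len >= range[1] & len <= range[2]
  if (any(keep)) {
    agg <- rowsum(tags$counts[keep, , drop = FALSE], len[keep])
    m[rownames(agg), ] <- agg
  }
  m
}
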