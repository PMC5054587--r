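## MIRNA locus prediction from perfectly placed tag pairs, plus annotation
## of tags against a known mature miRNA reference set.

#' Annotate tags against a known mature miRNA set
#'
#' Exact sequence matches only (U/T normalised); a tag matching several
#' reference matures reports all of them.
#'
#' @param tags an `srna_tags` object.
#' @param mature_set named character vector from [load_mature_mirnas()].
#' @return data.frame `tag`, `sequence`, `mirna_ids` (comma-joined).
#' @export
annotate_known <- function(tags, mature_set) {
  seqs <- chartr("U", "T", toupper(mature_set))
  idx <- which(tags$sequence %in% seqs)
  hits <- lapply(tags$sequence[idx], function(s)
    paste(names(seqs)[seqs == s], collapse = ","))
  data.frame(tag = idx, sequence = tags$sequence[idx],
             mirna_ids = unlist(hits, use.names = FALSE) %||% character(0),
             stringsAsFactors = FALSE)
}

#' Find candidate miRNA/miRNA* tag pairs
#'
#' All unordered pairs of distinct tags perfectly placed (0 mismatches,
#' no indel) on the same contig and strand, whose 5'-start distance is at
#' most `pair_window` bp (inclusive) and whose spans do not overlap.
#'
#' @param alignments an `srna_alignments` data.frame.
#' @param config an [apo_config()].
#' @return data.frame `i`, `j` (row indices of the left and right arm in
#'   `alignments`, left = smaller genome start), `contig`, `strand`,
#'   `distance`.
#' @export
find_pairs <- function(alignments, config = NULL) {
  config <- as_config(config)
  perfect <- alignments$mm == 0L & alignments$indel_len == 0L
  a <- alignments[perfect, , drop = FALSE]
  a$row <- which(perfect)
  out <- list()
  for (grp in split(a, paste(a$contig, a$strand))) {
    if (nrow(grp) < 2L) next
    grp <- grp[order(grp$start), , drop = FALSE]
    p5 <- ifelse(grp$strand == "+", grp$start, grp$end - 1L)
    for (i in seq_len(nrow(grp) - 1L)) {
      for (j in (i + 1L):nrow(grp)) {
        if (grp$tag[i] == grp$tag[j]) next
        d <- abs(p5[j] - p5[i])
        if (grp$start[j] - p5[i] > config$pair_window + 30L) break
        if (d > config$pair_window) next
        if (grp$start[j] < grp$end[i]) next  # overlapping spans
        out[[length(out) + 1L]] <- data.frame(
          i = grp$row[i], j = grp$row[j], contig = grp$contig[i],
          strand = grp$strand[i], distance = d, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(i = integer(), j = integer(), contig = character(),
                      strand = character(), distance = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$strand,
                   pmin(res$i, res$j), pmax(res$i, res$j)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# paired (Watson-Crick or G:U wobble) in DNA alphabet
wc_wobble <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G") |
    (a == "G" & b == "T") | (a == "T" & b == "G")
}

#' Maximum base pairing of a sequence (Nussinov recursion)
#'
#' Counts Watson-Crick plus G:U wobble pairs, minimum loop `min_loop`.
#'
#' @param seq DNA string.
#' @param min_loop minimum unpaired gap inside a pair (default 3).
#' @return list `n_pairs` and `partner` (0-based partner index or -1).
#' @export
nussinov_pairs <- function(seq, min_loop = 3L) {
  cpp_nussinov(toupper(seq), as.integer(min_loop))
}

#' Evaluate a candidate arm pair for hairpin structure
#'
#' The duplex between the left arm and the reversed right arm is scored by
#' complementarity (Watson-Crick + G:U) over a +/-2 nt offset scan; the
#' pair is accepted when (i) the best paired fraction reaches
#' `duplex_min_paired`, (ii) the inter-arm loop is at least `min_loop` nt,
#' (iii) the duplex contains a contiguous helix of at least 7 base pairs
#' (the guaranteed minimum for a star arm carrying up to 2 mismatches),
#' and (iv) a Nussinov-style recursion restricted to inter-arm pairs
#' (maximum non-crossing pairing with free bulges) can pair at least 3/4
#' of the left-arm bases into the right arm. Maximum-cardinality folding
#' of the whole precursor is deliberately not used as the arm test: it is
#' degenerate on random sequence and carries no discrimination.
#'
#' @param pair one row of [find_pairs()] output.
#' @param alignments the `srna_alignments` the pair indexes into.
#' @param genome named character vector of contigs.
#' @param config an [apo_config()].
#' @return one-row data.frame: spans, `pair_distance`, `loop_len`,
#'   `duplex_paired_fraction`, `arm_arm_fraction`, `accepted`, `reason`.
#' @export
evaluate_hairpin <- function(pair, alignments, genome, config = NULL) {
  config <- as_config(config)
  a <- alignments[pair$i, ]; b <- alignments[pair$j, ]
  res <- data.frame(contig = a$contig, strand = a$strand,
                    mir_start = a$start, mir_end = a$end,
                    star_start = b$start, star_end = b$end,
                    precursor_start = a$start, precursor_end = b$end,
                    pair_distance = pair$distance,
                    loop_len = b$start - a$end,
                    max_helix = NA_integer_,
                    duplex_paired_fraction = NA_real_,
                    arm_arm_fraction = NA_real_,
                    accepted = FALSE, reason = "", stringsAsFactors = FALSE)
  if (b$start < a$end) {
    res$reason <- "overlapping_arms"
    return(res)
  }
  contig <- genome[[a$contig]]
  armA <- substr0(contig, a$start, a$end)
  armB <- substr0(contig, b$start, b$end)
  ca <- strsplit(armA, "")[[1]]
  cb <- rev(strsplit(armB, "")[[1]])
  la <- length(ca); lb <- length(cb)
  best <- 0; best_run <- 0L
  for (off in -2:2) {
    i <- seq_len(la)
    jj <- i + off
    ok <- jj >= 1 & jj <= lb
    if (!any(ok)) next
    paired <- wc_wobble(ca[i[ok]], cb[jj[ok]])
    best <- max(best, sum(paired) / la)
    runs <- rle(paired)
    run <- suppressWarnings(max(0L, runs$lengths[runs$values]))
    best_run <- max(best_run, run)
  }
  res$duplex_paired_fraction <- best
  res$max_helix <- best_run

  if (res$loop_len < config$min_loop) {
    res$reason <- "loop_too_short"
    return(res)
  }
  if (best < config$duplex_min_paired) {
    res$reason <- "duplex_below_threshold"
    return(res)
  }
  if (best_run < 7L) {
    res$reason <- "no_contiguous_helix"
    return(res)
  }
  res$arm_arm_fraction <- cpp_duplex_max_pairs(armA, armB) / la
  if (res$arm_arm_fraction < 0.75) {
    res$reason <- "arms_fold_apart"
  } else {
    res$accepted <- TRUE
    res$reason <- "ok"
  }
  res
}

#' Predict MIRNA loci from small RNA tags
#'
#' Runs perfect-placement pair finding and hairpin evaluation end to end.
#'
#' @param tags filtered `srna_tags`.
#' @param genome named character vector of contigs.
#' @param config an [apo_config()].
#' @param alignments optional precomputed [align_tags()] result.
#' @return data.frame of evaluated candidates (see [evaluate_hairpin()]).
#' @export
predict_mirna <- function(tags, genome, config = NULL, alignments = NULL) {
  config <- as_config(config)
  if (is.null(alignments)) alignments <- align_tags(tags, genome, config)
  pairs <- find_pairs(alignments, config)
  if (!nrow(pairs)) {
    return(data.frame(contig = character(), strand = character(),
                      mir_start = integer(), mir_end = integer(),
                      star_start = integer(), star_end = integer(),
                      precursor_start = integer(), precursor_end = integer(),
                      pair_distance = integer(), loop_len = integer(),
                      max_helix = integer(),
                      duplex_paired_fraction = numeric(),
                      arm_arm_fraction = numeric(), accepted = logical(),
                      reason = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k)
    evaluate_hairpin(pairs[k, ], alignments, genome, config)))
  rownames(out) <- NULL
  out
}
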