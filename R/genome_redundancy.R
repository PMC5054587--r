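## Assembly sequence redundancy: fraction of fixed-length k-mers with a
## near-identical partner elsewhere in the assembly.

#' k-mer Hamming redundancy of an assembly
#'
#' A k-mer is redundant when another k-mer at a sufficiently separated
#' coordinate lies within Hamming distance `max_hamming` of it. Computed
#' exactly by pigeonhole partitioning: each k-mer is split into
#' `max_hamming + 1` segments; any partner within the distance must share
#' at least one segment verbatim, so candidate pairs are collected from
#' shared-segment groups and verified by direct Hamming count. k-mers
#' containing N are skipped and reported.
#'
#' @param contigs named character vector of contig sequences.
#' @param k k-mer length in bp (default 100).
#' @param max_hamming maximum substitutions for a partner (default 2).
#' @param sample_step enumerate k-mer starts every `sample_step` bp
#'   (default 1 = all k-mers; thins queries and partners alike).
#' @param both_strands also consider reverse-complement partners.
#' @param min_separation minimum start-coordinate separation (bp) between a
#'   k-mer and a partner on the same contig (default `k`, which suppresses
#'   trivial self-overlap matches).
#' @return list of class `redundancy_report`: `k`, `max_hamming`,
#'   `n_kmers_sampled`, `n_skipped_n`, `n_redundant`, `fraction_redundant`.
#' @export
kmer_redundancy <- function(contigs, k = 100L, max_hamming = 2L,
                            sample_step = 1L, both_strands = FALSE,
                            min_separation = k) {
  stopifnot_scalar_count(k, "k")
  stopifnot_scalar_count(sample_step, "sample_step")
  if (any(nchar(contigs) < k)) stop("all contigs must be at least k long")

  km <- do.call(rbind, lapply(names(contigs), function(id) {
    starts <- seq(0L, nchar(contigs[[id]]) - k, by = sample_step)
    data.frame(contig = id, start = as.integer(starts),
               seq = substring(contigs[[id]], starts + 1L, starts + k),
               strand = "+", stringsAsFactors = FALSE)
  }))
  has_n <- grepl("N", km$seq, fixed = TRUE)
  n_skip <- sum(has_n)
  km <- km[!has_n, , drop = FALSE]
  nq <- nrow(km)
  if (!nq)
    return(structure(list(k = k, max_hamming = max_hamming,
                          n_kmers_sampled = 0L, n_skipped_n = n_skip,
                          n_redundant = 0L, fraction_redundant = NaN),
                     class = "redundancy_report"))
  pool <- km
  if (both_strands) {
    rc <- km
    rc$seq <- revcomp(km$seq)
    rc$strand <- "-"
    pool <- rbind(km, rc)
  }

  nseg <- max_hamming + 1L
  bounds <- floor(seq(0, k, length.out = nseg + 1L))
  redundant <- rep(FALSE, nq)
  for (sgi in seq_len(nseg)) {
    a <- bounds[sgi] + 1L; b <- bounds[sgi + 1L]
    segs_q <- substr(km$seq, a, b)
    segs_p <- if (both_strands) substr(pool$seq, a, b) else segs_q
    groups <- split(seq_len(nrow(pool)), segs_p)
    qgroups <- split(seq_len(nq), segs_q)
    for (key in names(qgroups)) {
      qi <- qgroups[[key]]
      pi <- groups[[key]]
      if (length(pi) < 2L && !both_strands) next
      for (i in qi) {
        if (redundant[i]) next
        for (j in pi) {
          pj <- (j - 1L) %% nq + 1L   # underlying forward k-mer index
          if (pj == i && pool$strand[j] == "+") next
          if (pool$contig[j] == km$contig[i] &&
              abs(pool$start[j] - km$start[i]) < min_separation) next
          if (hamming(km$seq[i], pool$seq[j]) <= max_hamming) {
            redundant[i] <- TRUE
            break
          }
        }
      }
    }
  }
  structure(list(k = as.integer(k), max_hamming = as.integer(max_hamming),
                 n_kmers_sampled = nq, n_skipped_n = n_skip,
                 n_redundant = sum(redundant),
                 fraction_redundant = mean(redundant)),
            class = "redundancy_report")
}

#' @export
print.redundancy_report <- function(x, ...) {
  cat(sprintf(paste0("k-mer redundancy: k=%d, max Hamming=%d, %d k-mers ",
                     "(%d skipped for N), fraction redundant %.4f\n"),
              x$k, x$max_hamming, x$n_kmers_sampled, x$n_skipped_n,
              x$fraction_redundant))
  invisible(x)
}
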