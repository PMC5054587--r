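# Independent brute-force oracles and shared fixtures.
# Oracles deliberately avoid the package's computational paths: alignment is
# a full-genome scan with vectorised mismatch counting, annotation a nested
# loop, Nussinov an explicit enumeration of nested structures.

.fixture_env <- new.env(parent = emptyenv())

# moderate shared simulation reused across test files
shared_sim <- function() {
  if (is.null(.fixture_env$sim))
    .fixture_env$sim <- simulate_genome(
      n_contigs = 2L, contig_len = 60000L, n_genes = 40L,
      n_scenario1 = 8L, n_scenario2 = 5L, n_mirna = 6L, n_sirna = 5L,
      seed = 101L)
  .fixture_env$sim
}

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

pairable_dna <- function(a, b) {
  paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
}

# --- alignment oracle -------------------------------------------------------
# All placements of `tag` on `genome` with <= max_mm substitutions and at
# most one internal microindel of 1..max_indel nt; same per-start preference
# as the aligner (substitution-only, then fewest mismatches, then shortest
# indel, genome-insertion before genome-deletion).
oracle_align_tag <- function(genome, tag, max_mm = 2L, max_indel = 2L) {
  out <- list()
  for (ct in names(genome)) {
    S <- strsplit(genome[[ct]], "")[[1]]
    N <- length(S)
    for (strand in c("+", "-")) {
      tseq <- if (strand == "-") revcomp(tag) else tag
      tch <- strsplit(tseq, "")[[1]]
      L <- length(tch)
      if (N < L - max_indel) next
      mism <- function(schars, tchars)
        schars != tchars | schars == "N" | tchars == "N"
      # candidate list per start, in preference order
      n0 <- N - L + 1L
      best_mm <- rep(NA_integer_, N)
      best_d <- rep(0L, N)
      best_span <- rep(0L, N)
      locked <- rep(FALSE, N)  # substitution-only alignment wins outright
      consider <- function(starts, mm, d, span) {
        ok <- mm <= max_mm
        idx <- starts[ok] + 1L
        mmo <- mm[ok]
        keep <- !locked[idx]
        idx <- idx[keep]; mmo <- mmo[keep]
        improve <- is.na(best_mm[idx]) | mmo < best_mm[idx] |
          (mmo == best_mm[idx] & d < best_d[idx])
        idx <- idx[improve]
        best_mm[idx] <<- mmo[improve]
        best_d[idx] <<- d
        best_span[idx] <<- span
      }
      if (n0 >= 1) {
        M0 <- vapply(seq_len(L), function(k)
          mism(S[k:(n0 + k - 1L)], tch[k]), logical(n0))
        if (n0 == 1L) M0 <- matrix(M0, nrow = 1)
        mm0 <- rowSums(M0)
        consider(0:(n0 - 1L), mm0, 0L, L)
        locked[which(mm0 <= max_mm)] <- TRUE
      }
      for (d in seq_len(max_indel)) {
        # genome carries d extra bases at an internal breakpoint
        ni <- N - L - d + 1L
        if (ni >= 1) {
          M <- vapply(seq_len(L), function(k)
            mism(S[k:(ni + k - 1L)], tch[k]), logical(ni))
          M2 <- vapply(seq_len(L), function(k)
            mism(S[(k + d):(ni + k + d - 1L)], tch[k]), logical(ni))
          if (ni == 1L) { M <- matrix(M, 1); M2 <- matrix(M2, 1) }
          P <- t(apply(M, 1, cumsum))
          C2 <- t(apply(M2, 1, cumsum))
          tot2 <- C2[, L]
          tots <- vapply(1:(L - 1L), function(g)
            P[, g] + tot2 - C2[, g], numeric(ni))
          if (ni == 1L) tots <- matrix(tots, 1)
          consider(0:(ni - 1L), apply(tots, 1, min), d, L + d)
        }
        # genome lacks d bases: d tag bases bulge out
        if (L - d >= 2) {
          nd <- N - (L - d) + 1L
          if (nd >= 1) {
            M <- vapply(seq_len(L - d), function(k)
              mism(S[k:(nd + k - 1L)], tch[k]), logical(nd))
            M3 <- vapply((d + 1L):L, function(k)
              mism(S[(k - d):(nd + k - d - 1L)], tch[k]), logical(nd))
            if (nd == 1L) { M <- matrix(M, 1); M3 <- matrix(M3, 1) }
            P <- t(apply(M, 1, cumsum))
            C3 <- t(apply(M3, 1, cumsum))
            tot3 <- C3[, L - d]
            gmax <- L - d - 1L
            tots <- vapply(seq_len(gmax), function(g)
              P[, g] + tot3 - C3[, g], numeric(nd))
            if (nd == 1L) tots <- matrix(tots, 1)
            consider(0:(nd - 1L), apply(tots, 1, min), d, L - d)
          }
        }
      }
      found <- which(!is.na(best_mm))
      if (length(found))
        out[[length(out) + 1L]] <- data.frame(
          contig = ct, strand = strand, start = found - 1L,
          end = found - 1L + best_span[found], mm = best_mm[found],
          indel_len = best_d[found], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(contig = character(), strand = character(),
                      start = integer(), end = integer(), mm = integer(),
                      indel_len = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$contig, res$start, res$strand), , drop = FALSE]
}

# --- annotation oracle ------------------------------------------------------
# Nested-loop classification of a 5' position against one gene.
oracle_classify_pos <- function(pos, gene, gm, contig_len, flank = 500L) {
  rows <- gm[gm$gene_id == gene, , drop = FALSE]
  span <- c(min(rows$start), max(rows$end))
  region <- c(max(0L, span[1] - flank),
              min(contig_len, span[2] + flank))
  if (pos < region[1] || pos >= region[2]) return(NA_character_)
  cds <- rows[rows$type == "cds", , drop = FALSE]
  if (nrow(cds) && pos >= min(cds$start) && pos < max(cds$end))
    return("gene_body")
  for (tp in c("utr5", "utr3")) {
    sub <- rows[rows$type == tp, , drop = FALSE]
    for (r in seq_len(nrow(sub)))
      if (pos >= sub$start[r] && pos < sub$end[r]) return(tp)
  }
  if (pos >= span[1] && pos < span[2]) return("gene_body")
  left <- pos < span[1]
  if (rows$strand[1] == "+") {
    if (left) "upstream" else "downstream"
  } else {
    if (left) "downstream" else "upstream"
  }
}

# --- Nussinov enumeration oracle -------------------------------------------
# Exhaustive recursion over nested structures (no memoisation): position lo
# is unpaired, or paired with each feasible j.
oracle_max_pairs <- function(seq, min_loop = 3L) {
  ch <- strsplit(toupper(seq), "")[[1]]
  rec <- function(lo, hi) {
    if (hi - lo < min_loop + 1L) return(0L)
    best <- rec(lo + 1L, hi)
    for (j in (lo + min_loop + 1L):hi)
      if (pairable_dna(ch[lo], ch[j]))
        best <- max(best, 1L + rec(lo + 1L, j - 1L) + rec(j + 1L, hi))
    best
  }
  if (length(ch) < min_loop + 2L) return(0L)
  rec(1L, length(ch))
}

# --- redundancy brute force -------------------------------------------------
oracle_redundancy <- function(contigs, k, max_hamming, min_separation = k) {
  km <- do.call(rbind, lapply(names(contigs), function(id) {
    starts <- 0:(nchar(contigs[[id]]) - k)
    data.frame(contig = id, start = starts,
               seq = substring(contigs[[id]], starts + 1L, starts + k),
               stringsAsFactors = FALSE)
  }))
  km <- km[!grepl("N", km$seq, fixed = TRUE), , drop = FALSE]
  n <- nrow(km)
  ham <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))
  red <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (km$contig[i] == km$contig[j] &&
          abs(km$start[i] - km$start[j]) < min_separation) next
      if (ham(km$seq[i], km$seq[j]) <= max_hamming) { red[i] <- TRUE; break }
    }
  }
  mean(red)
}
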