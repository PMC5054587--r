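mk_tags <- function(seqs, counts = NULL, samples = "s1") {
  if (is.null(counts))
    counts <- matrix(10L, length(seqs), length(samples))
  colnames(counts) <- samples
  srna_tags(seqs, counts)
}

test_that("tag filtering applies length and abundance boundaries", {
  seqs <- c(rand_dna(17), rand_dna(18), rand_dna(25), rand_dna(26),
            rand_dna(21), rand_dna(21))
  counts <- matrix(c(9, 0,
                     5, 0,
                     0, 5,
                     9, 9,
                     4, 4,
                     4, 5), ncol = 2, byrow = TRUE)
  tg <- mk_tags(seqs, counts, c("a", "b"))
  ft <- filter_tags(tg)
  expect_setequal(ft$sequence, seqs[c(2, 3, 6)])
  # idempotent
  expect_identical(filter_tags(ft), ft)
  # brute-force filter oracle on random tags
  set.seed(5)
  seqs2 <- vapply(1:1000, function(i) rand_dna(sample(10:30, 1)),
                  character(1))
  seqs2 <- unique(seqs2)
  cnt <- matrix(sample(0:12, length(seqs2) * 3, TRUE), ncol = 3)
  tg2 <- mk_tags(seqs2, cnt, c("a", "b", "c"))
  keep <- nchar(seqs2) >= 18 & nchar(seqs2) <= 25 &
    apply(cnt, 1, max) >= 5
  expect_setequal(filter_tags(tg2)$sequence, seqs2[keep])
})

test_that("aligner reports exact, mismatch and indel placements", {
  set.seed(11)
  g <- c(c1 = rand_dna(500))
  sub <- substr(g, 101, 121)
  # identity placement
  tg <- mk_tags(sub)
  al <- align_tags(tg, g)
  hit <- al[al$start == 100 & al$strand == "+", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$mm, 0L)
  expect_equal(hit$indel_len, 0L)
  expect_equal(hit$end, 121L)
  # three substitutions: no placement at that locus
  s3 <- sub
  for (p in c(3, 10, 18))
    substr(s3, p, p) <- setdiff(c("A", "C", "G", "T"),
                                substr(s3, p, p))[1]
  al3 <- align_tags(mk_tags(s3), g)
  expect_false(any(al3$start == 100 & al3$strand == "+"))
  # reverse strand placement of the reverse complement
  alr <- align_tags(mk_tags(revcomp(sub)), g)
  expect_true(any(alr$start == 100 & alr$strand == "-" & alr$mm == 0))
  # deletion in the genome relative to the tag (tag carries 2 extra nt)
  tdel <- paste0(substr(sub, 1, 10), "CA", substr(sub, 11, 21))
  ald <- align_tags(mk_tags(tdel), g)
  h <- ald[ald$start == 100 & ald$strand == "+", ]
  expect_equal(nrow(h), 1L)
  expect_lte(h$mm + (h$indel_len > 0) * 1L, 3L)
})

test_that("aligner equals the exhaustive scan oracle", {
  set.seed(13)
  g <- c(cA = rand_dna(2000), cB = rand_dna(400))
  # tags: exact substrings, mutated substrings (1-3 subs), indel variants,
  # random tags, and an N-containing genome region probe
  mk_variant <- function() {
    ct <- sample(names(g), 1)
    L <- sample(18:25, 1)
    st <- sample(nchar(g[[ct]]) - L - 3, 1)
    s <- substr(g[[ct]], st, st + L - 1)
    kind <- sample(c("exact", "sub", "indel", "both", "random"), 1)
    if (kind %in% c("sub", "both")) {
      for (p in sample(L, sample(1:3, 1)))
        substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(s, p, p)), 1)
    }
    if (kind %in% c("indel", "both")) {
      p <- sample(2:(L - 2), 1)
      if (runif(1) < 0.5)
        s <- paste0(substr(s, 1, p), rand_dna(sample(1:2, 1)),
                    substr(s, p + 1, L))
      else
        s <- paste0(substr(s, 1, p), substr(s, p + sample(1:2, 1) + 1, L))
    }
    if (kind == "random") s <- rand_dna(L)
    if (runif(1) < 0.3) s <- revcomp(s)
    s
  }
  seqs <- unique(vapply(1:60, function(i) mk_variant(), character(1)))
  seqs <- seqs[nchar(seqs) >= 16]
  tg <- mk_tags(seqs)
  al <- align_tags(tg, g)
  for (i in seq_along(seqs)) {
    got <- as.data.frame(al[al$tag == i,
                             c("contig", "strand", "start", "end", "mm",
                               "indel_len")])
    rownames(got) <- NULL
    want <- oracle_align_tag(g, seqs[i])
    rownames(want) <- NULL
    got <- got[order(got$contig, got$start, got$strand), ]
    rownames(got) <- NULL
    expect_equal(got, want, info = paste("tag", i))
  }
})

test_that("N bases in the genome never match", {
  g <- c(c1 = paste0(strrep("A", 50), "NNNN", strrep("A", 50)))
  al <- align_tags(mk_tags(strrep("A", 20)), g)
  fwd <- al[al$strand == "+" & al$indel_len == 0, ]
  # mismatch count of each reported placement equals its N overlap
  overlap <- pmax(0L, pmin(fwd$end, 54L) - pmax(fwd$start, 50L))
  expect_equal(fwd$mm, overlap)
  expect_true(all(al$mm <= 2))
})

test_that("annotation classes match the nested-loop oracle and partition", {
  sim <- shared_sim()
  sg <- c(s1 = "R35", s2 = "m115")
  tg <- simulate_smallrna(sim, sg, n_reads = 6000, n_bg = 400, seed = 71)
  ft <- filter_tags(tg)
  al <- align_tags(ft, sim$genome)
  ann <- annotate_alignments(al, sim$gene_models, nchar(sim$genome), ft)
  asn <- ann$assignments
  # oracle check on a subsample of placements x genes
  clen <- nchar(sim$genome)
  genes <- unique(sim$gene_models$gene_id)
  set.seed(1)
  for (i in sample(nrow(asn), 100)) {
    a <- al[asn$alignment[i], ]
    pos5 <- if (a$strand == "+") a$start else a$end - 1L
    gsub <- sim$gene_models[sim$gene_models$contig_id == a$contig, ]
    want <- NA_character_
    gid <- NA_character_
    for (gn in unique(gsub$gene_id)) {
      cls <- oracle_classify_pos(pos5, gn, gsub, clen[[a$contig]])
      if (!is.na(cls) && (is.na(asn$gene_id[i]) || gn == asn$gene_id[i])) {
        want <- cls; gid <- gn
        if (!is.na(asn$gene_id[i])) break
      }
    }
    if (is.na(asn$gene_id[i])) {
      expect_true(is.na(want),
                  info = paste("intergenic call at row", i))
      expect_equal(asn$class[i], "intergenic")
    } else {
      expect_equal(asn$class[i], want, info = paste("row", i))
    }
  }
  # read-count conservation: class counts partition placement totals
  w <- ft$counts[al$tag[asn$alignment], , drop = FALSE]
  expect_equal(colSums(ann$counts[, colnames(ft$counts)]),
               colSums(w))
})

test_that("per-gene counts are invariant to tag input order", {
  sim <- shared_sim()
  sg <- c(s1 = "R35")
  tg <- simulate_smallrna(sim, sg, n_reads = 3000, n_bg = 200, seed = 72)
  ft <- filter_tags(tg)
  perm <- sample(length(ft$sequence))
  ft2 <- srna_tags(ft$sequence[perm], ft$counts[perm, , drop = FALSE])
  a1 <- annotate_alignments(align_tags(ft, sim$genome), sim$gene_models,
                            nchar(sim$genome), ft)
  a2 <- annotate_alignments(align_tags(ft2, sim$genome), sim$gene_models,
                            nchar(sim$genome), ft2)
  m1 <- srna_gene_counts(a1); m2 <- srna_gene_counts(a2)
  expect_equal(m1[order(rownames(m1)), , drop = FALSE],
               m2[order(rownames(m2)), , drop = FALSE])
})

test_that("alignments reconstruct to the recorded edit operations", {
  set.seed(19)
  g <- c(c1 = rand_dna(1500))
  seqs <- unique(vapply(1:25, function(i) {
    st <- sample(1400, 1); L <- sample(18:24, 1)
    s <- substr(g, st, st + L - 1)
    p <- sample(L, 1)
    substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1)
    s
  }, character(1)))
  tg <- mk_tags(seqs)
  al <- align_tags(tg, g)
  no_indel <- al[al$indel_len == 0, ]
  for (i in seq_len(nrow(no_indel))) {
    a <- no_indel[i, ]
    sub <- substr(g[[a$contig]], a$start + 1, a$end)
    tagseq <- if (a$strand == "-") revcomp(a$sequence) else a$sequence
    d <- sum(strsplit(sub, "")[[1]] != strsplit(tagseq, "")[[1]])
    expect_equal(d, a$mm)
  }
})

test_that("length distribution conserves reads and handles empty input", {
  tg <- mk_tags(c(rand_dna(21), rand_dna(24)),
                matrix(c(5L, 7L, 2L, 0L), 2, 2), c("a", "b"))
  h <- length_distribution(tg)
  expect_equal(colSums(h), colSums(tg$counts))
  expect_equal(h["21", "a"], 5L)
  empty <- srna_tags(character(0),
                     matrix(integer(0), 0, 1, dimnames = list(NULL, "a")))
  expect_true(all(length_distribution(empty) == 0L))
})
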