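test_that("configuration validates fractions and thresholds", {
  cfg <- apo_config()
  expect_s3_class(cfg, "apo_config")
  expect_equal(cfg$maf_min, 0.25)
  expect_equal(cfg$flank, 500L)
  expect_error(apo_config(maf_min = 1.2), "\\[0, 1\\]")
  expect_error(apo_config(min_depth = 0), "positive")
})

test_that("config YAML round trip and unknown-key rejection", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("maf_min: 0.3", "min_tag_count: 7"), f)
  cfg <- read_config(f)
  expect_equal(cfg$maf_min, 0.3)
  expect_equal(cfg$min_tag_count, 7L)
  writeLines("not_a_key: 1", f)
  expect_error(read_config(f), "unknown config keys")
})

test_that("GFF3 coordinates convert to 0-based half-open and back", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\tx\tmRNA\t101\t300\t.\t+\t.\tID=gA",
    "c1\tx\tfive_prime_UTR\t101\t140\t.\t+\t.\tParent=gA",
    "c1\tx\tCDS\t141\t200\t.\t+\t.\tParent=gA",
    "c1\tx\tCDS\t251\t280\t.\t+\t.\tParent=gA",
    "c1\tx\tthree_prime_UTR\t281\t300\t.\t+\t.\tParent=gA"), f)
  gm <- load_gene_models(f)
  cds <- gm[gm$type == "cds", ]
  expect_equal(cds$start, c(140L, 250L))   # 1-based 141 -> internal 140
  expect_equal(cds$end, c(200L, 280L))
  expect_equal(nrow(intron_intervals(gm)), 1L)
  expect_equal(intron_intervals(gm)$start, 200L)
  expect_equal(intron_intervals(gm)$end, 250L)
  sp <- gene_spans(gm)
  expect_equal(c(sp$start, sp$end), c(100L, 300L))
  # single CDS block -> no introns
  f2 <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tx\tCDS\t11\t40\t.\t-\t.\tParent=gB"), f2)
  expect_equal(nrow(intron_intervals(load_gene_models(f2))), 0L)
})

test_that("gene model writer round-trips canonical files byte-identically", {
  sim <- shared_sim()
  f1 <- tempfile(fileext = ".gff3")
  write_gene_models(sim$gene_models, f1)
  gm2 <- load_gene_models(f1, setNames(nchar(sim$genome), names(sim$genome)))
  f2 <- tempfile(fileext = ".gff3")
  write_gene_models(gm2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("gene model validation rejects out-of-contig intervals", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tx\tCDS\t90\t150\t.\t+\t.\tParent=g1"), f)
  expect_error(load_gene_models(f, c(c1 = 100L)), "outside contig")
})

test_that("genome FASTA round trip", {
  sim <- shared_sim()
  f <- tempfile(fileext = ".fa")
  write_genome(sim$genome, f)
  expect_identical(read_genome(f), sim$genome)
})

test_that("pileup TSV reader applies schema and sample checks", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("contig\tpos\tsample\tA\tC\tG\tT",
               "c1\t99\ts1\t9\t0\t3\t0"), f)
  p <- load_pileup(f)
  expect_equal(p$pos, 99L)
  expect_equal(p$A, 9L)
  expect_equal(p$G, 3L)
  expect_error(load_pileup(f, samples = c("sX")), "known samples")
})

test_that("SAM-derived pileup equals TSV-derived pileup for the same reads", {
  sim <- shared_sim()
  ctg <- names(sim$genome)[1]
  seqc <- sim$genome[[ctg]]
  set.seed(7)
  starts <- sort(sample(1000:2000, 30))  # 1-based
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    sprintf("@SQ\tSN:%s\tLN:%d", ctg, nchar(seqc)),
    vapply(seq_along(starts), function(i)
      sprintf("r%d\t0\t%s\t%d\t60\t40M\t*\t0\t0\t%s\t*", i, ctg,
              starts[i], substr(seqc, starts[i], starts[i] + 39L)),
      character(1))), sam)
  from_sam <- load_pileup_sam(sam, "s1")
  # equivalent TSV built by direct per-site counting
  cover <- table(unlist(lapply(starts, function(s) s:(s + 39L))))
  tsv <- data.frame(contig = ctg, pos = as.integer(names(cover)) - 1L,
                    sample = "s1", A = 0L, C = 0L, G = 0L, T = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tsv))) {
    b <- substr(seqc, tsv$pos[i] + 1L, tsv$pos[i] + 1L)
    tsv[[b]][i] <- as.integer(cover[i])
  }
  f <- tempfile(); write_pileup(tsv, f)
  from_tsv <- load_pileup(f)
  rownames(from_sam) <- rownames(from_tsv) <- NULL
  expect_equal(from_sam[order(from_sam$pos), ],
               from_tsv[order(from_tsv$pos), ])
})

test_that("SAM reader honours CIGAR reference/query consumption", {
  sam <- tempfile(fileext = ".sam")
  # 3M 2I 3M 2D 2M over reference ACGTT + AA insertion handling
  writeLines(c("@SQ\tSN:c1\tLN:20",
               "r1\t0\tc1\t5\t60\t3M2I3M2D2M\t*\t0\t0\tACGAATTTCC\t*"), sam)
  p <- load_pileup_sam(sam, "s1")
  # reference positions covered: 4-9 (M blocks) then skip 2 (D), 12-13
  expect_setequal(p$pos, c(4:9, 12:13))
  expect_equal(sum(p[, c("A", "C", "G", "T")]), 8L)  # insertions not counted
})

test_that("tag FASTA loader merges samples, maps U to T, conserves counts", {
  d <- tempfile(); dir.create(d)
  f1 <- file.path(d, "s1.fa"); f2 <- file.path(d, "s2.fa")
  writeLines(c(">t1_count=3", "ACGUACGUACGUACGUACGUA",
               ">t2_count=2", "GGGGGGGGGGGGGGGGGGGG"), f1)
  writeLines(c(">x_count=7", "ACGTACGTACGTACGTACGTA"), f2)
  tg <- load_tags(c(s1 = f1, s2 = f2))
  expect_equal(length(tg$sequence), 2L)
  i <- which(tg$sequence == "ACGTACGTACGTACGTACGTA")  # U normalised
  expect_equal(unname(tg$counts[i, ]), c(3L, 7L))
  expect_equal(sum(tg$counts), 3L + 2L + 7L)
  writeLines(c(">bad_count=1", "ACGTN"), f1)
  expect_error(load_tags(c(s1 = f1)), "non-nucleotide")
})

test_that("tag writer/loader round trip preserves counts", {
  sim <- shared_sim()
  tg <- simulate_smallrna(sim, c(a = "R35", b = "m115"),
                          n_reads = 2000L, n_bg = 150L, seed = 5)
  paths <- write_tags(tg, tempfile())
  t2 <- load_tags(paths)
  expect_equal(sum(t2$counts), sum(tg$counts))
  nz <- rowSums(tg$counts) > 0
  expect_setequal(t2$sequence, tg$sequence[nz])
})

test_that("count matrix and Ct table I/O round trip", {
  cm <- simulate_counts(paste0("g", 1:15), seed = 2)$counts
  f <- tempfile(); write_count_matrix(cm, f)
  expect_identical(load_count_matrix(f), cm)
  ct <- simulate_ct(c(gA = 2), n_bio = 2, seed = 3)
  f2 <- tempfile(fileext = ".csv")
  write.csv(ct, f2, row.names = FALSE)
  ct2 <- load_ct(f2)
  expect_equal(ct2$ct, ct$ct)
})
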