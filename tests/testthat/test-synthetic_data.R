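test_that("genome simulation is deterministic in the seed", {
  a <- simulate_genome(n_contigs = 1, contig_len = 30000, n_genes = 10,
                       n_scenario1 = 2, n_scenario2 = 1, n_mirna = 2,
                       n_sirna = 2, seed = 42)
  b <- simulate_genome(n_contigs = 1, contig_len = 30000, n_genes = 10,
                       n_scenario1 = 2, n_scenario2 = 1, n_mirna = 2,
                       n_sirna = 2, seed = 42)
  expect_identical(a$genome, b$genome)
  expect_identical(a$gene_models, b$gene_models)
  expect_identical(a$truth, b$truth)
  # and byte-identical emitted files
  f1 <- tempfile(); f2 <- tempfile()
  write_genome(a$genome, f1); write_genome(b$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("configured heterozygous fraction is honoured in the truth table", {
  sim <- simulate_genome(n_contigs = 1, contig_len = 90000, n_genes = 30,
                         het_frac = 0.3, n_scenario1 = 3, n_scenario2 = 2,
                         n_mirna = 0, n_sirna = 2, seed = 9)
  expect_length(sim$truth$het_genes, 9L)   # 30 genes x 0.3
  expect_true(all(sim$truth$snps$gene_id %in% sim$truth$het_genes))
})

test_that("homeolog haplotypes differ at exactly the implanted SNP count", {
  sim <- shared_sim()
  for (g in utils::head(sim$truth$het_genes, 4)) {
    hp <- homeolog_seqs(sim, g)
    d <- sum(strsplit(hp[["hapA"]], "")[[1]] !=
               strsplit(hp[["hapB"]], "")[[1]])
    expect_equal(d, sum(sim$truth$snps$gene_id == g))
  }
})

test_that("pileups implement the two deletion scenarios by construction", {
  sim <- shared_sim()
  pp <- simulate_mutant_pileups(sim, depth_mean = 25, error_rate = 0,
                                seed = 21)
  pl <- pp$pileup
  key_gene <- pp$gene_map$gene_id[match(paste(pl$contig, pl$pos),
                                        paste(pp$gene_map$contig,
                                              pp$gene_map$pos))]
  del <- sim$truth$deleted
  s2 <- del$gene_id[del$scenario == 2L]
  mut <- pl$sample %in% sim$truth$mutants
  # scenario 2: zero mutant depth everywhere on the gene
  expect_true(all(rowSums(pl[mut & key_gene %in% s2,
                             c("A", "C", "G", "T")]) == 0))
  # error 0, scenario 1: mutants carry only the retained allele
  s1 <- del$gene_id[del$scenario == 1L]
  rows <- which(mut & key_gene %in% s1)
  for (i in utils::head(rows, 25)) {
    snp <- sim$truth$snps[sim$truth$snps$gene_id == key_gene[i] &
                            sim$truth$snps$pos == pl$pos[i], ]
    expect_equal(pl[i, snp$alt], 0L)
  }
})

test_that("count generator hits Poisson limit and implanted fold changes", {
  # dispersion 0: variance tracks mean over repeated draws
  simp <- simulate_counts(paste0("g", 1:10000), groups = c("A", "B"),
                          n_reps = 1, mu_range = c(50, 50), dispersion = 0,
                          lib_range = c(1, 1), seed = 31)
  x <- simp$counts[, 1]
  expect_lt(abs(var(x) / mean(x) - 1), 0.05)
  # dispersion spec: var = mu + phi mu^2
  simn <- simulate_counts(paste0("g", 1:10000), n_reps = 1,
                          mu_range = c(100, 100), dispersion = 0.1,
                          lib_range = c(1, 1), seed = 32)
  y <- simn$counts[, 1]
  expect_lt(abs(var(y) / (100 + 0.1 * 100^2) - 1), 0.1)
  # implanted 4-fold genes at mu >= 100 recover log2fc ~ 2; at this
  # dispersion the log-ratio SD is ~0.22 in log2, so >90% fall within 0.5
  des <- data.frame(gene_id = paste0("g", 1:200), log2fc = 2)
  simf <- simulate_counts(paste0("g", 1:400), n_reps = 2,
                          mu_range = c(200, 800), dispersion = 0.02,
                          de_spec = des, seed = 33)
  m <- simf$counts
  lfc <- log2(rowMeans(m[des$gene_id, 1:2]) / rowMeans(m[des$gene_id, 3:4]))
  expect_gte(mean(abs(lfc - 2) <= 0.5), 0.9)
  expect_error(simulate_counts(paste0("g", 1:5), dispersion = -1),
               "dispersion")
})

test_that("small RNA generator matches requested length mixes", {
  sim <- shared_sim()
  sg <- c(ov = "R35", lf = "R35")
  mix <- rbind(ov = length_mix_default("ovary"),
               lf = length_mix_default("leaf"))
  tg <- simulate_smallrna(sim, sg, mix, n_reads = 50000, n_bg = 1500,
                          seed = 41)
  h <- length_distribution(tg)
  for (s in c("ov", "lf")) {
    tot <- sum(h[, s])
    obs <- h[, s] / tot
    # multinomial 99% bounds at n = 50k
    se <- sqrt(mix[s, ] * (1 - mix[s, ]) / tot)
    expect_true(all(abs(obs - mix[s, ]) < 2.58 * se + 1e-3))
  }
  # a sample with twice the 22-nt share shows ~2x reads in the 22-nt bin
  r <- h["22", "ov"] / h["22", "lf"]
  expect_lt(abs(r - 2), 0.2)
  # implanted arms place perfectly on the genome
  al <- align_tags(srna_tags(sim$truth$mirna_loci$mir_seq,
                             matrix(1L, nrow(sim$truth$mirna_loci), 1,
                                    dimnames = list(NULL, "x"))),
                   sim$genome)
  expect_true(all(sim$truth$mirna_loci$mir_start %in%
                    al$start[al$mm == 0 & al$indel_len == 0]))
  expect_error(simulate_smallrna(sim, sg, mix / 2, seed = 1), "sum to 1")
})

test_that("Ct generator recovers folds exactly without noise", {
  ct <- simulate_ct(c(g1 = 1, g2 = 8), ct_noise_sd = 0, n_bio = 2, seed = 51)
  r1 <- ddct_logfc(ct, "g1", "UBC21", "R35", "m115")
  r2 <- ddct_logfc(ct, "g2", "UBC21", "R35", "m115")
  expect_equal(r1$avg_log2fc, 0)
  expect_equal(r2$avg_log2fc, 3)
  expect_equal(r2$sd, 0)
  expect_error(simulate_ct(c(g = 2), n_bio = 1, seed = 1), "replicates")
  expect_error(simulate_ct(c(g = -2), seed = 1), "positive")
  # noise 0.2, 3 reps: mean recovered log2fc within 0.3 of truth
  tr <- setNames(rep(c(1, 4, 8), length.out = 60), paste0("q", 1:60))
  ctn <- simulate_ct(tr, ct_noise_sd = 0.2, n_bio = 3, seed = 52)
  res <- qpcr_analyze(ctn, "UBC21", "R35", "m115")
  err <- res$avg_log2fc - log2(tr[res$gene_id])
  expect_lt(max(abs(err)), 0.8)
  expect_lt(abs(mean(err)), 0.1)
})

test_that("generators restore the caller's RNG state", {
  set.seed(1234)
  before <- .Random.seed
  invisible(simulate_counts(paste0("g", 1:10), seed = 99))
  expect_identical(.Random.seed, before)
})
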