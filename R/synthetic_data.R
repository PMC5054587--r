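## Ground-truthed synthetic data emulating the study design: a heterozygous
## polyploid parent, two deletion mutants, NB mRNA counts with implanted
## fold changes, small RNA populations with 21/22/24-nt classes, hairpin
## MIRNA loci and 24-nt siRNA clusters over gene bodies, and qPCR Ct tables.
##
## All generators restore the caller's RNG state; outputs are pure
## functions of (parameters, seed).

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Simulate a genome with structured gene models and implanted truth
#'
#' Contigs have i.i.d. uniform base composition outside implanted features.
#' Each gene has a UTR5/CDS(+introns)/UTR3 structure on a random strand. A
#' configured fraction of genes are heterozygous (two homeolog haplotypes
#' differing at `n_snps` implanted CDS positions; the emitted FASTA carries
#' haplotype A, the truth table the alternate alleles). Deletion scenarios
#' are pre-assigned: scenario-1 genes (heterozygous, one copy lost in every
#' mutant) and scenario-2 genes (hemizygous, all copies lost). MIRNA
#' hairpin loci (miR arm + loop + near-reverse-complement star arm, both
#' arms perfect genome matches within 400 bp) are implanted in intergenic
#' space, and a set of siRNA target genes is designated.
#'
#' @param n_contigs,contig_len,n_genes,gene_len_range genome dimensions.
#' @param het_frac fraction of genes heterozygous in the parent.
#' @param n_snps implanted SNPs per heterozygous gene.
#' @param n_scenario1,n_scenario2 deleted genes of each scenario.
#' @param n_mirna implanted hairpin loci.
#' @param mirna_star_mm substitutions injected into each star arm (0-2).
#' @param n_sirna siRNA target genes.
#' @param sirna_fold true small RNA fold change (mutant/parent) at siRNA
#'   target genes.
#' @param mutants mutant genotype labels sharing the deletion sets.
#' @param seed RNG seed.
#' @return list of class `apo_sim`: `genome`, `gene_models`, `truth`.
#' @export
simulate_genome <- function(n_contigs = 2L, contig_len = 200000L,
                            n_genes = 200L, gene_len_range = c(400L, 1200L),
                            het_frac = 0.3, n_snps = 6L, n_scenario1 = 30L,
                            n_scenario2 = 20L, n_mirna = 10L,
                            mirna_star_mm = 1L, n_sirna = 15L,
                            sirna_fold = 4, mutants = c("m115", "m134"),
                            seed = 1L) with_seed(seed, {
  if (max(gene_len_range) + 1200L > contig_len)
    stop("gene longer than contig: increase contig_len")
  bases <- c("A", "C", "G", "T")
  contigs <- setNames(random_dna(n_contigs, contig_len),
                      paste0("ctg", seq_len(n_contigs)))

  per <- diff(floor(seq(0, n_genes, length.out = n_contigs + 1L)))
  gap <- 1100L  # keeps extended regions (500 bp flanks) disjoint
  # reserve an intergenic tail per contig for implanted hairpin loci
  loci_per_contig <- if (n_mirna > 0) ceiling(n_mirna / n_contigs) else 0L
  reserve <- loci_per_contig * 150L + 200L
  gene_space <- contig_len - reserve
  rows <- list(); gid <- 0L
  mirna_space <- list()
  for (ci in seq_len(n_contigs)) {
    ng <- per[ci]
    lens <- sample(seq(gene_len_range[1], gene_len_range[2]), ng,
                   replace = TRUE)
    need <- sum(lens) + (ng + 1L) * gap
    if (need > gene_space)
      stop("genes do not fit on contig: increase contig_len or reduce genes")
    slack <- gene_space - need
    extra <- floor(slack / (ng + 1L))
    pos <- gap + extra
    for (gi in seq_len(ng)) {
      gid <- gid + 1L
      L <- lens[gi]
      strand <- sample(c("+", "-"), 1L)
      u5 <- sample(50:120, 1L); u3 <- sample(60:150, 1L)
      n_intr <- sample(0:2, 1L)
      intr <- if (n_intr) sample(60:120, n_intr, replace = TRUE) else
        integer(0)
      cds_total <- L - u5 - u3 - sum(intr)
      if (cds_total < 90L) { n_intr <- 0L; intr <- integer(0)
        cds_total <- L - u5 - u3 }
      blocks <- rep(floor(cds_total / (n_intr + 1L)), n_intr + 1L)
      blocks[1] <- blocks[1] + cds_total - sum(blocks)
      left_utr <- if (strand == "+") "utr5" else "utr3"
      right_utr <- if (strand == "+") "utr3" else "utr5"
      left_len <- if (strand == "+") u5 else u3
      right_len <- if (strand == "+") u3 else u5
      id <- sprintf("g%03d", gid)
      p <- pos
      iv <- list(data.frame(gene_id = id, contig_id = names(contigs)[ci],
                            strand = strand, type = left_utr, start = p,
                            end = p + left_len, stringsAsFactors = FALSE))
      p <- p + left_len
      for (bi in seq_along(blocks)) {
        iv[[length(iv) + 1L]] <- data.frame(
          gene_id = id, contig_id = names(contigs)[ci], strand = strand,
          type = "cds", start = p, end = p + blocks[bi],
          stringsAsFactors = FALSE)
        p <- p + blocks[bi]
        if (bi <= length(intr)) p <- p + intr[bi]
      }
      iv[[length(iv) + 1L]] <- data.frame(
        gene_id = id, contig_id = names(contigs)[ci], strand = strand,
        type = right_utr, start = p, end = p + right_len,
        stringsAsFactors = FALSE)
      rows[[gid]] <- do.call(rbind, iv)
      pos <- pos + L + gap + extra
    }
    mirna_space[[ci]] <- c(gene_space + 100L, contig_len - 50L)
  }
  gm <- do.call(rbind, rows)
  rownames(gm) <- NULL
  class(gm) <- c("gene_models", "data.frame")
  ids <- unique(gm$gene_id)

  # heterozygous genes and their implanted SNPs
  n_het <- round(het_frac * n_genes)
  het_genes <- sort(sample(ids, n_het))
  snps <- list()
  for (g in het_genes) {
    cds <- gm[gm$gene_id == g & gm$type == "cds", , drop = FALSE]
    sites <- sort(sample(unlist(mapply(seq, cds$start, cds$end - 1L,
                                       SIMPLIFY = FALSE)), n_snps))
    ct <- cds$contig_id[1]
    ref <- vapply(sites, function(p) substr0(contigs[[ct]], p, p + 1L),
                  character(1))
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L),
                  character(1))
    snps[[g]] <- data.frame(gene_id = g, contig = ct, pos = sites,
                            ref = ref, alt = unname(alt),
                            stringsAsFactors = FALSE)
  }
  snps <- if (length(snps)) do.call(rbind, snps) else
    data.frame(gene_id = character(), contig = character(), pos = integer(),
               ref = character(), alt = character(), stringsAsFactors = FALSE)
  rownames(snps) <- NULL

  # deletion assignment, shared across mutants (the study selected SNPs
  # missing from both mutants)
  if (n_scenario1 > n_het) stop("n_scenario1 exceeds heterozygous genes")
  non_het <- setdiff(ids, het_genes)
  if (n_scenario2 > length(non_het)) stop("n_scenario2 exceeds genes")
  s1 <- sort(sample(het_genes, n_scenario1))
  s2 <- sort(sample(non_het, n_scenario2))
  deleted <- data.frame(gene_id = c(s1, s2),
                        scenario = c(rep(1L, length(s1)),
                                     rep(2L, length(s2))),
                        stringsAsFactors = FALSE)

  # hairpin MIRNA loci in the intergenic tail of each contig
  loci <- list()
  if (n_mirna > 0) {
    loop_len <- 15L
    for (k in seq_len(n_mirna)) {
      ci <- (k - 1L) %% n_contigs + 1L
      space <- mirna_space[[ci]]
      width <- 21L * 2L + loop_len
      slot_w <- floor((space[2] - space[1]) / ceiling(n_mirna / n_contigs))
      slot <- space[1] + (ceiling(k / n_contigs) - 1L) * slot_w
      if (slot + width > space[2]) stop("no intergenic space for MIRNA loci")
      mir <- random_dna(1L, 21L)
      star <- revcomp(mir)
      if (mirna_star_mm > 0) {
        pos_mm <- sample(21L, mirna_star_mm)
        sc <- strsplit(star, "")[[1]]
        for (pm in pos_mm) sc[pm] <- sample(setdiff(bases, sc[pm]), 1L)
        star <- paste(sc, collapse = "")
      }
      loop <- random_dna(1L, loop_len)
      ct <- names(contigs)[ci]
      contigs[[ct]] <- implant0(contigs[[ct]], slot,
                                paste0(mir, loop, star))
      loci[[k]] <- data.frame(
        locus_id = sprintf("mir%02d", k), contig = ct, strand = "+",
        mir_start = slot, mir_end = slot + 21L,
        star_start = slot + 21L + loop_len,
        star_end = slot + 42L + loop_len,
        mir_seq = mir, star_seq = star, stringsAsFactors = FALSE)
    }
  }
  mirna_loci <- if (length(loci)) do.call(rbind, loci) else
    data.frame(locus_id = character(), contig = character(),
               strand = character(), mir_start = integer(),
               mir_end = integer(), star_start = integer(),
               star_end = integer(), mir_seq = character(),
               star_seq = character(), stringsAsFactors = FALSE)

  sirna_pool <- setdiff(ids, deleted$gene_id)
  sirna <- data.frame(gene_id = sort(sample(sirna_pool, n_sirna)),
                      srna_fold = sirna_fold, stringsAsFactors = FALSE)

  truth <- list(het_genes = het_genes, snps = snps, deleted = deleted,
                mutants = mutants, mirna_loci = mirna_loci,
                sirna_targets = sirna)
  structure(list(genome = contigs, gene_models = gm, truth = truth),
            class = "apo_sim")
})

#' Homeolog haplotype sequences of a heterozygous gene
#'
#' @param sim an `apo_sim` object.
#' @param gene_id a heterozygous gene.
#' @return character vector `c(hapA=, hapB=)` of the gene-span sequences;
#'   haplotype B substitutes the implanted alternate alleles.
#' @export
homeolog_seqs <- function(sim, gene_id) {
  sp <- gene_spans(sim$gene_models)
  sp <- sp[sp$gene_id == gene_id, ]
  if (!nrow(sp)) stop("unknown gene ", gene_id)
  hapA <- substr0(sim$genome[[sp$contig_id]], sp$start, sp$end)
  s <- sim$truth$snps[sim$truth$snps$gene_id == gene_id, , drop = FALSE]
  hapB <- hapA
  for (i in seq_len(nrow(s)))
    substr(hapB, s$pos[i] - sp$start + 1L, s$pos[i] - sp$start + 1L) <-
      s$alt[i]
  c(hapA = hapA, hapB = hapB)
}

#' Simulate parent and mutant allele-count pileups
#'
#' Tracked sites are the implanted SNP positions of heterozygous genes plus
#' `n_snps`-like monomorphic sites per non-heterozygous gene. Per-site
#' depth is Poisson(`depth_mean`); the parent emits both alleles at ~50:50
#' at heterozygous sites; scenario-1 genes emit only the retained (A)
#' allele in mutants; scenario-2 genes emit zero mutant reads; a base-error
#' rate redistributes each read to a random other base.
#'
#' @param sim an `apo_sim` object.
#' @param parent parent sample label.
#' @param depth_mean mean per-site depth.
#' @param error_rate per-read base error probability.
#' @param sites_per_gene monomorphic tracked sites per non-het gene.
#' @param seed RNG seed.
#' @return list: `pileup` (long data.frame), `gene_map`
#'   (`contig`,`pos`,`gene_id`), `samples`.
#' @export
simulate_mutant_pileups <- function(sim, parent = "R35", depth_mean = 30,
                                    error_rate = 0.01, sites_per_gene = 4L,
                                    seed = 1L) with_seed(seed, {
  bases <- c("A", "C", "G", "T")
  truth <- sim$truth
  mutants <- truth$mutants
  samples <- c(parent, mutants)
  spans <- gene_spans(sim$gene_models)

  # tracked sites: implanted SNPs for het genes, random CDS sites otherwise
  site_rows <- list()
  if (nrow(truth$snps))
    site_rows[[1]] <- data.frame(contig = truth$snps$contig,
                                 pos = truth$snps$pos,
                                 gene_id = truth$snps$gene_id,
                                 ref = truth$snps$ref, alt = truth$snps$alt,
                                 het = TRUE, stringsAsFactors = FALSE)
  non_het <- setdiff(unique(spans$gene_id), truth$het_genes)
  cds <- sim$gene_models[sim$gene_models$type == "cds", , drop = FALSE]
  for (g in non_het) {
    d <- cds[cds$gene_id == g, , drop = FALSE]
    pool <- unlist(mapply(seq, d$start, d$end - 1L, SIMPLIFY = FALSE))
    pos <- sort(sample(pool, min(sites_per_gene, length(pool))))
    ref <- vapply(pos, function(p)
      substr0(sim$genome[[d$contig_id[1]]], p, p + 1L), character(1))
    site_rows[[length(site_rows) + 1L]] <-
      data.frame(contig = d$contig_id[1], pos = pos, gene_id = g,
                 ref = ref, alt = NA_character_, het = FALSE,
                 stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, site_rows)
  rownames(sites) <- NULL

  del1 <- truth$deleted$gene_id[truth$deleted$scenario == 1L]
  del2 <- truth$deleted$gene_id[truth$deleted$scenario == 2L]

  emit <- function(depth, true_counts) {
    # true_counts: named share over bases before sequencing error
    if (depth == 0L) return(setNames(rep(0L, 4L), bases))
    reads <- sample(bases, depth, replace = TRUE, prob = true_counts)
    err <- runif(depth) < error_rate
    if (any(err))
      reads[err] <- vapply(reads[err], function(b)
        sample(setdiff(bases, b), 1L), character(1))
    tab <- table(factor(reads, levels = bases))
    setNames(as.integer(tab), bases)
  }

  n_sites <- nrow(sites)
  out <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    s <- samples[si]
    is_mutant <- s %in% mutants
    counts <- matrix(0L, n_sites, 4L, dimnames = list(NULL, bases))
    for (i in seq_len(n_sites)) {
      g <- sites$gene_id[i]
      if (is_mutant && g %in% del2) next  # full loss: zero reads
      depth <- rpois(1L, depth_mean)
      prob <- setNames(rep(0, 4L), bases)
      if (sites$het[i] && !(is_mutant && g %in% del1)) {
        prob[sites$ref[i]] <- 0.5
        prob[sites$alt[i]] <- 0.5
      } else {
        prob[sites$ref[i]] <- 1  # retained allele only (or monomorphic)
      }
      counts[i, ] <- emit(depth, prob)
    }
    out[[si]] <- data.frame(contig = sites$contig, pos = sites$pos,
                            sample = s, counts, stringsAsFactors = FALSE)
  }
  pileup <- do.call(rbind, out)
  rownames(pileup) <- NULL
  list(pileup = pileup,
       gene_map = sites[, c("contig", "pos", "gene_id")],
       samples = samples)
})

#' Simulate an mRNA count matrix with implanted fold changes
#'
#' Counts are negative-binomial with gene-level means (log-uniform in
#' `mu_range`), a common dispersion (`variance = mu + dispersion * mu^2`;
#' dispersion 0 gives Poisson) and per-sample library-size multipliers.
#' `de_spec` lists true log2 fold changes with the package sign convention
#' log2(reference/comparison): the comparison group's mean is scaled by
#' `2^-log2fc`.
#'
#' @param gene_ids feature ids.
#' @param groups two group labels, reference first.
#' @param n_reps replicates per group (default 2, as in the study design).
#' @param mu_range range of gene mean expression.
#' @param dispersion common NB dispersion (>= 0).
#' @param de_spec data.frame `gene_id`, `log2fc` giving implanted effects
#'   (NULL or empty means all genes null).
#' @param lib_range range of library-size multipliers.
#' @param seed RNG seed.
#' @return list: `counts` (matrix), `truth` (`gene_id`, `true_log2fc`),
#'   `samples` (data.frame sample/group).
#' @export
simulate_counts <- function(gene_ids, groups = c("R35", "m115"),
                            n_reps = 2L, mu_range = c(20, 200),
                            dispersion = 0.1,
                            de_spec = NULL, lib_range = c(0.7, 1.3),
                            seed = 1L) with_seed(seed, {
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (length(groups) != 2L) stop("exactly two groups are supported")
  if (n_reps < 1L) stop("n_reps must be >= 1")
  ng <- length(gene_ids)
  mu <- exp(runif(ng, log(mu_range[1]), log(mu_range[2])))
  lfc <- setNames(rep(0, ng), gene_ids)
  if (!is.null(de_spec) && nrow(de_spec))
    lfc[de_spec$gene_id] <- de_spec$log2fc
  samples <- data.frame(
    sample = paste0(rep(groups, each = n_reps), "_r", seq_len(n_reps)),
    group = rep(groups, each = n_reps), stringsAsFactors = FALSE)
  libf <- runif(nrow(samples), lib_range[1], lib_range[2])
  counts <- matrix(0L, ng, nrow(samples),
                   dimnames = list(gene_ids, samples$sample))
  for (j in seq_len(nrow(samples))) {
    m <- mu * libf[j]
    if (samples$group[j] == groups[2]) m <- m * 2^(-lfc)
    counts[, j] <- as.integer(if (dispersion == 0) rpois(ng, m) else
      rnbinom(ng, size = 1 / dispersion, mu = m))
  }
  list(counts = counts,
       truth = data.frame(gene_id = gene_ids, true_log2fc = unname(lfc),
                          mu = mu, stringsAsFactors = FALSE),
       samples = samples)
})

#' Default small RNA length mixes
#'
#' Plant-style 21/24-nt bimodal mixes over 18-25 nt; the ovary profile
#' doubles the 22-nt proportion relative to leaf.
#'
#' @param type `"ovary"` or `"leaf"`.
#' @return named numeric vector over lengths 18-25 summing to 1.
#' @export
length_mix_default <- function(type = c("ovary", "leaf")) {
  type <- match.arg(type)
  mix <- if (type == "leaf")
    c(0.03, 0.04, 0.06, 0.25, 0.06, 0.07, 0.40, 0.09)
  else
    c(0.03, 0.04, 0.06, 0.24, 0.12, 0.07, 0.36, 0.08)
  setNames(mix, 18:25)
}

#' Simulate small RNA tag populations
#'
#' Per sample, `n_reads` reads are allocated to length bins by that
#' sample's `length_mix` row and distributed over distinct tag loci of the
#' matching length. Background tags are genome substrings at random
#' positions (perfect matches). Implanted miR/miR* tags join the 21-nt
#' pool; siRNA target genes contribute 24-nt tags tiling their CDS span
#' whose within-bin weight is multiplied by the truth fold change in
#' mutant-genotype samples.
#'
#' @param sim an `apo_sim` object.
#' @param sample_genotype named character vector mapping sample id to
#'   genotype label (parent label = anything not in `sim$truth$mutants`).
#' @param length_mix matrix samples x lengths 18-25 (rownames = sample
#'   ids); rows must each sum to 1.
#' @param n_reads reads per sample.
#' @param n_bg background tag loci.
#' @param seed RNG seed.
#' @return an `srna_tags` object; tag provenance in attribute `origin`
#'   (`background`/`mir`/`star`/`sirna`) and source gene in `origin_gene`.
#' @export
simulate_smallrna <- function(sim, sample_genotype,
                              length_mix = NULL, n_reads = 50000L,
                              n_bg = 2000L, seed = 1L) with_seed(seed, {
  samples <- names(sample_genotype)
  if (is.null(length_mix)) {
    length_mix <- do.call(rbind, lapply(samples, function(s)
      length_mix_default("ovary")))
    rownames(length_mix) <- samples
  }
  lens <- as.integer(colnames(length_mix) %||% 18:25)
  if (is.null(colnames(length_mix))) colnames(length_mix) <- lens
  if (is.null(rownames(length_mix)))
    stop("length_mix must have sample ids as rownames")
  if (any(abs(rowSums(length_mix) - 1) > 1e-8))
    stop("length_mix rows must sum to 1")

  genome <- sim$genome
  contig_len <- nchar(genome)
  # background loci: random genome substrings
  lens_bg <- sample(lens, n_bg, replace = TRUE,
                    prob = colMeans(length_mix))
  ct_bg <- sample(names(genome), n_bg, replace = TRUE)
  st_bg <- vapply(seq_len(n_bg), function(i)
    sample.int(contig_len[ct_bg[i]] - lens_bg[i], 1L) - 1L, numeric(1))
  strand_bg <- sample(c("+", "-"), n_bg, replace = TRUE)
  seq_bg <- vapply(seq_len(n_bg), function(i) {
    s <- substr0(genome[[ct_bg[i]]], st_bg[i], st_bg[i] + lens_bg[i])
    if (strand_bg[i] == "-") revcomp(s) else s
  }, character(1))
  tags <- data.frame(sequence = seq_bg, len = lens_bg,
                     origin = "background", gene = NA_character_,
                     weight = rexp(n_bg) + 0.05, stringsAsFactors = FALSE)

  ml <- sim$truth$mirna_loci
  if (nrow(ml)) {
    tags <- rbind(tags,
      data.frame(sequence = ml$mir_seq, len = 21L, origin = "mir",
                 gene = ml$locus_id, weight = 3, stringsAsFactors = FALSE),
      data.frame(sequence = ml$star_seq, len = 21L, origin = "star",
                 gene = ml$locus_id, weight = 1.5, stringsAsFactors = FALSE))
  }
  st <- sim$truth$sirna_targets
  if (nrow(st)) {
    cds <- sim$gene_models[sim$gene_models$type == "cds", , drop = FALSE]
    for (i in seq_len(nrow(st))) {
      d <- cds[cds$gene_id == st$gene_id[i], , drop = FALSE]
      lo <- min(d$start); hi <- max(d$end) - 24L
      starts <- seq(lo, hi, by = 30L)
      sq <- vapply(starts, function(p)
        substr0(genome[[d$contig_id[1]]], p, p + 24L), character(1))
      tags <- rbind(tags, data.frame(sequence = sq, len = 24L,
                                     origin = "sirna", gene = st$gene_id[i],
                                     weight = 1, stringsAsFactors = FALSE))
    }
  }
  tags <- tags[!duplicated(tags$sequence), , drop = FALSE]

  counts <- matrix(0L, nrow(tags), length(samples),
                   dimnames = list(NULL, samples))
  for (s in samples) {
    is_mut <- sample_genotype[[s]] %in% sim$truth$mutants
    w <- tags$weight
    if (is_mut && nrow(st)) {
      fold <- st$srna_fold[match(tags$gene, st$gene_id)]
      w <- ifelse(tags$origin == "sirna", w * fold, w)
    }
    for (li in seq_along(lens)) {
      idx <- which(tags$len == lens[li])
      n_l <- round(n_reads * length_mix[s, li])
      if (!length(idx) || n_l == 0) next
      counts[idx, s] <- counts[idx, s] +
        as.integer(rmultinom(1L, n_l, w[idx]))
    }
  }
  out <- srna_tags(tags$sequence, counts)
  attr(out, "origin") <- tags$origin
  attr(out, "origin_gene") <- tags$gene
  out
})

#' Simulate a qPCR Ct table
#'
#' Ct = baseline - log2(expression) + Gaussian noise; the reference gene
#' has equal expected expression in both groups, target genes have
#' expression 1 in the control group and the true fold in the test group.
#'
#' @param qpcr_truth named numeric vector of true fold changes
#'   (test/control) per target gene.
#' @param ref_gene reference gene id.
#' @param test_group,control_group group labels.
#' @param ct_noise_sd Gaussian Ct noise (cycles).
#' @param n_bio biological replicates per group (>= 2).
#' @param n_tech technical replicates per biological replicate.
#' @param seed RNG seed.
#' @return Ct records data.frame (`sample`, `gene`, `bio_rep`, `tech_rep`,
#'   `ct`).
#' @export
simulate_ct <- function(qpcr_truth, ref_gene = "UBC21",
                        test_group = "R35", control_group = "m115",
                        ct_noise_sd = 0.2, n_bio = 3L, n_tech = 2L,
                        seed = 1L) with_seed(seed, {
  if (any(qpcr_truth <= 0)) stop("true fold changes must be positive")
  if (n_bio < 2L) stop("need at least 2 biological replicates for a t-test")
  genes <- c(names(qpcr_truth), ref_gene)
  base <- setNames(runif(length(genes), 22, 30), genes)
  grid <- expand.grid(sample = c(test_group, control_group),
                      gene = genes, bio_rep = seq_len(n_bio),
                      tech_rep = seq_len(n_tech),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  expr <- ifelse(grid$gene == ref_gene, 1,
                 ifelse(grid$sample == test_group,
                        qpcr_truth[grid$gene], 1))
  grid$ct <- base[grid$gene] - log2(expr) +
    rnorm(nrow(grid), 0, ct_noise_sd)
  grid[order(grid$sample, grid$gene, grid$bio_rep, grid$tech_rep), ,
       drop = FALSE]
})
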