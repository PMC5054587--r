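## Core domain containers and format I/O.
##
## Internal conventions, used uniformly by every stage:
##   * coordinates are 0-based half-open intervals [start, end)
##   * GFF3 (1-based inclusive) and SAM (1-based POS) are converted at the
##     boundary and restored on export
##   * genome = named character vector of contig sequences over A/C/G/T/N
##   * gene models = data.frame of typed intervals, one row per CDS/UTR block

#' Read a genome FASTA into a named character vector of contigs
#'
#' @param path FASTA file.
#' @return Named character vector; names are contig ids.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate contig ids in ", path)
  if (any(Biostrings::width(ss) < 1)) stop("zero-length contig in ", path)
  setNames(as.character(ss), ids)
}

#' Write a genome to FASTA
#'
#' @param genome named character vector of contig sequences.
#' @param path output FASTA path.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Load gene models from GFF3
#'
#' One gene model per mRNA feature; CDS, five_prime_UTR and three_prime_UTR
#' children are collected by their Parent attribute. GFF3 1-based inclusive
#' coordinates are converted to internal 0-based half-open.
#'
#' @param path GFF3 file.
#' @param contig_lengths optional named integer vector used to validate that
#'   every interval lies within its contig.
#' @return A `gene_models` data.frame with columns `gene_id`, `contig_id`,
#'   `strand`, `type` (one of `cds`, `utr5`, `utr3`), `start`, `end`.
#' @export
load_gene_models <- function(path, contig_lengths = NULL) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("GFF3 parse error in ", path, ": ",
                                          conditionMessage(e)))
  keep <- as.character(gr$type) %in%
    c("CDS", "five_prime_UTR", "three_prime_UTR")
  gr <- gr[keep]
  if (!length(gr)) stop("no CDS/UTR features in ", path)
  parent <- vapply(gr$Parent, function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  if (anyNA(parent)) stop("CDS/UTR feature without Parent in ", path)
  type_map <- c(CDS = "cds", five_prime_UTR = "utr5",
                three_prime_UTR = "utr3")
  gm <- data.frame(
    gene_id = parent,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    type = unname(type_map[as.character(gr$type)]),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  gm <- gm[order(gm$gene_id, gm$start, gm$end), , drop = FALSE]
  rownames(gm) <- NULL
  validate_gene_models(gm, contig_lengths)
  class(gm) <- c("gene_models", "data.frame")
  gm
}

validate_gene_models <- function(gm, contig_lengths = NULL) {
  if (any(gm$end <= gm$start)) stop("empty or inverted gene model interval")
  if (!all(gm$strand %in% c("+", "-"))) stop("gene model strand must be +/-")
  by_gene <- split(seq_len(nrow(gm)), gm$gene_id)
  for (idx in by_gene) {
    if (length(unique(gm$contig_id[idx])) != 1L)
      stop("gene ", gm$gene_id[idx[1]], " spans multiple contigs")
    if (length(unique(gm$strand[idx])) != 1L)
      stop("gene ", gm$gene_id[idx[1]], " has mixed strands")
    s <- gm$start[idx]; e <- gm$end[idx]
    o <- order(s)
    if (any(e[o][-length(o)] > s[o][-1]))
      stop("overlapping intervals in gene ", gm$gene_id[idx[1]])
  }
  if (!is.null(contig_lengths)) {
    len <- contig_lengths[gm$contig_id]
    if (anyNA(len)) stop("gene model on unknown contig")
    if (any(gm$start < 0 | gm$end > len))
      stop("gene model interval outside contig bounds")
  }
  invisible(gm)
}

#' Write gene models to canonical GFF3
#'
#' Emits one mRNA row per gene followed by its CDS/UTR rows, restoring the
#' GFF3 1-based inclusive convention. `write_gene_models(load_gene_models(f))`
#' reproduces a canonical file byte-for-byte.
#'
#' @param gm a `gene_models` data.frame.
#' @param path output path.
#' @export
write_gene_models <- function(gm, path) {
  type_map <- c(cds = "CDS", utr5 = "five_prime_UTR",
                utr3 = "three_prime_UTR")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  spans <- gene_spans(gm)
  spans <- spans[order(spans$gene_id), , drop = FALSE]
  for (i in seq_len(nrow(spans))) {
    g <- spans$gene_id[i]
    writeLines(sprintf("%s\taposeq\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s",
                       spans$contig_id[i], spans$start[i] + 1L, spans$end[i],
                       spans$strand[i], g), con)
    sub <- gm[gm$gene_id == g, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    writeLines(sprintf("%s\taposeq\t%s\t%d\t%d\t.\t%s\t.\tParent=%s",
                       sub$contig_id, type_map[sub$type], sub$start + 1L,
                       sub$end, sub$strand, g), con)
  }
  invisible(path)
}

#' Gene spans
#'
#' The span of a gene is the smallest interval covering all of its CDS and
#' UTR blocks.
#'
#' @param gm a `gene_models` data.frame.
#' @return data.frame with one row per gene: `gene_id`, `contig_id`,
#'   `strand`, `start`, `end`.
#' @export
gene_spans <- function(gm) {
  sp <- do.call(rbind, lapply(split(gm, gm$gene_id), function(d)
    data.frame(gene_id = d$gene_id[1], contig_id = d$contig_id[1],
               strand = d$strand[1], start = min(d$start), end = max(d$end),
               stringsAsFactors = FALSE)))
  rownames(sp) <- NULL
  sp
}

#' Intron intervals of each gene
#'
#' Introns are the gaps between consecutive CDS blocks.
#'
#' @param gm a `gene_models` data.frame.
#' @return data.frame `gene_id`, `contig_id`, `strand`, `start`, `end`
#'   (possibly zero rows).
#' @export
intron_intervals <- function(gm) {
  out <- lapply(split(gm[gm$type == "cds", , drop = FALSE],
                      gm$gene_id[gm$type == "cds"]), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) < 2L) return(NULL)
    data.frame(gene_id = d$gene_id[1], contig_id = d$contig_id[1],
               strand = d$strand[1], start = d$end[-nrow(d)],
               end = d$start[-1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene_id = character(), contig_id = character(),
                      strand = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Extended genic regions
#'
#' Each gene span widened by `flank` bp on each side, clipped to the contig.
#'
#' @param gm a `gene_models` data.frame.
#' @param contig_lengths named integer vector of contig lengths.
#' @param flank flank width in bp (default 500).
#' @return data.frame `gene_id`, `contig_id`, `strand`, `start`, `end`.
#' @export
extended_regions <- function(gm, contig_lengths, flank = 500L) {
  sp <- gene_spans(gm)
  len <- contig_lengths[sp$contig_id]
  if (anyNA(len)) stop("gene on contig absent from contig_lengths")
  sp$start <- pmax(0L, sp$start - as.integer(flank))
  sp$end <- pmin(as.integer(len), sp$end + as.integer(flank))
  sp
}

## ---- pileups --------------------------------------------------------------

pileup_template <- function() {
  data.frame(contig = character(), pos = integer(), sample = character(),
             A = integer(), C = integer(), G = integer(), T = integer(),
             stringsAsFactors = FALSE)
}

#' Load a per-site allele-count pileup from TSV
#'
#' Columns: `contig`, `pos` (0-based), `sample`, `A`, `C`, `G`, `T`.
#'
#' @param path TSV file with header.
#' @param samples optional character vector of expected sample ids; an
#'   unknown id in the file is an error listing the known ids.
#' @return pileup data.frame.
#' @export
load_pileup <- function(path, samples = NULL) {
  p <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("contig", "pos", "sample", "A", "C", "G", "T")
  if (!all(need %in% names(p)))
    stop("pileup TSV must have columns ", paste(need, collapse = ", "))
  p <- p[, need]
  if (!is.null(samples)) {
    bad <- setdiff(unique(p$sample), samples)
    if (length(bad))
      stop("unknown sample id(s) ", paste(bad, collapse = ", "),
           "; known samples: ", paste(samples, collapse = ", "))
  }
  if (any(p[, c("A", "C", "G", "T")] < 0)) stop("negative allele count")
  p$pos <- as.integer(p$pos)
  p
}

#' Write a pileup to TSV
#'
#' @param pileup pileup data.frame.
#' @param path output path.
#' @export
write_pileup <- function(pileup, path) {
  write.table(pileup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive a per-site allele-count pileup from a plain-text SAM file
#'
#' Reads the minimal SAM columns (FLAG, RNAME, POS, CIGAR, SEQ) and counts
#' the aligned base at every reference position covered by an M/=/X CIGAR
#' operation. Insertions and soft clips consume query only; deletions and
#' skips consume reference only. SAM POS (1-based) is converted to internal
#' 0-based coordinates.
#'
#' @param path SAM file.
#' @param sample sample id to assign to all reads in the file.
#' @return pileup data.frame (same schema as [load_pileup()]).
#' @export
load_pileup_sam <- function(path, sample) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  counts <- new.env(parent = emptyenv())
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 10)
      stop("malformed SAM line (fewer than 10 fields): ", substr(ln, 1, 60))
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0L) next  # unmapped
    rname <- f[3]; pos0 <- as.integer(f[4]) - 1L
    cigar <- f[6]; seq <- f[10]
    ops <- gregexpr("(\\d+)([MIDNSHP=X])", cigar)[[1]]
    if (ops[1] == -1) next
    lens <- as.integer(regmatches(cigar, gregexpr("\\d+", cigar))[[1]])
    chars <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
    rp <- pos0; qp <- 0L
    for (k in seq_along(chars)) {
      op <- chars[k]; l <- lens[k]
      if (op %in% c("M", "=", "X")) {
        for (j in seq_len(l)) {
          base <- substr(seq, qp + j, qp + j)
          if (base %in% c("A", "C", "G", "T")) {
            key <- paste(rname, rp + j - 1L, base, sep = "\r")
            counts[[key]] <- (counts[[key]] %||% 0L) + 1L
          }
        }
        rp <- rp + l; qp <- qp + l
      } else if (op %in% c("I", "S")) {
        qp <- qp + l
      } else if (op %in% c("D", "N")) {
        rp <- rp + l
      }  # H, P consume nothing we track
    }
  }
  keys <- ls(counts)
  if (!length(keys)) return(pileup_template())
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  df <- data.frame(contig = parts[, 1], pos = as.integer(parts[, 2]),
                   base = parts[, 3],
                   n = vapply(keys, function(k) counts[[k]], integer(1)),
                   stringsAsFactors = FALSE)
  wide <- pileup_template()
  for (site in split(df, paste(df$contig, df$pos))) {
    row <- data.frame(contig = site$contig[1], pos = site$pos[1],
                      sample = sample, A = 0L, C = 0L, G = 0L, T = 0L,
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(site))) row[[site$base[i]]] <- site$n[i]
    wide <- rbind(wide, row)
  }
  wide <- wide[order(wide$contig, wide$pos), , drop = FALSE]
  rownames(wide) <- NULL
  wide
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- small RNA tags -------------------------------------------------------

#' Construct a small RNA tag set
#'
#' @param sequence character vector of distinct tag sequences (A/C/G/T).
#' @param counts integer matrix, tags x samples, column names = sample ids.
#' @return An `srna_tags` object.
#' @export
srna_tags <- function(sequence, counts) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (length(sequence) != nrow(counts))
    stop("sequence/counts dimension mismatch")
  if (anyDuplicated(sequence)) stop("duplicate tag sequences")
  if (any(counts < 0)) stop("negative tag counts")
  if (is.null(colnames(counts))) stop("counts must have sample column names")
  structure(list(sequence = as.character(sequence), counts = counts),
            class = "srna_tags")
}

#' @export
print.srna_tags <- function(x, ...) {
  cat(sprintf("srna_tags: %d distinct tags x %d samples, %d reads total\n",
              length(x$sequence), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Load small RNA tags from per-sample FASTA files
#'
#' Headers carry read counts as `id_count=N`. Identical sequences across
#' samples are merged into one tag with a per-sample count vector; within a
#' file, counts of identical sequences are summed. U is normalised to T.
#'
#' @param paths named character vector of FASTA paths; names are sample ids.
#' @return An `srna_tags` object.
#' @export
load_tags <- function(paths) {
  if (is.null(names(paths)) || any(names(paths) == ""))
    stop("'paths' must be named by sample id")
  per <- lapply(paths, function(p) {
    ss <- Biostrings::readBStringSet(p)
    seqs <- toupper(as.character(ss))
    seqs <- chartr("U", "T", seqs)
    if (any(grepl("[^ACGT]", seqs)))
      stop("non-nucleotide character in tag FASTA ", p)
    m <- regmatches(names(ss), regexpr("_count=\\d+$", names(ss)))
    if (length(m) != length(ss))
      stop("tag FASTA header without _count=N suffix in ", p)
    n <- as.integer(sub("_count=", "", m))
    tapply(n, seqs, sum)
  })
  all_seq <- sort(unique(unlist(lapply(per, names))))
  counts <- matrix(0L, length(all_seq), length(paths),
                   dimnames = list(NULL, names(paths)))
  for (s in names(paths)) {
    v <- per[[s]]
    counts[match(names(v), all_seq), s] <- as.integer(v)
  }
  srna_tags(all_seq, counts)
}

#' Write small RNA tags to per-sample FASTA files
#'
#' @param tags an `srna_tags` object.
#' @param dir output directory; one `<sample>.fa` per sample, zero-count
#'   tags omitted.
#' @return named vector of written paths.
#' @export
write_tags <- function(tags, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- character(0)
  for (s in colnames(tags$counts)) {
    keep <- tags$counts[, s] > 0L
    path <- file.path(dir, paste0(s, ".fa"))
    ids <- sprintf("tag%06d_count=%d", which(keep), tags$counts[keep, s])
    writeLines(paste0(">", ids, "\n", tags$sequence[keep]), path)
    out[s] <- path
  }
  out
}

## ---- count matrices, annotation, Ct tables --------------------------------

#' Load a feature x sample count matrix from TSV
#'
#' @param path TSV; first column `feature`, remaining columns samples.
#' @return integer matrix with feature rownames.
#' @export
load_count_matrix <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- d[[1]]
  if (any(m < 0)) stop("negative counts in ", path)
  m
}

#' Write a count matrix to TSV
#'
#' @param counts integer matrix with feature rownames.
#' @param path output path.
#' @export
write_count_matrix <- function(counts, path) {
  d <- data.frame(feature = rownames(counts), counts, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load an ortholog/GO annotation map from TSV
#'
#' Columns `gene`, `ortholog`, `go_terms` (comma-separated term ids; may be
#' empty).
#'
#' @param path TSV file.
#' @return data.frame `gene`, `ortholog`, `go_terms` (list column).
#' @export
load_annotation_map <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene", "ortholog", "go_terms")
  if (!all(need %in% names(d)))
    stop("annotation map needs columns ", paste(need, collapse = ", "))
  d$go_terms <- lapply(strsplit(d$go_terms, ",", fixed = TRUE),
                       function(x) x[nzchar(x)])
  d
}

#' Load a qPCR Ct table from CSV
#'
#' Columns `sample` (group label, e.g. genotype), `gene`, `bio_rep`,
#' `tech_rep`, `ct`.
#'
#' @param path CSV file.
#' @return data.frame of Ct records.
#' @export
load_ct <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "gene", "bio_rep", "tech_rep", "ct")
  if (!all(need %in% names(d)))
    stop("Ct table needs columns ", paste(need, collapse = ", "))
  if (any(d$ct <= 0)) stop("Ct values must be positive")
  d
}

#' Load a mature miRNA reference set from FASTA
#'
#' @param path FASTA of mature miRNA sequences (RNA or DNA alphabet).
#' @return named character vector, U normalised to T.
#' @export
load_mature_mirnas <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- chartr("U", "T", toupper(as.character(ss)))
  setNames(seqs, sub("\\s.*$", "", names(ss)))
}
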