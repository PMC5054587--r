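## Relative qPCR quantification by the delta-delta-Ct method.
##
## Technical replicates are averaged first; biological replicates carry the
## statistics. Sign convention: log2fc = log2(test / control) expression,
## i.e. deltaCt_control - deltaCt_test.

#' Delta-delta-Ct log2 fold change for one target gene
#'
#' Per (group, biological replicate): technical replicate Ct values are
#' averaged, then deltaCt = Ct_target - Ct_reference. Per replicate pair
#' (matched by biological replicate index), log2fc = deltaCt_control -
#' deltaCt_test; the average and SD over replicates are reported together
#' with a t-test on the replicate deltaCt values.
#'
#' @param records Ct data.frame (see [load_ct()]): `sample` (group label),
#'   `gene`, `bio_rep`, `tech_rep`, `ct`.
#' @param target_gene gene to quantify.
#' @param ref_gene reference gene (must be measured in every group and
#'   biological replicate).
#' @param test_group,control_group group labels in `sample`.
#' @param paired use a paired t-test on replicate deltaCt values
#'   (default FALSE: unpaired).
#' @return one-row data.frame: `gene_id`, `avg_log2fc`, `sd`, `t_p`,
#'   `n_reps`, plus per-replicate deltaCt attributes `dct_test`,
#'   `dct_control`.
#' @export
ddct_logfc <- function(records, target_gene, ref_gene, test_group,
                       control_group, paired = FALSE) {
  dct <- lapply(c(test = test_group, control = control_group), function(g) {
    sub <- records[records$sample == g, , drop = FALSE]
    tgt <- sub[sub$gene == target_gene, , drop = FALSE]
    ref <- sub[sub$gene == ref_gene, , drop = FALSE]
    if (!nrow(ref))
      stop("reference gene '", ref_gene, "' missing for group '", g, "'")
    if (!nrow(tgt))
      stop("target gene '", target_gene, "' missing for group '", g, "'")
    t_ct <- tapply(tgt$ct, tgt$bio_rep, mean)   # average technical reps
    r_ct <- tapply(ref$ct, ref$bio_rep, mean)
    reps <- intersect(names(t_ct), names(r_ct))
    if (length(reps) < length(t_ct) || length(reps) < length(r_ct))
      stop("reference gene '", ref_gene,
           "' not measured in every biological replicate of group '", g, "'")
    setNames(t_ct[reps] - r_ct[reps], reps)
  })
  dt <- dct$test; dc <- dct$control
  if (length(dt) < 2 || length(dc) < 2)
    stop("need at least two biological replicates per group")
  if (paired) {
    reps <- intersect(names(dt), names(dc))
    per_rep <- dc[reps] - dt[reps]
    avg <- mean(per_rep); s <- sd(per_rep)
  } else {
    avg <- mean(dc) - mean(dt)
    per_rep <- NULL
    # SD of the replicate-pair fold changes (matched by replicate index
    # where possible, the reported spread of the study's tables)
    reps <- intersect(names(dt), names(dc))
    s <- if (length(reps) >= 2) sd(dc[reps] - dt[reps]) else NA_real_
  }
  tt <- tryCatch(t.test(dc, dt, paired = paired), error = function(e) {
    # noise-free data: zero within-group variance, decide by the means
    list(p.value = if (isTRUE(all.equal(mean(dc), mean(dt)))) 1 else 0)
  })
  out <- data.frame(gene_id = target_gene, avg_log2fc = unname(avg),
                    sd = unname(s), t_p = tt$p.value,
                    n_reps = length(dt), stringsAsFactors = FALSE)
  attr(out, "dct_test") <- dt
  attr(out, "dct_control") <- dc
  out
}

#' Apply the qPCR significance rule
#'
#' A gene is called differentially expressed when its absolute fold change
#' exceeds `qpcr_fc_min` (strictly, i.e. |avg_log2fc| > log2(1.5) at the
#' default) and the replicate-level t-test p-value is below `qpcr_alpha`.
#'
#' @param result one-row data.frame from [ddct_logfc()].
#' @param config an [apo_config()].
#' @return `result` with logical column `significant`.
#' @export
call_significant <- function(result, config = NULL) {
  config <- as_config(config)
  if (result$n_reps < 2) stop("need at least two biological replicates")
  result$significant <- 2^abs(result$avg_log2fc) > config$qpcr_fc_min &
    result$t_p < config$qpcr_alpha
  result
}

#' Delta-delta-Ct analysis of every target gene in a Ct table
#'
#' @inheritParams ddct_logfc
#' @param config an [apo_config()].
#' @return data.frame, one row per target gene, with `significant` flags.
#' @export
qpcr_analyze <- function(records, ref_gene, test_group, control_group,
                         config = NULL, paired = FALSE) {
  config <- as_config(config)
  genes <- setdiff(unique(records$gene), ref_gene)
  out <- do.call(rbind, lapply(genes, function(g)
    call_significant(ddct_logfc(records, g, ref_gene, test_group,
                                control_group, paired = paired), config)))
  rownames(out) <- NULL
  out
}
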