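## Count normalisation and two-group differential calling.
##
## TMM scaling, the conditional negative-binomial exact test and the BH
## step-up are authored here; the package-wide sign convention is
## log2(reference group / comparison group).

#' TMM normalisation factors
#'
#' Trimmed mean of M-values: per-gene log-ratios (M) against a reference
#' sample are doubly trimmed on M (`trim_m` total) and average log
#' abundance A (`trim_a` total), then averaged with inverse asymptotic
#' variance weights. Factors are rescaled so their geometric mean is 1.
#'
#' @param counts non-negative feature x sample matrix.
#' @param ref_sample reference column (name or index); when `NULL`, the
#'   sample whose upper-quartile scaled count is closest to the mean of all
#'   samples' is used.
#' @param trim_m total trim fraction on M values (default 0.30).
#' @param trim_a total trim fraction on A values (default 0.05).
#' @return list of class `norm_factors`: `factors` (named, geometric mean
#'   1), `lib_sizes`, `ref_sample`.
#' @export
tmm_factors <- function(counts, ref_sample = NULL, trim_m = 0.30,
                        trim_a = 0.05) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (any(lib == 0)) stop("all-zero sample in count matrix")
  if (is.null(ref_sample)) {
    uq <- apply(counts, 2, function(x) quantile(x, 0.75)) / lib
    ref_idx <- unname(which.min(abs(uq - mean(uq))))
  } else if (is.character(ref_sample)) {
    ref_idx <- match(ref_sample, colnames(counts))
    if (is.na(ref_idx)) stop("unknown ref_sample '", ref_sample, "'")
  } else ref_idx <- as.integer(ref_sample)
  ref <- counts[, ref_idx]
  nR <- lib[ref_idx]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j]; nO <- lib[j]
    if (j == ref_idx || all(obs == ref)) return(1)
    keep <- obs > 0 & ref > 0
    o <- obs[keep]; r <- ref[keep]
    M <- log2((o / nO) / (r / nR))
    A <- (log2(o / nO) + log2(r / nR)) / 2
    v <- (nO - o) / (nO * o) + (nR - r) / (nR * r)
    n <- length(M)
    if (!n) return(1)
    # trim fractions apply per tail (the TMM convention)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    rM <- rank(M, ties.method = "first")
    rA <- rank(A, ties.method = "first")
    sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(sel)) return(1)
    fbar <- sum(M[sel] / v[sel]) / sum(1 / v[sel])
    if (!is.finite(fbar) || abs(fbar) < 1e-10) return(1)
    2^fbar
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  structure(list(factors = setNames(f, colnames(counts)), lib_sizes = lib,
                 ref_sample = ref_idx), class = "norm_factors")
}

#' Method-of-moments common dispersion estimate
#'
#' Per feature and group, the moment estimate `(s2 - m) / m^2` of the NB
#' dispersion (`variance = mean + dispersion * mean^2`) is computed on
#' effective-library-size scaled counts; the common dispersion is the mean
#' over all (feature, group) estimates with mean count of at least 10.
#' Individual estimates are extremely noisy with few replicates, but for
#' well-expressed features their sampling variance is nearly constant, so
#' the unweighted mean combines them stably and almost without bias.
#'
#' @param counts feature x sample matrix.
#' @param groups list of two character/integer vectors of columns.
#' @param eff_lib effective library sizes (lib size x TMM factor).
#' @return non-negative scalar dispersion.
#' @export
estimate_dispersion_mom <- function(counts, groups, eff_lib) {
  scale_to <- exp(mean(log(eff_lib)))
  norm <- sweep(as.matrix(counts), 2, eff_lib / scale_to, "/")
  ests <- numeric(0)
  for (g in groups) {
    if (length(g) < 2) next
    x <- norm[, g, drop = FALSE]
    m <- rowMeans(x)
    s2 <- apply(x, 1, var)
    keep <- m >= 10
    ests <- c(ests, (s2[keep] - m[keep]) / m[keep]^2)
  }
  if (!length(ests)) return(0)
  max(0, mean(ests))
}

#' Conditional negative-binomial exact test
#'
#' For each feature the group sums `a` and `b` (on counts already rescaled
#' to a common effective library size) are compared under a shared-mean NB
#' model with the given dispersion (`variance = mu + dispersion * mu^2`).
#' The two-sided p-value sums, over the conditional distribution of the
#' group-A sum given the total, all outcomes no more probable than the one
#' observed. At dispersion 0 this is the exact binomial split.
#'
#' @param countsA,countsB feature x replicate matrices (or vectors) of
#'   equalised counts.
#' @param dispersion common NB dispersion (>= 0).
#' @return numeric vector of p-values, one per feature.
#' @export
nb_exact_test <- function(countsA, countsB, dispersion = 0.1) {
  countsA <- as.matrix(countsA); countsB <- as.matrix(countsB)
  if (any(countsA < 0) || any(countsB < 0)) stop("negative counts")
  if (dispersion < 0) stop("dispersion must be >= 0")
  nA <- ncol(countsA); nB <- ncol(countsB)
  sumA <- round(rowSums(countsA)); sumB <- round(rowSums(countsB))
  vapply(seq_along(sumA), function(i) {
    exact_p_one(sumA[i], sumB[i], nA, nB, dispersion)
  }, numeric(1))
}

exact_p_one <- function(a, b, nA, nB, phi) {
  t <- a + b
  if (t == 0) return(1)
  x <- 0:t
  if (phi == 0) {
    logp <- dbinom(x, t, nA / (nA + nB), log = TRUE)
  } else {
    mu <- t / (nA + nB)
    logp <- dnbinom(x, size = nA / phi, mu = nA * mu, log = TRUE) +
      dnbinom(t - x, size = nB / phi, mu = nB * mu, log = TRUE)
    logp <- logp - log(sum(exp(logp - max(logp)))) - max(logp)
  }
  p_obs <- logp[a + 1]
  min(1, sum(exp(logp[logp <= p_obs + 1e-8])))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorted p-values are multiplied by n/rank, a running minimum is enforced
#' from the largest rank down, results are capped at 1 and returned in the
#' original order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  n <- length(p)
  if (n == 0) return(numeric(0))
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

#' Flag differential features
#'
#' mRNA mode flags features with BH-adjusted p at most `de_alpha` and
#' absolute log2 fold change at least `log2(fc_min)` (both boundaries
#' inclusive). sRNA mode (single replicates, no test) flags on fold change
#' alone: |log2((a+1)/(b+1))| strictly greater than `log2(fc_min)` on
#' normalised counts with pseudocount 1.
#'
#' @param results data.frame with `log2fc` and (mRNA mode) `p_adj`.
#' @param config an [apo_config()].
#' @param mode `"mrna"` or `"srna"`.
#' @return `results` with logical column `is_differential`.
#' @export
call_differential <- function(results, config = NULL,
                              mode = c("mrna", "srna")) {
  config <- as_config(config)
  mode <- match.arg(mode)
  lfc_min <- log2(config$fc_min)
  if (mode == "mrna") {
    results$is_differential <- results$p_adj <= config$de_alpha &
      abs(results$log2fc) >= lfc_min
  } else {
    results$is_differential <- abs(results$log2fc) > lfc_min
  }
  results
}

#' Two-group differential expression analysis
#'
#' TMM-normalises, equalises counts to a common effective library size,
#' estimates a common dispersion by method of moments when both groups have
#' replicates (a fixed default otherwise), runs the conditional NB exact
#' test, BH-adjusts, and flags by the study thresholds. `log2fc` is
#' log2(reference/comparison) of normalised group means (pseudocount 0.5
#' per mean; pseudocount 1 in sRNA mode).
#'
#' @param counts feature x sample count matrix.
#' @param ref_samples,cmp_samples column names of the reference and
#'   comparison groups.
#' @param config an [apo_config()].
#' @param mode `"mrna"` (exact test + fold) or `"srna"` (fold only).
#' @param dispersion optional fixed dispersion overriding estimation.
#' @return data.frame of class `de_result`: `feature_id`, `log2fc`, `p`,
#'   `p_adj`, `is_differential`; the TMM factors and dispersion used are
#'   attached as attributes.
#' @export
de_test <- function(counts, ref_samples, cmp_samples, config = NULL,
                    mode = c("mrna", "srna"), dispersion = NULL) {
  config <- as_config(config)
  mode <- match.arg(mode)
  counts <- as.matrix(counts[, c(ref_samples, cmp_samples), drop = FALSE])
  nf <- tmm_factors(counts)
  eff <- nf$lib_sizes * nf$factors
  common <- exp(mean(log(eff)))
  eq <- sweep(counts, 2, common / eff, "*")
  A <- eq[, ref_samples, drop = FALSE]
  B <- eq[, cmp_samples, drop = FALSE]
  pc <- if (mode == "srna") 1 else 0.5
  log2fc <- log2((rowMeans(A) + pc) / (rowMeans(B) + pc))
  if (mode == "mrna") {
    if (is.null(dispersion)) {
      dispersion <- if (length(ref_samples) > 1 || length(cmp_samples) > 1)
        estimate_dispersion_mom(counts, list(ref_samples, cmp_samples), eff)
      else 0.1
    }
    p <- nb_exact_test(round(A), round(B), dispersion)
    p_adj <- adjust_bh(p)
  } else {
    if (is.null(dispersion)) dispersion <- 0.1
    p <- rep(NA_real_, nrow(counts))
    p_adj <- rep(NA_real_, nrow(counts))
  }
  res <- data.frame(feature_id = rownames(counts), log2fc = log2fc,
                    p = p, p_adj = p_adj, stringsAsFactors = FALSE)
  res <- call_differential(res, config, mode)
  rownames(res) <- NULL
  attr(res, "norm_factors") <- nf
  attr(res, "dispersion") <- dispersion
  class(res) <- c("de_result", "data.frame")
  res
}
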