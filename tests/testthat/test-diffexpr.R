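test_that("TMM factors are unit for identical and scaled libraries", {
  set.seed(3)
  base <- rnbinom(300, size = 5, mu = 50) + 1L
  m <- cbind(a = base, b = base)
  expect_equal(unname(tmm_factors(m)$factors), c(1, 1))
  m2 <- cbind(a = base, b = 2L * base)
  expect_equal(unname(tmm_factors(m2)$factors), c(1, 1))
  expect_error(tmm_factors(cbind(a = base, b = 0L * base)), "all-zero")
})

test_that("a spiked gene is trimmed and the factor matches a hand formula", {
  set.seed(4)
  base <- rep(100L, 20)
  spiked <- base; spiked[1] <- 10000L
  m <- cbind(ref = base, obs = spiked)
  f <- tmm_factors(m, ref_sample = "ref")$factors
  # hand evaluation: after trimming on M, the spiked gene is excluded and
  # the surviving genes share M = log2((100/11900)/(100/2000)), a pure
  # library-size artefact, so the weighted mean equals that M exactly
  nO <- sum(spiked); nR <- sum(base)
  M <- log2((100 / nO) / (100 / nR))
  expected_obs <- 2^M
  # factors are rescaled to geometric mean 1
  expected <- c(ref = 1, obs = expected_obs) /
    exp(mean(log(c(1, expected_obs))))
  expect_equal(f, expected, tolerance = 1e-10)
})

test_that("TMM agrees with an independent reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(42)
  mu <- exp(runif(1500, log(5), log(500)))
  m <- matrix(rnbinom(1500 * 4, size = 10, mu = rep(mu, 4)), 1500, 4)
  colnames(m) <- paste0("s", 1:4)
  m[1:40, 2] <- m[1:40, 2] * 25L
  f1 <- tmm_factors(m)$factors
  f2 <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(unname(f1), unname(f2), tolerance = 0.002)
})

test_that("exact test is symmetric under equal sums and handles zero", {
  expect_equal(nb_exact_test(matrix(c(20, 20), 1, 2),
                             matrix(c(20, 20), 1, 2), 0.1), 1)
  expect_equal(nb_exact_test(matrix(0, 1, 2), matrix(0, 1, 2), 0.1), 1)
})

test_that("dispersion-0 p-values equal exhaustive binomial enumeration", {
  binom_oracle <- function(a, t, pr) {
    pm <- dbinom(0:t, t, pr)
    sum(pm[pm <= pm[a + 1] * (1 + 1e-8)])
  }
  for (tot in c(5, 12, 30)) {
    for (a in 0:tot) {
      p <- nb_exact_test(matrix(c(a, 0), 1, 2), matrix(c(tot - a, 0), 1, 2),
                         0)
      expect_equal(p, binom_oracle(a, tot, 0.5), tolerance = 1e-12,
                   info = paste(a, tot))
    }
  }
  # unequal group sizes shift the binomial split probability
  p <- nb_exact_test(matrix(c(4, 3, 3), 1, 3), matrix(10, 1, 1), 0)
  expect_equal(p, {
    pm <- dbinom(0:20, 20, 3 / 4)
    sum(pm[pm <= pm[11] * (1 + 1e-8)])
  })
})

test_that("BH adjustment matches hand computation and p.adjust", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(adjust_bh(0.7), 0.7)
  expect_equal(adjust_bh(numeric(0)), numeric(0))
  set.seed(6)
  for (i in 1:5) {
    p <- runif(200)^sample(1:3, 1)
    expect_equal(adjust_bh(p), p.adjust(p, "BH"))
    expect_true(all(adjust_bh(p) >= p))
  }
  expect_error(adjust_bh(c(0.5, 1.2)), "outside")
})

test_that("differential flags apply inclusive boundaries per mode", {
  res <- data.frame(feature_id = c("a", "b", "c", "d"),
                    log2fc = c(1.0, 0.9, -1.2, 3),
                    p_adj = c(0.01, 0.001, 0.009, 0.2))
  out <- call_differential(res, mode = "mrna")
  expect_equal(out$is_differential, c(TRUE, FALSE, TRUE, FALSE))
  # sRNA mode: pseudocount-1 fold only, strict inequality
  r2 <- data.frame(feature_id = c("x", "y"),
                   log2fc = c(log2(31 / 11), 1.0))
  out2 <- call_differential(r2, mode = "srna")
  expect_equal(out2$is_differential, c(TRUE, FALSE))
})

test_that("sRNA fold mode computes pseudocount-1 fold changes", {
  counts <- matrix(c(30L, 10L), 1, 2,
                   dimnames = list("g1", c("a", "b")))
  # equal library sizes: no normalisation shift beyond TMM=1
  counts <- rbind(counts,
                  matrix(rep(50L, 40), 20, 2,
                         dimnames = list(paste0("bg", 1:20), c("a", "b"))))
  de <- de_test(counts, "a", "b", mode = "srna")
  g1 <- de[de$feature_id == "g1", ]
  expect_equal(g1$log2fc, log2(31 / 11), tolerance = 0.05)
  expect_true(g1$is_differential)
})

test_that("flags are invariant to global library rescaling", {
  sim <- simulate_counts(paste0("g", 1:300), n_reps = 2,
                         mu_range = c(50, 500), dispersion = 0.1,
                         de_spec = data.frame(gene_id = paste0("g", 1:30),
                                              log2fc = rep(c(2, -2), 15)),
                         seed = 91)
  ref <- sim$samples$sample[sim$samples$group == "R35"]
  cmp <- sim$samples$sample[sim$samples$group == "m115"]
  d1 <- de_test(sim$counts, ref, cmp, dispersion = 0.1)
  d2 <- de_test(sim$counts * 3L, ref, cmp, dispersion = 0.1)
  # invariance holds up to pseudocount and count-rounding discreteness:
  # genes sitting exactly on a decision boundary may flip, others not
  clear <- abs(abs(d1$log2fc) - 1) > 0.05 &
    (d1$p_adj < 0.005 | d1$p_adj > 0.02)
  expect_equal(d1$is_differential[clear], d2$is_differential[clear])
  expect_equal(d1$log2fc, d2$log2fc, tolerance = 0.01)
})

test_that("sign convention: genes higher in the reference get positive fold", {
  sim <- simulate_counts(paste0("g", 1:200), n_reps = 2,
                         mu_range = c(200, 400), dispersion = 0.05,
                         de_spec = data.frame(gene_id = "g1", log2fc = 2),
                         seed = 92)
  ref <- sim$samples$sample[sim$samples$group == "R35"]
  cmp <- sim$samples$sample[sim$samples$group == "m115"]
  de <- de_test(sim$counts, ref, cmp)
  expect_gt(de$log2fc[de$feature_id == "g1"], 0)
})

test_that("common dispersion is recovered by the moment estimator", {
  sim <- simulate_counts(paste0("g", 1:3000), n_reps = 4,
                         mu_range = c(50, 500), dispersion = 0.1,
                         lib_range = c(1, 1), seed = 93)
  est <- estimate_dispersion_mom(sim$counts,
                                 list(1:4, 5:8),
                                 rep(mean(colSums(sim$counts)), 8))
  expect_equal(est, 0.1, tolerance = 0.03)
})
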