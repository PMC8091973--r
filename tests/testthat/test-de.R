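test_that("gDNA prenormalization cancels mixing variation", {
  spike <- tibble::tibble(gene_id = c("s1", "s2"),
                          a = c(100L, 50L), b = c(100L, 50L))
  pre <- prenormalize_spike(spike, c(a = 0.2, b = 0.4))
  expect_equal(pre$a, c(500, 250))
  expect_equal(pre$b, c(250, 125))
  expect_error(prenormalize_spike(spike, c(a = 0.2, b = -1)), "positive")
  # equal rho scales all columns alike: size-factor ratios unchanged
  sf_raw <- size_factors(spike)
  sf_pre <- size_factors(prenormalize_spike(spike, c(a = 0.3, b = 0.3)))
  expect_equal(sf_pre / sf_pre[1], sf_raw / sf_raw[1])
})

test_that("median-of-ratios size factors match the hand-computable case", {
  m <- matrix(c(4, 1, 9, 16, 4, 36), ncol = 2,
              dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
  expect_equal(unname(size_factors(m)), c(0.5, 2.0))
  same <- cbind(a = c(3, 8, 1), b = c(3, 8, 1))
  expect_equal(unname(size_factors(same)), c(1, 1))
  allzero <- matrix(c(0, 0, 5, 0), ncol = 2)
  expect_error(size_factors(allzero), "nonzero")
})

test_that("size factors match brute-force and reference implementations", {
  set.seed(41)
  for (trial in 1:100) {
    m <- matrix(rpois(60, lambda = 20) + 1, ncol = 4)
    colnames(m) <- paste0("s", 1:4)
    expect_equal(unname(size_factors(m)), unname(oracle_size_factors(m)),
                 tolerance = 1e-12)
  }
  # independent reference implementation on one instance (odd gene count:
  # the reference takes the log-scale median, which agrees at odd n)
  m <- matrix(rpois(404, lambda = 50) + 1, ncol = 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("BH adjustment matches the step-up oracle and passes NAs through", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  p <- c(0.01, NA, 0.5)
  adj <- bh_adjust(p)
  expect_true(is.na(adj[2]))
  # NAs excluded from m: the non-NA entries are adjusted as a length-2 set
  expect_equal(adj[c(1, 3)], oracle_bh(p[c(1, 3)]))
  set.seed(43)
  for (trial in 1:100) {
    pv <- runif(sample(3:40, 1))
    expect_equal(bh_adjust(pv), oracle_bh(pv), tolerance = 1e-12)
    expect_true(all(bh_adjust(pv) >= pv))
  }
})

test_that("the NB Wald test is exact on degenerate and symmetric inputs", {
  m <- matrix(rep(c(10, 20, 30), 4), ncol = 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  cond <- c("A", "A", "B", "B")
  res <- nb_wald_test(m, sf = rep(1, 4), condition = cond)
  expect_equal(res$lfc_mle, rep(0, 3))
  expect_equal(res$p, rep(1, 3))
  # all-zero genes are NA and excluded from multiple testing
  m2 <- rbind(m, g4 = c(0, 0, 0, 0))
  res2 <- nb_wald_test(m2, sf = rep(1, 4), condition = cond)
  expect_true(is.na(res2$p[4]))
  expect_equal(sum(!is.na(bh_adjust(res2$p))), 3L)
  # swapping conditions negates the LFC and preserves p
  set.seed(47)
  m3 <- matrix(rnbinom(600, mu = 100, size = 20), ncol = 6)
  rownames(m3) <- paste0("g", 1:100)
  colnames(m3) <- paste0("s", 1:6)
  cond3 <- rep(c("A", "B"), each = 3)
  fwd <- nb_wald_test(m3, rep(1, 6), cond3, contrast = c("B", "A"))
  rev <- nb_wald_test(m3, rep(1, 6), cond3, contrast = c("A", "B"))
  expect_equal(fwd$lfc_mle, -rev$lfc_mle)
  expect_equal(fwd$p, rev$p)
})

test_that("normal-prior shrinkage interpolates between MLE and zero", {
  set.seed(53)
  lfc <- rnorm(500, 0, 1)
  se_small <- rep(1e-6, 500)
  expect_equal(shrink_lfc(lfc, se_small), lfc, tolerance = 1e-4)
  se_huge <- rep(100, 500)
  expect_true(all(abs(shrink_lfc(lfc, se_huge)) < 0.01))
  # shrinkage never crosses zero or grows the estimate
  se_mix <- runif(500, 0.1, 2)
  sh <- shrink_lfc(lfc, se_mix)
  expect_true(all(abs(sh) <= abs(lfc)))
  expect_true(all(sign(sh) == sign(lfc) | sh == 0))
})

test_that("significance classes apply both thresholds", {
  expect_equal(classify_significance(0.01, log2(1.6)), "up")
  expect_equal(classify_significance(0.01, log2(1.4)), "no_change")
  expect_equal(classify_significance(0.01, log2(1 / 1.6)), "down")
  expect_equal(classify_significance(0.2, log2(3)), "no_change")
  expect_equal(classify_significance(NA, 2), "no_change")
})

test_that("RPKM arithmetic and the expression threshold behave as stated", {
  # mean count 100, length 2 kb, total 1e6: RPKM 50
  m <- matrix(c(100, 999900), ncol = 1,
              dimnames = list(c("g1", "filler"), "s1"))
  rk <- rpkm_and_threshold(m, gene_lengths = c(2000, 1e6),
                           threshold = 2.838)
  expect_equal(rk$rpkm[1], 50)
  expect_equal(rk$log2_rpkm[1], log2(51))
  expect_equal(round(rk$log2_rpkm[1], 3), 5.672)
  # a gene just above the threshold used in the calibrated analyses (2.838)
  # counts as expressed
  m2 <- matrix(c(3, 999997), ncol = 1,
               dimnames = list(c("g1", "filler"), "s1"))
  rk2 <- rpkm_and_threshold(m2, gene_lengths = c(1000, 1e6),
                            threshold = 2.838)
  expect_equal(rk2$rpkm[1], 3)
  expect_true(rk2$expressed[1])
  expect_error(rpkm_and_threshold(m, gene_lengths = c(0, 1)), "> 0")
})

test_that("the density valley splits a bimodal expression distribution", {
  set.seed(59)
  x <- c(rnorm(2000, 0, 1), rnorm(2000, 5, 1))
  valley <- expression_valley(x)
  expect_lt(abs(valley - 2.5), 0.3)
  expect_warning(v1 <- expression_valley(rnorm(2000)), "unimodal")
  expect_true(is.na(v1))
})

test_that("spike-derived size factors recover simulated depth factors", {
  gt <- tibble::tibble(gene_id = sprintf("g%03d", 1:300), length = 2000)
  gsk <- tibble::tibble(gene_id = sprintf("s%03d", 1:200))
  sf_true <- c(0.6, 1, 1.5, 0.8, 1.2, 1)
  sim <- simulate_rna_counts(gt, gsk, lfc = 0, baseline = 300,
                             spike_baseline = 300, dispersion = 0.02,
                             sf = sf_true, n_rep = 3, seed = 61)
  pre <- prenormalize_spike(
    sim$spike_counts, stats::setNames(sim$samples$rho, sim$samples$sample))
  sf_est <- size_factors(pre)
  rel <- (sf_est / exp(mean(log(sf_est)))) /
    (sf_true / exp(mean(log(sf_true))))
  expect_true(all(abs(rel - 1) < 0.05))
  # prenormalization improves recovery when mixing is jittered
  sf_raw <- size_factors(sim$spike_counts)
  rel_raw <- (sf_raw / exp(mean(log(sf_raw)))) /
    (sf_true / exp(mean(log(sf_true))))
  expect_lt(max(abs(rel - 1)), max(abs(rel_raw - 1)))
})

test_that("shrunken fold changes rank true effects at least as well", {
  gt <- tibble::tibble(gene_id = sprintf("g%04d", 1:1000), length = 2000)
  gsk <- tibble::tibble(gene_id = sprintf("s%03d", 1:200))
  set.seed(67)
  true_lfc <- rnorm(1000, 0, 0.7)
  sim <- simulate_rna_counts(gt, gsk, lfc = true_lfc, n_rep = 3,
                             dispersion = 0.05, seed = 67)
  de <- run_calibrated_de(sim$counts, sim$spike_counts, sim$samples)
  r <- tidy(de)
  ok <- !is.na(r$lfc_mle)
  cor_mle <- cor(r$lfc_mle[ok], true_lfc[ok], method = "spearman")
  cor_shr <- cor(r$lfc_shrunk[ok], true_lfc[ok], method = "spearman")
  expect_gte(cor_shr, cor_mle - 1e-9)
  expect_gt(cor_shr, 0.8)
})

test_that("tidiers and plots expose the fitted DE object", {
  gt <- tibble::tibble(gene_id = sprintf("g%03d", 1:200), length = 2000)
  gsk <- tibble::tibble(gene_id = sprintf("s%03d", 1:100))
  sim <- simulate_rna_counts(gt, gsk, lfc = 0, n_rep = 2,
                             dispersion = 0.05, seed = 71)
  de <- run_calibrated_de(sim$counts, sim$spike_counts, sim$samples)
  td <- tidy(de)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("gene_id", "baseMean", "lfc_mle", "lfc_shrunk", "p",
                    "padj", "sig_class") %in% names(td)))
  expect_true(all(td$padj >= td$p, na.rm = TRUE))
  gl <- glance(de)
  expect_equal(gl$n_genes, 200L)
  expect_s3_class(autoplot(de), "ggplot")
  expect_output(print(de), "calibrated differential expression")
})
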