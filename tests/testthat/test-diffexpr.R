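make_em <- function(values, treatments) {
  n <- ncol(values)
  rownames(values) <- sprintf("p%02d", seq_len(nrow(values)))
  colnames(values) <- sprintf("s%02d", seq_len(n))
  expression_matrix(values, data.frame(
    sample_id = colnames(values), cell_line = "L", treatment = treatments,
    replicate = ave(seq_len(n), treatments, FUN = seq_along)))
}

test_that("log2 fold change is the difference of group means", {
  vals <- rbind(c(5, 5, 6, 6), c(3, 3, 3, 3))
  em <- make_em(vals, c("ctl", "ctl", "trt", "trt"))
  fc <- log2_fold_changes(em, "trt", "ctl")
  expect_equal(unname(fc), c(1, 0))
  expect_error(log2_fold_changes(em, "missing", "ctl"), "missing")
})

test_that("pooled t statistic matches hand computation and t.test", {
  em <- make_em(rbind(c(1, 2, 3, 4, 5, 6)), c(rep("a", 3), rep("b", 3)))
  tt <- two_sample_test(em, "b", "a")
  # groups {1,2,3} vs {4,5,6}: t = 3 / (1 * sqrt(2/3)) = 3.674, df = 4
  expect_equal(tt$t_stat, 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tt$p_raw, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)

  # cross-check against stats::t.test on random data
  set.seed(1)
  vals <- matrix(rnorm(40 * 8), 40)
  em2 <- make_em(vals, rep(c("a", "b"), each = 4))
  tt2 <- two_sample_test(em2, "b", "a")
  ref <- apply(vals, 1, function(r)
    unlist(t.test(r[5:8], r[1:4], var.equal = TRUE)[c("statistic", "p.value")]))
  expect_equal(unname(tt2$t_stat), unname(ref[1, ]), tolerance = 1e-10)
  expect_equal(unname(tt2$p_raw), unname(ref[2, ]), tolerance = 1e-10)
})

test_that("degenerate zero-variance probes follow the documented convention", {
  vals <- rbind(c(2, 2, 2, 2), c(2, 2, 3, 3))
  em <- make_em(vals, c("a", "a", "b", "b"))
  tt <- two_sample_test(em, "b", "a")
  expect_equal(tt$t_stat[1], 0)            # no variance, no difference
  expect_equal(tt$p_raw[1], 1)
  expect_true(is.infinite(tt$t_stat[2]))   # no variance, real difference
  expect_equal(tt$p_raw[2], 0)
})

test_that("identical groups give t = 0 and p = 1 everywhere", {
  set.seed(2)
  base <- matrix(rnorm(20 * 3), 20)
  em <- make_em(cbind(base, base), rep(c("a", "b"), each = 3))
  tt <- two_sample_test(em, "b", "a")
  expect_true(all(tt$t_stat == 0))
  expect_true(all(tt$p_raw == 1))
})

test_that("BH adjustment matches hand-worked examples and rejects bad input", {
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(0.005, 0.1)), c(0.01, 0.1))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1)), "\\[0, 1\\]")
})

test_that("BH adjustment equals the brute-force min-over-tail definition", {
  set.seed(7)
  for (i in 1:100) {
    m <- sample(1:60, 1)
    p <- round(runif(m), sample(c(1, 2, 6), 1))  # coarse rounding forces ties
    expect_equal(bh_adjust(p), bh_brute_force(p), tolerance = 1e-12)
  }
})

test_that("DE calls apply strict fold-change and FDR thresholds", {
  de <- data.frame(log2fc = c(1, log2(1.5), -1, -1, 0.1),
                   p_adj = c(0.01, 0.001, 0.2, 0.01, 0.001))
  called <- call_de(de)
  expect_equal(as.character(called$call), c("up", "ns", "ns", "down", "ns"))
  # threshold is parameterizable
  relaxed <- call_de(de, fc_threshold = 1.05, alpha = 0.05)
  expect_equal(as.character(relaxed$call), c("up", "up", "ns", "down", "up"))
  expect_error(call_de(de, fc_threshold = 1), "fc_threshold")
})

test_that("adjusted p-values dominate raw ones and respect rank monotonicity", {
  sim <- small_study(seed = 17)
  de <- de_table(sim$matrix, "BPA", "control")
  expect_true(all(de$p_adj >= de$p_raw - 1e-15))
  ord <- order(de$p_raw)
  expect_true(all(diff(de$p_adj[ord]) >= -1e-15))
  # calls are consistent with their defining thresholds
  up <- de$call == "up"; down <- de$call == "down"
  expect_true(all(2^de$log2fc[up] > 1.5 & de$p_adj[up] < 0.05))
  expect_true(all(2^de$log2fc[down] < 1 / 1.5 & de$p_adj[down] < 0.05))
})

test_that("pooled-t p agrees with the exact permutation p on 4v4 data", {
  # with 4v4 groups the permutation distribution has 35 distinct splits, so
  # per-probe p-values are quantized and condition on the observed data;
  # calibration is asserted on the average absolute discrepancy and on rank
  # agreement across probes
  sim <- generate_expression(sim_config(
    n_probes = 150L, n_replicates = 4L, shared_de_count = 30L,
    private_de_count = 0L, effect_mean = 1, effect_sd = 0.3,
    noise_sd = 0.4, seed = 31))
  em <- sim$matrix
  tt <- two_sample_test(em, "BPA", "control")
  ci <- which(em$samples$treatment == "control")
  ti <- which(em$samples$treatment == "BPA")
  perm_p <- apply(em$values, 1, function(r) perm_t_pvalue(r[ti], r[ci]))
  expect_lt(mean(abs(tt$p_raw - perm_p)), 0.08)
  expect_gt(cor(tt$p_raw, perm_p, method = "spearman"), 0.95)
  # strong-signal probes agree tightly in both routes
  strong <- tt$p_raw < 0.01
  expect_gt(sum(strong), 10)
  expect_lt(max(perm_p[strong]), 0.08)
})

test_that("planted effects are recovered with high sensitivity and low FDR", {
  # with only 200 signals among 4000 probes the BH gate needs raw p below
  # roughly alpha * 200 / 4000 = 0.0025, so the condition uses clearly
  # separated effects (1.5 log2 units against 0.15 noise at n = 4)
  stats <- vapply(1:10, function(s) {
    sim <- generate_expression(sim_config(
      n_probes = 4000L, n_replicates = 4L, shared_de_count = 100L,
      private_de_count = 50L, effect_mean = 1.5, effect_sd = 0.25,
      noise_sd = 0.15, seed = 500 + s))
    de <- de_table(sim$matrix, "BPA", "control")
    true_de <- sim$truth$effect_BPA != 0
    called <- de$call != "ns"
    c(sens = sum(called & true_de) / sum(true_de),
      fdr = if (sum(called)) sum(called & !true_de) / sum(called) else 0)
  }, numeric(2))
  expect_gte(mean(stats["sens", ]), 0.9)
  expect_lte(mean(stats["fdr", ]), 0.1)
})

test_that("DE tables round-trip through TSV", {
  sim <- small_study(n_probes = 80L, shared_de_count = 20L)
  de <- de_table(sim$matrix, "BPA", "control")
  path <- tempfile(fileext = ".tsv")
  write_de_table(de, path)
  back <- read_de_table(path)
  expect_equal(back$call, de$call)
  expect_equal(back$log2fc, de$log2fc, tolerance = 1e-12)
  expect_equal(de_probes(back, "up"), de_probes(de, "up"))
})
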