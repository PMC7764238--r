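test_that("interaction df bookkeeping follows the 2-group, 3-session design", {
  mt <- fake_metric_table(n_per_group = 9, seed = 1)
  res <- rm_anova_interaction(mt)
  expect_equal(unique(res$df_num), 2L)
  expect_equal(unique(res$df_den), 32L)   # (18 - 2) * (3 - 1)
  mt12 <- fake_metric_table(n_per_group = 12, seed = 2)
  expect_equal(unique(rm_anova_interaction(mt12)$df_den), 44L)
})

test_that("parallel group profiles give an interaction F of zero", {
  mt <- fake_metric_table(n_per_group = 4, nodes = "A", seed = 3)
  base <- c(T0 = 1, T1 = 4, T2 = 2)
  grp_off <- c(OMT = 0, P = 3)
  # per-session deviations that cancel within each group keep every
  # group-session cell mean exactly on the (parallel) group profile while
  # leaving a nonzero error sum of squares
  dev <- c(0.7, -0.7, 0.3, -0.3)
  names(dev) <- NULL
  subj_idx <- as.integer(factor(mt$subject))
  mt$value <- base[mt$session] + grp_off[mt$group] +
    dev[(subj_idx - 1L) %% 4L + 1L] * match(mt$session, names(base))
  res <- rm_anova_interaction(mt)
  expect_lt(res$F, 1e-15)
})

test_that("interaction F matches the split-plot aov stratum", {
  for (seed in c(1, 2, 3)) {
    mt <- fake_metric_table(n_per_group = 3 + seed, nodes = c("A", "B"),
                            seed = seed)
    res <- rm_anova_interaction(mt)
    for (nd in c("A", "B")) {
      ref <- aov_interaction_f(mt[mt$node == nd, ])
      row <- res[res$node == nd, ]
      expect_equal(row$F, ref$F, tolerance = 1e-10)
      expect_equal(row$df_num, ref$df_num)
      expect_equal(row$df_den, ref$df_den)
      expect_equal(row$p, ref$p, tolerance = 1e-10)
    }
  }
})

test_that("incomplete subjects are dropped and small groups rejected", {
  mt <- fake_metric_table(n_per_group = 4, nodes = "A", seed = 4)
  mt_drop <- mt[!(mt$subject == "O01" & mt$session == "T2"), ]
  res <- rm_anova_interaction(mt_drop)
  expect_equal(attr(res, "n_complete"), 7L)
  expect_equal(res$df_den, (7L - 2L) * 2L)
  tiny <- mt[mt$subject %in% c("O01", "P01", "P02"), ]
  expect_error(rm_anova_interaction(tiny), "fewer than 2")
})

test_that("Benjamini-Hochberg adjustment reproduces the step-up rule", {
  expect_equal(fdr_adjust(rep(0.01, 7)), rep(0.01, 7))
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.03), 0.03)
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  expect_equal(fdr_adjust(p), p.adjust(p, "BH"))
  expect_true(all(fdr_adjust(p) >= p))
})

test_that("post-hoc contrast is the group difference of change scores", {
  mt <- fake_metric_table(n_per_group = 6, nodes = "A", seed = 5)
  # identical deltas in both groups: delta = 0
  mt$value <- ave(mt$value, mt$subject, FUN = function(x) seq_along(x))
  res <- posthoc_contrast(mt, c("T0", "T1"))
  expect_equal(res$delta, 0)
  # planting a known shift in the treated group at T1
  mt2 <- fake_metric_table(n_per_group = 6, nodes = "A", seed = 6)
  bump <- mt2$group == "OMT" & mt2$session == "T1"
  mt2$value[bump] <- mt2$value[bump] + 10
  res2 <- posthoc_contrast(mt2, c("T0", "T1"))
  expect_gt(res2$delta, 5)
  # antisymmetry under group relabeling
  mt3 <- mt2
  mt3$group <- ifelse(mt2$group == "OMT", "P", "OMT")
  res3 <- posthoc_contrast(mt3, c("T0", "T1"))
  expect_equal(res3$delta, -res2$delta, tolerance = 1e-12)
  expect_equal(res3$p, res2$p, tolerance = 1e-12)
})

test_that("dysfunction correlation recovers exact linear dependence", {
  delta <- data.frame(subject = sprintf("O%02d", 1:10), group = "OMT",
                      node = "A", metric = "betweenness",
                      delta = 2 * (1:10))
  counts <- setNames(1:10, delta$subject)
  res <- dysfunction_correlation(counts, delta)
  expect_equal(res$r, 1)
  expect_lt(res$p, 1e-8)
  expect_warning(
    res0 <- dysfunction_correlation(setNames(rep(3, 10), delta$subject), delta),
    "zero variance")
  expect_true(is.na(res0$r))
})

test_that("dysfunction correlation has nominal type-I error under the null", {
  set.seed(77)
  n <- 12
  subj <- sprintf("O%02d", seq_len(n))
  hits <- replicate(1000, {
    delta <- data.frame(subject = subj, group = "OMT", node = "A",
                        metric = "clustering", delta = rnorm(n))
    counts <- setNames(rnorm(n), subj)   # independent of the change scores
    dysfunction_correlation(counts, delta)$p < 0.05
  })
  expect_lt(abs(mean(hits) - 0.05), 0.025)
})

test_that("Mann-Whitney matches closed forms and the exact distribution", {
  same <- mann_whitney(c(1, 3, 5), c(1, 3, 5))
  expect_equal(same$p, 1)
  sep <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(sep$U), 0)
  # exact two-sided p by enumeration over all rank assignments (8 + 8)
  set.seed(10)
  a <- rnorm(8); b <- rnorm(8)
  got <- mann_whitney(a, b)
  ranks <- rank(c(a, b))
  u_obs <- sum(ranks[1:8]) - 8 * 9 / 2
  combos <- combn(16, 8)
  u_all <- apply(combos, 2, function(idx) sum(seq_len(16)[idx]) - 36)
  p_exact <- mean(pmin(u_all, 64 - u_all) <= min(u_obs, 64 - u_obs))
  expect_equal(got$p, p_exact, tolerance = 1e-12)
  expect_equal(unname(got$U), unname(u_obs))
})

test_that("summary-statistic t test agrees with a full-data t test", {
  res <- summary_ttest(28.0, 5.5, 15, 25.4, 3.2, 15)
  expect_equal(res$df, 28)
  set.seed(9)
  x <- rnorm(12, 5, 2); y <- rnorm(17, 6, 2.5)
  full <- t.test(y, x, var.equal = TRUE)
  summ <- summary_ttest(mean(x), sd(x), 12, mean(y), sd(y), 17)
  expect_equal(summ$t, unname(full$statistic), tolerance = 1e-12)
  expect_equal(summ$p, full$p.value, tolerance = 1e-12)
  expect_equal(summ$ci95, as.numeric(full$conf.int), tolerance = 1e-12)
  expect_equal(summary_ttest(5, 1, 10, 5, 2, 10)$t, 0)
})

test_that("2x2 chi-square is the Pearson statistic without correction", {
  res <- chi_square_2x2(10, 20, 20, 10)
  expected <- matrix(15, 2, 2)
  obs <- matrix(c(10, 20, 20, 10), 2, byrow = TRUE)
  expect_equal(res$chisq, sum((obs - expected)^2 / expected),
               tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_equal(chi_square_2x2(5, 5, 5, 5)$chisq, 0)
  expect_error(chi_square_2x2(0, 0, 3, 4), "marginal")
})

test_that("paired sample size is minimal and monotone in effect size", {
  n <- paired_sample_size(0.55, alpha = 0.05, power = 0.80, tails = 1)
  expect_gte(paired_t_power(n, 0.55, tails = 1), 0.80)
  expect_lt(paired_t_power(n - 1, 0.55, tails = 1), 0.80)
  expect_lt(paired_sample_size(1.1, tails = 1), n)
  expect_gt(paired_sample_size(0.55, tails = 2), n)
  expect_error(paired_sample_size(0), "positive")
})
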