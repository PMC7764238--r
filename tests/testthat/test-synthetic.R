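test_that("ground-truth covariance is SPD with modular block structure", {
  gt <- make_ground_truth(n_nodes = 6, n_modules = 2, seed = 1)
  r <- gt$base_covariance
  expect_equal(r, t(r))
  expect_true(min(eigen(r, only.values = TRUE)$values) > 0)
  same <- outer(gt$modules, gt$modules, "==") & upper.tri(r)
  diff <- outer(gt$modules, gt$modules, "!=") & upper.tri(r)
  expect_gt(mean(r[same]), mean(r[diff]))
})

test_that("zero-magnitude effects leave the covariance untouched", {
  eff <- data.frame(group = "OMT", timepoint = "T1", node = 3,
                    effect = "clustering_down", magnitude = 0)
  gt <- make_ground_truth(n_nodes = 9, n_modules = 3, effect_spec = eff,
                          seed = 4)
  expect_identical(covariance_for(gt, "OMT", "T1"), gt$base_covariance)
  # and conditions without a registered effect are always the base model
  expect_identical(covariance_for(gt, "P", "T1"), gt$base_covariance)
})

test_that("clustering_down lowers covariance among the target's neighbours", {
  eff <- data.frame(group = "OMT", timepoint = "T1", node = 3,
                    effect = "clustering_down", magnitude = 0.5)
  gt <- make_ground_truth(n_nodes = 12, n_modules = 3, effect_spec = eff,
                          seed = 2)
  pert <- covariance_for(gt, "OMT", "T1")
  nbr <- setdiff(which(gt$modules == gt$modules[3]), 3)
  off <- upper.tri(matrix(0, length(nbr), length(nbr)))
  expect_lt(mean(pert[nbr, nbr][off]), mean(gt$base_covariance[nbr, nbr][off]))
})

test_that("invalid effect specs are rejected", {
  expect_error(make_ground_truth(9, 3, effect_spec = data.frame(
    group = "OMT", timepoint = "T1", node = 99, effect = "clustering_down",
    magnitude = 0.5), seed = 1), "out of range")
  expect_error(make_ground_truth(9, 3, effect_spec = data.frame(
    group = "OMT", timepoint = "T1", node = 2, effect = "clustering_down",
    magnitude = 1.5), seed = 1), "magnitude")
})

test_that("simulated BOLD has the contracted shape and is seed-reproducible", {
  gt <- make_ground_truth(n_nodes = 6, n_modules = 2, seed = 1)
  b1 <- simulate_bold(gt, "OMT", "T0", n_volumes = 240, tr_seconds = 3,
                      seed = 7)
  expect_equal(dim(b1), c(6L, 240L))
  expect_equal(b1$tr, 3)
  b2 <- simulate_bold(gt, "OMT", "T0", n_volumes = 240, tr_seconds = 3,
                      seed = 7)
  expect_identical(b1$data, b2$data)
  expect_error(simulate_bold(gt, "OMT", "T0", n_volumes = 10), "n_volumes")
})

test_that("sample covariance converges to the generating covariance", {
  gt <- make_ground_truth(n_nodes = 8, n_modules = 2, ar_coefficient = 0,
                          seed = 3)
  frob <- vapply(c(500, 2500, 10000), function(v) {
    b <- simulate_bold(gt, "P", "T0", n_volumes = v, seed = 11)
    norm(cov(t(b$data)) - gt$base_covariance, "F")
  }, 0)
  expect_true(all(diff(frob) < 0))
  expect_lt(frob[3], 0.15)
})

test_that("AR(1) simulation preserves the stationary marginal covariance", {
  gt <- make_ground_truth(n_nodes = 6, n_modules = 2, ar_coefficient = 0.5,
                          seed = 5)
  b <- simulate_bold(gt, "P", "T0", n_volumes = 20000, seed = 9)
  expect_lt(norm(cov(t(b$data)) - gt$base_covariance, "F"), 0.25)
  # lag-1 autocorrelation close to the requested coefficient
  ac <- mean(apply(b$data, 1, function(x) cor(x[-1], x[-length(x)])))
  expect_equal(ac, 0.5, tolerance = 0.05)
})

test_that("physiological contamination is additive, aligned and optional", {
  gt <- make_ground_truth(n_nodes = 6, n_modules = 2, seed = 1)
  b <- simulate_bold(gt, "OMT", "T0", n_volumes = 100, seed = 2)
  none <- add_physio(b, amplitudes = c(cardiac = 0, resp = 0), seed = 3)
  expect_identical(none$series$data, b$data)
  cont <- add_physio(b, seed = 3)
  expect_equal(length(cont$physio$cardiac_phase), 100L)
  expect_equal(length(cont$physio$respiratory_phase), 100L)
  expect_false(identical(cont$series$data, b$data))
  expect_error(add_physio(b, amplitudes = c(cardiac = -1, resp = 0)),
               "non-negative")
})

test_that("a dominant cardiac artifact loads on the first cardiac harmonic pair", {
  set.seed(42)
  noise <- roi_ts(matrix(rnorm(4 * 200, sd = 0.05), 4, 200), tr = 3)
  cont <- add_physio(noise, amplitudes = c(cardiac = 5, resp = 0), seed = 6)
  d <- retroicor_design(cont$physio)$matrix
  x <- cont$series$data[1, ]
  r2_pair <- vapply(seq(1, 11, by = 2), function(j) {
    f <- lm.fit(cbind(1, d[, j:(j + 1)]), x)
    1 - sum(f$residuals^2) / sum((x - mean(x))^2)
  }, 0)
  expect_equal(which.max(r2_pair), 1L)  # pair 1 = first cardiac harmonic
  expect_gt(r2_pair[1], 0.7)
})

test_that("motion traces are smooth without spikes and reproducible", {
  m0 <- simulate_motion(240, spike_rate = 0, seed = 1)
  expect_equal(dim(m0), c(240L, 6L))
  expect_lt(max(abs(diff(m0))), 0.05)
  expect_identical(m0, simulate_motion(240, spike_rate = 0, seed = 1))
  m1 <- simulate_motion(240, spike_rate = 0.1, seed = 2)
  expect_gt(max(abs(diff(m1[, 1:3]))), 0.1)
})

test_that("toy volume rendering round-trips through parcellation", {
  gt <- make_ground_truth(n_nodes = 6, n_modules = 2, seed = 1)
  b <- simulate_bold(gt, "OMT", "T0", n_volumes = 30, seed = 4)
  toy <- render_toy_nifti(b, voxels_per_roi = 4, noise_sd = 0)
  expect_equal(dim(toy$volume), c(6L, 4L, 1L, 30L))
  expect_equal(sort(unique(as.integer(toy$labels[toy$labels > 0]))), 1:6)
  rec <- parcellate(toy$volume, toy$labels, tr = 3,
                    node_labels = b$node_labels)
  expect_equal(rec$data, b$data, tolerance = 1e-12)
})

test_that("cohort generation matches the requested design and demographics", {
  coh <- make_cohort(n_per_group = 15, dropout_spec = default_dropout()[0, ],
                     seed = 1)
  expect_equal(nrow(coh), 30L)
  expect_equal(as.vector(table(coh$group)), c(15L, 15L))
  expect_true(all(coh$has_T0 & coh$has_T1 & coh$has_T2))
  omt <- coh[coh$group == "OMT", ]
  expect_equal(mean(omt$age), 28.0, tolerance = 1e-9)
  expect_equal(sd(omt$age), 5.5, tolerance = 1e-9)
  expect_true(all(omt$n_dysfunctions >= 1))
  expect_identical(coh, make_cohort(15, default_dropout()[0, ], seed = 1))
})

test_that("trial dropout removes sessions from the dropout point onward", {
  coh <- make_cohort(n_per_group = 15, seed = 2)
  # 2 placebo subjects lose everything from T0; complete cases 12 + 12
  gone <- coh[coh$group == "P" & !coh$has_T0, ]
  expect_equal(nrow(gone), 2L)
  expect_true(all(!gone$has_T1 & !gone$has_T2))
  omt_t1 <- coh[coh$group == "OMT" & !coh$has_T1 & coh$has_T0, ]
  expect_true(all(!omt_t1$has_T2))
  complete <- coh$has_T0 & coh$has_T1 & coh$has_T2
  expect_equal(as.vector(table(coh$group[complete])), c(12L, 12L))
})
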