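test_that("the epoch statistic matches a hand computation", {
  # single feature, morning {1,1,1}, evening {0,0}: after scaling to unit
  # sd the squared mean difference is (1/sd)^2 with sd of (1,1,1,0,0)
  v <- matrix(c(1, 1, 1, 0, 0), ncol = 1, dimnames = list(NULL, "f1"))
  morning <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  s <- epoch_statistic(v, morning)
  sd_v <- sd(v)
  expect_equal(s$statistic, (1 / sd_v)^2, tolerance = 1e-12)
  expect_equal(s$n_features_used, 1L)

  # identical epoch means -> T = 0
  v2 <- matrix(c(2, 5, 8, 2, 5, 8), ncol = 1, dimnames = list(NULL, "f"))
  s2 <- epoch_statistic(v2, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(s2$statistic, 0, tolerance = 1e-12)

  # zero-variance features are excluded and reported
  v3 <- cbind(f1 = c(1, 1, 1, 0, 0), const = rep(3, 5))
  s3 <- epoch_statistic(v3, morning)
  expect_equal(s3$excluded, "const")
  expect_equal(s3$n_features_used, 1L)
  expect_error(epoch_statistic(v, rep(TRUE, 5)), "non-empty")
})

test_that("doubling a planted effect increases T on noise-free data", {
  stat_for <- function(beta) {
    cfg <- generator_config(
      seed = 5, omics = list(metabolome = list(
        n_features = 6, fraction_rhythmic = 1, beta = beta,
        sigma_s = 0.5, sigma_e = 0.01)))
    om <- generate_omics(cfg, "metabolome")
    epoch_statistic(log10(om$values),
                    om$sample_meta$epoch == "morning")$statistic
  }
  expect_gt(stat_for(2), stat_for(1))
})

test_that("the reference design enumerates 100 arrangements and a constant matrix gives p = 1", {
  d <- ref_design(2)
  meta <- design_samples(d)
  arr <- chronovar:::enumerate_epoch_assignments(meta, d)
  expect_equal(nrow(arr), choose(5, 3)^2)
  expect_false(any(duplicated(arr)))
  # every arrangement keeps 3 morning timepoints per session
  expect_equal(unique(rowSums(arr)), 6 * 2 * 3)
  # first row is the observed labelling
  expect_equal(arr[1, ], meta$epoch == "morning", ignore_attr = TRUE)

  v <- matrix(5, nrow(meta), 4,
              dimnames = list(meta$sample_id, paste0("f", 1:4)))
  res <- exhaustive_permutation_test(v, design = d, meta = meta)
  expect_equal(res$p_value, 1)
  expect_equal(res$n_permutations, 100L)
  expect_equal(res$min_achievable_p, 0.01)
})

test_that("a strong planted signal hits the permutation floor and Monte-Carlo agrees", {
  cfg <- generator_config(
    seed = 19, omics = list(metabolome = list(
      n_features = 20, fraction_rhythmic = 0.5, beta = 4,
      sigma_s = 0.5, sigma_e = 0.05)))
  om <- generate_omics(cfg, "metabolome")
  ex <- exhaustive_permutation_test(om)
  expect_equal(ex$p_value, ex$min_achievable_p)
  expect_equal(ex$n_at_least_as_extreme, 1L)

  set.seed(331)
  mc <- exhaustive_permutation_test(om, mode = "montecarlo", n_mc = 20000)
  se <- sqrt(ex$p_value * (1 - ex$p_value) / 20000)
  expect_lt(abs(mc$p_value - ex$p_value), 3 * se + 2 / 20000)
})

test_that("p-values lie on the achievable grid and are valid probabilities", {
  cfg <- fast_config(seed = 23, n_features = 10)
  om <- generate_omics(cfg, "metabolome")
  res <- exhaustive_permutation_test(om)
  expect_true(res$p_value >= res$min_achievable_p && res$p_value <= 1)
  expect_equal(res$p_value * res$n_permutations,
               round(res$p_value * res$n_permutations))
  # per-feature scope returns one row per usable feature
  pf <- exhaustive_permutation_test(om, scope = "feature")
  expect_equal(nrow(pf), 10)
  expect_true(all(pf$p_value >= 0.01 & pf$p_value <= 1))
})

test_that("T is invariant to feature order and affine feature rescaling", {
  set.seed(41)
  d <- ref_design(1)
  meta <- design_samples(d)
  v <- matrix(rnorm(nrow(meta) * 5, 10), nrow(meta), 5,
              dimnames = list(meta$sample_id, paste0("f", 1:5)))
  morning <- meta$epoch == "morning"
  t0 <- epoch_statistic(v, morning)$statistic
  expect_equal(epoch_statistic(v[, c(3, 1, 5, 2, 4)], morning)$statistic,
               t0, tolerance = 1e-12)
  v_scaled <- v
  v_scaled[, 2] <- v[, 2] * 13 + 7
  expect_equal(epoch_statistic(v_scaled, morning)$statistic, t0,
               tolerance = 1e-12)
})

test_that("null permutation p-values are uniform on the achievable grid", {
  set.seed(47)
  n_rep <- 300
  d <- ref_design(2)
  meta <- design_samples(d)
  ps <- vapply(seq_len(n_rep), function(i) {
    v <- matrix(rnorm(nrow(meta) * 4), nrow(meta), 4,
                dimnames = list(meta$sample_id, paste0("f", 1:4)))
    exhaustive_permutation_test(v, design = d, meta = meta)$p_value
  }, numeric(1))
  # mean of a uniform on {0.01, ..., 1} is 0.505
  se_mean <- sqrt(1 / 12 / n_rep)
  expect_lt(abs(mean(ps) - 0.505), 3 * se_mean)
  # rejection at 0.05 occurs for 5 of the 100 grid points
  se_rej <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(mean(ps <= 0.05) - 0.05), 3 * se_rej)
})
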