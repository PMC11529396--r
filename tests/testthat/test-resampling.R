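make_cohort <- function(panel_size = 20L, n_per_arm = 6L, f = 5e-3,
                        mean_depth = 150, seed = 1234, priming_fold = 19,
                        fraction_shift = 1) {
  simulate_cohort(scenario_config(
    panel_size = panel_size, n_samples_per_arm = n_per_arm,
    true_fraction_grid = f, mean_depth = mean_depth,
    depth_dispersion = 0.2, priming_fold = priming_fold,
    fraction_shift = fraction_shift, seed = seed))
}

test_that("resampling_plan validates its fields", {
  expect_error(resampling_plan(integer()), "panel_sizes")
  expect_error(resampling_plan(10, thresholds = -1), ">= 0")
  expect_error(resampling_plan(10, fractions = 2), "\\[0, 1\\]")
  expect_error(resampling_plan(10, n_replicates = 1), ">= 2")
  plan <- resampling_plan(c(50, 10, 10), seed = 3)
  expect_equal(plan$panel_sizes, c(10L, 50L))
  expect_equal(plan$thresholds, 2:10)
})

test_that("downsample_panel: saturated and all-zero tables give SE = 0", {
  panel <- toy_panel(6L)
  ids <- sprintf("m%d", 1:4)
  t <- rep(10L, 24)
  md <- toy_metadata(ids)
  plan <- resampling_plan(panel_sizes = c(3L, 6L), thresholds = c(1L, 2L),
                          n_replicates = 30L, seed = 11)
  # f = 1 equivalent: every site mutant -> sensitivity 1, SE 0 everywhere
  sat <- toy_counts(panel, ids, t = t, n = t)
  g <- downsample_panel(sat, md, panel, plan)
  expect_true(all(g$mean == 1))
  expect_true(all(g$se == 0))
  expect_true(all(g$n_replicates == 30L))
  # all-zero mutants -> sensitivity 0, SE 0 at thresholds >= 1
  zero <- toy_counts(panel, ids, t = t, n = rep(0L, 24))
  g0 <- downsample_panel(zero, md, panel, plan)
  expect_true(all(g0$mean == 0))
  expect_true(all(g0$se == 0))
  # panel_size beyond the full panel errors
  expect_error(
    downsample_panel(sat, md, panel, resampling_plan(7L, n_replicates = 5L)),
    "exceed")
})

test_that("bootstrap mean at any panel size matches a brute-force resampling
           average on a small panel", {
  co <- make_cohort(panel_size = 8L, n_per_arm = 10L, f = 8e-3,
                    mean_depth = 60, seed = 42, priming_fold = 2)
  md <- co$metadata
  mats_n <- matrix(co$counts$n, nrow = nrow(md), byrow = TRUE)
  # rows of counts are ordered sample-major, panel-site order within sample
  det <- mats_n >= 1L
  for (ps in c(4L, 8L)) {
    for (k in c(1L, 2L)) {
      plan <- resampling_plan(panel_sizes = ps, thresholds = k,
                              n_replicates = 2000L, seed = 7)
      g <- downsample_panel(co$counts, md, co$panel, plan)
      got <- sum(g$mean * table(md$arm)[g$arm]) / nrow(md)  # pooled over arms
      want <- brute_bootstrap_sensitivity(det, ps, k, n_draws = 4000L,
                                          seed = 99)
      expect_lt(abs(got - want), 0.03)
      want_exact <- exact_bootstrap_sensitivity(det, ps, k)
      expect_lt(abs(got - want_exact), 0.03)
    }
  }
})

test_that("without-replacement subsampling at full size is the plain panel", {
  co <- make_cohort(panel_size = 12L, n_per_arm = 5L, f = 5e-3,
                    mean_depth = 100, seed = 8)
  det <- detect_samples(co$counts, co$panel, thresholds = 2L)
  plan <- resampling_plan(panel_sizes = 12L, thresholds = 2L,
                          n_replicates = 10L, seed = 2, replace = FALSE)
  g <- downsample_panel(co$counts, co$metadata, co$panel, plan)
  for (a in unique(co$metadata$arm)) {
    direct <- sensitivity(det[det$sample_id %in%
                                co$metadata$sample_id[co$metadata$arm == a], ])
    expect_equal(g$mean[g$arm == a], direct)
    expect_equal(g$se[g$arm == a], 0)
  }
})

test_that("downscale_fraction: degenerate targets and extrapolation warning", {
  co <- make_cohort(panel_size = 10L, n_per_arm = 4L, f = 5e-3,
                    mean_depth = 80, seed = 31)
  plan <- resampling_plan(panel_sizes = 10L, thresholds = c(1L, 2L),
                          fractions = 0, n_replicates = 20L, seed = 5)
  g <- downscale_fraction(co$counts, co$metadata, co$panel, plan)
  expect_true(all(g$mean == 0))
  expect_true(all(g$se == 0))
  plan_hi <- resampling_plan(panel_sizes = 10L, thresholds = 2L,
                             fractions = 0.5, n_replicates = 5L, seed = 5)
  expect_warning(
    downscale_fraction(co$counts, co$metadata, co$panel, plan_hi),
    "extrapolation")
  expect_error(
    downscale_fraction(co$counts, co$metadata, co$panel,
                       resampling_plan(10L, fractions = "observed")),
    "numeric")
})

test_that("downscale_fraction at the cohort's own fraction reproduces the
           directly simulated sensitivity (self-consistency)", {
  f_true <- 6e-3
  co <- make_cohort(panel_size = 25L, n_per_arm = 12L, f = f_true,
                    mean_depth = 40, seed = 64, priming_fold = 3)
  det <- detect_samples(co$counts, co$panel, thresholds = 3L)
  plan <- resampling_plan(panel_sizes = 25L, thresholds = 3L,
                          fractions = f_true, n_replicates = 400L, seed = 12,
                          replace = FALSE)
  g <- downscale_fraction(co$counts, co$metadata, co$panel, plan)
  for (a in unique(co$metadata$arm)) {
    ids <- co$metadata$sample_id[co$metadata$arm == a]
    direct <- sensitivity(det[det$sample_id %in% ids, ])
    row <- g[g$arm == a, ]
    tol <- 4 * sqrt(max(row$se^2 * (1 + 1 / row$n_replicates), 1e-4))
    expect_lt(abs(row$mean - direct), tol)
  }
})

test_that("replicate SE tracks the binomial-proportion SE within a factor
           of 2 on i.i.d. samples", {
  co <- make_cohort(panel_size = 25L, n_per_arm = 16L, f = 4e-3,
                    mean_depth = 40, seed = 100, priming_fold = 1)
  plan <- resampling_plan(panel_sizes = 25L, thresholds = 2L,
                          fractions = 4e-3, n_replicates = 300L, seed = 9,
                          replace = FALSE)
  g <- downscale_fraction(co$counts, co$metadata, co$panel, plan)
  m <- 16
  for (i in seq_len(nrow(g))) {
    s <- g$mean[i]
    if (s > 0.05 && s < 0.95) {
      analytic <- sqrt(s * (1 - s) / m)
      expect_lt(g$se[i], 2 * analytic)
      expect_gt(g$se[i], analytic / 2)
    }
  }
})

test_that("grids are deterministic given (seed, plan, table) and monotone", {
  co <- make_cohort(panel_size = 30L, n_per_arm = 8L, f = 3e-3,
                    mean_depth = 100, seed = 55)
  plan <- resampling_plan(panel_sizes = c(5L, 15L, 30L),
                          thresholds = c(2L, 4L, 8L),
                          fractions = c(5e-4, 2e-3, 3e-3),
                          n_replicates = 80L, seed = 77)
  g1 <- downsample_panel(co$counts, co$metadata, co$panel, plan)
  g2 <- downsample_panel(co$counts, co$metadata, co$panel, plan)
  expect_identical(g1, g2)
  d1 <- downscale_fraction(co$counts, co$metadata, co$panel, plan)
  d2 <- downscale_fraction(co$counts, co$metadata, co$panel, plan)
  expect_identical(d1, d2)

  # monotone within MC error bands (2 * combined SE + floor)
  band <- function(a, b) 2 * sqrt(a^2 + b^2) + 0.02
  for (a in unique(d1$arm)) {
    for (k in unique(d1$threshold)) {
      sub <- d1[d1$arm == a & d1$threshold == k & d1$panel_size == 30L, ]
      sub <- sub[order(sub$fraction), ]
      expect_true(all(diff(sub$mean) >= -band(sub$se[-1],
                                              sub$se[-nrow(sub)])))
    }
    sub <- g1[g1$arm == a & g1$threshold == 2L, ]
    sub <- sub[order(sub$panel_size), ]
    expect_true(all(diff(sub$mean) >= -band(sub$se[-1], sub$se[-nrow(sub)])))
    sub <- g1[g1$arm == a & g1$panel_size == 30L, ]
    sub <- sub[order(sub$threshold), ]
    expect_true(all(diff(sub$mean) <= band(sub$se[-1], sub$se[-nrow(sub)])))
  }
})

test_that("binomial_model_check is calibrated under the null and rejects a
           hot-spot alternative", {
  co <- make_cohort(panel_size = 40L, n_per_arm = 15L, f = 5e-3,
                    mean_depth = 200, seed = 2025, priming_fold = 1)
  rep_null <- binomial_model_check(co$counts, co$panel, n_boot = 99L,
                                   seed = 4)
  expect_false(any(rep_null$skipped))
  # null p-values should not pile up at small values: rejection rate at
  # alpha = 0.1 within 4 binomial SDs of nominal over 30 samples
  rej <- mean(rep_null$p_value <= 0.1)
  expect_lt(abs(rej - 0.1), 4 * sqrt(0.1 * 0.9 / nrow(rep_null)) + 0.05)

  # hot-spot contamination: one site at f = 0.5, the rest at 1e-4
  panel <- toy_panel(30L)
  t <- rep(500L, 30L)
  set.seed(77)
  n <- rbinom(30, t, 1e-4)
  n[1] <- rbinom(1, t[1], 0.5)
  hot <- toy_counts(panel, "hot", t = t, n = n)
  rep_hot <- binomial_model_check(hot, panel, n_boot = 199L, seed = 4)
  expect_lt(rep_hot$p_value, 0.02)

  # zero-depth sample is skipped with a warning, and noted in the report
  tab0 <- duplex_count_table(c("z", "ok", "ok"), c("s01", "s01", "s02"),
                             c(0L, 100L, 100L), c(0L, 1L, 0L),
                             panel = toy_panel(2L))
  expect_warning(rep0 <- binomial_model_check(tab0, toy_panel(2L),
                                              n_boot = 19L, seed = 1),
                 "zero total depth|treated as t = 0")
  expect_true(rep0$skipped[rep0$sample_id == "z"])
  expect_false(rep0$skipped[rep0$sample_id == "ok"])
})
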