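test_that("z-scoring centers, scales, flags constants, and is idempotent", {
  expect_equal(zscore_counts(c(1, 2, 3)), c(-1, 0, 1))
  expect_true(all(is.na(zscore_counts(c(5, 5, 5)))))
  z <- zscore_counts(c(2, 9, 4, 4, 1))
  expect_equal(zscore_counts(z), z)
  expect_error(zscore_counts(3))
})

test_that("outlier removal is one-pass, strict, and inert for constant vectors", {
  # 19 trials of count 1 plus one of 50: that trial's z is ~4.25 > 3
  a <- c(rep(1, 19), 50)
  b <- rep(2:3, 10)
  keep <- remove_outlier_trials(zscore_counts(a), zscore_counts(b))
  expect_equal(which(!keep), 20L)
  expect_equal(unname(abs(zscore_counts(a))[20]) > 3, TRUE)

  # constant counts: undefined z-scores remove nothing
  keep <- remove_outlier_trials(zscore_counts(rep(4, 10)), zscore_counts(rep(1, 10)))
  expect_true(all(keep))

  # |z| exactly at the threshold is kept (strictly-greater removes)
  za <- c(rep(0, 9), 3)
  expect_true(all(remove_outlier_trials(za, rep(0, 10), threshold = 3)))
})

test_that("Pearson r matches hand-computed values and respects affine invariance", {
  expect_equal(spike_count_correlation(c(1, 2, 3, 4), c(2, 4, 6, 8)), 1)
  expect_equal(spike_count_correlation(c(0, 1, 2), c(2, 1, 0)), -1)
  expect_equal(spike_count_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(spike_count_correlation(c(2, 2, 2), c(1, 2, 3))))
  expect_error(spike_count_correlation(1:3, 1:4))

  x <- withr::with_seed(1, rpois(50, 4))
  y <- withr::with_seed(2, rpois(50, 4)) + x
  expect_equal(spike_count_correlation(2 * x + 7, y),
               spike_count_correlation(x, y))
})

test_that("shuffling destroys trial pairing: null mean ~ 0, SD ~ 1/sqrt(n-1)", {
  cc <- simulate_correlated_counts(400, 4, 1, seed = 3)
  null <- shuffled_null(cc$count_a, cc$count_b, 1000, seed = 4)
  expect_length(null, 1000)
  expect_lt(abs(mean(null)), 0.02)
  expect_equal(sd(null), 1 / sqrt(399), tolerance = 0.1)
  expect_identical(null, shuffled_null(cc$count_a, cc$count_b, 1000, seed = 4))
  expect_length(shuffled_null(cc$count_a, cc$count_b, 0), 0)
})

test_that("tercile partition splits by rank with documented tie handling", {
  expect_equal(tercile_partition(c(-0.2, -0.1, 0, 0.05, 0.1, 0.3)),
               c(1L, 1L, 2L, 2L, 3L, 3L))
  # 7 values: sizes (3, 2, 2), extras to the lower terciles
  lab7 <- tercile_partition(c(5, 1, 4, 2, 7, 3, 6))
  expect_equal(as.integer(table(lab7)), c(3L, 2L, 2L))
  expect_equal(lab7[2], 1L)  # smallest value in tercile 1
  expect_warning(labeq <- tercile_partition(rep(1, 6)), regexp = "equal")
  expect_equal(labeq, c(1L, 1L, 2L, 2L, 3L, 3L))
  expect_error(tercile_partition(c(1, 2)))
  # NA values keep NA labels and do not shift the split
  labna <- tercile_partition(c(1, NA, 2, 3, 4, 5, 6))
  expect_true(is.na(labna[2]))
  expect_equal(as.integer(table(labna)), c(2L, 2L, 2L))
})

test_that("conditioned r_sc recovers the gated common-input targets", {
  sim <- simulate_session(sim_config(
    n_trials = 300,
    acc_pairs = replicate(30, lc_gate_spec(), simplify = FALSE),
    pupil_sample_rate_hz = 50, seed = 7
  ))
  s <- sim$session
  ep <- extract_stable_fixation_epochs(s)
  labs <- partner_trial_groups(s)
  ct <- spike_count_table(s, ep, c(300, 1100), units = region_units(s, "ACC"))
  rec <- conditioned_rsc(ct, labs, pairs = truth_pairs(sim))
  expect_true(all(abs(rec$r) <= 1, na.rm = TRUE))
  expect_true(all(rec$condition %in% c("all", "zero", "nonzero",
                                       "0", "1", "2", "3", "4+")))
  # conditions 'zero' and '0' are the same trial set
  r0 <- rec[rec$condition %in% c("zero", "0"), ]
  expect_equal(r0$r[r0$condition == "zero"], r0$r[r0$condition == "0"])

  d <- rsc_difference(rec)
  d11 <- d[d$bin_size_ms == 1100, ]
  ci <- bootstrap_median_ci(d11$delta_rsc, seed = 1)
  expect_lt(ci$lower, -0.2 + 0.08)
  expect_gt(ci$upper, -0.2 - 0.08)
  # r_sc grows toward the reference-window target with bin size
  d3 <- d[d$bin_size_ms == 300, ]
  expect_lt(median(d3$r_zero, na.rm = TRUE), median(d11$r_zero, na.rm = TRUE))
  # terciles balanced within 1
  tsz <- table(d11$tercile)
  expect_lte(diff(range(tsz)), 1)
})

test_that("conditioned r_sc on shuffled trials is null", {
  sim <- simulate_session(sim_config(
    n_trials = 300,
    acc_pairs = replicate(30, lc_gate_spec(), simplify = FALSE),
    pupil_sample_rate_hz = 50, seed = 13
  ))
  s <- sim$session
  ep <- extract_stable_fixation_epochs(s)
  labs <- partner_trial_groups(s)
  ct <- spike_count_table(s, ep, 1100, units = region_units(s, "ACC"))
  shuf <- shuffle_count_table(ct, seed = 99)
  d <- rsc_difference(conditioned_rsc(shuf, labs, pairs = truth_pairs(sim)))
  ci <- bootstrap_median_ci(d$delta_rsc, seed = 1)
  expect_lte(ci$lower, 0)
  expect_gte(ci$upper, 0)
})

test_that("records flag insufficient trials instead of reporting noisy r", {
  labels <- partition_trials_by_partner(c(0, 0, 0, rep(2, 37)), 1:40)
  ct <- withr::with_seed(5, purrr::map_dfr(c("x", "y"), function(u) {
    tibble::tibble(trial_id = 1:40, unit_id = u, bin_size_ms = 500,
                   count = rpois(40, 4))
  }))
  rec <- conditioned_rsc(ct, labels)
  rz <- rec[rec$condition == "zero", ]
  expect_true(is.na(rz$r))
  expect_equal(rz$n_trials_used, 3L)
})

test_that("delta r_sc relates to rate/Fano differences through the joined tables", {
  sim <- simulate_session(sim_config(
    n_trials = 150, acc_pairs = replicate(10, lc_gate_spec(), simplify = FALSE),
    pupil_sample_rate_hz = 50, seed = 29
  ))
  s <- sim$session
  ep <- extract_stable_fixation_epochs(s)
  labs <- partner_trial_groups(s)
  ct <- spike_count_table(s, ep, 1100, units = region_units(s, "ACC"))
  d <- rsc_difference(conditioned_rsc(ct, labs, pairs = truth_pairs(sim)))
  sd_ <- conditioned_stat_difference(ct, labs)
  rel <- rsc_rate_fano_relation(d, sd_, truth_pairs(sim))
  expect_equal(nrow(rel$relations), 2)
  expect_setequal(rel$relations$measure, c("delta_mean", "delta_fano"))
  expect_equal(nrow(rel$pairs), 10)
})
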