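test_that("per-bin t and p match the textbook t-test to 6 decimals", {
  set.seed(101)
  g <- bin_grid(400, bin_ms = 20)
  n <- 30
  A <- matrix(runif(n * g$n_bins, 0.1, 0.9), n)
  B <- matrix(runif(n * g$n_bins, 0.05, 0.5), n)
  ser <- series_from_matrices(A, B, g)
  for (tail in c("one_sided", "two_sided")) {
    ct <- contrast_spec("CP", "target", "cu_target", g, sub_experiment = "1",
                        tail = tail)
    bt <- bin_tests(ser, ct)
    for (b in seq_len(g$n_bins)) {
      d <- A[, b] - B[, b]
      ref <- t.test(d, alternative = ifelse(tail == "one_sided", "greater",
                                            "two.sided"))
      expect_equal(bt$t[b], unname(ref$statistic), tolerance = 1e-7)
      expect_equal(bt$p[b], ref$p.value, tolerance = 1e-7)
      expect_equal(bt$significant[b],
                   ref$p.value < 0.05 &&
                     (tail == "two_sided" || mean(d) > 0))
    }
  }
})

test_that("degenerate bins follow the limiting t-test verdict", {
  g <- bin_grid(60, bin_ms = 20)
  # bin 1: constant +0.3; bin 2: constant 0; bin 3: constant -0.3
  A <- matrix(rep(c(0.55, 0.25, 0.1), each = 5), 5)
  B <- matrix(0.25, 5, 3)
  bt <- bin_tests(series_from_matrices(A, B, g),
                  contrast_spec("CP", "target", "cu_target", g,
                                sub_experiment = "1"))
  expect_equal(bt$significant, c(TRUE, FALSE, FALSE))
  expect_equal(bt$p[1], 0)
  # fewer than two participants with data is never significant
  A2 <- matrix(c(0.9, NA, NA, NA, NA, 0.9, 0.8, 0.7, 0.9, 0.8), 5)
  bt2 <- bin_tests(series_from_matrices(A2, B[, 1:2], bin_grid(40, 20)),
                   contrast_spec("CP", "target", "cu_target",
                                 bin_grid(40, 20), sub_experiment = "1"))
  expect_false(bt2$significant[1])
  expect_true(is.na(bt2$t[1]))
})

test_that("onset detection finds the first sustained run", {
  g <- bin_grid(3900, bin_ms = 20)  # 195 bins
  flags <- rep(FALSE, g$n_bins)
  expect_true(is.na(detect_onset(flags, g)))
  flags[37:g$n_bins] <- TRUE  # significant from bin index 36 (0-based)
  expect_equal(detect_onset(flags, g), 720)
  # a run of 9 does not qualify under the 10-bin criterion
  f9 <- rep(FALSE, g$n_bins)
  f9[20:28] <- TRUE
  expect_true(is.na(detect_onset(f9, g)))
  expect_equal(detect_onset(f9, g, consec_bins = 9), bin_starts(g)[20])
})

test_that("onset detection equals the exhaustive window scan on random flags", {
  set.seed(202)
  g <- bin_grid(1200, bin_ms = 20)  # 60 bins
  starts <- bin_starts(g)
  for (i in 1:1000) {
    flags <- runif(g$n_bins) < runif(1, 0.2, 0.9)
    k <- sample(1:12, 1)
    expect_identical(detect_onset(flags, g, consec_bins = k),
                     onset_scan(flags, starts, k))
  }
})

test_that("longer run criteria never move the onset earlier", {
  set.seed(303)
  g <- bin_grid(1200, bin_ms = 20)
  for (i in 1:50) {
    flags <- runif(g$n_bins) < 0.6
    onsets <- sapply(1:15, function(k) detect_onset(flags, g, consec_bins = k))
    onsets <- onsets[!is.na(onsets)]
    expect_true(all(diff(onsets) >= 0))
  }
})

test_that("a deterministic cohort bootstraps to a point distribution", {
  g <- default_grid()
  ser <- deterministic_series(12, g, onset_bin = 40)
  ct <- contrast_spec("CP", "target", "cu_target", g, sub_experiment = "1")
  est <- bootstrap_dp(ser, ct, n_boot = 100, seed = 9, group = "G")
  expect_equal(est$observed_dp_ms, 800)
  expect_equal(est$n_convergent, 100L)
  expect_true(all(est$boot_dps_ms == 800))
  expect_equal(est$boot_mean_ms, 800)
  expect_equal(c(est$ci_low_ms, est$ci_high_ms), c(800, 800))
})

test_that("bootstrap results are reproducible and bin-aligned", {
  coh <- tiny_cohort(n = 8, n_items = 6, seed = 31)
  g <- default_grid()
  ser <- preprocess_cohort(coh$samples, coh$trials, grid = g)
  ct <- contrast_spec("CP", "target", "cu_target", g, sub_experiment = "1")
  e1 <- bootstrap_dp(ser, ct, n_boot = 60, seed = 4, group = "G1")
  e2 <- bootstrap_dp(ser, ct, n_boot = 60, seed = 4, group = "G1")
  expect_identical(e1$boot_all_ms, e2$boot_all_ms)
  # different master seed, different resamples
  e3 <- bootstrap_dp(ser, ct, n_boot = 60, seed = 5, group = "G1")
  expect_false(identical(e1$boot_all_ms, e3$boot_all_ms))
  # DPs live on the bin grid; the mean may be fractional
  expect_true(all(e1$boot_dps_ms %% g$bin_ms == 0))
  expect_true(all(e1$boot_dps_ms >= g$window_start_ms &
                    e1$boot_dps_ms < g$window_end_ms))
  expect_equal(e1$boot_mean_ms, mean(e1$boot_dps_ms))
  expect_lte(e1$ci_low_ms, e1$ci_high_ms)
})

test_that("a flat cohort yields no convergent resamples, reported not hidden", {
  g <- bin_grid(400, bin_ms = 20)
  A <- matrix(0.25, 6, g$n_bins)
  ser <- series_from_matrices(A, A, g)
  ct <- contrast_spec("CP", "target", "cu_target", g, sub_experiment = "1")
  expect_warning(
    est <- bootstrap_dp(ser, ct, n_boot = 30, seed = 1, group = "flat"),
    "no convergent"
  )
  expect_equal(est$n_convergent, 0L)
  expect_true(is.na(est$boot_mean_ms))
})

test_that("group comparison pairs resamples and classifies the CI", {
  g <- default_grid()
  ct <- contrast_spec("CP", "target", "cu_target", g, sub_experiment = "1")
  ser <- deterministic_series(10, g, onset_bin = 40)
  est <- bootstrap_dp(ser, ct, n_boot = 50, seed = 2, group = "A")
  self <- compare_groups(est, est)
  expect_equal(self$mean_diff_ms, 0)
  expect_false(identical(self$classification, "different"))
  # a shifted copy differs by exactly the shift
  ser2 <- deterministic_series(10, g, onset_bin = 50)
  est2 <- bootstrap_dp(ser2, ct, n_boot = 50, seed = 2, group = "B")
  d <- compare_groups(est, est2)
  expect_equal(d$mean_diff_ms, 200)
  expect_equal(d$classification, "different")
  expect_equal(d$n_pairs, 50L)
  # mismatched settings are refused
  est3 <- bootstrap_dp(ser, ct, n_boot = 40, seed = 2, group = "A")
  expect_error(compare_groups(est, est3), "n_boot")
  ct2 <- contrast_spec("CP", "target", "cu_target", g, sub_experiment = "1",
                       alpha = 0.01)
  est4 <- bootstrap_dp(ser, ct2, n_boot = 50, seed = 2, group = "A")
  expect_error(compare_groups(est, est4), "contrast")
})

test_that("CI classification follows the strict-containment convention", {
  expect_equal(classify_difference(-20, 180), "not_different")
  expect_equal(classify_difference(0, 200), "marginal")
  expect_equal(classify_difference(100, 280), "different")
  expect_equal(classify_difference(-120, -20), "different")
  expect_equal(classify_difference(-140, 0), "marginal")
  expect_equal(classify_difference(0, 0), "marginal")
  expect_error(classify_difference(10, -10), "exceed")
})

test_that("groups with distinct true latencies are declared different", {
  g <- default_grid()
  ct <- contrast_spec("CP", "target", "cu_target", g, sub_experiment = "1")
  verdicts <- sapply(1:3, function(i) {
    coh <- simulate_cohort(cohort_spec(
      groups = list(
        list(label = "fast", n_participants = 30, latencies = list(cp = 800)),
        list(label = "slow", n_participants = 30, latencies = list(cp = 1000))
      ),
      n_items = c(cp = 24L), seed = 400 + i
    ))
    ser <- preprocess_cohort(coh$samples, coh$trials, grid = g)
    res <- dpa_by_group(ser, coh$participants, ct, baseline = "fast",
                        n_boot = 100, seed = 400 + i)
    res$differences$slow$classification
  })
  expect_gte(sum(verdicts == "different"), 2)
})
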