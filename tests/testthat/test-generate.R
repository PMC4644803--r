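test_that("array geometry matches the recording layout", {
  g <- map_geometry()
  expect_equal(nrow(g), 128)
  expect_equal(length(unique(g$penetration_id)), 2)
  p1 <- g[g$penetration_id == 1, ]
  expect_equal(diff(sort(unique(p1$x_um))), rep(375, 7))
  expect_equal(diff(sort(unique(p1$y_um))), rep(500, 7))
  expect_false(anyDuplicated(g[, c("x_um", "y_um")]) > 0)
})

test_that("sampled truth tables are deterministic and complete", {
  p <- make_protocol()
  pre <- condition_preset("control")
  t1 <- sample_map(p, pre, seed = 5)
  t2 <- sample_map(p, pre, seed = 5)
  t3 <- sample_map(p, pre, seed = 6)
  expect_identical(t1, t2)
  expect_false(identical(t1, t3))
  expect_equal(nrow(t1), 128)
  expect_error(sample_map(p, pre), "seed")
  resp <- t1[t1$is_responsive, ]
  expect_true(all(resp$true_cf_hz >= 1000 & resp$true_cf_hz <= 70000))
  expect_true(all(resp$true_thr_db %in% p$intensities_db))
  expect_true(all(resp$true_bw10_oct > 0))
})

test_that("a noiseless gradient gives CFs increasing rostro-caudally", {
  p <- make_protocol()
  pre <- condition_preset("control", cf_jitter_oct_sd = 0, hi_freq_bias = 0,
                          p_non_ai = 0)
  tr <- sample_map(p, pre, seed = 1)
  by_x <- tapply(tr$true_cf_hz, tr$x_um, unique)
  expect_true(all(diff(unlist(by_x)) > 0))
  expect_true(all(tr$is_ai))
})

test_that("shape-class and threshold draws match preset probabilities", {
  p <- make_protocol()
  n <- 5000
  for (nm in c("control", "vpa")) {
    pre <- condition_preset(nm)
    tr <- sample_site_truths(n, p, pre, seed = 99)
    probs <- c(single_v = pre$p_single, multi = pre$p_multi,
               flat = pre$p_flat)
    for (cls in names(probs)) {
      k <- sum(tr$true_shape == cls)
      ci <- qbinom(c(0.005, 0.995), n, probs[[cls]])
      expect_gte(k, ci[1])
      expect_lte(k, ci[2])
    }
    k_hi <- sum(tr$true_thr_db > 50)
    ci <- qbinom(c(0.005, 0.995), n, pre$p_thr_above50)
    expect_gte(k_hi, ci[1])
    expect_lte(k_hi, ci[2])
  }
})

test_that("rate surface realizes the analytic tuning-curve geometry", {
  # grid chosen so the BW10 edges fall exactly on tested tones
  p <- make_protocol(frequencies_hz = 1000 * 2^seq(0, 3, by = 0.25),
                     intensities_db = seq(0, 40, 10))
  pre <- condition_preset("custom", evoked_max_hz = 1e6)
  tr <- truth_row(p, cf_idx = which(p$frequencies_hz == 1000 * 2^1.5),
                  thr = 30, bw10 = 1)
  surf <- expected_rate_surface(tr, p, pre)
  i40 <- which(p$intensities_db == 40)
  sup <- which(surf$evoked_hz[, i40] > 0)
  expect_equal(log2(p$frequencies_hz[max(sup)] / p$frequencies_hz[min(sup)]),
               1)  # supra span 10 dB above the tip is exactly BW10
  # nothing below threshold anywhere
  expect_true(all(surf$evoked_hz[, p$intensities_db < 30] == 0))
  # the tip is the arg-min of thr(f): strongest response at the top level
  expect_equal(which.max(surf$evoked_hz[, i40]),
               which(p$frequencies_hz == 1000 * 2^1.5))
  # unresponsive truth: all-baseline surface
  tr$is_responsive <- FALSE
  surf0 <- expected_rate_surface(tr, p, pre)
  expect_true(all(surf0$evoked_hz == 0))
})

test_that("simulated counts are Poisson around the expected surface", {
  p <- make_protocol(frequencies_hz = 1000 * 2^seq(0, 2, by = 0.5),
                     intensities_db = c(20, 40), n_trials = 60)
  pre <- crisp_preset()
  tr <- truth_row(p, cf_idx = 3, thr = 20, bw10 = 1, latency = 10)
  sp <- simulate_site(tr, p, pre, seed = 8)
  surf <- expected_rate_surface(tr, p, pre)
  # total spikes across the whole recording vs its analytic expectation
  bins <- seq(-50, 99)
  prof <- pmax(0, pmin(bins + 1, 10 + 35) - pmax(bins, 10))
  npres <- length(p$frequencies_hz) * length(p$intensities_db) * p$n_trials
  lam <- pre$baseline_rate_hz * 1e-3 * length(bins) * npres +
    sum(surf$evoked_hz) * 1e-3 * sum(prof) * p$n_trials
  expect_lt(abs(sum(sp$count) - lam), 3 * sqrt(lam))
  # determinism and the zero-rate edge case
  expect_identical(sp, simulate_site(tr, p, pre, seed = 8))
  silent <- condition_preset("custom", baseline_rate_hz = 0)
  tr$is_responsive <- FALSE
  expect_equal(nrow(simulate_site(tr, p, silent, seed = 1)), 0)
})

test_that("noise-free estimators recover single-peak truths to grid resolution", {
  p <- make_protocol()
  pre <- crisp_preset()
  step <- log2(70) / 65
  truths <- sample_site_truths(120, p, pre, seed = 31, shape = "single_v",
                               cf_margin_oct = 3, thr_max_db = 60)
  for (i in seq_len(nrow(truths))) {
    tr <- truths[i, ]
    surf <- expected_rate_surface(tr, p, pre)
    fra <- fra_stub(surf$evoked_hz > 0, p)
    ct <- extract_cf_threshold(fra)
    expect_equal(ct$cf_hz, tr$true_cf_hz)
    expect_equal(ct$threshold_db, tr$true_thr_db)
    bw <- compute_bw10(fra, ct$threshold_db)
    # floor-quantized on each side: within one grid step per flank
    expect_lte(tr$true_bw10_oct - bw, 2 * step + 1e-9)
    expect_gte(bw, 0)
  }
})

test_that("cohorts are reproducible and sized by the study design", {
  p <- tiny_protocol()
  g <- map_geometry(n_rows = 3, n_cols = 3, n_penetrations = 2)
  d1 <- generate_cohort(n_control = 2, n_vpa = 1, seed = 4, protocol = p,
                        geometry = g)
  d2 <- generate_cohort(n_control = 2, n_vpa = 1, seed = 4, protocol = p,
                        geometry = g)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$spikes, d2$spikes)
  expect_equal(nrow(d1$sites), 3 * 18)
  expect_equal(unique(table(d1$sites$animal_id)), 18L)
  expect_setequal(unique(d1$sites$group), c("control", "vpa"))
  # a preset with no evoked response at all: the analyzer finds nothing
  dead <- condition_preset("custom", evoked_onset_hz = 0, evoked_gain = 0,
                           baseline_rate_hz = 0.5)
  d3 <- generate_cohort(n_control = 1, n_vpa = 0, seed = 2, protocol = p,
                        geometry = map_geometry(n_rows = 2, n_cols = 2,
                                                n_penetrations = 1),
                        presets = list(control = dead))
  an <- analyze_dataset(d3)
  expect_equal(sum(an$site_metrics$responsive), 0)
})
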