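test_that("FRA significance needs a cluster, not an isolated hot cell", {
  p <- tiny_protocol()
  # no baseline spikes; evoked spikes at three adjacent cells on every trial,
  # plus one isolated noisy cell
  sp <- dplyr::bind_rows(
    spike_rows(p, f_idx = 2, i_idx = 2, trial = c(1, 2), bin_ms = 15, count = 5),
    spike_rows(p, f_idx = 3, i_idx = 2, trial = c(1, 2), bin_ms = 15, count = 5),
    spike_rows(p, f_idx = 4, i_idx = 2, trial = c(1, 2), bin_ms = 15, count = 5),
    spike_rows(p, f_idx = 8, i_idx = 4, trial = 1, bin_ms = 20, count = 5))
  fra <- build_fra(sp, p)
  expect_true(all(fra$sig_mask[2:4, 2]))
  expect_false(fra$sig_mask[8, 4])
  expect_equal(sum(fra$sig_mask), 3)
  expect_true(all(fra$evoked[fra$sig_mask] > 0))
  expect_equal(fra$baseline_mean, 0)
})

test_that("a baseline-only recording yields an empty mask", {
  p <- tiny_protocol()
  pre <- condition_preset("custom", baseline_rate_hz = 5)
  tr <- truth_row(p, responsive = FALSE)
  fra <- build_fra(simulate_site(tr, p, pre, seed = 3), p)
  expect_equal(sum(fra$sig_mask), 0)
  m <- analyze_site(simulate_site(tr, p, pre, seed = 3), p)
  expect_false(m$responsive)
  expect_true(is.na(m$cf_hz) && is.na(m$threshold_db) && is.na(m$bw10_oct))
})

test_that("a strongly driven v-shaped site yields a contiguous V mask", {
  p <- make_protocol()
  pre <- crisp_preset()
  tr <- truth_row(p, cf_idx = 33, thr = 20, bw10 = 1.24, latency = 12)
  fra <- build_fra(simulate_site(tr, p, pre, seed = 12), p)
  surf <- expected_rate_surface(tr, p, pre)
  expect_equal(fra$sig_mask, surf$evoked_hz > 0)
  # every intensity row of the V is a single contiguous frequency run
  for (i in which(colSums(fra$sig_mask) > 0)) {
    rows <- which(fra$sig_mask[, i])
    expect_true(all(diff(rows) == 1))
  }
})

test_that("CF sits at the tuning-curve tip, with the flat-tip median rule", {
  p <- tiny_protocol()
  # single cell at (4, 3) with support above
  fra <- fra_stub(mask_at(p, list(c(4, 3), c(3, 4), c(4, 4), c(5, 4))), p)
  ct <- extract_cf_threshold(fra)
  expect_equal(ct$cf_hz, p$frequencies_hz[4])
  expect_equal(ct$threshold_db, p$intensities_db[3])
  # five significant cells at the minimal intensity: the median (middle) one
  fra <- fra_stub(mask_at(p, lapply(3:7, function(f) c(f, 2))), p)
  expect_equal(extract_cf_threshold(fra)$cf_hz, p$frequencies_hz[5])
  # even count: lower median
  fra <- fra_stub(mask_at(p, lapply(3:6, function(f) c(f, 2))), p)
  expect_equal(extract_cf_threshold(fra)$cf_hz, p$frequencies_hz[4])
  # two apexes with different thresholds: the lower-threshold apex wins
  fra <- fra_stub(mask_at(p, list(c(2, 3), c(8, 2), c(8, 3))), p)
  ct <- extract_cf_threshold(fra)
  expect_equal(ct$cf_hz, p$frequencies_hz[8])
  expect_equal(ct$threshold_db, p$intensities_db[2])
  # tie at threshold: lower-frequency run
  fra <- fra_stub(mask_at(p, list(c(2, 2), c(8, 2))), p)
  expect_equal(extract_cf_threshold(fra)$cf_hz, p$frequencies_hz[2])
  # empty mask: undefined
  ct <- extract_cf_threshold(fra_stub(mask_at(p, list()), p))
  expect_true(is.na(ct$cf_hz) && is.na(ct$threshold_db))
})

test_that("BW10 is the octave span of the row 10 dB above threshold", {
  p <- make_protocol(
    frequencies_hz = c(4000, 4000 * 2^0.5, 8000, 8000 * 2^0.5, 16000),
    intensities_db = seq(0, 40, 10))
  # significant from 5.66 to 11.3 kHz at threshold + 10
  fra <- fra_stub(mask_at(p, list(c(3, 2), c(2, 3), c(3, 3), c(4, 3))), p)
  expect_equal(compute_bw10(fra, 10), 1.0)
  # single cell in the row: zero bandwidth
  fra <- fra_stub(mask_at(p, list(c(3, 2), c(3, 3))), p)
  expect_equal(compute_bw10(fra, 10), 0)
  # full default-protocol row spans log2(70) octaves
  pd <- make_protocol()
  m <- matrix(FALSE, 66, 8); m[, 2] <- TRUE; m[30, 1] <- TRUE
  expect_equal(compute_bw10(fra_stub(m, pd), 0), log2(70))
  # threshold at the top intensity: undefined
  m2 <- matrix(FALSE, 66, 8); m2[30, 8] <- TRUE
  expect_true(is.na(compute_bw10(fra_stub(m2, pd), 70)))
  expect_true(is.na(compute_bw10(fra_stub(m2, pd), NA_real_)))
})

test_that("irregularity index matches hand-computed autocorrelation terms", {
  one <- irregularity_index(matrix(TRUE, 1, 1))
  expect_equal(one$c00, 1)
  expect_equal(one$index, 1 - 3)
  sq <- irregularity_index(matrix(TRUE, 2, 2))
  expect_equal(c(sq$c00, sq$c10, sq$c01), c(4, 2, 2))
  expect_equal(sq$index, (4 - 2) / 2 - 3)
  diagm <- irregularity_index(diag(2) > 0)
  expect_equal(diagm$index, 2 / sqrt(2) - 3)  # scattered beats compact
  expect_gt(diagm$index, sq$index)
  expect_true(is.na(irregularity_index(matrix(FALSE, 3, 3))$index))
  # invariant to padding with unresponsive rows/columns
  m <- matrix(FALSE, 6, 6); m[2:3, 2:4] <- TRUE
  padded <- matrix(FALSE, 10, 9); padded[4:5, 3:5] <- TRUE
  expect_equal(irregularity_index(m)$index, irregularity_index(padded)$index)
  # mask terms obey c00 >= c10, c01 >= 0
  expect_true(with(irregularity_index(m), c00 >= c10 && c10 >= 0 &&
                     c00 >= c01 && c01 >= 0))
})

test_that("latency is the first sustained 4-SD crossing of the pooled PSTH", {
  # single-presentation protocol so the PSTH equals the raw counts
  p <- make_protocol(frequencies_hz = c(1000), intensities_db = 70,
                     n_trials = 1)
  base <- spike_rows(p, 1, 1, 1, bin_ms = -50:-2, count = 1)  # one quiet bin
  crit <- mean(c(rep(1, 49), 0)) + 4 * sd(c(rep(1, 49), 0))
  evoked <- spike_rows(p, 1, 1, 1, bin_ms = c(12, 15, 16), count = 2)
  expect_gt(2, crit)  # the evoked bins do cross
  lat <- estimate_latency(dplyr::bind_rows(base, evoked), p, threshold_db = 70)
  # bin 12 crosses alone (run of 1); bins 15,16 are the first sustained run
  expect_equal(lat, 15)
  expect_equal(estimate_latency(dplyr::bind_rows(
    base, spike_rows(p, 1, 1, 1, bin_ms = 12, count = 2)), p, 70),
    NA_real_)
  # flat recording: undefined
  expect_true(is.na(estimate_latency(base, p, threshold_db = 70)))
  expect_true(is.na(estimate_latency(base, p, threshold_db = NA_real_)))
})

test_that("latency estimation is translation-equivariant", {
  p <- make_protocol()
  pre <- crisp_preset()
  for (L in c(9.4, 12)) {
    t1 <- truth_row(p, cf_idx = 30, thr = 20, latency = L)
    t2 <- truth_row(p, cf_idx = 30, thr = 20, latency = L + 5)
    m1 <- analyze_site(simulate_site(t1, p, pre, seed = 77), p)
    m2 <- analyze_site(simulate_site(t2, p, pre, seed = 77), p)
    expect_equal(m2$latency_ms - m1$latency_ms, 5)
  }
})

test_that("latency recovery: cohort mean lands within 1 ms of the truth", {
  p <- make_protocol()
  pre <- crisp_preset()
  truths <- sample_site_truths(40, p, pre, seed = 15, shape = "single_v",
                               latency_ms = 14.97, cf_margin_oct = 1,
                               thr_max_db = 60)
  lat <- vapply(seq_len(nrow(truths)), function(i) {
    sp <- simulate_site(truths[i, ], p, pre, seed = 400 + i)
    fra <- build_fra(sp, p)
    estimate_latency(sp, p, extract_cf_threshold(fra)$threshold_db)
  }, numeric(1))
  expect_lt(abs(mean(lat, na.rm = TRUE) - 14.97), 1)
})

test_that("shape classification follows the apex and plateau rules", {
  p <- make_protocol()
  pre <- crisp_preset()
  for (sh in c("single_v", "multi", "flat")) {
    tr <- truth_row(p, cf_idx = 28, thr = 30, bw10 = 1.3, shape = sh)
    fra <- build_fra(simulate_site(tr, p, pre, seed = 50), p)
    expect_equal(classify_shape(fra), sh)
  }
  # constant threshold across ~2 octaves: flat by the plateau rule
  m <- matrix(FALSE, 66, 8)
  m[20:41, 4:8] <- TRUE
  expect_equal(classify_shape(fra_stub(m, p)), "flat")
  expect_true(is.na(classify_shape(fra_stub(matrix(FALSE, 66, 8), p))))
})

test_that("shape classifier accuracy exceeds 90% at default SNR", {
  p <- make_protocol()
  pre <- condition_preset("control")
  truths <- sample_site_truths(150, p, pre, seed = 61, cf_margin_oct = 0.5)
  hit <- vapply(seq_len(nrow(truths)), function(i) {
    fra <- build_fra(simulate_site(truths[i, ], p, pre, seed = 500 + i), p)
    identical(classify_shape(fra), truths$true_shape[i])
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})
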