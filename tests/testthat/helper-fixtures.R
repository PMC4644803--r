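# Small fixtures shared across test files. Everything is built in code.

# compact protocol: 10 tones over 3 octaves, 5 intensities, 2 trials
tiny_protocol <- function() {
  make_protocol(frequencies_hz = 1000 * 2^seq(0, 3, length.out = 10),
                intensities_db = seq(0, 40, 10), n_trials = 2)
}

# an FRA object built directly from a significance mask, for estimator tests
fra_stub <- function(mask, protocol = make_protocol()) {
  stopifnot(nrow(mask) == length(protocol$frequencies_hz),
            ncol(mask) == length(protocol$intensities_db))
  structure(list(
    evoked = mask * 5,
    sig_mask = mask,
    baseline_mean = 0,
    baseline_sd = 0,
    resp_total = mask * 15,
    n_resp_bins = 45,
    frequencies_hz = protocol$frequencies_hz,
    intensities_db = protocol$intensities_db,
    n_trials = protocol$n_trials
  ), class = "fra")
}

mask_at <- function(protocol, cells) {
  m <- matrix(FALSE, length(protocol$frequencies_hz),
              length(protocol$intensities_db))
  for (cl in cells) m[cl[1], cl[2]] <- TRUE
  m
}

# long spike rows for hand-built recordings
spike_rows <- function(protocol, f_idx, i_idx, trial, bin_ms, count = 1,
                       site_id = "s001") {
  tibble::tibble(site_id = site_id,
                 freq_hz = protocol$frequencies_hz[f_idx],
                 intensity_db = protocol$intensities_db[i_idx],
                 trial = as.integer(trial), bin_ms = bin_ms,
                 count = as.integer(count))
}

# one-row truth list for simulator-driven tests
truth_row <- function(protocol, cf_idx = 30, thr = 30, bw10 = 1.24,
                      latency = 12, shape = "single_v", responsive = TRUE,
                      site_id = "s001") {
  list(site_id = site_id, is_responsive = responsive,
       true_cf_hz = protocol$frequencies_hz[cf_idx], true_thr_db = thr,
       true_bw10_oct = bw10, true_latency_ms = latency, true_shape = shape)
}

# high-SNR preset used where estimators are tested against exact truths
crisp_preset <- function(name = "control", ...) {
  condition_preset(name, evoked_onset_hz = 100, evoked_gain = 10, ...)
}
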