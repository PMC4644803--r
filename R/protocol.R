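#' Construct a tone-pip stimulus protocol
#'
#' Defines the frequency x intensity x trial grid of pure-tone pips shared by
#' the simulator and all analyzers. The default protocol is the classic AI
#' mapping design: 66 tone frequencies spanning 1--70 kHz (geometric spacing,
#' approximately 0.094 octave steps), eight sound intensities from 0 to 70 dB
#' SPL in 10-dB increments, three trials per tone-level pair, 25-ms tones with
#' 5-ms ramps delivered at 2 stimuli per second, and 1-ms PSTH bins.
#'
#' @param frequencies_hz Strictly increasing vector of tone frequencies (Hz).
#'   Defaults to `n_freq` geometrically spaced tones over `freq_range_hz`.
#' @param intensities_db Strictly increasing vector of sound levels (dB SPL).
#' @param n_freq Number of default frequencies when `frequencies_hz` is NULL.
#' @param freq_range_hz Length-2 range (Hz) for the default frequency grid.
#' @param n_trials Trials per frequency-intensity pair (>= 1).
#' @param tone_ms Tone duration (ms).
#' @param ramp_ms Onset/offset ramp duration (ms).
#' @param isi_ms Stimulus period (ms); must be a multiple of `bin_ms`.
#' @param bin_ms PSTH bin width (ms).
#'
#' @return An object of class `stim_protocol`: a validated list with the
#'   fields above plus a format `version` string.
#' @examples
#' p <- make_protocol()
#' length(p$frequencies_hz) # 66
#' range(p$frequencies_hz)  # 1000 70000
#' @export
make_protocol <- function(frequencies_hz = NULL, intensities_db = NULL,
                          n_freq = 66, freq_range_hz = c(1000, 70000),
                          n_trials = 3, tone_ms = 25, ramp_ms = 5,
                          isi_ms = 500, bin_ms = 1) {
  if (is.null(frequencies_hz)) {
    frequencies_hz <- 2^seq(log2(freq_range_hz[1]), log2(freq_range_hz[2]),
                            length.out = n_freq)
    # pin the endpoints exactly
    frequencies_hz[1] <- freq_range_hz[1]
    frequencies_hz[n_freq] <- freq_range_hz[2]
  }
  if (is.null(intensities_db)) intensities_db <- seq(0, 70, by = 10)
  p <- structure(list(
    frequencies_hz = as.numeric(frequencies_hz),
    intensities_db = as.numeric(intensities_db),
    n_trials = as.integer(n_trials),
    tone_ms = as.numeric(tone_ms),
    ramp_ms = as.numeric(ramp_ms),
    isi_ms = as.numeric(isi_ms),
    bin_ms = as.numeric(bin_ms),
    version = "1.0"
  ), class = "stim_protocol")
  validate_protocol(p)
  p
}

validate_protocol <- function(p) {
  stopifnot(inherits(p, "stim_protocol"))
  chk_increasing <- function(x, nm) {
    if (length(x) < 1 || anyNA(x) || !is.numeric(x))
      stop(nm, " must be a non-empty numeric vector", call. = FALSE)
    if (length(x) > 1 && any(diff(x) <= 0))
      stop(nm, " must be strictly increasing", call. = FALSE)
  }
  chk_increasing(p$frequencies_hz, "frequencies_hz")
  chk_increasing(p$intensities_db, "intensities_db")
  if (any(p$frequencies_hz <= 0))
    stop("frequencies_hz must be positive", call. = FALSE)
  if (is.na(p$n_trials) || p$n_trials < 1L)
    stop("n_trials must be >= 1", call. = FALSE)
  for (nm in c("tone_ms", "isi_ms", "bin_ms"))
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop(nm, " must be positive", call. = FALSE)
  if (!is.finite(p$ramp_ms) || p$ramp_ms < 0)
    stop("ramp_ms must be >= 0", call. = FALSE)
  if (p$isi_ms < p$tone_ms)
    stop("isi_ms must be at least tone_ms", call. = FALSE)
  if (abs(p$isi_ms / p$bin_ms - round(p$isi_ms / p$bin_ms)) > 1e-9)
    stop("bin_ms must divide isi_ms", call. = FALSE)
  invisible(p)
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(
    "<stim_protocol> %d frequencies %.3g-%.3g kHz, %d intensities %g-%g dB SPL, %d trials\n",
    length(x$frequencies_hz), min(x$frequencies_hz) / 1000,
    max(x$frequencies_hz) / 1000, length(x$intensities_db),
    min(x$intensities_db), max(x$intensities_db), x$n_trials))
  cat(sprintf("  tone %g ms (ramps %g ms), period %g ms, bins %g ms\n",
              x$tone_ms, x$ramp_ms, x$isi_ms, x$bin_ms))
  invisible(x)
}

n_presentations <- function(protocol) {
  length(protocol$frequencies_hz) * length(protocol$intensities_db) *
    protocol$n_trials
}

# nearest grid value (log spacing for frequencies)
snap_to_freq_grid <- function(f_hz, protocol) {
  lg <- log2(protocol$frequencies_hz)
  protocol$frequencies_hz[
    vapply(log2(f_hz), function(v) which.min(abs(lg - v)), integer(1))]
}

snap_to_intensity_grid <- function(db, protocol) {
  g <- protocol$intensities_db
  g[vapply(db, function(v) which.min(abs(g - v)), integer(1))]
}
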