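#' Condition presets for the synthetic cohort generator
#'
#' A `condition_preset` bundles the site-level receptive-field statistics that
#' the generator draws from: the spread of characteristic frequencies (CF)
#' around the smooth rostro-caudal gradient, the distributions of true BW10,
#' intensity threshold and onset latency, the tuning-curve shape-class mixture,
#' and the firing-rate model parameters. Two presets ship with the package:
#'
#' * `"control"` encodes a well-ordered AI: mean BW10 1.24 octaves, mean onset
#'   latency 14.97 ms, 93.47% single-peaked (v-shaped) sites, and roughly 10%
#'   of sites with intensity threshold above 50 dB SPL.
#' * `"vpa"` encodes the disorganized AI of rats prenatally exposed to
#'   valproic acid: mean BW10 3.02 octaves, mean latency 10.27 ms, 76.25%
#'   single-peaked sites, roughly 37.6% high-threshold sites, a larger CF
#'   jitter around the tonotopic gradient and a stronger bias of CFs into the
#'   10--50 kHz band.
#'
#' Thresholds are drawn from a normal distribution and rounded to the tested
#' 10-dB intensity grid; `thr_mean_db` is calibrated per preset so that the
#' probability that a rounded draw exceeds 50 dB equals `p_thr_above50`
#' (i.e. `thr_mean_db = 55 - qnorm(1 - p_thr_above50) * thr_sd_db`).
#'
#' @param name `"control"`, `"vpa"`, or `"custom"`.
#' @param ... Named overrides of any preset field (see Details). Fields:
#'   `cf_jitter_oct_sd` (octaves), `bw10_mean_oct`, `bw10_sd_oct`,
#'   `thr_mean_db`, `thr_sd_db`, `p_thr_above50`, `latency_mean_ms`,
#'   `latency_sd_ms`, `p_single`, `p_multi`, `p_flat`, `baseline_rate_hz`,
#'   `evoked_gain` (Hz per dB above threshold), `evoked_onset_hz` (rate step
#'   at threshold), `evoked_max_hz` (saturation cap), `hi_freq_bias`
#'   (probability that a site's CF is resampled uniformly, in log frequency,
#'   from the 10--50 kHz band), `p_non_ai` (fraction of border sites marked
#'   outside AI).
#'
#' @return An object of class `condition_preset`.
#' @examples
#' condition_preset("control")$bw10_mean_oct # 1.24
#' condition_preset("vpa", cf_jitter_oct_sd = 0.6)
#' @export
condition_preset <- function(name = c("custom", "control", "vpa"), ...) {
  name <- match.arg(name)
  base <- list(
    name = name,
    cf_jitter_oct_sd = 0.4,
    bw10_mean_oct = 1.24, bw10_sd_oct = 0.25,
    thr_mean_db = 35.8, thr_sd_db = 15, p_thr_above50 = 0.0999,
    latency_mean_ms = 14.97, latency_sd_ms = 1.5,
    p_single = 0.9347, p_multi = 0.0392, p_flat = 0.0261,
    baseline_rate_hz = 2,
    evoked_gain = 4, evoked_onset_hz = 60, evoked_max_hz = 100,
    hi_freq_bias = 0.135,
    p_non_ai = 0.15
  )
  if (name == "vpa") {
    base[c("cf_jitter_oct_sd", "bw10_mean_oct", "bw10_sd_oct",
           "thr_mean_db", "p_thr_above50",
           "latency_mean_ms", "p_single", "p_multi", "p_flat",
           "hi_freq_bias")] <-
      list(1.0, 3.02, 0.6, 50.3, 0.3758, 10.27, 0.7625, 0.1425, 0.095, 0.36)
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(base))
  if (length(unknown))
    stop("unknown preset field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  base[names(dots)] <- dots
  preset <- structure(base, class = "condition_preset")
  validate_preset(preset)
  preset
}

validate_preset <- function(x) {
  stopifnot(inherits(x, "condition_preset"))
  for (nm in c("cf_jitter_oct_sd", "bw10_sd_oct", "thr_sd_db", "latency_sd_ms"))
    if (!is.finite(x[[nm]]) || x[[nm]] < 0)
      stop(nm, " must be a nonnegative number", call. = FALSE)
  probs <- c(x$p_single, x$p_multi, x$p_flat)
  if (any(probs < 0 | probs > 1))
    stop("shape-class probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(sum(probs) - 1) > 1e-9)
    stop("p_single + p_multi + p_flat must sum to 1", call. = FALSE)
  for (nm in c("p_thr_above50", "hi_freq_bias", "p_non_ai"))
    if (x[[nm]] < 0 || x[[nm]] > 1)
      stop(nm, " must lie in [0, 1]", call. = FALSE)
  for (nm in c("baseline_rate_hz", "evoked_gain", "evoked_onset_hz",
               "evoked_max_hz", "bw10_mean_oct", "latency_mean_ms"))
    if (!is.finite(x[[nm]]) || x[[nm]] < 0)
      stop(nm, " must be a nonnegative number", call. = FALSE)
  invisible(x)
}

#' @export
print.condition_preset <- function(x, ...) {
  cat(sprintf("<condition_preset> '%s'\n", x$name))
  cat(sprintf("  CF jitter %.2f oct; BW10 %.2f +/- %.2f oct; thr %.1f +/- %.1f dB (P>50dB = %.3f)\n",
              x$cf_jitter_oct_sd, x$bw10_mean_oct, x$bw10_sd_oct,
              x$thr_mean_db, x$thr_sd_db, x$p_thr_above50))
  cat(sprintf("  latency %.2f +/- %.2f ms; shapes single/multi/flat = %.3f/%.3f/%.3f\n",
              x$latency_mean_ms, x$latency_sd_ms,
              x$p_single, x$p_multi, x$p_flat))
  invisible(x)
}
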