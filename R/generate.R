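#' Electrode-array geometry for one animal
#'
#' Builds the recording-site coordinate table for one animal: `n_penetrations`
#' placements of an `n_rows` x `n_cols` microelectrode array with 375 um
#' between columns and 500 um between rows (the 8 x 8 array used for AI
#' mapping; two penetrations give the standard 128 sites per animal).
#' Penetrations are laid side by side along the rostro-caudal (x) axis.
#'
#' @param n_rows,n_cols Array dimensions.
#' @param col_pitch_um,row_pitch_um Electrode spacing (um).
#' @param n_penetrations Array placements per animal.
#' @return A tibble with `site_id`, `penetration_id`, `grid_row`, `grid_col`,
#'   `x_um`, `y_um`.
#' @examples
#' nrow(map_geometry()) # 128
#' @export
map_geometry <- function(n_rows = 8, n_cols = 8, col_pitch_um = 375,
                         row_pitch_um = 500, n_penetrations = 2) {
  stopifnot(n_rows >= 1, n_cols >= 1, n_penetrations >= 1,
            col_pitch_um > 0, row_pitch_um > 0)
  per_pen <- n_rows * n_cols
  pen <- rep(seq_len(n_penetrations), each = per_pen)
  col <- rep(rep(seq_len(n_cols), each = n_rows), n_penetrations)
  row <- rep(rep(seq_len(n_rows), n_cols), n_penetrations)
  tibble::tibble(
    site_id = sprintf("s%03d", seq_along(pen)),
    penetration_id = pen,
    grid_row = row,
    grid_col = col,
    x_um = ((pen - 1) * n_cols + (col - 1)) * col_pitch_um,
    y_um = (row - 1) * row_pitch_um
  )
}

# deterministic 32-bit child seed from (master, animal index, site index)
child_seed <- function(master, animal = 0L, site = 0L) {
  m <- 2147483647
  s <- (as.numeric(master) %% m) * 48271 %% m
  s <- (s + as.numeric(animal) * 1299721 + as.numeric(site) * 7919) %% m
  as.integer(s)
}

#' Sample ground-truth receptive-field parameters for one cortical map
#'
#' Draws, for every electrode position, the "true" receptive-field parameters
#' that the spike simulator will realize: CF placed on a rostro-caudal
#' log-frequency gradient with Gaussian jitter (optionally resampled into the
#' 10--50 kHz band with probability `hi_freq_bias`), intensity threshold on
#' the tested 10-dB grid, BW10, onset latency, and tuning-curve shape class.
#' A fraction `p_non_ai` of border-ring sites is marked outside AI, split
#' between high-threshold-only sites (responsive only at 60--70 dB SPL) and
#' unresponsive sites, mimicking the response phenomenology of the fields
#' surrounding AI.
#'
#' @param protocol A [make_protocol()] object.
#' @param preset A [condition_preset()].
#' @param geometry A [map_geometry()] tibble.
#' @param gradient_oct_per_mm Tonotopic gradient steepness (octaves/mm).
#'   Default spans the full protocol frequency range over the map extent.
#' @param seed Integer seed (required; the truth table is fully reproducible).
#' @return A tibble: geometry columns plus `true_cf_hz`, `true_thr_db`,
#'   `true_bw10_oct`, `true_latency_ms`, `true_shape`, `is_ai`,
#'   `is_responsive`. True CFs are snapped to the protocol frequency grid
#'   and thresholds to the intensity grid.
#' @examples
#' truth <- sample_map(make_protocol(), condition_preset("control"), seed = 1)
#' nrow(truth) # 128
#' @export
sample_map <- function(protocol, preset, geometry = map_geometry(),
                       gradient_oct_per_mm = NULL, seed) {
  validate_protocol(protocol)
  validate_preset(preset)
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  n <- nrow(geometry)
  fmin <- min(protocol$frequencies_hz)
  fmax <- max(protocol$frequencies_hz)
  x_mm <- (geometry$x_um - min(geometry$x_um)) / 1000
  extent <- max(x_mm)
  if (is.null(gradient_oct_per_mm)) {
    if (extent <= 0) stop("map has zero rostro-caudal extent; give gradient_oct_per_mm",
                          call. = FALSE)
    gradient_oct_per_mm <- log2(fmax / fmin) / extent
  }
  if (gradient_oct_per_mm <= 0)
    stop("gradient_oct_per_mm must be > 0", call. = FALSE)

  # CF: smooth gradient + jitter, with optional high-frequency resampling
  cf_oct <- gradient_oct_per_mm * x_mm +
    rnorm(n, 0, preset$cf_jitter_oct_sd)
  hi <- runif(n) < preset$hi_freq_bias
  if (any(hi)) {
    lo_oct <- log2(10000 / fmin)
    hi_oct <- log2(50000 / fmin)
    cf_oct[hi] <- runif(sum(hi), lo_oct, hi_oct)
  }
  cf_hz <- fmin * 2^cf_oct
  cf_hz <- pmin(pmax(cf_hz, fmin), fmax)
  cf_hz <- snap_to_freq_grid(cf_hz, protocol)

  thr <- rnorm(n, preset$thr_mean_db, preset$thr_sd_db)
  thr <- snap_to_intensity_grid(
    pmin(pmax(thr, min(protocol$intensities_db)), max(protocol$intensities_db)),
    protocol)
  bw10 <- pmin(pmax(rnorm(n, preset$bw10_mean_oct, preset$bw10_sd_oct), 0.3), 5.5)
  lat <- pmin(pmax(rnorm(n, preset$latency_mean_ms, preset$latency_sd_ms), 6), 40)
  shape <- sample(c("single_v", "multi", "flat"), n, replace = TRUE,
                  prob = c(preset$p_single, preset$p_multi, preset$p_flat))

  is_ai <- rep(TRUE, n)
  is_responsive <- rep(TRUE, n)
  border <- geometry$grid_row %in% range(geometry$grid_row) |
    geometry$grid_col %in% range(geometry$grid_col)
  k <- round(preset$p_non_ai * n)
  if (k > 0) {
    pick <- sample(which(border), min(k, sum(border)))
    is_ai[pick] <- FALSE
    half <- length(pick) %/% 2
    hi_thr_sites <- pick[seq_len(half)]
    unresp_sites <- setdiff(pick, hi_thr_sites)
    # high-threshold-only surround sites respond only at the top two levels
    top2 <- tail(protocol$intensities_db, 2)
    thr[hi_thr_sites] <- sample(top2, length(hi_thr_sites), replace = TRUE)
    is_responsive[unresp_sites] <- FALSE
  }
  truth <- geometry
  truth$true_cf_hz <- ifelse(is_responsive, cf_hz, NA_real_)
  truth$true_thr_db <- ifelse(is_responsive, thr, NA_real_)
  truth$true_bw10_oct <- ifelse(is_responsive, bw10, NA_real_)
  truth$true_latency_ms <- ifelse(is_responsive, lat, NA_real_)
  truth$true_shape <- ifelse(is_responsive, shape, NA_character_)
  truth$is_ai <- is_ai
  truth$is_responsive <- is_responsive
  truth
}

#' Sample standalone site truths for parameter-recovery experiments
#'
#' Draws ground-truth receptive-field parameters for `n` sites without any
#' map geometry -- the input for estimator-recovery studies where a known
#' parameter is fixed and the rest are drawn from a condition preset. CFs
#' are sampled uniformly from the protocol frequency grid, optionally
#' keeping `cf_margin_oct` octaves clear of both grid edges so that a
#' bandwidth of interest fits inside the tested range (a receptive field
#' extending past the tested frequencies has a censored, not estimable,
#' bandwidth).
#'
#' @inheritParams sample_map
#' @param n Number of sites.
#' @param shape Fix the tuning-curve shape class (otherwise drawn from the
#'   preset mixture).
#' @param bw10_oct,latency_ms Fix the true BW10 or latency (otherwise drawn
#'   from the preset distributions).
#' @param cf_margin_oct Minimum distance (octaves) of sampled CFs from the
#'   frequency-grid edges.
#' @param thr_max_db Cap on sampled thresholds (e.g. the highest tested
#'   intensity minus 10 dB when BW10 must be defined for every site).
#' @return A truth tibble with `site_id` and the `true_*` columns of
#'   [sample_map()]; all sites responsive.
#' @export
sample_site_truths <- function(n, protocol, preset, seed,
                               shape = NULL, bw10_oct = NULL,
                               latency_ms = NULL, cf_margin_oct = 0,
                               thr_max_db = NULL) {
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  f <- protocol$frequencies_hz
  oct <- log2(f / f[1])
  ok <- oct >= cf_margin_oct & oct <= max(oct) - cf_margin_oct
  if (!any(ok)) stop("cf_margin_oct leaves no admissible frequencies",
                     call. = FALSE)
  if (is.null(thr_max_db)) thr_max_db <- max(protocol$intensities_db)
  thr <- rnorm(n, preset$thr_mean_db, preset$thr_sd_db)
  thr <- snap_to_intensity_grid(
    pmin(pmax(thr, min(protocol$intensities_db)), max(protocol$intensities_db)),
    protocol)
  tibble::tibble(
    site_id = sprintf("r%04d", seq_len(n)),
    true_cf_hz = sample(f[ok], n, replace = TRUE),
    true_thr_db = pmin(thr, thr_max_db),
    true_bw10_oct = if (is.null(bw10_oct))
      pmin(pmax(rnorm(n, preset$bw10_mean_oct, preset$bw10_sd_oct), 0.3), 5.5)
    else rep(bw10_oct, n),
    true_latency_ms = if (is.null(latency_ms))
      pmin(pmax(rnorm(n, preset$latency_mean_ms, preset$latency_sd_ms), 6), 40)
    else rep(latency_ms, n),
    true_shape = if (is.null(shape))
      sample(c("single_v", "multi", "flat"), n, replace = TRUE,
             prob = c(preset$p_single, preset$p_multi, preset$p_flat))
    else rep(shape, n),
    is_ai = TRUE,
    is_responsive = TRUE)
}

# frequency-dependent threshold curve of a single v-shaped peak:
# thr(f) = thr + (20 / bw10) * |log2(f / cf)|, so the supra-threshold span
# measured 10 dB above the minimum is exactly bw10 octaves.
v_threshold_curve <- function(f_hz, cf_hz, thr_db, bw10_oct) {
  thr_db + (20 / bw10_oct) * abs(log2(f_hz / cf_hz))
}

# per-peak bandwidth and layout of multi-peaked truths: two narrow v-shapes
# 3 octaves apart, secondary apex 10 dB above the primary
multi_peak_params <- function(truth, protocol) {
  fmin <- min(protocol$frequencies_hz)
  fmax <- max(protocol$frequencies_hz)
  bwp <- min(truth$true_bw10_oct, 1.5)
  sep <- 3
  cf2 <- if (log2(fmax / truth$true_cf_hz) >= sep)
    truth$true_cf_hz * 2^sep else truth$true_cf_hz / 2^sep
  cf2 <- min(max(cf2, fmin), fmax)
  thr2 <- min(truth$true_thr_db + 10, max(protocol$intensities_db))
  list(bwp = bwp, cf2 = cf2, thr2 = thr2)
}

#' Noise-free expected firing-rate surface of a synthetic site
#'
#' The generative inverse of the FRA: the mean multiunit firing rate (Hz) the
#' simulator targets for every tone frequency x intensity cell, together with
#' the temporal profile of the evoked response. For a `single_v` site the
#' frequency-dependent threshold is
#' `thr(f) = thr + (20 / bw10) * |log2(f / cf)|`, so the supra-threshold
#' frequency span measured 10 dB above the tip equals the true BW10 exactly.
#' Above threshold the evoked rate is `onset + gain * (I - thr(f))`, capped at
#' `evoked_max_hz`. `multi` sites are the sum of two such peaks (3 octaves
#' apart, secondary apex 10 dB higher, per-peak bandwidth at most 1.5
#' octaves); `flat` sites have a constant threshold across a 1.5-octave span.
#' Evoked mass is confined to `[latency, latency + tone_ms + 10]` ms after
#' tone onset. Unresponsive sites yield an all-baseline surface.
#'
#' @param truth One row of a [sample_map()] truth table (or a named list).
#' @param protocol A [make_protocol()] object.
#' @param preset A [condition_preset()] supplying baseline rate, gain, onset
#'   step and cap.
#' @return An object of class `rate_surface`: list with `evoked_hz` (frequency
#'   x intensity matrix), `baseline_hz`, `latency_ms`, `evoked_dur_ms`.
#' @export
expected_rate_surface <- function(truth, protocol, preset) {
  validate_protocol(protocol)
  f <- protocol$frequencies_hz
  I <- protocol$intensities_db
  E <- matrix(0, length(f), length(I),
              dimnames = list(NULL, NULL))
  responsive <- isTRUE(truth$is_responsive)
  lat <- NA_real_
  if (responsive) {
    lat <- truth$true_latency_ms
    rate_above <- function(thrf) {
      # supra-threshold rate, 0 below; step onset + linear growth, saturating
      sapply(I, function(ii) {
        ifelse(ii >= thrf,
               pmin(preset$evoked_max_hz,
                    preset$evoked_onset_hz + preset$evoked_gain * (ii - thrf)),
               0)
      })
    }
    shape <- truth$true_shape
    if (shape == "single_v") {
      thrf <- v_threshold_curve(f, truth$true_cf_hz, truth$true_thr_db,
                                truth$true_bw10_oct)
      E <- rate_above(thrf)
    } else if (shape == "multi") {
      mp <- multi_peak_params(truth, protocol)
      thrf1 <- v_threshold_curve(f, truth$true_cf_hz, truth$true_thr_db, mp$bwp)
      thrf2 <- v_threshold_curve(f, mp$cf2, mp$thr2, mp$bwp)
      E <- pmin(rate_above(thrf1) + rate_above(thrf2), preset$evoked_max_hz)
    } else if (shape == "flat") {
      span <- 1.5
      thrf <- ifelse(abs(log2(f / truth$true_cf_hz)) <= span / 2,
                     truth$true_thr_db, Inf)
      E <- rate_above(thrf)
    } else stop("unknown shape class: ", shape, call. = FALSE)
  }
  structure(list(
    evoked_hz = E,
    baseline_hz = preset$baseline_rate_hz,
    latency_ms = lat,
    evoked_dur_ms = protocol$tone_ms + 10,
    frequencies_hz = f,
    intensities_db = I
  ), class = "rate_surface")
}

#' Simulate the spike-count table of one recording site
#'
#' Draws independent Poisson spike counts in every 1-bin x trial cell of the
#' recording window (`pre_ms` of pre-stimulus baseline through `post_ms`
#' after tone onset) around the expected rate surface of the site. Counts are
#' returned sparse (zero bins omitted) in long format with bin offsets
#' relative to tone onset (baseline bins have negative offsets).
#'
#' @inheritParams expected_rate_surface
#' @param seed Optional integer seed; identical seeds give identical tables.
#' @param pre_ms Pre-stimulus baseline recorded per presentation (ms, >= 50).
#' @param post_ms Post-onset window recorded per presentation (ms).
#' @return A tibble: `site_id`, `freq_hz`, `intensity_db`, `trial`,
#'   `bin_ms`, `count`.
#' @export
simulate_site <- function(truth, protocol, preset, seed = NULL,
                          pre_ms = 50, post_ms = 100) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  stopifnot(pre_ms >= 1, post_ms >= protocol$tone_ms)
  surf <- expected_rate_surface(truth, protocol, preset)
  f <- protocol$frequencies_hz
  ints <- protocol$intensities_db
  nf <- length(f); ni <- length(ints); nt <- protocol$n_trials
  bin <- protocol$bin_ms
  bins <- seq(-pre_ms, post_ms - bin, by = bin)
  nb <- length(bins)
  npres <- nf * ni * nt

  out <- list()
  # baseline: one pooled Poisson total scattered uniformly over
  # (presentation, bin) cells -- equivalent to independent per-bin draws
  lam_tot <- surf$baseline_hz * 1e-3 * bin * nb * npres
  if (lam_tot > 0) {
    N <- rpois(1, lam_tot)
    if (N > 0) {
      pres <- sample.int(npres, N, replace = TRUE)
      b <- sample.int(nb, N, replace = TRUE)
      fi <- (pres - 1) %% (nf * ni)
      out$base <- data.frame(
        fidx = fi %% nf + 1L,
        iidx = fi %/% nf + 1L,
        trial = (pres - 1) %/% (nf * ni) + 1L,
        bin_ms = bins[b],
        count = 1L)
    }
  }
  # evoked: per supra-threshold cell, per trial, per bin overlapping the
  # evoked window
  sup <- which(surf$evoked_hz > 0, arr.ind = TRUE)
  if (nrow(sup) > 0 && is.finite(surf$latency_ms)) {
    t0 <- surf$latency_ms
    t1 <- surf$latency_ms + surf$evoked_dur_ms
    prof <- pmax(0, pmin(bins + bin, t1) - pmax(bins, t0)) / bin
    bsel <- which(prof > 0)
    if (length(bsel) > 0) {
      rates <- surf$evoked_hz[sup]            # Hz per supra cell
      lam <- outer(rates, prof[bsel]) * 1e-3 * bin  # K x B expected counts
      K <- nrow(sup); B <- length(bsel)
      counts <- rpois(K * B * nt, rep(as.vector(lam), nt))
      nz <- which(counts > 0)
      if (length(nz) > 0) {
        cell <- (nz - 1) %% (K * B)
        out$evoked <- data.frame(
          fidx = sup[cell %% K + 1L, 1L],
          iidx = sup[cell %% K + 1L, 2L],
          trial = (nz - 1) %/% (K * B) + 1L,
          bin_ms = bins[bsel][cell %/% K + 1L],
          count = counts[nz])
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(site_id = character(), freq_hz = numeric(),
                          intensity_db = numeric(), trial = integer(),
                          bin_ms = numeric(), count = integer()))
  }
  d <- do.call(rbind, out)
  # aggregate duplicates (baseline + evoked spikes in the same cell)
  key <- ((d$fidx - 1) * ni + (d$iidx - 1)) * nt + (d$trial - 1)
  key <- key * (pre_ms + post_ms + 1) + (d$bin_ms + pre_ms)
  agg <- rowsum(d$count, key)
  first <- !duplicated(key)
  d <- d[first, ]
  d$count <- as.integer(agg[match(as.character(key[first]), rownames(agg))])
  ord <- order(d$fidx, d$iidx, d$trial, d$bin_ms)
  d <- d[ord, ]
  tibble::tibble(
    site_id = if (!is.null(truth$site_id)) truth$site_id else "s001",
    freq_hz = f[d$fidx],
    intensity_db = ints[d$iidx],
    trial = as.integer(d$trial),
    bin_ms = d$bin_ms,
    count = d$count)
}

#' Generate a ground-truthed synthetic cohort
#'
#' Simulates `n_control` control and `n_vpa` VPA-like animals (two 8 x 8
#' penetrations each, 128 sites per animal) under the given stimulus protocol
#' and condition presets. Per-animal and per-site seeds are derived
#' deterministically from the master seed, so identical calls produce
#' identical datasets.
#'
#' @param n_control,n_vpa Animals per group (either may be 0).
#' @param seed Master integer seed (required).
#' @param protocol A [make_protocol()] object.
#' @param presets Named list with elements `control` and `vpa`
#'   ([condition_preset()] objects).
#' @param geometry A [map_geometry()] tibble used for every animal.
#' @param dir Optional output directory; when given the dataset is written
#'   with [write_dataset()].
#' @param overwrite Refuse to write into an existing directory unless TRUE.
#' @return A `map_dataset` list: `protocol`, `sites`, `spikes`, `truth`
#'   (invisibly when `dir` is given).
#' @export
generate_cohort <- function(n_control = 6, n_vpa = 8, seed,
                            protocol = make_protocol(),
                            presets = list(control = condition_preset("control"),
                                           vpa = condition_preset("vpa")),
                            geometry = map_geometry(),
                            dir = NULL, overwrite = FALSE) {
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  if (n_control < 0 || n_vpa < 0 || n_control + n_vpa < 1)
    stop("need at least one animal", call. = FALSE)
  groups <- c(rep("control", n_control), rep("vpa", n_vpa))
  ids <- c(sprintf("C%02d", seq_len(n_control)),
           sprintf("V%02d", seq_len(n_vpa)))
  sites_l <- truth_l <- spikes_l <- vector("list", length(ids))
  for (a in seq_along(ids)) {
    preset <- presets[[groups[a]]]
    if (is.null(preset)) stop("presets must contain '", groups[a], "'",
                              call. = FALSE)
    truth <- sample_map(protocol, preset, geometry,
                        seed = child_seed(seed, a, 0L))
    truth$site_id <- paste0(ids[a], "_", truth$site_id)
    truth$animal_id <- ids[a]
    truth$group <- groups[a]
    sp <- vector("list", nrow(truth))
    for (s in seq_len(nrow(truth))) {
      sp[[s]] <- simulate_site(truth[s, ], protocol, preset,
                               seed = child_seed(seed, a, s))
    }
    spikes_l[[a]] <- dplyr::bind_rows(sp)
    sites_l[[a]] <- truth[, c("site_id", "animal_id", "group",
                              "penetration_id", "grid_row", "grid_col",
                              "x_um", "y_um")]
    truth_l[[a]] <- truth[, c("site_id", "animal_id", "group",
                              "true_cf_hz", "true_thr_db", "true_bw10_oct",
                              "true_latency_ms", "true_shape",
                              "is_ai", "is_responsive")]
  }
  ds <- structure(list(
    protocol = protocol,
    sites = dplyr::bind_rows(sites_l),
    spikes = dplyr::bind_rows(spikes_l),
    truth = dplyr::bind_rows(truth_l)
  ), class = "map_dataset")
  if (!is.null(dir)) {
    write_dataset(ds, dir, overwrite = overwrite)
    return(invisible(ds))
  }
  ds
}

#' @export
print.map_dataset <- function(x, ...) {
  cat(sprintf("<map_dataset> %d sites, %d animals, %d spike rows\n",
              nrow(x$sites), length(unique(x$sites$animal_id)),
              nrow(x$spikes)))
  invisible(x)
}
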