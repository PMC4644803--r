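#' Reconstruct the frequency-intensity response area (FRA) of one site
#'
#' Converts the long-format spike-count table of a single recording site into
#' a frequency x intensity matrix of baseline-corrected mean evoked counts,
#' together with a per-cell significance mask. A cell is significant when the
#' total spike count in the response window (across trials) exceeds the
#' pooled pre-stimulus baseline expectation with an upper Poisson tail
#' probability below `alpha`, and the cell belongs to a 4-connected cluster
#' of at least `min_cluster` such cells.
#'
#' @param spikes Long spike table of one site: columns `freq_hz`,
#'   `intensity_db`, `trial`, `bin_ms` (offset from tone onset; baseline bins
#'   negative), `count`.
#' @param protocol A [make_protocol()] object.
#' @param opts An [analysis_options()] object.
#' @return Object of class `fra`: list with `evoked` (spikes/presentation,
#'   floored at 0), `sig_mask`, `baseline_mean` and `baseline_sd` (spikes per
#'   bin per presentation), `resp_total` (raw response-window counts) and the
#'   grid vectors.
#' @export
build_fra <- function(spikes, protocol, opts = analysis_options()) {
  validate_protocol(protocol)
  f <- protocol$frequencies_hz
  ints <- protocol$intensities_db
  nf <- length(f); ni <- length(ints); nt <- protocol$n_trials
  bin <- protocol$bin_ms
  n_resp_bins <- (opts$resp_win_ms[2] - opts$resp_win_ms[1]) / bin
  n_base_bins <- opts$base_win_ms / bin
  npres <- nf * ni * nt

  fi <- match_grid(spikes$freq_hz, f, "freq_hz")
  ii <- match_grid(spikes$intensity_db, ints, "intensity_db")

  in_base <- spikes$bin_ms >= -opts$base_win_ms & spikes$bin_ms < 0
  in_resp <- spikes$bin_ms >= opts$resp_win_ms[1] &
    spikes$bin_ms < opts$resp_win_ms[2]

  base_total <- sum(spikes$count[in_base])
  n_base_cells <- npres * n_base_bins
  baseline_mean <- base_total / n_base_cells
  # SD over all (presentation, bin) baseline cells; zeros included
  ssq <- sum(spikes$count[in_base]^2)
  baseline_sd <- if (n_base_cells > 1)
    sqrt(max(0, (ssq - base_total^2 / n_base_cells) / (n_base_cells - 1)))
  else 0

  resp_total <- matrix(0, nf, ni)
  if (any(in_resp)) {
    idx <- (ii[in_resp] - 1L) * nf + fi[in_resp]
    tab <- rowsum(spikes$count[in_resp], idx)
    resp_total[as.integer(rownames(tab))] <- tab[, 1]
  }
  expected <- baseline_mean * n_resp_bins * nt
  evoked <- pmax(0, resp_total / nt - baseline_mean * n_resp_bins)

  pval <- ppois(resp_total - 1, expected, lower.tail = FALSE)
  cand <- pval < opts$alpha & resp_total > expected
  sig_mask <- filter_clusters(cand, opts$min_cluster)

  structure(list(
    evoked = evoked,
    sig_mask = sig_mask,
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    resp_total = resp_total,
    n_resp_bins = n_resp_bins,
    frequencies_hz = f,
    intensities_db = ints,
    n_trials = nt
  ), class = "fra")
}

match_grid <- function(x, grid, nm) {
  i <- match(x, grid)
  if (anyNA(i)) {
    # tolerate floating-point round-trip error from CSV storage
    for (k in which(is.na(i))) {
      j <- which.min(abs(grid - x[k]))
      if (abs(grid[j] - x[k]) > 1e-6 * max(1, abs(grid[j])))
        stop(nm, " value ", x[k], " is not on the protocol grid",
             call. = FALSE)
      i[k] <- j
    }
  }
  i
}

# keep only cells in 4-connected components of size >= min_size
filter_clusters <- function(mask, min_size) {
  if (min_size <= 1 || !any(mask)) return(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  mask & matrix(lab %in% keep, nrow(mask), ncol(mask))
}

# 4-connected component labelling on a logical matrix
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  current <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    current <- current + 1L
    queue <- start
    lab[start] <- current
    while (length(queue)) {
      cell <- queue[[1]]
      queue <- queue[-1]
      r <- (cell - 1L) %% nr + 1L
      cc <- (cell - 1L) %/% nr + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        r2 <- r + d[1]; c2 <- cc + d[2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
          cell2 <- (c2 - 1L) * nr + r2
          if (mask[cell2] && lab[cell2] == 0L) {
            lab[cell2] <- current
            queue <- c(queue, cell2)
          }
        }
      }
    }
  }
  lab
}

#' @export
print.fra <- function(x, ...) {
  cat(sprintf("<fra> %d x %d grid, %d significant cells, baseline %.4g spikes/bin\n",
              length(x$frequencies_hz), length(x$intensities_db),
              sum(x$sig_mask), x$baseline_mean))
  invisible(x)
}

#' Characteristic frequency and intensity threshold from an FRA
#'
#' The threshold is the lowest tested intensity containing any significant
#' cell; the CF is the "tip" of the tuning curve: the significant frequency
#' at that intensity. When several frequencies are significant at threshold
#' (a flat tip) the median frequency is taken (lower median for even counts);
#' when the threshold row splits into several disjoint frequency runs
#' (multiple apexes tied at the lowest threshold) the lower-frequency run is
#' used.
#'
#' @param fra A [build_fra()] object.
#' @return List with `cf_hz` and `threshold_db` (both `NA` for an empty
#'   significance mask).
#' @export
extract_cf_threshold <- function(fra) {
  stopifnot(inherits(fra, "fra"))
  m <- fra$sig_mask
  if (!any(m)) return(list(cf_hz = NA_real_, threshold_db = NA_real_))
  icol <- which(colSums(m) > 0)[1]
  rows <- which(m[, icol])
  runs <- split(rows, cumsum(c(1L, diff(rows) != 1L)))
  run <- runs[[1]]                     # ties broken toward lower frequency
  cf_idx <- run[floor((length(run) + 1) / 2)]  # lower median
  list(cf_hz = fra$frequencies_hz[cf_idx],
       threshold_db = fra$intensities_db[icol])
}

#' Bandwidth 10 dB above threshold (BW10)
#'
#' The frequency span, in octaves, of significant cells in the FRA row 10 dB
#' above the intensity threshold: `log2(f_max / f_min)` over that row's
#' significant cells, 0 when exactly one cell is significant, and `NA` when
#' threshold + 10 dB was not tested or the row has no significant cells.
#'
#' @param fra A [build_fra()] object.
#' @param threshold_db The site's intensity threshold (dB SPL).
#' @return BW10 in octaves, or `NA`.
#' @export
compute_bw10 <- function(fra, threshold_db) {
  stopifnot(inherits(fra, "fra"))
  if (is.na(threshold_db)) return(NA_real_)
  icol <- which(abs(fra$intensities_db - (threshold_db + 10)) < 1e-6)
  if (length(icol) != 1) return(NA_real_)
  rows <- which(fra$sig_mask[, icol])
  if (length(rows) == 0) return(NA_real_)
  if (length(rows) == 1) return(0)
  log2(fra$frequencies_hz[max(rows)] / fra$frequencies_hz[min(rows)])
}

#' Receptive-field irregularity index
#'
#' A compactness statistic of the binarized receptive field built from its
#' central and one-step autocorrelation terms. With `M` the 0/1 significance
#' mask, `c00 = sum(M^2)` is the central term and
#' `c10 = sum(M[i, j] * M[i + 1, j])`, `c01 = sum(M[i, j] * M[i, j + 1])` the
#' one-step terms along the two grid axes; the index is
#' `(c00 - (c10 + c01) / 2) / sqrt(c00) - 3`. Compact (v-shaped) fields give
#' low values; fragmented fields give high values, with values above 2
#' conventionally counted as irregular.
#'
#' @param x A [build_fra()] object or a logical/0-1 matrix.
#' @return List with class `irregularity`: terms `c00`, `c10`, `c01` and
#'   `index` (`NA` for an empty mask).
#' @examples
#' irregularity_index(matrix(c(TRUE, FALSE, FALSE, TRUE), 2))$index # 2/sqrt(2) - 3
#' @export
irregularity_index <- function(x) {
  m <- if (inherits(x, "fra")) x$sig_mask else x
  if (is.logical(m)) m <- m * 1
  stopifnot(is.matrix(m))
  c00 <- sum(m^2)
  if (c00 == 0)
    return(structure(list(c00 = 0, c10 = 0, c01 = 0, index = NA_real_),
                     class = "irregularity"))
  nr <- nrow(m); nc <- ncol(m)
  c10 <- if (nr > 1) sum(m[-nr, , drop = FALSE] * m[-1, , drop = FALSE]) else 0
  c01 <- if (nc > 1) sum(m[, -nc, drop = FALSE] * m[, -1, drop = FALSE]) else 0
  structure(list(c00 = c00, c10 = c10, c01 = c01,
                 index = (c00 - (c10 + c01) / 2) / sqrt(c00) - 3),
            class = "irregularity")
}

#' @export
print.irregularity <- function(x, ...) {
  cat(sprintf("<irregularity> c00 %g, c10 %g, c01 %g, index %.4g\n",
              x$c00, x$c10, x$c01, x$index))
  invisible(x)
}

#' Onset latency of the pooled multiunit response
#'
#' Pools all presentations at or above the site's intensity threshold into a
#' mean PSTH (spikes/bin per presentation) and returns the time from tone
#' onset to the start of the first run of `latency_consec` consecutive bins
#' whose rate reaches the mean pre-stimulus level plus 4 standard deviations
#' (both computed from the pooled PSTH's baseline bins), searched within
#' `latency_search_ms`. Undefined (`NA`) when no crossing occurs or the site
#' has no threshold.
#'
#' @inheritParams build_fra
#' @param threshold_db The site's intensity threshold.
#' @return Latency in ms, or `NA`.
#' @export
estimate_latency <- function(spikes, protocol, threshold_db,
                             opts = analysis_options()) {
  if (is.na(threshold_db)) return(NA_real_)
  bin <- protocol$bin_ms
  sel_int <- protocol$intensities_db[protocol$intensities_db >= threshold_db - 1e-9]
  n_sel <- length(protocol$frequencies_hz) * length(sel_int) * protocol$n_trials
  if (n_sel == 0) return(NA_real_)
  keep <- spikes$intensity_db >= threshold_db - 1e-9
  bins <- seq(-opts$base_win_ms, opts$latency_search_ms[2] + 10, by = bin)
  psth <- setNames(numeric(length(bins)), bins)
  if (any(keep)) {
    tab <- rowsum(spikes$count[keep], spikes$bin_ms[keep])
    hit <- match(as.numeric(rownames(tab)), bins)
    ok <- !is.na(hit)
    psth[hit[ok]] <- tab[ok, 1] / n_sel
  }
  base <- psth[bins < 0 & bins >= -opts$base_win_ms]
  crit <- mean(base) + 4 * sd(base)
  search <- which(bins >= opts$latency_search_ms[1] &
                    bins < opts$latency_search_ms[2])
  qual <- psth[search] >= crit & psth[search] > 0
  k <- opts$latency_consec
  if (length(qual) < k) return(NA_real_)
  run_ok <- vapply(seq_len(length(qual) - k + 1),
                   function(i) all(qual[i:(i + k - 1)]), logical(1))
  hit <- which(run_ok)
  if (length(hit) == 0) return(NA_real_)
  bins[search[hit[1]]]
}

#' Tuning-curve shape class
#'
#' Classifies a site's tuning curve as `single_v`, `multi` (more than one
#' apex) or `flat` (no apex, or a minimal-threshold plateau wider than
#' `flat_plateau_oct` octaves). The per-frequency threshold curve (lowest
#' significant intensity per frequency column) is median-filtered with a
#' 3-column window; apexes are its local minima with prominence of at least
#' `apex_prominence_db`, merged when closer than `apex_min_sep_oct` octaves.
#'
#' @inheritParams compute_bw10
#' @param opts An [analysis_options()] object.
#' @return `"single_v"`, `"multi"`, `"flat"`, or `NA` for an empty mask.
#' @export
classify_shape <- function(fra, opts = analysis_options()) {
  stopifnot(inherits(fra, "fra"))
  m <- fra$sig_mask
  if (!any(m)) return(NA_character_)
  defined <- which(rowSums(m) > 0)
  thr_f <- vapply(defined,
                  function(r) fra$intensities_db[which(m[r, ])[1]],
                  numeric(1))
  oct <- log2(fra$frequencies_hz[defined] / fra$frequencies_hz[1])
  s <- if (length(thr_f) >= 3) as.numeric(runmed(thr_f, 3)) else thr_f
  apexes <- find_apexes(s, oct, opts$apex_prominence_db, opts$apex_min_sep_oct)
  if (length(apexes) > 1) return("multi")
  if (length(apexes) == 0) return("flat")
  # plateau width is judged on the raw threshold curve: median filtering
  # widens a sharp single-column tip into its 10-dB neighborhood
  plateau <- which(thr_f == min(thr_f))
  runs <- split(plateau, cumsum(c(1L, diff(plateau) != 1L)))
  span <- max(vapply(runs, function(r) max(oct[r]) - min(oct[r]), numeric(1)))
  if (span > opts$flat_plateau_oct) "flat" else "single_v"
}

# local minima of s (threshold curve) with prominence >= prom, merged when
# closer than min_sep octaves (keeping the deeper apex)
find_apexes <- function(s, oct, prom, min_sep) {
  n <- length(s)
  if (n == 0) return(integer(0))
  if (n == 1) return(integer(0))  # a single column carries no apex evidence
  # plateau-aware local minima: centers of runs lower than both flanks
  cand <- integer(0)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && s[j + 1] == s[i]) j <- j + 1
    left_ok <- i == 1 || s[i - 1] > s[i]
    right_ok <- j == n || s[j + 1] > s[i]
    if (left_ok && right_ok) cand <- c(cand, (i + j) %/% 2L)
    i <- j + 1
  }
  if (length(cand) == 0) return(integer(0))
  prominence <- vapply(cand, function(k) {
    # rise on each flank up to the first strictly lower point; a flank that
    # reaches the grid edge without any lower point does not bound the
    # prominence (edge-truncated apexes stay detectable)
    flank_rise <- function(idx_seq) {
      rise <- 0
      for (t in idx_seq) {
        if (s[t] < s[k]) return(rise)
        rise <- max(rise, s[t] - s[k])
      }
      Inf
    }
    min(flank_rise(rev(seq_len(k - 1))),
        flank_rise(seq(k + 1, length.out = n - k)))
  }, numeric(1))
  keep <- cand[prominence >= prom]
  if (length(keep) <= 1) return(keep)
  # merge apexes closer than min_sep, retaining the lower-threshold one
  keep <- keep[order(s[keep], oct[keep])]
  out <- integer(0)
  for (k in keep) {
    if (all(abs(oct[k] - oct[out]) >= min_sep) || length(out) == 0)
      out <- c(out, k)
  }
  sort(out)
}

#' Full receptive-field analysis of one recording site
#'
#' Runs [build_fra()], [extract_cf_threshold()], [compute_bw10()],
#' [estimate_latency()], [irregularity_index()] and [classify_shape()] and
#' collects the results in a one-row tibble. All undefined metrics are `NA`.
#'
#' @inheritParams build_fra
#' @return A one-row tibble: `site_id`, `responsive`, `n_sig`, `cf_hz`,
#'   `threshold_db`, `bw10_oct`, `latency_ms`, `irregularity`, `shape`,
#'   `resp_above_30db` (TRUE when any significant cell lies at or above the
#'   VAF exclusion level).
#' @param site_id Optional site label for the output row (taken from the
#'   spike table when omitted).
#' @export
analyze_site <- function(spikes, protocol, opts = analysis_options(),
                         site_id = NULL) {
  fra <- build_fra(spikes, protocol, opts)
  ct <- extract_cf_threshold(fra)
  responsive <- !is.na(ct$cf_hz)
  bw10 <- if (responsive) compute_bw10(fra, ct$threshold_db) else NA_real_
  lat <- if (responsive)
    estimate_latency(spikes, protocol, ct$threshold_db, opts) else NA_real_
  irr <- if (responsive) irregularity_index(fra)$index else NA_real_
  shape <- if (responsive) classify_shape(fra, opts) else NA_character_
  above <- fra$intensities_db >= opts$vaf_level_db
  if (is.null(site_id))
    site_id <- if (nrow(spikes) > 0) spikes$site_id[1] else NA_character_
  tibble::tibble(
    site_id = site_id,
    responsive = responsive,
    n_sig = sum(fra$sig_mask),
    cf_hz = ct$cf_hz,
    threshold_db = ct$threshold_db,
    bw10_oct = bw10,
    latency_ms = lat,
    irregularity = irr,
    shape = shape,
    resp_above_30db = any(fra$sig_mask[, above, drop = FALSE])
  )
}
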