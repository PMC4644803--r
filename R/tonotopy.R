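#' Normalize a characteristic frequency to the 0-1 tonotopic scale
#'
#' Converts the logarithmic 1--63 kHz CF range to a linear 0--1 range:
#' `clip(log2(cf_hz / 1000) / log2(63), 0, 1)`. CFs above 63 kHz are clipped
#' to 1 rather than discarded so that every AI site contributes to the
#' tonotopic index.
#'
#' @param cf_hz Characteristic frequencies (Hz, positive).
#' @return Values in `[0, 1]` (`NA` propagated).
#' @examples
#' normalize_cf(c(1000, 8000, 63000)) # 0, 0.502, 1
#' @export
normalize_cf <- function(cf_hz) {
  if (any(cf_hz <= 0, na.rm = TRUE))
    stop("cf_hz must be positive", call. = FALSE)
  pmin(pmax(log2(cf_hz / 1000) / log2(63), 0), 1)
}

#' Normalized rostro-caudal position along the tonotopic axis
#'
#' Fits a line to the site coordinates by least squares, rotates the map so
#' the fitted line is horizontal, collapses the coordinates onto it, and
#' min-max normalizes to `[0, 1]`. Because synthetic maps carry no anatomical
#' rostral reference, the axis is flipped, when `cf_norm` is supplied, so
#' that position correlates non-negatively with normalized CF.
#'
#' With `axis_fit = "ols"` the line is an ordinary regression of y on x,
#' with axes swapped when the fitted slope would exceed 1 in magnitude
#' (near-vertical maps); `"tls"` uses the principal axis instead.
#'
#' @param x_um,y_um Site coordinates (um); at least 3 non-coincident sites.
#' @param cf_norm Optional normalized CFs used only for the orientation flip.
#' @param opts An [analysis_options()] object (`axis_fit`).
#' @return Normalized positions in `[0, 1]`, or `NULL` when the axis is
#'   undefined (fewer than 3 sites or zero spatial extent).
#' @export
normalized_axis <- function(x_um, y_um, cf_norm = NULL,
                            opts = analysis_options()) {
  ok <- is.finite(x_um) & is.finite(y_um)
  if (sum(ok) < 3) return(NULL)
  x <- x_um[ok]; y <- y_um[ok]
  if (max(x) == min(x) && max(y) == min(y)) return(NULL)
  if (opts$axis_fit == "tls") {
    v <- prcomp(cbind(x, y))$rotation[, 1]
  } else {
    v <- if (max(x) == min(x)) {
      c(0, 1)
    } else {
      b <- coef(lm(y ~ x))[2]
      if (!is.finite(b)) b <- 0
      if (abs(b) <= 1) c(1, b) else c(coef(lm(x ~ y))[2], 1)
    }
  }
  v <- v / sqrt(sum(v^2))
  pos <- x * v[1] + y * v[2]
  rng <- range(pos)
  if (diff(rng) == 0) return(NULL)
  pos <- (pos - rng[1]) / diff(rng)
  out <- rep(NA_real_, length(x_um))
  out[ok] <- pos
  if (!is.null(cf_norm)) {
    r <- suppressWarnings(cor(out, cf_norm, use = "complete.obs"))
    if (is.finite(r) && r < 0) out <- 1 - out
  }
  out
}

#' Tonotopic index of a cortical map
#'
#' The mean minimum (perpendicular) distance of the points (normalized
#' position, normalized CF) to the identity diagonal from (0, 0) to (1, 1):
#' `mean(|pos - cf|) / sqrt(2)`. A perfectly ordered tonotopic gradient gives
#' 0; larger values mean a more disorganized map.
#'
#' @param pos_norm,cf_norm Equal-length vectors in `[0, 1]`.
#' @return The tonotopic index (`NA` for empty input after NA removal).
#' @examples
#' tonotopic_index(c(0, 0.5, 1), c(0.1, 0.6, 0.9)) # 0.0707
#' @export
tonotopic_index <- function(pos_norm, cf_norm) {
  stopifnot(length(pos_norm) == length(cf_norm))
  ok <- is.finite(pos_norm) & is.finite(cf_norm)
  if (!any(ok)) return(NA_real_)
  mean(abs(pos_norm[ok] - cf_norm[ok])) / sqrt(2)
}

#' Delineate the primary auditory cortex (AI) on a site-metrics table
#'
#' Applies the functional AI criteria to per-site metrics: a site belongs to
#' AI iff it (1) is responsive with a defined CF, (2) has an intensity
#' threshold at or below `ai_thr_db` (strong responses to low-intensity
#' tones) or is 4-neighbor-adjacent on the electrode grid to at least
#' `ai_min_neighbors` directly qualifying sites, and (3) is not VAF-like,
#' i.e. does not respond exclusively below `vaf_level_db`. Unresponsive and
#' high-intensity-only sites are thereby excluded, as are the patchy
#' low-level-only response profiles of the ventral field.
#'
#' @param metrics Site-metrics tibble for one animal, with columns
#'   `responsive`, `cf_hz`, `threshold_db`, `resp_above_30db`,
#'   `penetration_id`, `x_um`, `y_um`.
#' @param opts An [analysis_options()] object.
#' @return Logical AI-membership vector, one element per row of `metrics`.
#' @export
delineate_ai <- function(metrics, opts = analysis_options()) {
  n <- nrow(metrics)
  if (n == 0) return(logical(0))
  has_cf <- metrics$responsive & !is.na(metrics$cf_hz)
  vaf_like <- has_cf & !metrics$resp_above_30db
  low_thr <- !is.na(metrics$threshold_db) &
    metrics$threshold_db <= opts$ai_thr_db
  qualifying <- has_cf & !vaf_like & low_thr
  # rescue high-threshold sites embedded among qualifying neighbors
  g <- grid_positions(metrics)
  rescue <- has_cf & !vaf_like & !qualifying
  if (any(rescue)) {
    for (i in which(rescue)) {
      nb <- g$penetration == g$penetration[i] &
        (abs(g$col - g$col[i]) + abs(g$row - g$row[i])) == 1L
      if (sum(qualifying & nb) < opts$ai_min_neighbors) rescue[i] <- FALSE
    }
  }
  qualifying | rescue
}

# electrode-grid positions from coordinates (per penetration)
grid_positions <- function(metrics) {
  if (all(c("grid_row", "grid_col") %in% names(metrics)))
    return(list(penetration = metrics$penetration_id,
                row = metrics$grid_row, col = metrics$grid_col))
  pen <- metrics$penetration_id
  col <- integer(nrow(metrics)); row <- integer(nrow(metrics))
  for (p in unique(pen)) {
    s <- pen == p
    col[s] <- match(metrics$x_um[s], sort(unique(metrics$x_um[s])))
    row[s] <- match(metrics$y_um[s], sort(unique(metrics$y_um[s])))
  }
  list(penetration = pen, row = row, col = col)
}

#' Tonotopy of one animal's cortical map
#'
#' Delineates AI, computes normalized positions and CFs for the AI sites and
#' the map's tonotopic index.
#'
#' @inheritParams delineate_ai
#' @return List: `in_ai` (logical per site), `pos_norm`, `cf_norm` (per site,
#'   `NA` outside AI), `tonotopic_index`, `n_ai`.
#' @export
map_tonotopy <- function(metrics, opts = analysis_options()) {
  in_ai <- delineate_ai(metrics, opts)
  pos <- rep(NA_real_, nrow(metrics))
  cfn <- rep(NA_real_, nrow(metrics))
  ti <- NA_real_
  if (sum(in_ai) >= 3) {
    cfn[in_ai] <- normalize_cf(metrics$cf_hz[in_ai])
    p <- normalized_axis(metrics$x_um[in_ai], metrics$y_um[in_ai],
                         cf_norm = cfn[in_ai], opts = opts)
    if (!is.null(p)) {
      pos[in_ai] <- p
      ti <- tonotopic_index(pos[in_ai], cfn[in_ai])
    }
  }
  list(in_ai = in_ai, pos_norm = pos, cf_norm = cfn,
       tonotopic_index = ti, n_ai = sum(in_ai))
}
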