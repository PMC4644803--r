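#' Analysis options
#'
#' Collects every tunable of the receptive-field and map analyses in one
#' validated object. Unknown names are rejected, and the fully resolved
#' options are echoed into every results directory.
#'
#' @param resp_win_ms Response-counting window after tone onset (ms,
#'   length 2). The default 5--50 ms brackets the 6--20 ms AI onset latencies
#'   and the 25-ms tone.
#' @param base_win_ms Pre-stimulus baseline length (ms).
#' @param alpha Per-cell Poisson tail probability for calling an FRA cell
#'   significantly responsive.
#' @param min_cluster Minimum 4-connected cluster size of significant cells;
#'   isolated false positives among the 528 cells of a default FRA are
#'   suppressed by requiring clusters of at least 3.
#' @param latency_search_ms Window searched for the onset-latency crossing
#'   (ms after tone onset).
#' @param latency_consec Consecutive supra-criterion PSTH bins required for a
#'   latency crossing (set to 1 to accept single-bin crossings).
#' @param irregularity_cutoff Irregularity-index value above which a site is
#'   counted as irregular (non-v-shaped).
#' @param band_edges_khz Frequency band edges (kHz) used for the per-animal
#'   fraction-of-sites-per-band summary.
#' @param ai_thr_db AI criterion: sites with threshold at or below this level
#'   qualify directly; higher-threshold sites need at least
#'   `ai_min_neighbors` qualifying 4-neighbors.
#' @param ai_min_neighbors See `ai_thr_db`.
#' @param vaf_level_db Sites with significant responses only below this level
#'   (and none at or above it) are excluded as VAF-like.
#' @param apex_prominence_db,apex_min_sep_oct Shape-classifier apex rules:
#'   local minima of the (median-filtered) per-frequency threshold curve with
#'   at least this prominence, merged when closer than the separation.
#' @param flat_plateau_oct A single-apex site whose minimal-threshold plateau
#'   spans more than this many octaves is classed `flat`.
#' @param axis_fit `"ols"` (regress y on x, axes swapped for steep maps) or
#'   `"tls"` (principal axis) for the tonotopic-axis line fit.
#' @param pooled_percentages If TRUE, group percentages pool sites across
#'   animals instead of averaging per-animal percentages.
#' @return An object of class `analysis_options`.
#' @export
analysis_options <- function(resp_win_ms = c(5, 50), base_win_ms = 50,
                             alpha = 0.01, min_cluster = 3,
                             latency_search_ms = c(5, 50), latency_consec = 2,
                             irregularity_cutoff = 2,
                             band_edges_khz = c(1, 4.3, 10, 50, 70),
                             ai_thr_db = 50, ai_min_neighbors = 2,
                             vaf_level_db = 30,
                             apex_prominence_db = 10, apex_min_sep_oct = 0.3,
                             flat_plateau_oct = 1,
                             axis_fit = c("ols", "tls"),
                             pooled_percentages = FALSE) {
  axis_fit <- match.arg(axis_fit)
  o <- structure(as.list(environment()), class = "analysis_options")
  validate_options(o)
  o
}

validate_options <- function(o) {
  stopifnot(inherits(o, "analysis_options"))
  if (length(o$resp_win_ms) != 2 || diff(o$resp_win_ms) <= 0)
    stop("resp_win_ms must be an increasing length-2 window", call. = FALSE)
  if (o$base_win_ms <= 0) stop("base_win_ms must be > 0", call. = FALSE)
  if (o$alpha <= 0 || o$alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (o$min_cluster < 1) stop("min_cluster must be >= 1", call. = FALSE)
  if (length(o$latency_search_ms) != 2 || diff(o$latency_search_ms) <= 0)
    stop("latency_search_ms must be an increasing length-2 window", call. = FALSE)
  if (o$latency_consec < 1) stop("latency_consec must be >= 1", call. = FALSE)
  if (length(o$band_edges_khz) < 2 || any(diff(o$band_edges_khz) <= 0))
    stop("band_edges_khz must be strictly increasing", call. = FALSE)
  invisible(o)
}

# rebuild options from a plain (possibly JSON-parsed) list, rejecting
# unknown keys via the constructor signature
options_from_list <- function(x) {
  stopifnot(is.list(x))
  known <- names(formals(analysis_options))
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown analysis option(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(analysis_options, lapply(x, unlist))
}
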